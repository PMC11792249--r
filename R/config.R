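#' Simulation parameters for a synthetic twin cohort
#'
#' Collects every parameter of the synthetic cohort generator: the study
#' layout (twin pairs nested in ewes, three treatment arms), the SNP panel,
#' the phenotype model and the pharmacokinetic laws. Defaults reproduce the
#' design of the twin-lamb ANS study this package analyses: 11 CS1 pairs
#' (single maternal 0.25 mg/kg betamethasone dose), 10 CS2 pairs (two doses
#' 24 h apart) and 10 saline control pairs, i.e. 31 ewes / 62 fetuses.
#'
#' Treated fetuses draw a latent responder status from the logistic model
#' \deqn{logit P(responder) = \beta_0 + \beta_{sex} I(female) +
#'   \beta_{order} I(second) + \sum_k \beta_k d_k}
#' where \eqn{d_k} is the B-allele dosage (0/1/2) at the k-th planted SNP.
#' 30-minute PaCO2 is then drawn from the responder or non-responder Normal
#' law; controls draw from the control Normal law.
#'
#' @param pairs_per_arm named integer vector, twin pairs per arm
#'   (CS1, CS2, CONTROL). Default `c(11, 10, 10)`.
#' @param n_snps number of biallelic SNPs on the simulated array panel.
#' @param maf_law list with `min`, `max`: minor-allele frequencies are drawn
#'   uniformly on this interval (frequencies refer to the B allele).
#' @param mz_fraction probability that a pair is monozygotic. Default 0: the
#'   study cohort was all-dizygotic, and natural MZ twinning in sheep is rare.
#' @param genotype_error_rate per-call probability that one allele of the
#'   call is flipped (symmetric error). Default 0.
#' @param missing_rate per-call probability that the call is dropped.
#' @param gentrain_law,gc_law lists with `shape1`, `shape2`: Beta laws for
#'   the per-SNP GenTrain score and the per-call GC score.
#' @param control_paco2_mean,control_paco2_sd Normal law (mmHg) for
#'   steroid-naive control PaCO2 at 30 min of ventilation.
#' @param responder_paco2,nonresponder_paco2 named vectors `c(mean=, sd=)`
#'   (mmHg) for the PaCO2 law of latent responders / non-responders.
#' @param beta0 log-odds intercept of the response model.
#' @param beta_sex log-odds of response, female vs male.
#' @param beta_order log-odds of response, second- vs first-delivered.
#' @param planted_snps `NULL` or a data.frame with columns `snp_index`
#'   (1-based position in the panel) and `beta` (per-B-allele-copy log-odds).
#' @param pk_params pharmacokinetic laws, see [default_pk_params()].
#' @param sex_pattern optional character vector (one of "MM", "MF", "FF" per
#'   pair, recycled) forcing the twin sex combinations; by default each fetus
#'   is male or female independently with probability 1/2.
#' @param seed master seed; per-component streams are derived from it
#'   deterministically (see [derive_seed()]).
#'
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [simulate_cohort()], [analysis_config()]
#' @export
cohort_config <- function(pairs_per_arm = c(CS1 = 11L, CS2 = 10L, CONTROL = 10L),
                          n_snps = 5000L,
                          maf_law = list(min = 0.1, max = 0.5),
                          mz_fraction = 0,
                          genotype_error_rate = 0,
                          missing_rate = 0,
                          gentrain_law = list(shape1 = 20, shape2 = 4),
                          gc_law = list(shape1 = 25, shape2 = 3),
                          control_paco2_mean = 130.1,
                          control_paco2_sd = 24.6,
                          responder_paco2 = c(mean = 60, sd = 13),
                          nonresponder_paco2 = c(mean = 120, sd = 20),
                          beta0 = -1.35,
                          beta_sex = log(7.786),
                          beta_order = -log(0.258),
                          planted_snps = NULL,
                          pk_params = default_pk_params(),
                          sex_pattern = NULL,
                          seed = 1L) {
  cfg <- list(
    pairs_per_arm = setNames(as.integer(pairs_per_arm), c("CS1", "CS2", "CONTROL")),
    n_snps = as.integer(n_snps),
    maf_law = maf_law,
    mz_fraction = mz_fraction,
    genotype_error_rate = genotype_error_rate,
    missing_rate = missing_rate,
    gentrain_law = gentrain_law,
    gc_law = gc_law,
    control_paco2_mean = control_paco2_mean,
    control_paco2_sd = control_paco2_sd,
    responder_paco2 = responder_paco2,
    nonresponder_paco2 = nonresponder_paco2,
    beta0 = beta0,
    beta_sex = beta_sex,
    beta_order = beta_order,
    planted_snps = planted_snps,
    pk_params = pk_params,
    sex_pattern = sex_pattern,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop("invalid cohort config: '", field, "' must be a probability in [0, 1]",
           call. = FALSE)
  }
  if (length(cfg$pairs_per_arm) != 3 || any(is.na(cfg$pairs_per_arm)) ||
      any(cfg$pairs_per_arm < 1L))
    stop("invalid cohort config: 'pairs_per_arm' must give >= 1 pair for each of CS1, CS2, CONTROL",
         call. = FALSE)
  if (is.na(cfg$n_snps) || cfg$n_snps < 1L)
    stop("invalid cohort config: 'n_snps' must be >= 1", call. = FALSE)
  chk_prob(cfg$mz_fraction, "mz_fraction")
  chk_prob(cfg$genotype_error_rate, "genotype_error_rate")
  chk_prob(cfg$missing_rate, "missing_rate")
  if (!is.list(cfg$maf_law) || cfg$maf_law$min <= 0 || cfg$maf_law$max > 0.5 ||
      cfg$maf_law$min > cfg$maf_law$max)
    stop("invalid cohort config: 'maf_law' must satisfy 0 < min <= max <= 0.5",
         call. = FALSE)
  for (f in c("control_paco2_sd")) {
    if (cfg[[f]] <= 0)
      stop("invalid cohort config: '", f, "' must be > 0", call. = FALSE)
  }
  for (f in c("responder_paco2", "nonresponder_paco2")) {
    v <- cfg[[f]]
    if (!all(c("mean", "sd") %in% names(v)) || v[["sd"]] <= 0)
      stop("invalid cohort config: '", f, "' needs mean and sd > 0", call. = FALSE)
  }
  if (!is.null(cfg$planted_snps)) {
    ps <- cfg$planted_snps
    if (!is.data.frame(ps) || !all(c("snp_index", "beta") %in% names(ps)))
      stop("invalid cohort config: 'planted_snps' must be a data.frame with snp_index and beta",
           call. = FALSE)
    if (any(ps$snp_index < 1L) || any(ps$snp_index > cfg$n_snps))
      stop("invalid cohort config: 'planted_snps' snp_index out of range 1..n_snps",
           call. = FALSE)
  }
  if (!is.null(cfg$sex_pattern) &&
      !all(cfg$sex_pattern %in% c("MM", "MF", "FF")))
    stop("invalid cohort config: 'sex_pattern' entries must be MM, MF or FF",
         call. = FALSE)
  cfg
}

#' Default betamethasone pharmacokinetic laws
#'
#' Terminal (delivery-time) concentrations only; no time-course is modelled.
#' Maternal plasma is drawn per ewe from an arm-specific log-normal law; each
#' fetus gets plasma = maternal x fetal/maternal ratio and lung = plasma x
#' lung/plasma ratio, with the ratios drawn per fetus from narrow log-normal
#' laws so that twins (sharing one maternal value) differ only through their
#' ratios. Defaults are chosen so arm-level means and spreads sit near the
#' reported cohort values (maternal ~15 and ~8 ng/mL for one- and two-dose
#' arms, fetal/maternal ratio ~0.17-0.21, lung/plasma ratio ~13-17).
#' Control animals carry no drug.
#'
#' @return nested list of `c(meanlog=, sdlog=)` laws per arm.
#' @export
default_pk_params <- function() {
  list(
    maternal = list(CS1 = c(meanlog = 2.462, sdlog = 0.682),
                    CS2 = c(meanlog = 2.016, sdlog = 0.277)),
    fetal_ratio = list(CS1 = c(meanlog = log(0.169), sdlog = 0.10),
                       CS2 = c(meanlog = log(0.205), sdlog = 0.10)),
    lung_ratio = list(CS1 = c(meanlog = log(17.0), sdlog = 0.15),
                      CS2 = c(meanlog = log(12.9), sdlog = 0.15))
  )
}

#' Analysis thresholds and constants
#'
#' Every threshold of the analysis in one validated object: SNP-level
#' GenTrain and call-level GC quality minima (calls are kept only when the
#' score is strictly above the minimum), the two association-stage alpha
#' levels, the zygosity concordance threshold (strictly greater than
#' `zygosity_threshold` is called monozygotic), the responder-cutoff SD
#' multiplier, and the assay limits of detection.
#'
#' @param gentrain_min SNPs with GenTrain score <= this are dropped. Default 0.7.
#' @param gc_min calls with GC score <= this are dropped. Default 0.15.
#' @param stage1_alpha chi-square shortlist threshold (strict). Default 0.01.
#' @param stage2_alpha logistic-regression threshold (strict). Default 0.05.
#' @param zygosity_threshold concordance above which a pair is called MZ. Default 0.9.
#' @param sd_multiplier number of control SDs below the control mean defining
#'   the responder PaCO2 cutoff. Default 2.
#' @param lod_plasma,lod_tissue limits of detection for betamethasone in
#'   plasma (0.5 ng/mL) and lung tissue (1 ng/g-equivalent).
#' @param lod_substitute if `TRUE`, below-LOD values are replaced by LOD/2 in
#'   summaries instead of being excluded. Default `FALSE` (exclusion).
#'
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(gentrain_min = 0.7, gc_min = 0.15,
                            stage1_alpha = 0.01, stage2_alpha = 0.05,
                            zygosity_threshold = 0.9, sd_multiplier = 2,
                            lod_plasma = 0.5, lod_tissue = 1.0,
                            lod_substitute = FALSE) {
  cfg <- list(gentrain_min = gentrain_min, gc_min = gc_min,
              stage1_alpha = stage1_alpha, stage2_alpha = stage2_alpha,
              zygosity_threshold = zygosity_threshold,
              sd_multiplier = sd_multiplier,
              lod_plasma = lod_plasma, lod_tissue = lod_tissue,
              lod_substitute = isTRUE(lod_substitute))
  in01 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
  for (f in c("gentrain_min", "gc_min", "zygosity_threshold"))
    if (!in01(cfg[[f]]))
      stop("invalid analysis config: '", f, "' must be in [0, 1]", call. = FALSE)
  for (f in c("stage1_alpha", "stage2_alpha"))
    if (!in01(cfg[[f]]) || cfg[[f]] == 0 || cfg[[f]] == 1)
      stop("invalid analysis config: '", f, "' must be in (0, 1)", call. = FALSE)
  if (cfg$sd_multiplier <= 0)
    stop("invalid analysis config: 'sd_multiplier' must be > 0", call. = FALSE)
  if (cfg$lod_plasma <= 0 || cfg$lod_tissue <= 0)
    stop("invalid analysis config: limits of detection must be > 0", call. = FALSE)
  class(cfg) <- "analysis_config"
  cfg
}

#' Derive a per-component RNG seed from the master seed
#'
#' One master seed drives the whole simulation; each subsystem (pedigree
#' structure, genotypes, quality scores, phenotypes, pharmacokinetics) seeds
#' its own stream with `(master * 1009 + 97 * stream index) mod (2^31 - 1)`,
#' so a subsystem can be re-run in isolation and still match a full run.
#'
#' @param seed master integer seed.
#' @param stream one of "structure", "genotypes", "scores", "phenotypes", "pk".
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, stream = c("structure", "genotypes", "scores",
                                         "phenotypes", "pk")) {
  stream <- match.arg(stream)
  idx <- match(stream, c("structure", "genotypes", "scores", "phenotypes", "pk"))
  as.integer((as.numeric(seed) * 1009 + 97 * idx) %% 2147483647)
}

#' Read a run configuration from YAML
#'
#' Expects two top-level blocks, `cohort` and `analysis`, whose entries
#' override the defaults of [cohort_config()] and [analysis_config()].
#' `cohort$planted_snps` may be given as a list of `{snp_index, beta}` maps.
#'
#' @param path YAML file.
#' @return list with elements `cohort` and `analysis`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  co <- raw$cohort %||% list()
  if (!is.null(co$planted_snps) && !is.data.frame(co$planted_snps))
    co$planted_snps <- do.call(rbind, lapply(co$planted_snps, as.data.frame))
  if (!is.null(co$pairs_per_arm)) co$pairs_per_arm <- unlist(co$pairs_per_arm)
  list(cohort = do.call(cohort_config, co),
       analysis = do.call(analysis_config, raw$analysis %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
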
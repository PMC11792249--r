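#' Simulate genotypes for one twin pair
#'
#' Dizygotic pairs are drawn as full siblings: at each SNP the sire and dam
#' genotypes are drawn under Hardy-Weinberg equilibrium at the given B-allele
#' frequency, and each sib independently receives one transmitted allele from
#' each parent. Monozygotic pairs are a single full-sib draw duplicated.
#' SNPs are independent (no linkage disequilibrium is modelled). Genotyping
#' error and missingness are applied downstream by [simulate_cohort()], not
#' here.
#'
#' @param n_snps number of SNPs.
#' @param mafs vector of B-allele frequencies in (0, 0.5], length `n_snps`
#'   (a frequency of 0 is tolerated and yields a monomorphic AA locus).
#' @param zygosity "DZ" or "MZ".
#' @param seed optional integer seed (set only when supplied, so the function
#'   can also run inside an existing RNG stream).
#' @return list with integer B-dosage vectors `geno1`, `geno2` (values 0/1/2).
#' @export
simulate_pair_genotypes <- function(n_snps, mafs, zygosity = c("DZ", "MZ"),
                                    seed = NULL) {
  zygosity <- match.arg(zygosity)
  if (length(mafs) != n_snps)
    stop("'mafs' must have length n_snps", call. = FALSE)
  if (any(mafs < 0) || any(mafs > 0.5))
    stop("'mafs' must lie in [0, 0.5]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sire <- rbinom(n_snps, 2L, mafs)
  dam <- rbinom(n_snps, 2L, mafs)
  g1 <- rbinom(n_snps, 1L, sire / 2) + rbinom(n_snps, 1L, dam / 2)
  g2 <- if (zygosity == "MZ") g1 else
    rbinom(n_snps, 1L, sire / 2) + rbinom(n_snps, 1L, dam / 2)
  list(geno1 = as.integer(g1), geno2 = as.integer(g2))
}

#' Expected full-sib genotype concordance at a biallelic SNP
#'
#' Closed form for the probability that two dizygotic (full-sib) twins carry
#' the same unordered genotype at a SNP with allele frequency `maf`, obtained
#' by conditioning on the number of alleles shared identical by descent
#' (0/1/2 with probabilities 1/4, 1/2, 1/4):
#' \deqn{1/4 + (p^2+q^2)/2 + (p^4 + 4 p^2 q^2 + q^4)/4.}
#' Evaluates to 0.59375 at maf 0.5 and 0.83215 at maf 0.1. Monozygotic pairs
#' have concordance 1 by construction.
#'
#' @param maf B-allele frequency (vectorized).
#' @return expected concordance in (0.59, 1].
#' @export
dz_concordance_expected <- function(maf) {
  p <- maf; q <- 1 - maf
  0.25 + 0.5 * (p^2 + q^2) + 0.25 * (p^4 + 4 * p^2 * q^2 + q^4)
}

# arm / pair / fetus scaffold ------------------------------------------------

build_structure <- function(config) {
  n_pairs <- sum(config$pairs_per_arm)
  arm <- rep(names(config$pairs_per_arm), config$pairs_per_arm)
  ewe_id <- sprintf("EWE%03d", seq_len(n_pairs))
  set.seed(derive_seed(config$seed, "structure"))
  if (is.null(config$sex_pattern)) {
    sex <- matrix(sample(c("M", "F"), 2 * n_pairs, replace = TRUE), ncol = 2)
  } else {
    pat <- rep_len(config$sex_pattern, n_pairs)
    sex <- t(vapply(pat, function(p) switch(p, MM = c("M", "M"),
                                            FF = c("F", "F"), c("M", "F")),
                    character(2)))
  }
  zyg <- ifelse(runif(n_pairs) < config$mz_fraction, "MZ", "DZ")
  fetuses <- data.frame(
    fetus_id = sprintf("F%03d%s", rep(seq_len(n_pairs), each = 2), c("a", "b")),
    ewe_id = rep(ewe_id, each = 2),
    arm = rep(arm, each = 2),
    sex = as.vector(t(sex)),
    delivery_order = rep(c(1L, 2L), n_pairs),
    stringsAsFactors = FALSE
  )
  pairs <- data.frame(
    ewe_id = ewe_id,
    fetus_id1 = fetuses$fetus_id[seq(1, 2 * n_pairs, 2)],
    fetus_id2 = fetuses$fetus_id[seq(2, 2 * n_pairs, 2)],
    arm = arm,
    twin_type = ifelse(sex[, 1] == sex[, 2],
                       ifelse(sex[, 1] == "M", "MM", "FF"), "MF"),
    zygosity_true = zyg,
    stringsAsFactors = FALSE
  )
  list(fetuses = fetuses, pairs = pairs)
}

# genotype dosage matrix (fetus x SNP), then per-call error + missingness;
# runs inside the caller's "genotypes" RNG stream
simulate_dosages <- function(pairs, config, mafs) {
  n_pairs <- nrow(pairs)
  dos <- matrix(NA_integer_, nrow = 2 * n_pairs, ncol = config$n_snps)
  for (i in seq_len(n_pairs)) {
    g <- simulate_pair_genotypes(config$n_snps, mafs, pairs$zygosity_true[i])
    dos[2 * i - 1, ] <- g$geno1
    dos[2 * i, ] <- g$geno2
  }
  if (config$genotype_error_rate > 0) {
    flip <- matrix(runif(length(dos)) < config$genotype_error_rate, nrow = nrow(dos))
    up <- matrix(runif(length(dos)) < 0.5, nrow = nrow(dos))  # direction for hets
    d <- dos
    d[flip & dos == 0L] <- 1L
    d[flip & dos == 2L] <- 1L
    d[flip & dos == 1L & up] <- 2L
    d[flip & dos == 1L & !up] <- 0L
    dos <- d
  }
  if (config$missing_rate > 0) {
    dos[matrix(runif(length(dos)) < config$missing_rate, nrow = nrow(dos))] <- NA_integer_
  }
  dos
}

simulate_manifest <- function(config) {
  n <- config$n_snps
  chrom <- sample(c(as.character(1:26), "X"), n, replace = TRUE,
                  prob = c(rep(0.037, 26), 0.038))
  data.frame(
    snp_id = sprintf("SNP%06d", seq_len(n)),
    chromosome = chrom,
    position = sample.int(250000000L, n, replace = TRUE),
    gentrain = rbeta(n, config$gentrain_law$shape1, config$gentrain_law$shape2),
    gene = ifelse(runif(n) < 0.4, sprintf("GENE%04d", sample.int(9999L, n, replace = TRUE)), ""),
    consequence = sample(c("intron variant", "intergenic variant",
                           "3' UTR variant", "downstream gene variant"),
                         n, replace = TRUE, prob = c(0.45, 0.4, 0.05, 0.1)),
    stringsAsFactors = FALSE
  )
}

dosage_to_calls <- function(dos, sample_ids, snp_ids, gc) {
  n_s <- length(sample_ids); n_m <- length(snp_ids)
  d <- as.vector(t(dos))  # row-major: sample blocks
  data.frame(
    sample_id = rep(sample_ids, each = n_m),
    snp_id = rep(snp_ids, times = n_s),
    allele1 = ifelse(is.na(d), "-", ifelse(d >= 1L, "B", "A")),
    allele2 = ifelse(is.na(d), "-", ifelse(d == 2L, "B", "A")),
    gc_score = as.vector(t(gc)),
    stringsAsFactors = FALSE
  )
}

#' Simulate ventilation phenotypes and drug levels for a cohort skeleton
#'
#' Control fetuses draw 30-min PaCO2 from the control Normal law and carry no
#' drug. ANS-treated fetuses draw a latent responder status from the logistic
#' response model (intercept, sex, delivery order, planted SNP dosages) and
#' then PaCO2 from the responder or non-responder Normal law. Terminal
#' betamethasone concentrations follow the configured log-normal laws, with
#' twins sharing one maternal plasma value; censoring at the limits of
#' detection is applied by the caller (see [censor_lod()]) or by
#' [simulate_cohort()].
#'
#' @param skeleton data.frame with columns `fetus_id`, `ewe_id`, `arm`,
#'   `sex`, `delivery_order`.
#' @param config a [cohort_config()].
#' @param planted_dosage optional numeric matrix (fetus x planted SNP) of
#'   B-allele dosages, column order matching `config$planted_snps`.
#' @param seed optional seed; defaults to the config's derived phenotype stream.
#' @return list: `fetuses` (skeleton + `birthweight_kg`, `cord_ph`,
#'   `cord_paco2`, `paco2_30min`, `plasma_beta`, `lung_beta`,
#'   `responder_true`), `maternal` (per-ewe maternal plasma values).
#' @export
simulate_phenotypes <- function(skeleton, config, planted_dosage = NULL,
                                seed = derive_seed(config$seed, "phenotypes")) {
  n <- nrow(skeleton)
  set.seed(seed)
  treated <- skeleton$arm %in% c("CS1", "CS2")
  eta <- config$beta0 +
    config$beta_sex * (skeleton$sex == "F") +
    config$beta_order * (skeleton$delivery_order == 2L)
  if (!is.null(config$planted_snps) && !is.null(planted_dosage)) {
    d <- planted_dosage
    d[is.na(d)] <- 0
    eta <- eta + as.vector(d %*% config$planted_snps$beta)
  }
  resp <- runif(n) < plogis(eta)
  resp[!treated] <- NA
  mu <- ifelse(treated,
               ifelse(resp, config$responder_paco2[["mean"]],
                      config$nonresponder_paco2[["mean"]]),
               config$control_paco2_mean)
  sig <- ifelse(treated,
                ifelse(resp, config$responder_paco2[["sd"]],
                       config$nonresponder_paco2[["sd"]]),
                config$control_paco2_sd)
  paco2 <- pmax(rnorm(n, mu, sig), 5)
  out <- skeleton
  out$birthweight_kg <- round(pmax(rnorm(n, 2.85, 0.38), 0.8), 2)
  out$cord_ph <- round(rnorm(n, 7.27, 0.11), 2)
  out$cord_paco2 <- round(pmax(rnorm(n, 60.8, 14), 15), 1)
  out$paco2_30min <- round(paco2, 1)
  out$responder_true <- resp

  # terminal drug levels: maternal value shared within a pair
  set.seed(derive_seed(config$seed, "pk") + seed %% 97L)
  ewes <- unique(skeleton[, c("ewe_id", "arm")])
  pk <- config$pk_params
  mat <- numeric(nrow(ewes))
  for (a in c("CS1", "CS2")) {
    sel <- ewes$arm == a
    if (any(sel))
      mat[sel] <- rlnorm(sum(sel), pk$maternal[[a]][["meanlog"]],
                         pk$maternal[[a]][["sdlog"]])
  }
  mat[ewes$arm == "CONTROL"] <- 0
  m <- mat[match(skeleton$ewe_id, ewes$ewe_id)]
  fr <- lr <- numeric(n)
  for (a in c("CS1", "CS2")) {
    sel <- skeleton$arm == a
    if (any(sel)) {
      fr[sel] <- rlnorm(sum(sel), pk$fetal_ratio[[a]][["meanlog"]],
                        pk$fetal_ratio[[a]][["sdlog"]])
      lr[sel] <- rlnorm(sum(sel), pk$lung_ratio[[a]][["meanlog"]],
                        pk$lung_ratio[[a]][["sdlog"]])
    }
  }
  out$plasma_beta <- round(m * fr, 3)
  out$lung_beta <- round(m * fr * lr, 3)
  list(fetuses = out,
       maternal = data.frame(ewe_id = ewes$ewe_id, arm = ewes$arm,
                             maternal_beta = round(mat, 3),
                             stringsAsFactors = FALSE))
}

#' Simulate a complete synthetic twin cohort
#'
#' Generates the full input set of the pipeline: twin pairs nested in ewes
#' across three treatment arms, a biallelic SNP panel with full-sib Mendelian
#' sharing within dizygotic pairs, per-SNP GenTrain and per-call GC quality
#' scores, ventilation phenotypes from the logistic response model, and
#' LOD-censorable betamethasone concentrations. The same config and seed
#' always reproduce the same cohort.
#'
#' @param config a [cohort_config()].
#' @param analysis an [analysis_config()]; only the limits of detection are
#'   used, to censor the simulated drug levels.
#' @return object of class `twin_cohort`: list with `fetuses`, `pairs`,
#'   `calls` (long genotype call table), `manifest`, `truth` (planted
#'   parameters: true zygosities and responder states, MAFs, planted effects,
#'   uncensored drug levels, dosage matrix), and the echoed `config`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            analysis = analysis_config()) {
  config <- validate_cohort_config(config)
  st <- build_structure(config)
  set.seed(derive_seed(config$seed, "genotypes"))
  mafs <- runif(config$n_snps, config$maf_law$min, config$maf_law$max)
  dos <- simulate_dosages(st$pairs, config, mafs)
  set.seed(derive_seed(config$seed, "scores"))
  manifest <- simulate_manifest(config)
  gc <- matrix(rbeta(length(dos), config$gc_law$shape1, config$gc_law$shape2),
               nrow = nrow(dos))
  gc <- round(gc, 4)
  calls <- dosage_to_calls(dos, st$fetuses$fetus_id, manifest$snp_id, gc)

  planted_dos <- if (!is.null(config$planted_snps))
    dos[, config$planted_snps$snp_index, drop = FALSE] else NULL
  ph <- simulate_phenotypes(st$fetuses, config, planted_dos)
  fet <- ph$fetuses

  # censor drug levels at the assay limits of detection
  pl <- censor_lod(fet$plasma_beta, analysis$lod_plasma)
  lu <- censor_lod(fet$lung_beta, analysis$lod_tissue)
  truth_plasma <- fet$plasma_beta
  truth_lung <- fet$lung_beta
  fet$plasma_beta <- pl$value; fet$plasma_below_lod <- pl$below_lod
  fet$lung_beta <- lu$value; fet$lung_below_lod <- lu$below_lod

  pairs <- st$pairs
  mm <- censor_lod(ph$maternal$maternal_beta, analysis$lod_plasma)
  pairs$maternal_beta <- mm$value
  pairs$maternal_below_lod <- mm$below_lod

  truth <- list(mafs = mafs, zygosity = st$pairs$zygosity_true,
                responder = fet$responder_true,
                planted_snps = config$planted_snps,
                planted_snp_ids = if (!is.null(config$planted_snps))
                  manifest$snp_id[config$planted_snps$snp_index] else character(0),
                plasma_beta = truth_plasma, lung_beta = truth_lung,
                maternal_beta = ph$maternal$maternal_beta,
                dosage = dos)
  fet$responder_true <- NULL
  rownames(dos) <- st$fetuses$fetus_id
  colnames(dos) <- manifest$snp_id

  structure(list(fetuses = fet, pairs = pairs, calls = calls,
                 manifest = manifest, truth = truth, config = config),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat("Synthetic twin cohort:", nrow(x$pairs), "pairs /", nrow(x$fetuses),
      "fetuses (", paste(x$config$pairs_per_arm, collapse = "/"),
      "CS1/CS2/control )\n")
  cat("  SNP panel:", nrow(x$manifest), "SNPs;",
      nrow(x$calls), "genotype calls\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

#' Write a simulated cohort to the pipeline's standard input files
#'
#' Emits `pheno.csv` (phenotype table, below-LOD encoded as `<LOD`),
#' `geno.tsv` (genotype call report), `manifest.tsv` (SNP manifest),
#' `pairs.csv` (twin pair table) and `truth.json` (planted parameters) under
#' `dir`.
#'
#' @param cohort a `twin_cohort`.
#' @param dir output directory, created if needed.
#' @param settings ventilation settings written into the phenotype table.
#' @return invisibly, the vector of file paths.
#' @export
write_cohort <- function(cohort, dir, settings = ventilation_settings()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- cohort$fetuses
  pheno <- data.frame(
    fetus_id = f$fetus_id, ewe_id = f$ewe_id, arm = f$arm, sex = f$sex,
    delivery_order = f$delivery_order, birthweight_kg = f$birthweight_kg,
    cord_ph = f$cord_ph, cord_paco2 = f$cord_paco2,
    paco2_30min = f$paco2_30min,
    pip = settings$pip, peep = settings$peep, rate = settings$rate,
    plasma_beta = ifelse(f$plasma_below_lod, "<LOD", as.character(f$plasma_beta)),
    lung_beta = ifelse(f$lung_below_lod, "<LOD", as.character(f$lung_beta)),
    stringsAsFactors = FALSE
  )
  paths <- c(pheno = file.path(dir, "pheno.csv"),
             geno = file.path(dir, "geno.tsv"),
             manifest = file.path(dir, "manifest.tsv"),
             pairs = file.path(dir, "pairs.csv"),
             truth = file.path(dir, "truth.json"))
  write.csv(pheno, paths["pheno"], row.names = FALSE, quote = FALSE)
  write_genotype_report(cohort$calls, paths["geno"])
  write_snp_manifest(cohort$manifest, paths["manifest"])
  write.csv(cohort$pairs, paths["pairs"], row.names = FALSE, quote = FALSE)
  tr <- cohort$truth
  tr$dosage <- NULL  # matrix too bulky for the JSON record
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(paths)
}
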
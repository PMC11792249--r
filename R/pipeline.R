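PHENO_COLS <- c("fetus_id", "ewe_id", "arm", "sex", "delivery_order",
                "birthweight_kg", "cord_ph", "cord_paco2", "paco2_30min",
                "pip", "peep", "rate", "plasma_beta", "lung_beta")

#' Read a phenotype CSV
#'
#' One row per fetus with the fixed column set
#' `fetus_id,ewe_id,arm,sex,delivery_order,birthweight_kg,cord_ph,cord_paco2,paco2_30min,pip,peep,rate,plasma_beta,lung_beta`.
#' Below-LOD drug concentrations are encoded as `<LOD` and parsed into an NA
#' value plus a `*_below_lod` flag.
#'
#' @param path CSV path.
#' @return fetus data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path, call. = FALSE)
  ph <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(plasma_beta = "character",
                                lung_beta = "character"))
  if (!identical(names(ph), PHENO_COLS))
    stop("phenotype header must be exactly: ", paste(PHENO_COLS, collapse = ","),
         call. = FALSE)
  if (!all(ph$arm %in% c("CS1", "CS2", "CONTROL")))
    stop("arm must be CS1, CS2 or CONTROL", call. = FALSE)
  if (any(ph$paco2_30min <= 0)) stop("paco2_30min must be > 0", call. = FALSE)
  parse_lod <- function(x) {
    below <- x == "<LOD"
    list(value = ifelse(below, NA_real_, suppressWarnings(as.numeric(x))),
         below = below)
  }
  pl <- parse_lod(ph$plasma_beta); lu <- parse_lod(ph$lung_beta)
  ph$plasma_beta <- pl$value; ph$plasma_below_lod <- pl$below
  ph$lung_beta <- lu$value; ph$lung_below_lod <- lu$below
  ph
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> responder classification -> genotype QC
#' and zygosity -> two-stage allele association -> twin statistics (response
#' concordance, GEE prognostic model, PK summaries) into one reproducible
#' report. Stage boundaries are logged with record counts.
#'
#' @param cohort_cfg a [cohort_config()] (used when `simulate = TRUE`).
#' @param analysis_cfg an [analysis_config()].
#' @param seed optional master seed overriding `cohort_cfg$seed`.
#' @param simulate if `TRUE` (default) generate the cohort; otherwise
#'   `input` must name the real input files.
#' @param input list with paths `pheno`, `geno`, `manifest`, `pairs` when
#'   `simulate = FALSE`.
#' @param out_dir optional directory; when given, all stage outputs and a
#'   JSON report are written there.
#' @param quiet suppress stage logging.
#' @return object of class `run_report` (nested list of all stage results).
#' @export
run_pipeline <- function(cohort_cfg = cohort_config(),
                         analysis_cfg = analysis_config(),
                         seed = NULL, simulate = TRUE, input = NULL,
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[twinans] ", ...)
  if (!is.null(seed)) cohort_cfg$seed <- as.integer(seed)

  if (simulate) {
    say("simulate: ", sum(cohort_cfg$pairs_per_arm), " pairs, ",
        cohort_cfg$n_snps, " SNPs (seed ", cohort_cfg$seed, ")")
    cohort <- simulate_cohort(cohort_cfg, analysis_cfg)
    fet <- cohort$fetuses; pairs <- cohort$pairs
    calls <- cohort$calls; manifest <- cohort$manifest
  } else {
    if (is.null(input) || !all(c("pheno", "geno", "manifest", "pairs") %in% names(input)))
      stop("with simulate = FALSE, 'input' must list pheno, geno, manifest and pairs paths",
           call. = FALSE)
    say("load: reading input files")
    fet <- read_phenotypes(input$pheno)
    calls <- read_genotype_report(input$geno)
    manifest <- read_snp_manifest(input$manifest)
    pairs <- read.csv(input$pairs, stringsAsFactors = FALSE)
    cohort <- NULL
  }
  say("cohort: ", nrow(fet), " fetuses in ", nrow(pairs), " pairs")

  # stage: responder classification
  ctrl <- fet$paco2_30min[fet$arm == "CONTROL"]
  cutoff <- derive_cutoff(ctrl, analysis_cfg$sd_multiplier)
  fet$responder <- NA_character_
  treated <- fet$arm != "CONTROL"
  fet$responder[treated] <- classify_responder(fet$paco2_30min[treated], cutoff)
  fet$vei <- compute_vei(fet$paco2_30min)
  summaries <- summarize_groups(fet[treated, , drop = FALSE], c("arm", "sex"))
  say("classify: cutoff ", round(cutoff$cutoff, 1), " mmHg; ",
      sum(fet$responder == "responder", na.rm = TRUE), "/", sum(treated),
      " treated fetuses respond")

  # stage: genotype QC + zygosity
  qc <- qc_filter(calls, manifest, analysis_cfg)
  say("qc: ", qc$report$n_calls_retained, "/", qc$report$n_calls_total,
      " calls retained (", qc$report$n_snps_pass_gentrain, "/",
      qc$report$n_snps_total, " SNPs pass GenTrain)")
  zyg <- zygosity_table(qc$calls, pairs, analysis_cfg)
  say("zygosity: ", sum(zyg$zygosity == "DZ"), " DZ / ",
      sum(zyg$zygosity == "MZ"), " MZ pairs (concordance ",
      round(min(zyg$concordance), 2), "-", round(max(zyg$concordance), 2), ")")

  # stage: association (treated, classified fetuses only)
  pheno_assoc <- fet[treated, c("fetus_id", "responder", "sex")]
  assoc_calls <- qc$calls[qc$calls$sample_id %in% pheno_assoc$fetus_id, ,
                          drop = FALSE]
  assoc <- run_association(assoc_calls, manifest, pheno_assoc, analysis_cfg)
  say("association: ", nrow(assoc$shortlist), " shortlisted, ",
      length(unique(assoc$significant$snp_id)), " significant SNPs")

  # stage: twin statistics
  conc <- pair_response_concordance(fet[treated, , drop = FALSE])
  gee <- fit_gee(merge(fet, pairs[, c("ewe_id", "twin_type")], by = "ewe_id"))
  pk <- summarize_pk(fet, pairs, analysis_cfg)
  say("twinstats: ", conc$concordant, "/", conc$n_pairs,
      " pairs concordant (", round(conc$percent), "%)")

  report <- structure(list(
    config = list(cohort = if (simulate) unclass(cohort_cfg) else NULL,
                  analysis = unclass(analysis_cfg)),
    n_fetuses = nrow(fet), n_pairs = nrow(pairs),
    cutoff = unclass(cutoff),
    summaries = summaries,
    zygosity = zyg,
    qc = qc$report,
    association = assoc$results,
    concordance = conc,
    gee = gee$coefficients,
    gee_alpha = gee$alpha,
    pk = pk,
    stamp = list(package = "twinans",
                 version = as.character(packageVersion("twinans")),
                 seed = cohort_cfg$seed)
  ), class = "run_report")
  report$fetuses <- fet
  report$cohort <- cohort

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("twinans run report (seed ", x$stamp$seed, ")\n", sep = "")
  cat(sprintf("  %d fetuses / %d pairs; cutoff %.1f mmHg\n",
              x$n_fetuses, x$n_pairs, x$cutoff$cutoff))
  cat(sprintf("  twin response concordance: %d/%d (%.0f%%)\n",
              x$concordance$concordant, x$concordance$n_pairs,
              x$concordance$percent))
  cat("  significant SNPs:",
      length(unique(x$association$snp_id[x$association$direction != "none"])), "\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fet <- report$fetuses
  fet$vei <- round(fet$vei, 5)
  write.csv(fet, file.path(out_dir, "classified.csv"), row.names = FALSE,
            quote = FALSE, na = "")
  write.table(report$summaries, file.path(out_dir, "summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(report$zygosity, file.path(out_dir, "zygosity.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(report$association, file.path(out_dir, "association.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(report$gee, file.path(out_dir, "gee.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(report$pk, file.path(out_dir, "pk.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(report$cutoff), file.path(out_dir, "cutoff.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$concordance, file.path(out_dir, "concordance.json"),
                       auto_unbox = TRUE, digits = NA)
  slim <- report
  slim$fetuses <- NULL; slim$cohort <- NULL
  jsonlite::write_json(unclass(slim), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(out_dir)
}
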
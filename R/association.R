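#' Pivot a long call table to a sample-by-SNP B-dosage matrix
#'
#' Missing calls become NA. Used internally by the association stage; also
#' handy for tests.
#'
#' @param calls genotype call table.
#' @return integer matrix, rownames = sample ids, colnames = SNP ids.
#' @export
calls_to_dosage <- function(calls) {
  samples <- unique(calls$sample_id)
  snps <- unique(calls$snp_id)
  d <- matrix(NA_integer_, length(samples), length(snps),
              dimnames = list(samples, snps))
  d[cbind(match(calls$sample_id, samples), match(calls$snp_id, snps))] <-
    call_dosage(calls$allele1, calls$allele2)
  d
}

#' Build per-SNP allele-by-phenotype count tables
#'
#' Each classified, ANS-treated fetus with a non-missing call contributes its
#' two alleles to the column of its phenotype class, giving a 2x2 table
#' (allele A/B x responder/non-responder) per SNP. Fetuses with genotypes but
#' no phenotype are excluded with a warning; SNPs with no calls among the
#' phenotyped fetuses are skipped.
#'
#' @param calls genotype call table (post-QC).
#' @param phenotypes data.frame with `fetus_id` and `responder`
#'   ("responder"/"non-responder"); control fetuses must not appear.
#' @return data.frame of class `allele_tables`: `snp_id`, `A_resp`, `A_non`,
#'   `B_resp`, `B_non`.
#' @export
build_allele_tables <- function(calls, phenotypes) {
  phenotypes <- phenotypes[!is.na(phenotypes$responder), , drop = FALSE]
  orphan <- setdiff(unique(calls$sample_id), phenotypes$fetus_id)
  if (length(orphan) > 0) {
    warning(length(orphan),
            " genotyped sample(s) without a phenotype excluded from association",
            call. = FALSE)
    calls <- calls[!(calls$sample_id %in% orphan), , drop = FALSE]
  }
  dos <- calls_to_dosage(calls)
  status <- phenotypes$responder[match(rownames(dos), phenotypes$fetus_id)]
  resp <- status == "responder"
  count_class <- function(rows) {
    sub <- dos[rows, , drop = FALSE]
    called <- colSums(!is.na(sub))
    b <- colSums(sub, na.rm = TRUE)
    list(B = b, A = 2 * called - b)
  }
  cr <- count_class(resp)
  cn <- count_class(!resp)
  out <- data.frame(snp_id = colnames(dos),
                    A_resp = cr$A, A_non = cn$A,
                    B_resp = cr$B, B_non = cn$B,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[rowSums(out[, -1]) > 0, , drop = FALSE]  # skip all-missing SNPs
  class(out) <- c("allele_tables", "data.frame")
  out
}

#' Pearson chi-square allele test
#'
#' Pearson chi-square on each 2x2 allele-by-phenotype table, 1 df, no
#' continuity correction, via the closed form
#' \eqn{N (ad - bc)^2 / (r_1 r_2 c_1 c_2)}; p-values from the upper tail of
#' the chi-square distribution. Tables with a zero marginal (monomorphic
#' allele or an empty phenotype class) are flagged NA and should be skipped
#' downstream.
#'
#' @param tables an [build_allele_tables()] result (or any data.frame with
#'   the same count columns).
#' @return `tables` with `chisq_stat` and `chisq_p` columns appended.
#' @export
chisq_allele_test <- function(tables) {
  a <- tables$A_resp; b <- tables$A_non; c <- tables$B_resp; d <- tables$B_non
  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  ok <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  stat <- rep(NA_real_, length(N))
  stat[ok] <- N[ok] * (a[ok] * d[ok] - b[ok] * c[ok])^2 /
    (r1[ok] * r2[ok] * c1[ok] * c2[ok])
  out <- as.data.frame(tables)
  out$chisq_stat <- stat
  out$chisq_p <- pchisq(stat, df = 1, lower.tail = FALSE)
  out
}

#' Stage-1 shortlist
#'
#' Retains SNPs whose allele chi-square p-value is strictly below
#' `stage1_alpha` (0.01) and annotates them with gene, chromosome, position
#' and consequence from the manifest. SNPs with an undefined test (zero
#' marginal) are never retained.
#'
#' @param results a [chisq_allele_test()] result.
#' @param manifest SNP manifest.
#' @param config an [analysis_config()].
#' @return annotated data.frame of shortlisted SNPs.
#' @export
shortlist <- function(results, manifest, config = analysis_config()) {
  keep <- !is.na(results$chisq_p) & results$chisq_p < config$stage1_alpha
  out <- results[keep, , drop = FALSE]
  i <- match(out$snp_id, manifest$snp_id)
  out$gene <- manifest$gene[i]
  out$chromosome <- manifest$chromosome[i]
  out$position <- manifest$position[i]
  out$effect <- manifest$consequence[i]
  rownames(out) <- NULL
  out
}

#' Sex-adjusted logistic allele test
#'
#' Maximum-likelihood fit of
#' \deqn{logit P(responder) = \alpha + \beta \cdot dosage + \gamma I(female)}
#' by iteratively reweighted least squares; returns the additive per-allele
#' log-odds and its Wald p-value. Complete separation is flagged (p is set
#' NA) rather than reported with a meaningless Wald statistic.
#'
#' @param dosage per-fetus allele counts 0..2 (NA allowed, dropped).
#' @param phenotype responder indicator: logical, 0/1 numeric, or
#'   "responder"/"non-responder" character.
#' @param sex optional covariate, "F"/"M" character or factor.
#' @return list with `beta`, `se`, `p`, `separation`.
#' @export
logistic_allele_test <- function(dosage, phenotype, sex = NULL) {
  if (is.character(phenotype)) phenotype <- phenotype == "responder"
  y <- as.numeric(phenotype)
  df <- data.frame(y = y, dosage = dosage)
  form <- y ~ dosage
  if (!is.null(sex)) {
    df$female <- as.numeric(sex == "F")
    form <- y ~ dosage + female
  }
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df$y)) < 2)
    stop("both phenotype classes must be present", call. = FALSE)
  if (length(unique(df$dosage)) < 2)
    stop("no dosage variation at this SNP", call. = FALSE)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(form, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  beta <- cf["dosage", "Estimate"]
  se <- cf["dosage", "Std. Error"]
  # separation also shows as an absurd dosage SE even without the glm warning
  if (sep || se > 100) {
    return(list(beta = beta, se = se, p = NA_real_, separation = TRUE))
  }
  list(beta = beta, se = se, p = cf["dosage", "Pr(>|z|)"], separation = FALSE)
}

#' Categorize direction of association per allele
#'
#' For each shortlisted SNP, fits the sex-adjusted logistic model on B-allele
#' dosage and, when the regression p-value is strictly below `stage2_alpha`
#' (0.05), emits one row per allele: the allele whose dosage carries a
#' positive log-odds is responder-associated, the opposite allele
#' non-responder-associated (its log-odds is the negation, with the same
#' p-value), so both direction categories appear for every significant SNP.
#' SNPs failing stage 2 (or separated fits) keep direction "none".
#'
#' @param shortlisted a [shortlist()] result.
#' @param calls post-QC genotype call table.
#' @param phenotypes data.frame with `fetus_id`, `responder`, `sex`.
#' @param config an [analysis_config()].
#' @return data.frame mirroring the final association table: `snp_id`,
#'   `gene`, `chromosome`, `position`, `effect`, `allele`, `chisq_stat`,
#'   `chisq_p`, `lr_beta`, `lr_p`, `direction`.
#' @export
categorize_directions <- function(shortlisted, calls, phenotypes,
                                  config = analysis_config()) {
  cols <- c("snp_id", "gene", "chromosome", "position", "effect",
            "allele", "chisq_stat", "chisq_p", "lr_beta", "lr_p", "direction")
  if (nrow(shortlisted) == 0) {
    out <- shortlisted[, intersect(names(shortlisted), cols), drop = FALSE]
    out$allele <- character(0); out$lr_beta <- numeric(0)
    out$lr_p <- numeric(0); out$direction <- character(0)
    return(out[, cols])
  }
  phenotypes <- phenotypes[!is.na(phenotypes$responder), , drop = FALSE]
  dos <- calls_to_dosage(calls[calls$snp_id %in% shortlisted$snp_id &
                                 calls$sample_id %in% phenotypes$fetus_id, ,
                               drop = FALSE])
  i <- match(rownames(dos), phenotypes$fetus_id)
  pheno <- phenotypes$responder[i]
  sex <- phenotypes$sex[i]
  rows <- lapply(seq_len(nrow(shortlisted)), function(k) {
    sl <- shortlisted[k, ]
    fit <- logistic_allele_test(dos[, sl$snp_id], pheno, sex)
    sig <- !fit$separation && !is.na(fit$p) && fit$p < config$stage2_alpha
    dir_b <- if (!sig) "none" else if (fit$beta > 0) "responder" else "non-responder"
    dir_a <- if (!sig) "none" else if (fit$beta > 0) "non-responder" else "responder"
    data.frame(snp_id = sl$snp_id, gene = sl$gene, chromosome = sl$chromosome,
               position = sl$position, effect = sl$effect,
               allele = c("B", "A"),
               chisq_stat = sl$chisq_stat, chisq_p = sl$chisq_p,
               lr_beta = c(fit$beta, -fit$beta), lr_p = fit$p,
               direction = c(dir_b, dir_a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, cols]
}

#' Two-stage allele association scan
#'
#' Runs the full association machinery on post-QC calls and classified
#' phenotypes: per-SNP allele count tables, Pearson chi-square
#' allele-frequency screen (shortlist at p < 0.01), then sex-adjusted
#' additive logistic regression on the shortlist (significance at p < 0.05)
#' with direction-of-association categorization. No multiple-testing
#' correction is applied beyond the two staged raw-p thresholds.
#'
#' @param calls post-QC genotype call table (ANS-treated fetuses).
#' @param manifest SNP manifest.
#' @param phenotypes data.frame with `fetus_id`, `responder`, `sex`.
#' @param config an [analysis_config()].
#' @return list of class `association_scan`: `tables` (all per-SNP chi-square
#'   results), `shortlist`, `results` (per-allele rows with directions), and
#'   `significant` (rows passing both stages).
#' @export
run_association <- function(calls, manifest, phenotypes,
                            config = analysis_config()) {
  tab <- chisq_allele_test(build_allele_tables(calls, phenotypes))
  sl <- shortlist(tab, manifest, config)
  res <- categorize_directions(sl, calls, phenotypes, config)
  structure(list(tables = tab, shortlist = sl, results = res,
                 significant = res[res$direction != "none", , drop = FALSE]),
            class = "association_scan")
}

#' @export
print.association_scan <- function(x, ...) {
  cat("Two-stage allele association scan\n")
  cat("  SNPs tested:", nrow(x$tables),
      "| stage-1 shortlist (chi-square p < 0.01):", nrow(x$shortlist),
      "| significant after logistic stage:",
      length(unique(x$significant$snp_id)), "SNPs\n")
  if (nrow(x$significant) > 0) {
    print(utils::head(x$significant[x$significant$direction == "responder",
                                    c("snp_id", "gene", "chisq_p", "lr_p", "lr_beta")], 10))
  }
  invisible(x)
}
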
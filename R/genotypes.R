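MANIFEST_COLS <- c("snp_id", "chromosome", "position", "gentrain", "gene",
                   "consequence")
GENO_COLS <- c("sample_id", "snp_id", "allele1", "allele2", "gc_score")

#' Read a SNP manifest TSV
#'
#' Tab-separated with header `snp_id chromosome position gentrain gene
#' consequence`. Positions are 1-based base pairs; GenTrain is the SNP-level
#' clustering-quality score in \[0, 1\]. Duplicate SNP ids are rejected.
#'
#' @param path file path.
#' @return data.frame of SNP records.
#' @export
read_snp_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path, call. = FALSE)
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, MANIFEST_COLS))
    stop("manifest header must be exactly: ", paste(MANIFEST_COLS, collapse = ", "),
         call. = FALSE)
  m <- read.delim(path, stringsAsFactors = FALSE, colClasses = list(
    snp_id = "character", chromosome = "character", gene = "character",
    consequence = "character"))
  m$gene[is.na(m$gene)] <- ""
  bad <- which(is.na(m$position) | m$position < 1 |
                 is.na(m$gentrain) | m$gentrain < 0 | m$gentrain > 1)
  if (length(bad) > 0)
    stop("malformed manifest row at line ", bad[1] + 1L,
         ": position must be >= 1 and gentrain in [0, 1]", call. = FALSE)
  if (anyDuplicated(m$snp_id))
    stop("duplicate snp_id in manifest: ",
         m$snp_id[duplicated(m$snp_id)][1], call. = FALSE)
  m
}

#' @rdname read_snp_manifest
#' @param manifest a manifest data.frame to write.
#' @export
write_snp_manifest <- function(manifest, path) {
  stopifnot(all(MANIFEST_COLS %in% names(manifest)))
  write.table(manifest[MANIFEST_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a genotype call report TSV
#'
#' Final-report-style table, one call per row, with header `sample_id snp_id
#' allele1 allele2 gc_score`. Alleles are the abstract chip labels A/B; a
#' missing call carries `-` for both alleles (one-sided missingness is
#' rejected). GC is the per-call confidence score in \[0, 1\].
#'
#' @param path file path.
#' @return data.frame of genotype calls.
#' @export
read_genotype_report <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path, call. = FALSE)
  g <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "character",
                                 "character", "numeric"))
  if (!identical(names(g), GENO_COLS))
    stop("genotype header must be exactly: ", paste(GENO_COLS, collapse = ", "),
         call. = FALSE)
  bad_allele <- which(!(g$allele1 %in% c("A", "B", "-")) |
                        !(g$allele2 %in% c("A", "B", "-")))
  if (length(bad_allele) > 0)
    stop("parse error at line ", bad_allele[1] + 1L,
         ": allele labels must be A, B or -", call. = FALSE)
  half <- which((g$allele1 == "-") != (g$allele2 == "-"))
  if (length(half) > 0)
    stop("parse error at line ", half[1] + 1L,
         ": alleles must be both present or both missing", call. = FALSE)
  bad_gc <- which(is.na(g$gc_score) | g$gc_score < 0 | g$gc_score > 1)
  if (length(bad_gc) > 0)
    stop("parse error at line ", bad_gc[1] + 1L, ": gc_score must be in [0, 1]",
         call. = FALSE)
  g
}

#' @rdname read_genotype_report
#' @param calls a call data.frame to write.
#' @export
write_genotype_report <- function(calls, path) {
  stopifnot(all(GENO_COLS %in% names(calls)))
  write.table(calls[GENO_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Quality-filter genotype calls
#'
#' Two-step filter: (1) drop every SNP whose manifest GenTrain score is not
#' strictly above `gentrain_min` (0.7), removing all its calls; (2) among the
#' remaining calls, keep only those whose GC score is strictly above `gc_min`
#' (0.15). Both thresholds are exclusive: a call at exactly the threshold is
#' dropped. The filter is idempotent.
#'
#' @param calls genotype call table (see [read_genotype_report()]).
#' @param manifest SNP manifest (see [read_snp_manifest()]).
#' @param config an [analysis_config()].
#' @return list of class `qc_result`: `calls` (retained calls) and `report`
#'   (counts at each step).
#' @export
qc_filter <- function(calls, manifest, config = analysis_config()) {
  unknown <- setdiff(unique(calls$snp_id), manifest$snp_id)
  if (length(unknown) > 0)
    stop("calls reference SNPs absent from the manifest, e.g. ", unknown[1],
         call. = FALSE)
  keep_snps <- manifest$snp_id[manifest$gentrain > config$gentrain_min]
  snp_pass <- calls$snp_id %in% keep_snps
  after_snp <- calls[snp_pass, , drop = FALSE]
  gc_pass <- after_snp$gc_score > config$gc_min
  retained <- after_snp[gc_pass, , drop = FALSE]
  report <- list(
    n_snps_total = nrow(manifest),
    n_snps_pass_gentrain = length(keep_snps),
    n_calls_total = nrow(calls),
    n_calls_after_snp_filter = nrow(after_snp),
    n_calls_retained = nrow(retained)
  )
  structure(list(calls = retained, report = report), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("QC: %d/%d SNPs pass GenTrain; calls %d -> %d (SNP filter) -> %d (GC filter)\n",
              r$n_snps_pass_gentrain, r$n_snps_total, r$n_calls_total,
              r$n_calls_after_snp_filter, r$n_calls_retained))
  invisible(x)
}

# unordered allele pair -> B-allele dosage (NA when missing)
call_dosage <- function(a1, a2) {
  d <- (a1 == "B") + (a2 == "B")
  d[a1 == "-" | a2 == "-"] <- NA_integer_
  as.integer(d)
}

#' Genotype concordance between two samples
#'
#' Over the SNPs called (non-missing) in both samples, the fraction at which
#' the two carry identical unordered allele pairs (AB and BA match).
#' Symmetric in its arguments.
#'
#' @param calls_a,calls_b call tables for the two samples (typically
#'   post-QC subsets of one report).
#' @return list with `rate` and `n_compared`.
#' @export
pair_concordance <- function(calls_a, calls_b) {
  da <- call_dosage(calls_a$allele1, calls_a$allele2)
  db <- call_dosage(calls_b$allele1, calls_b$allele2)
  idx <- match(calls_a$snp_id, calls_b$snp_id)
  ok <- !is.na(idx) & !is.na(da) & !is.na(db[idx])
  n <- sum(ok)
  if (n == 0)
    stop("undefined concordance: no SNP is called in both samples", call. = FALSE)
  list(rate = mean(da[ok] == db[idx][ok]), n_compared = n)
}

#' Call twin zygosity from genotype concordance
#'
#' Pairs with concordance strictly greater than the threshold (0.9) are
#' monozygotic; all others, dizygotic. Full sibs share 0/1/2 alleles IBD with
#' probabilities 1/4, 1/2, 1/4, which keeps dizygotic concordance well below
#' 0.9 on any polymorphic panel (see [dz_concordance_expected()]).
#'
#' @param rate concordance in \[0, 1\] (vectorized).
#' @param config an [analysis_config()].
#' @return character, "MZ" or "DZ".
#' @export
classify_zygosity <- function(rate, config = analysis_config()) {
  if (any(rate < 0 | rate > 1)) stop("'rate' must be in [0, 1]", call. = FALSE)
  ifelse(rate > config$zygosity_threshold, "MZ", "DZ")
}

#' Zygosity table for all twin pairs
#'
#' Computes post-QC genotype concordance and the zygosity call for each twin
#' pair.
#'
#' @param calls post-QC genotype call table covering both twins of each pair.
#' @param pairs data.frame with `ewe_id`, `fetus_id1`, `fetus_id2` (and
#'   optionally `twin_type`).
#' @param config an [analysis_config()].
#' @return `pairs` with `concordance`, `n_compared` and `zygosity` columns.
#' @export
zygosity_table <- function(calls, pairs, config = analysis_config()) {
  by_sample <- split(calls, calls$sample_id)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- by_sample[[pairs$fetus_id1[i]]]
    b <- by_sample[[pairs$fetus_id2[i]]]
    if (is.null(a) || is.null(b))
      stop("no post-QC calls for pair ", pairs$ewe_id[i], call. = FALSE)
    pair_concordance(a, b)
  })
  pairs$concordance <- vapply(res, `[[`, numeric(1), "rate")
  pairs$n_compared <- vapply(res, `[[`, numeric(1), "n_compared")
  pairs$zygosity <- classify_zygosity(pairs$concordance, config)
  pairs
}
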
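#' Twin-pair response concordance
#'
#' A treated twin pair is concordant when both fetuses carry the same
#' responder status. Control pairs (unclassified) are excluded and reported.
#'
#' @param fetuses fetus table with `ewe_id`, `arm` and `responder`.
#' @return list: `n_pairs` (ANS pairs assessed), `concordant`, `fraction`,
#'   `percent`, `n_excluded` (control/unclassifiable pairs).
#' @export
pair_response_concordance <- function(fetuses) {
  by_ewe <- split(fetuses$responder, fetuses$ewe_id)
  assessable <- vapply(by_ewe, function(s) length(s) == 2 && !anyNA(s), logical(1))
  n_excl <- sum(!assessable)
  if (n_excl > 0)
    message(n_excl, " pair(s) without two classified twins excluded from concordance")
  conc <- vapply(by_ewe[assessable], function(s) s[1] == s[2], logical(1))
  if (length(conc) == 0)
    stop("no assessable ANS twin pairs", call. = FALSE)
  list(n_pairs = length(conc), concordant = sum(conc),
       fraction = mean(conc), percent = 100 * mean(conc),
       n_excluded = n_excl)
}

#' Censor concentrations at the assay limit of detection
#'
#' Values strictly below the LOD are reported as below-LOD (value NA); a
#' value exactly at the LOD counts as detected, since the LOD is defined as
#' the lowest reportable concentration.
#'
#' @param value concentrations in ng/mL (vectorized, non-negative).
#' @param lod limit of detection, > 0 (0.5 ng/mL for plasma, 1 for lung
#'   tissue under the default [analysis_config()]).
#' @return data.frame with `value` (NA where censored) and `below_lod`.
#' @export
censor_lod <- function(value, lod) {
  if (lod <= 0) stop("'lod' must be > 0", call. = FALSE)
  if (any(value < 0, na.rm = TRUE))
    stop("concentrations must be non-negative", call. = FALSE)
  below <- !is.na(value) & value < lod
  data.frame(value = ifelse(below, NA_real_, value), below_lod = below)
}

#' Mean absolute within-pair difference
#'
#' Mean over twin pairs of |x1 - x2| for a concentration variable. Pairs in
#' which either twin is below the LOD (NA value) are excluded from the mean
#' and counted.
#'
#' @param fetuses fetus table with `ewe_id` and the variable column.
#' @param variable column name, e.g. `"plasma_beta"`.
#' @return list: `mean_abs_diff`, `n_pairs_used`, `n_excluded`.
#' @export
twin_abs_difference <- function(fetuses, variable) {
  if (!variable %in% names(fetuses))
    stop("unknown variable: ", variable, call. = FALSE)
  by_ewe <- split(fetuses[[variable]], fetuses$ewe_id)
  pairs <- Filter(function(v) length(v) == 2, by_ewe)
  usable <- vapply(pairs, function(v) !anyNA(v), logical(1))
  if (!any(usable))
    return(list(mean_abs_diff = NA_real_, n_pairs_used = 0L,
                n_excluded = length(pairs),
                note = "no pair with both values detected"))
  d <- vapply(pairs[usable], function(v) abs(v[1] - v[2]), numeric(1))
  list(mean_abs_diff = mean(d), n_pairs_used = length(d),
       n_excluded = sum(!usable))
}

#' Betamethasone concentration summaries by arm and compartment
#'
#' Per treatment arm and compartment (maternal plasma, fetal plasma, lung
#' tissue): number of samples, mean and SD over detected values, mean
#' absolute within-twin-pair difference (fetal compartments; both twins
#' detected) and the count of below-LOD samples. Below-LOD values are
#' excluded from means by default; with `config$lod_substitute` they are
#' replaced by LOD/2 instead.
#'
#' @param fetuses fetus table with `plasma_beta`/`plasma_below_lod` and
#'   `lung_beta`/`lung_below_lod` columns.
#' @param pairs optional pair table with `maternal_beta` and
#'   `maternal_below_lod` for the maternal compartment.
#' @param config an [analysis_config()].
#' @return data.frame: `group`, `compartment`, `n`, `mean`, `sd`,
#'   `mean_abs_twin_diff`, `n_below_lod`.
#' @export
summarize_pk <- function(fetuses, pairs = NULL, config = analysis_config()) {
  subst <- function(v, below, lod) {
    if (config$lod_substitute) ifelse(below, lod / 2, v) else v
  }
  one <- function(group, compartment, v, below, lod, diff_src = NULL) {
    vv <- subst(v, below, lod)
    det <- vv[!is.na(vv)]
    data.frame(
      group = group, compartment = compartment, n = length(v),
      mean = if (length(det)) mean(det) else NA_real_,
      sd = if (length(det) >= 2) sd(det) else NA_real_,
      mean_abs_twin_diff = if (is.null(diff_src)) NA_real_ else
        twin_abs_difference(diff_src$fet, diff_src$var)$mean_abs_diff,
      n_below_lod = sum(below),
      stringsAsFactors = FALSE
    )
  }
  out <- list()
  for (a in c("CS1", "CS2", "CONTROL")) {
    f <- fetuses[fetuses$arm == a, , drop = FALSE]
    if (nrow(f) == 0) next
    if (!is.null(pairs)) {
      p <- pairs[pairs$arm == a, , drop = FALSE]
      out[[length(out) + 1]] <- one(a, "maternal plasma", p$maternal_beta,
                                    p$maternal_below_lod, config$lod_plasma)
    }
    out[[length(out) + 1]] <- one(a, "fetal plasma", f$plasma_beta,
                                  f$plasma_below_lod, config$lod_plasma,
                                  list(fet = f, var = "plasma_beta"))
    out[[length(out) + 1]] <- one(a, "lung tissue", f$lung_beta,
                                  f$lung_below_lod, config$lod_tissue,
                                  list(fet = f, var = "lung_beta"))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
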
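#' Standardized ventilator settings
#'
#' The ventilation protocol is fixed across the cohort: peak inspiratory
#' pressure 35 cmH2O, positive end-expiratory pressure 5 cmH2O, 50
#' breaths/min, 0.5 s inspiratory time. The constant 3800 is the conventional
#' numerator of the ventilation efficacy index.
#'
#' @param pip peak inspiratory pressure, cmH2O.
#' @param peep positive end-expiratory pressure, cmH2O.
#' @param rate respiratory rate, breaths/min.
#' @param inspiratory_time seconds.
#' @param vei_constant dimensionless VEI numerator.
#' @return object of class `ventilation_settings`.
#' @export
ventilation_settings <- function(pip = 35, peep = 5, rate = 50,
                                 inspiratory_time = 0.5, vei_constant = 3800) {
  if (peep < 0 || pip <= peep)
    stop("ventilation settings require pip > peep >= 0", call. = FALSE)
  if (rate <= 0) stop("ventilation settings require rate > 0", call. = FALSE)
  structure(list(pip = pip, peep = peep, rate = rate,
                 inspiratory_time = inspiratory_time,
                 vei_constant = vei_constant),
            class = "ventilation_settings")
}

#' Ventilation efficacy index
#'
#' VEI = 3800 / (rate x (PIP - PEEP) x PaCO2): an integrated measure of
#' ventilation efficiency, higher when adequate gas exchange is achieved at
#' lower ventilator load. Strictly decreasing in rate, driving pressure and
#' PaCO2.
#'
#' @param paco2 arterial PaCO2 in mmHg (vectorized, must be > 0).
#' @param settings a [ventilation_settings()].
#' @return dimensionless VEI values.
#' @examples
#' compute_vei(84.3)  # ~0.0301 under default settings
#' @export
compute_vei <- function(paco2, settings = ventilation_settings()) {
  if (!inherits(settings, "ventilation_settings"))
    settings <- do.call(ventilation_settings, settings)
  if (any(!is.finite(paco2)) || any(paco2 <= 0))
    stop("'paco2' must be positive", call. = FALSE)
  settings$vei_constant /
    (settings$rate * (settings$pip - settings$peep) * paco2)
}

#' Derive the responder PaCO2 cutoff from control animals
#'
#' The responsiveness threshold is experimentally derived: the cutoff is the
#' mean 30-min PaCO2 of the steroid-naive control animals minus
#' `sd_multiplier` (default 2) sample standard deviations. Controls of both
#' sexes are pooled. The sample SD uses the n-1 denominator.
#'
#' @param control_paco2 numeric vector of control-arm 30-min PaCO2 (mmHg),
#'   at least two values.
#' @param sd_multiplier number of SDs below the mean. Default 2.
#' @return object of class `cutoff_result` with fields `control_mean`,
#'   `control_sd`, `sd_multiplier`, `cutoff`, `n_controls`.
#' @examples
#' derive_cutoff(c(100, 120, 140))  # mean 120, sd 20, cutoff 80
#' @export
derive_cutoff <- function(control_paco2, sd_multiplier = 2) {
  control_paco2 <- control_paco2[!is.na(control_paco2)]
  if (length(control_paco2) < 2)
    stop("insufficient data: the cutoff needs at least 2 control PaCO2 values",
         call. = FALSE)
  m <- mean(control_paco2)
  s <- sd(control_paco2)
  structure(list(control_mean = m, control_sd = s,
                 sd_multiplier = sd_multiplier,
                 cutoff = m - sd_multiplier * s,
                 n_controls = length(control_paco2)),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("PaCO2 responder cutoff: %.1f mmHg (control mean %.1f - %g x SD %.1f, n = %d)\n",
              x$cutoff, x$control_mean, x$sd_multiplier, x$control_sd,
              x$n_controls))
  invisible(x)
}

#' Classify ANS-treated fetuses as responders or non-responders
#'
#' A treated fetus responds if its 30-min PaCO2 falls strictly below the
#' control-derived cutoff; a value equal to the cutoff (i.e. within two
#' control SDs of the control mean) is a non-responder.
#'
#' @param paco2 30-min PaCO2 values (mmHg, > 0), vectorized.
#' @param cutoff a [derive_cutoff()] result or a numeric cutoff in mmHg.
#' @return character vector, "responder" or "non-responder".
#' @export
classify_responder <- function(paco2, cutoff) {
  if (inherits(cutoff, "cutoff_result")) cutoff <- cutoff$cutoff
  if (any(paco2 <= 0, na.rm = TRUE) || cutoff <= 0)
    stop("'paco2' and 'cutoff' must be positive", call. = FALSE)
  ifelse(paco2 < cutoff, "responder", "non-responder")
}

#' Pool means and SDs across groups
#'
#' Combines per-group summary statistics into the summary the concatenated
#' raw data would give: the pooled mean is the n-weighted mean, and the
#' pooled variance is
#' \deqn{[\sum (n_i - 1) s_i^2 + \sum n_i (m_i - \bar m)^2] / (N - 1),}
#' i.e. within-group plus between-group sums of squares over N - 1. Groups
#' of size one contribute only to the between-group term.
#'
#' @param groups data.frame with columns `n`, `mean`, `sd` (`sd` may be NA
#'   only where `n` is 1); an optional `label` column is ignored.
#' @return one-row data.frame with `n`, `mean`, `sd`.
#' @examples
#' # female treated arms: pooled mean 76.5, sd 38.0
#' pooled_moments(data.frame(n = c(9, 11), mean = c(88.6, 66.6),
#'                           sd = c(49.9, 22.6)))
#' @export
pooled_moments <- function(groups) {
  if (!is.data.frame(groups) || nrow(groups) == 0)
    stop("'groups' must be a non-empty data.frame", call. = FALSE)
  if (!all(c("n", "mean") %in% names(groups)))
    stop("'groups' needs columns n, mean, sd", call. = FALSE)
  n <- groups$n; m <- groups$mean
  s <- if ("sd" %in% names(groups)) groups$sd else rep(NA_real_, nrow(groups))
  if (any(n < 1)) stop("group sizes must be >= 1", call. = FALSE)
  if (any(n >= 2 & is.na(s)))
    stop("groups with n >= 2 must supply an SD", call. = FALSE)
  s[n == 1] <- 0
  N <- sum(n)
  mbar <- sum(n * m) / N
  pooled_sd <- if (N >= 2)
    sqrt((sum((n - 1) * s^2) + sum(n * (m - mbar)^2)) / (N - 1)) else NA_real_
  data.frame(n = N, mean = mbar, sd = pooled_sd)
}

#' Stratified PaCO2 and response-rate summaries
#'
#' Groups fetus records by the given keys and reports, per stratum, the
#' count, mean and sample SD of 30-min PaCO2, the responder count and the
#' response rate in percent. Rates are carried as exact fractions; use
#' `round()` at report time (printed tables round to the nearest integer
#' percent). Strata containing control (unclassified) fetuses report NA
#' responder counts and rates.
#'
#' @param records fetus table with `paco2_30min` and `responder` columns
#'   (`responder` in "responder"/"non-responder"/NA).
#' @param keys character vector of grouping columns, e.g. `c("arm", "sex")`.
#' @return data.frame, one row per stratum: keys, `n`, `mean`, `sd`,
#'   `responders`, `response_rate`.
#' @export
summarize_groups <- function(records, keys = c("arm", "sex")) {
  if (nrow(records) == 0) stop("'records' is empty", call. = FALSE)
  missing_keys <- setdiff(keys, names(records))
  if (length(missing_keys) > 0)
    stop("unknown grouping key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  split_idx <- split(seq_len(nrow(records)),
                     interaction(records[keys], drop = TRUE, lex.order = TRUE))
  rows <- lapply(split_idx, function(idx) {
    sub <- records[idx, , drop = FALSE]
    classified <- !is.na(sub$responder)
    resp <- if (all(classified)) sum(sub$responder == "responder") else NA_integer_
    cbind(
      sub[1, keys, drop = FALSE],
      data.frame(
        n = nrow(sub),
        mean = mean(sub$paco2_30min),
        sd = if (nrow(sub) >= 2) sd(sub$paco2_30min) else NA_real_,
        responders = resp,
        response_rate = if (is.na(resp)) NA_real_ else 100 * resp / nrow(sub)
      )
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
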
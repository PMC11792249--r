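#' Logistic GEE with exchangeable working correlation
#'
#' Generalized estimating equations for a binary outcome with logit link and
#' an exchangeable working correlation within clusters, solved by Fisher
#' scoring with moment estimation of the scale and correlation parameters at
#' each step (Liang-Zeger). Standard errors are robust (sandwich), so
#' inference is valid even when the exchangeable structure is misspecified.
#' With all clusters of size one the estimates coincide with ordinary
#' logistic regression.
#'
#' @param formula model formula; the response must be binary (0/1 or logical).
#' @param data data.frame.
#' @param id cluster identifier: a vector, or the name of a column of `data`.
#' @param tol convergence tolerance on the coefficient update.
#' @param maxit maximum Fisher-scoring iterations.
#' @param conf_level confidence level for the odds-ratio intervals.
#' @return object of class `gee_fit`: list with `coefficients` (data.frame of
#'   term, estimate, robust se, odds ratio, CI bounds, Wald p), `alpha`
#'   (working correlation), `phi` (scale), `n_clusters`, `converged`.
#' @export
gee_logit <- function(formula, data, id, tol = 1e-8, maxit = 200,
                      conf_level = 0.95) {
  if (is.character(id) && length(id) == 1) id <- data[[id]]
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- as.numeric(stats::model.response(mf))
  X <- model.matrix(formula, mf)
  ok <- complete.cases(cbind(y, X)) & !is.na(id)
  y <- y[ok]; X <- X[ok, , drop = FALSE]; id <- id[ok]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  # drop aliased columns so the scoring step stays full rank
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  p <- ncol(X)
  N <- length(y)
  clusters <- split(seq_len(N), id)
  if (length(clusters) < 2) stop("GEE needs at least 2 clusters", call. = FALSE)

  beta <- coef(glm.fit(X, y, family = binomial()))
  alpha <- 0; phi <- 1
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- pmin(pmax(plogis(eta), 1e-10), 1 - 1e-10)
    v <- mu * (1 - mu)
    r <- (y - mu) / sqrt(v)
    phi <- sum(r^2) / (N - p)
    num <- 0; npairs <- 0
    for (idx in clusters) {
      ni <- length(idx)
      if (ni > 1) {
        num <- num + (sum(r[idx])^2 - sum(r[idx]^2)) / 2
        npairs <- npairs + ni * (ni - 1) / 2
      }
    }
    alpha <- if (npairs > p) num / ((npairs - p) * phi) else
      if (npairs > 0) num / (npairs * phi) else 0
    max_n <- max(lengths(clusters))
    alpha <- min(max(alpha, -1 / (max_n - 1) + 1e-6), 1 - 1e-6)

    B <- matrix(0, p, p)
    U <- numeric(p)
    acc_ok <- tryCatch({
      for (idx in clusters) {
        ni <- length(idx)
        Xi <- X[idx, , drop = FALSE]
        vi <- v[idx]
        Di <- Xi * vi
        R <- matrix(alpha, ni, ni); diag(R) <- 1
        Vi <- (sqrt(vi) %o% sqrt(vi)) * R * phi
        W <- solve(Vi, cbind(y[idx] - mu[idx], Di))
        U <- U + drop(crossprod(Di, W[, 1]))
        B <- B + crossprod(Di, W[, -1, drop = FALSE])
      }
      TRUE
    }, error = function(e) FALSE)
    delta <- if (acc_ok) tryCatch(solve(B, U), error = function(e) rep(NA_real_, p))
    else rep(NA_real_, p)
    if (any(!is.finite(delta))) {
      warning("GEE scoring step is singular (possible separation); ",
              "estimates from the last stable iteration are returned",
              call. = FALSE)
      break
    }
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GEE did not converge in ", maxit, " iterations", call. = FALSE)

  # robust (sandwich) covariance at the solution
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(plogis(eta), 1e-10), 1 - 1e-10)
  v <- mu * (1 - mu)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  vcov_r <- tryCatch({
    for (idx in clusters) {
      ni <- length(idx)
      Xi <- X[idx, , drop = FALSE]
      vi <- v[idx]
      Di <- Xi * vi
      R <- matrix(alpha, ni, ni); diag(R) <- 1
      Vi <- (sqrt(vi) %o% sqrt(vi)) * R * phi
      W <- solve(Vi, cbind(y[idx] - mu[idx], Di))
      u_i <- drop(crossprod(Di, W[, 1]))
      B <- B + crossprod(Di, W[, -1, drop = FALSE])
      M <- M + u_i %o% u_i
    }
    Binv <- solve(B)
    Binv %*% M %*% Binv
  }, error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcov_r), 0))
  z <- beta / se
  zq <- qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(
    term = colnames(X),
    estimate = unname(beta),
    se = unname(se),
    odds_ratio = exp(unname(beta)),
    ci_low = exp(unname(beta - zq * se)),
    ci_high = exp(unname(beta + zq * se)),
    p_value = 2 * pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE
  )
  structure(list(coefficients = coefs, alpha = alpha, phi = phi,
                 n_clusters = length(clusters), n_obs = N,
                 vcov = vcov_r, converged = converged),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic GEE (exchangeable working correlation, alpha = %.3f; %d clusters, %d obs)\n",
              x$alpha, x$n_clusters, x$n_obs))
  cf <- x$coefficients
  cf[-1] <- lapply(cf[-1], signif, digits = digits)
  print(cf, row.names = FALSE)
  if (!x$converged) cat("  WARNING: not converged\n")
  invisible(x)
}

#' Prognostic GEE model for ANS responsiveness
#'
#' Fits the study's prognostic model: responder status of ANS-treated
#' fetuses (CS1 and CS2 pooled) on treatment, fetal sex, twin sex
#' combination and delivery order, with ewes as clusters, logit link,
#' exchangeable working correlation and robust standard errors. Covariate
#' coding is fixed and reported in the term labels so the direction of each
#' odds ratio is unambiguous: treatment CS2 vs CS1; sex female vs male; twin
#' type MF and FF vs MM; delivery order first- vs second-delivered.
#'
#' @param records fetus table with columns `arm`, `sex`, `delivery_order`,
#'   `ewe_id` and `responder` (controls and unclassified rows are dropped);
#'   twin type is derived from the two sexes within each ewe if no
#'   `twin_type` column is present.
#' @param covariates subset of `c("treatment", "sex", "twin_type",
#'   "delivery_order")` to include.
#' @param cluster name of the cluster id column. Default `"ewe_id"`.
#' @return a [gee_logit()] fit with study-specific term labels.
#' @export
fit_gee <- function(records,
                    covariates = c("treatment", "sex", "twin_type",
                                   "delivery_order"),
                    cluster = "ewe_id") {
  covariates <- match.arg(covariates, several.ok = TRUE)
  rec <- records[records$arm %in% c("CS1", "CS2") & !is.na(records$responder), ,
                 drop = FALSE]
  if (!"twin_type" %in% names(rec)) {
    tt <- tapply(rec$sex, rec$ewe_id, function(s)
      if (length(s) == 2 && s[1] != s[2]) "MF"
      else if (all(s == "M")) "MM" else "FF")
    rec$twin_type <- unname(tt[rec$ewe_id])
  }
  df <- data.frame(
    y = as.numeric(rec$responder == "responder"),
    treatment_CS2 = as.numeric(rec$arm == "CS2"),
    sex_female = as.numeric(rec$sex == "F"),
    twin_type_MF = as.numeric(rec$twin_type == "MF"),
    twin_type_FF = as.numeric(rec$twin_type == "FF"),
    delivery_first = as.numeric(rec$delivery_order == 1L)
  )
  terms <- c(treatment = "treatment_CS2", sex = "sex_female",
             twin_type = "twin_type_MF + twin_type_FF",
             delivery_order = "delivery_first")
  rhs <- paste(terms[covariates], collapse = " + ")
  gee_logit(stats::as.formula(paste("y ~", rhs)), df, id = rec[[cluster]])
}
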
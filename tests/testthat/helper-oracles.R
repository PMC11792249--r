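# Independent oracles used across the suite. These deliberately take the
# brute-force route (enumeration, expected-count formulas, direct likelihood
# maximization) so they share no code with the implementation they check.

# P(two full sibs share the same unordered genotype) by exhaustive enumeration
# over parental genotypes and the four transmission choices.
oracle_dz_concordance <- function(p) {
  gfreq <- c((1 - p)^2, 2 * p * (1 - p), p^2)      # parent dosage 0/1/2
  trans <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1))    # P(transmit B | dosage)
  tot <- 0
  for (s in 1:3) for (d in 1:3) {
    child <- numeric(3)
    for (a in 1:2) for (b in 1:2)
      child[(a - 1) + (b - 1) + 1] <- child[(a - 1) + (b - 1) + 1] +
        trans[s, a] * trans[d, b]
    tot <- tot + gfreq[s] * gfreq[d] * sum(child^2)
  }
  tot
}

# Pearson chi-square through the expected-count route
oracle_chisq <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# logistic MLE by direct likelihood maximization (no IRLS)
oracle_logistic <- function(X, y) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  optim(rep(0, ncol(X)), nll, method = "BFGS",
        control = list(maxit = 1000, reltol = 1e-14))$par
}

# frozen GEE fixture: regenerated identically here and fitted once with an
# external exchangeable-GEE implementation; see expected values in test-gee.R
make_gee_fixture <- function() {
  set.seed(4242)
  n_cl <- 60
  id <- rep(seq_len(n_cl), each = 2)
  u <- rep(rnorm(n_cl, 0, 1), each = 2)
  x1 <- rbinom(2 * n_cl, 1, 0.5)
  x2 <- round(rnorm(2 * n_cl), 3)
  eta <- -0.3 + 1.1 * x1 - 0.7 * x2 + u
  y <- as.integer(runif(2 * n_cl) < plogis(eta))
  data.frame(id = id, y = y, x1 = x1, x2 = x2)
}

# minimal call-table constructor for genotype tests
make_calls <- function(sample_id, snp_id, dosage, gc = 0.9) {
  data.frame(
    sample_id = sample_id, snp_id = snp_id,
    allele1 = ifelse(is.na(dosage), "-", ifelse(dosage >= 1, "B", "A")),
    allele2 = ifelse(is.na(dosage), "-", ifelse(dosage == 2, "B", "A")),
    gc_score = gc, stringsAsFactors = FALSE
  )
}

# classify a simulated cohort's treated fetuses with its own control cutoff
classify_cohort <- function(cohort) {
  fet <- cohort$fetuses
  cut <- derive_cutoff(fet$paco2_30min[fet$arm == "CONTROL"])
  fet$responder <- NA_character_
  tr <- fet$arm != "CONTROL"
  fet$responder[tr] <- classify_responder(fet$paco2_30min[tr], cut)
  fet
}
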
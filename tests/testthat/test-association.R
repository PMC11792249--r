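test_that("allele tables count two alleles per called fetus per class", {
  # responders {AA, AB}, non-responder {BB}
  calls <- make_calls(c("F1", "F2", "F3"), "S1", dosage = c(0, 1, 2))
  pheno <- data.frame(fetus_id = c("F1", "F2", "F3"),
                      responder = c("responder", "responder", "non-responder"),
                      sex = c("M", "F", "M"))
  tab <- build_allele_tables(calls, pheno)
  expect_equal(tab$A_resp, 3)
  expect_equal(tab$A_non, 0)
  expect_equal(tab$B_resp, 1)
  expect_equal(tab$B_non, 2)
  # conservation: column sums are twice the called class sizes
  expect_equal(tab$A_resp + tab$B_resp, 2 * 2)
  expect_equal(tab$A_non + tab$B_non, 2 * 1)
})

test_that("all-missing SNPs are skipped and orphans excluded with warning", {
  calls <- rbind(make_calls(c("F1", "F2"), "S1", c(1, 2)),
                 make_calls(c("F1", "F2"), "S2", c(NA, NA)),
                 make_calls("F9", "S1", 2))
  pheno <- data.frame(fetus_id = c("F1", "F2"),
                      responder = c("responder", "non-responder"),
                      sex = c("M", "F"))
  expect_warning(tab <- build_allele_tables(calls, pheno), "without a phenotype")
  expect_equal(tab$snp_id, "S1")
  expect_equal(tab$B_non, 2)  # F9's BB call did not leak in
})

test_that("the allele chi-square matches its closed form and brute force", {
  t1 <- data.frame(snp_id = "S", A_resp = 30, A_non = 10, B_resp = 10, B_non = 30)
  r <- chisq_allele_test(t1)
  expect_equal(r$chisq_stat, 20, tolerance = 1e-12)
  expect_equal(r$chisq_p, 7.744216e-06, tolerance = 1e-6)
  expect_equal(r$chisq_stat, oracle_chisq(30, 10, 10, 30), tolerance = 1e-12)
  # base-R cross-check, no continuity correction
  ct <- stats::chisq.test(matrix(c(30, 10, 10, 30), 2), correct = FALSE)
  expect_equal(r$chisq_stat, unname(ct$statistic), tolerance = 1e-12)
  # no association
  t0 <- data.frame(snp_id = "S", A_resp = 20, A_non = 20, B_resp = 20, B_non = 20)
  expect_equal(chisq_allele_test(t0)$chisq_stat, 0)
  expect_equal(chisq_allele_test(t0)$chisq_p, 1)
  # invariance under swapping both row and column labels
  tsw <- data.frame(snp_id = "S", A_resp = 25, A_non = 10, B_resp = 5, B_non = 40)
  tsw2 <- data.frame(snp_id = "S", A_resp = 40, A_non = 5, B_resp = 10, B_non = 25)
  expect_equal(chisq_allele_test(tsw)$chisq_stat,
               chisq_allele_test(tsw2)$chisq_stat, tolerance = 1e-12)
  # zero marginal flagged NA
  tz <- data.frame(snp_id = "S", A_resp = 10, A_non = 10, B_resp = 0, B_non = 0)
  expect_true(is.na(chisq_allele_test(tz)$chisq_stat))
})

test_that("chi-square agrees with the expected-count oracle on random tables", {
  set.seed(12)
  for (i in 1:200) {
    x <- sample(1:60, 4, replace = TRUE)
    tab <- data.frame(snp_id = "S", A_resp = x[1], A_non = x[2],
                      B_resp = x[3], B_non = x[4])
    expect_equal(chisq_allele_test(tab)$chisq_stat,
                 oracle_chisq(x[1], x[2], x[3], x[4]), tolerance = 1e-10)
  }
})

test_that("the stage-1 shortlist applies a strict 0.01 cut", {
  res <- data.frame(snp_id = c("S1", "S2", "S3"),
                    A_resp = 1, A_non = 1, B_resp = 1, B_non = 1,
                    chisq_stat = 5, chisq_p = c(0.008, 0.01, 0.011))
  manifest <- data.frame(snp_id = c("S1", "S2", "S3"), chromosome = "1",
                         position = 1:3, gentrain = 0.9,
                         gene = c("MET", "X", "Y"), consequence = "intron variant")
  sl <- shortlist(res, manifest)
  expect_equal(sl$snp_id, "S1")
  expect_equal(sl$gene, "MET")
})

test_that("the logistic allele fit is the MLE", {
  # 8/10 responders among carriers vs 2/10 among non-carriers: beta = ln 16
  dosage <- rep(c(1, 0), each = 10)
  y <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  fit <- logistic_allele_test(dosage, y)
  expect_equal(fit$beta, log(16), tolerance = 1e-6)
  expect_false(fit$separation)

  # sex-adjusted three-parameter fit against direct likelihood maximization
  set.seed(33)
  n <- 300
  dos <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  y2 <- rbinom(n, 1, plogis(-0.5 + 0.8 * dos + 0.6 * (sex == "F")))
  fit2 <- logistic_allele_test(dos, y2, sex)
  X <- cbind(1, dos, sex == "F")
  expect_equal(fit2$beta, oracle_logistic(X, y2)[2], tolerance = 1e-4)

  # null consistency
  y3 <- rbinom(2000, 1, 0.5)
  dos3 <- sample(0:2, 2000, replace = TRUE)
  expect_lt(abs(logistic_allele_test(dos3, y3)$beta), 0.15)

  # complete separation is flagged, not reported as a Wald p
  ys <- rep(c(1, 0), each = 10)
  ds <- rep(c(2, 0), each = 10)
  fs <- logistic_allele_test(ds, ys)
  expect_true(fs$separation)
  expect_true(is.na(fs$p))
})

test_that("direction categories mirror the allele log-odds signs", {
  set.seed(55)
  n <- 400
  dos <- sample(0:2, n, replace = TRUE)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  y <- rbinom(n, 1, plogis(-1 + 2 * dos))
  calls <- make_calls(sprintf("F%03d", 1:n), "S1", dos)
  pheno <- data.frame(fetus_id = sprintf("F%03d", 1:n),
                      responder = ifelse(y == 1, "responder", "non-responder"),
                      sex = sex)
  tab <- chisq_allele_test(build_allele_tables(calls, pheno))
  manifest <- data.frame(snp_id = "S1", chromosome = "2", position = 5,
                         gentrain = 0.9, gene = "G1", consequence = "intron variant")
  res <- categorize_directions(shortlist(tab, manifest), calls, pheno)
  # both rows emitted: B responder-associated, A non-responder-associated
  expect_equal(nrow(res), 2)
  expect_equal(res$direction[res$allele == "B"], "responder")
  expect_equal(res$direction[res$allele == "A"], "non-responder")
  expect_equal(res$lr_beta[res$allele == "A"], -res$lr_beta[res$allele == "B"])
  expect_true(all(sign(res$lr_beta) == ifelse(res$direction == "responder", 1, -1)))
})

test_that("the scan recovers planted effects on a small cohort", {
  planted <- data.frame(snp_index = c(10, 40, 70), beta = c(2, -2, 2))
  cfg <- cohort_config(pairs_per_arm = c(60, 60, 10), n_snps = 100,
                       planted_snps = planted, seed = 71)
  co <- simulate_cohort(cfg)
  fet <- classify_cohort(co)
  q <- qc_filter(co$calls, co$manifest)
  tr <- fet$arm != "CONTROL"
  scan <- run_association(q$calls[q$calls$sample_id %in% fet$fetus_id[tr], ],
                          co$manifest, fet[tr, c("fetus_id", "responder", "sex")])
  hit <- co$truth$planted_snp_ids %in% scan$significant$snp_id
  expect_gte(sum(hit), 2)
})
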
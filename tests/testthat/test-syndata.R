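test_that("identical config and seed reproduce the cohort bit-identically", {
  cfg <- cohort_config(n_snps = 100, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$calls, b$calls)
  expect_identical(a$fetuses, b$fetuses)
  expect_identical(a$manifest, b$manifest)
  c2 <- simulate_cohort(cohort_config(n_snps = 100, seed = 12))
  expect_false(identical(a$calls, c2$calls))
})

test_that("the default arm layout yields 31 pairs and 62 fetuses", {
  co <- simulate_cohort(cohort_config(n_snps = 20, seed = 3))
  expect_equal(nrow(co$pairs), 31)
  expect_equal(nrow(co$fetuses), 62)
  expect_equal(as.vector(table(co$pairs$arm)[c("CS1", "CS2", "CONTROL")]),
               c(11, 10, 10))
  # every fetus belongs to exactly one pair and shares its ewe
  expect_setequal(co$fetuses$fetus_id, c(co$pairs$fetus_id1, co$pairs$fetus_id2))
  expect_equal(co$fetuses$ewe_id[match(co$pairs$fetus_id1, co$fetuses$fetus_id)],
               co$pairs$ewe_id)
  # call table references only manifest SNPs and cohort samples
  expect_true(all(co$calls$snp_id %in% co$manifest$snp_id))
  expect_true(all(co$calls$sample_id %in% co$fetuses$fetus_id))
})

test_that("config validation names the offending field", {
  expect_error(cohort_config(mz_fraction = 1.5), "mz_fraction")
  expect_error(cohort_config(pairs_per_arm = c(0, 10, 10)), "pairs_per_arm")
  expect_error(cohort_config(maf_law = list(min = 0, max = 0.5)), "maf_law")
  expect_error(cohort_config(n_snps = 5,
                             planted_snps = data.frame(snp_index = 9, beta = 1)),
               "planted_snps")
})

test_that("monozygotic pairs without error are fully concordant", {
  co <- simulate_cohort(cohort_config(n_snps = 300, mz_fraction = 1, seed = 5))
  z <- zygosity_table(co$calls, co$pairs)
  expect_true(all(z$concordance == 1))
})

test_that("a monomorphic locus is homozygous reference in both sibs", {
  g <- simulate_pair_genotypes(50, rep(0, 50), "DZ", seed = 1)
  expect_true(all(g$geno1 == 0) && all(g$geno2 == 0))
})

test_that("DZ concordance matches the full-sib enumeration oracle", {
  # closed form against enumeration, across the MAF range
  for (p in c(0.05, 0.1, 0.25, 0.5))
    expect_equal(dz_concordance_expected(p), oracle_dz_concordance(p),
                 tolerance = 1e-12)
  expect_equal(oracle_dz_concordance(0.5), 0.59375, tolerance = 1e-12)
  expect_equal(oracle_dz_concordance(0.1), 0.83215, tolerance = 1e-10)

  # simulated DZ pairs over a mixed-MAF panel, within 3 Monte-Carlo SEs
  set.seed(91)
  mafs <- runif(2000, 0.1, 0.5)
  obs <- replicate(40, {
    g <- simulate_pair_genotypes(2000, mafs, "DZ")
    mean(g$geno1 == g$geno2)
  })
  expected <- mean(dz_concordance_expected(mafs))
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expected), 3 * se)
})

test_that("a degenerate mixture collapses to the single PaCO2 law", {
  skel <- data.frame(fetus_id = sprintf("F%05d", 1:10000),
                     ewe_id = sprintf("E%05d", rep(1:5000, each = 2)),
                     arm = "CS1", sex = rep(c("M", "F"), 5000),
                     delivery_order = rep(1:2, 5000))
  cfg <- cohort_config(n_snps = 2, beta0 = 0, beta_sex = 0, beta_order = 0,
                       responder_paco2 = c(mean = 100, sd = 10),
                       nonresponder_paco2 = c(mean = 100, sd = 10), seed = 2)
  ph <- simulate_phenotypes(skel, cfg)
  expect_lt(abs(mean(ph$fetuses$paco2_30min) - 100), 3 * 10 / sqrt(10000))
  expect_lt(abs(sd(ph$fetuses$paco2_30min) - 10), 0.35)
})

test_that("a planted sex effect reproduces the target odds ratio", {
  skel <- data.frame(fetus_id = sprintf("F%05d", 1:10000),
                     ewe_id = sprintf("E%05d", rep(1:5000, each = 2)),
                     arm = "CS1", sex = rep(c("M", "F"), each = 5000),
                     delivery_order = rep(1:2, 5000))
  cfg <- cohort_config(n_snps = 2, beta0 = -1, beta_sex = log(7.786),
                       beta_order = 0, seed = 7)
  resp <- simulate_phenotypes(skel, cfg)$fetuses$responder_true
  pf <- mean(resp[skel$sex == "F"]); pm <- mean(resp[skel$sex == "M"])
  or <- (pf / (1 - pf)) / (pm / (1 - pm))
  expect_gt(or, 6.0)
  expect_lt(or, 10.0)
})

test_that("control PaCO2 draws recover the control law mean", {
  skel <- data.frame(fetus_id = sprintf("F%05d", 1:10000),
                     ewe_id = sprintf("E%05d", rep(1:5000, each = 2)),
                     arm = "CONTROL", sex = "F", delivery_order = rep(1:2, 5000))
  cfg <- cohort_config(n_snps = 2, control_paco2_mean = 130,
                       control_paco2_sd = 24, seed = 13)
  ph <- simulate_phenotypes(skel, cfg)
  expect_lt(abs(mean(ph$fetuses$paco2_30min) - 130), 1)
  expect_true(all(is.na(ph$fetuses$responder_true)))
})

test_that("below-LOD fraction matches the configured law's CDF at the LOD", {
  # push fetal plasma down so a sizeable fraction is censored at 0.5 ng/mL
  pk <- default_pk_params()
  pk$maternal$CS2 <- c(meanlog = log(2), sdlog = 0.4)
  pk$fetal_ratio$CS2 <- c(meanlog = log(0.3), sdlog = 0.3)
  cfg <- cohort_config(pairs_per_arm = c(1, 2000, 1), n_snps = 1,
                       pk_params = pk, seed = 17)
  co <- simulate_cohort(cfg)
  f <- co$fetuses[co$fetuses$arm == "CS2", ]
  # fetal plasma = maternal x ratio: product of independent log-normals
  p_cens <- plnorm(0.5, log(2) + log(0.3), sqrt(0.4^2 + 0.3^2))
  obs <- mean(f$plasma_below_lod)
  se <- sqrt(p_cens * (1 - p_cens) / nrow(f))
  expect_lt(abs(obs - p_cens), 3 * se + 0.005)  # rounding to 3 dp shifts ties
})

test_that("genotype error and missingness leave dosages valid", {
  co <- simulate_cohort(cohort_config(n_snps = 400, genotype_error_rate = 0.05,
                                      missing_rate = 0.1, seed = 23))
  d <- call_dosage(co$calls$allele1, co$calls$allele2)
  expect_true(all(is.na(d) | d %in% 0:2))
  expect_gt(mean(is.na(d)), 0.07)
  expect_lt(mean(is.na(d)), 0.13)
})

test_that("written cohort files round-trip through the readers", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cohort_config(n_snps = 60, seed = 29))
  paths <- write_cohort(co, dir)
  expect_identical(read_snp_manifest(paths["manifest"])$snp_id,
                   co$manifest$snp_id)
  g <- read_genotype_report(paths["geno"])
  expect_equal(nrow(g), nrow(co$calls))
  expect_identical(g$allele1, co$calls$allele1)
  ph <- read_phenotypes(paths["pheno"])
  expect_equal(ph$paco2_30min, co$fetuses$paco2_30min)
  expect_equal(ph$plasma_below_lod, co$fetuses$plasma_below_lod)
})
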
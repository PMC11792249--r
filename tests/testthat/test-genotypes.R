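write_lines <- function(lines, file) writeLines(lines, file)

test_that("manifest reader validates structure and content", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("snp_id\tchromosome\tposition\tgentrain\tgene\tconsequence",
                "S1\t1\t100\t0.9\tMET\tintron variant",
                "S2\tX\t200\t0.8\t\tintergenic variant",
                "S3\t2\t300\t0.75\tSTAT1\tintron variant"), f)
  m <- read_snp_manifest(f)
  expect_equal(nrow(m), 3)
  expect_equal(m$gene, c("MET", "", "STAT1"))

  write_lines(c("snp_id\tchromosome\tposition\tgentrain\tgene\tconsequence",
                "S1\t1\t100\t0.9\tMET\tx", "S1\t1\t200\t0.9\t\tx"), f)
  expect_error(read_snp_manifest(f), "duplicate snp_id")

  write_lines(c("snp_id\tchromosome\tposition\tgentrain\tgene\tconsequence",
                "S1\t1\t100\t1.4\tMET\tx"), f)
  expect_error(read_snp_manifest(f), "line 2")

  write_lines("snp_id\tchromosome\tposition", f)
  expect_error(read_snp_manifest(f), "header")
})

test_that("genotype report reader enforces the call invariants", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "sample_id\tsnp_id\tallele1\tallele2\tgc_score"
  write_lines(c(hdr, "F1\tS1\tA\tB\t0.8", "F1\tS2\t-\t-\t0.1"), f)
  g <- read_genotype_report(f)
  expect_equal(nrow(g), 2)
  expect_equal(call_dosage(g$allele1, g$allele2), c(1L, NA))

  write_lines(c(hdr, "F1\tS1\tA\t-\t0.8"), f)
  expect_error(read_genotype_report(f), "both present or both missing")

  write_lines(c(hdr, "F1\tS1\tA\tC\t0.8"), f)
  expect_error(read_genotype_report(f), "allele labels")

  write_lines(hdr, f)
  expect_equal(nrow(read_genotype_report(f)), 0)
})

test_that("QC drops SNPs at GenTrain <= 0.7 and calls at GC <= 0.15", {
  manifest <- data.frame(snp_id = paste0("S", 1:5),
                         chromosome = "1", position = 1:5,
                         gentrain = c(0.8, 0.8, 0.65, 0.71, 0.9),
                         gene = "", consequence = "")
  calls <- make_calls("F1", paste0("S", 1:5), dosage = c(1, 1, 1, 1, 1),
                      gc = c(0.2, 0.15, 0.9, 0.16, 0.10))
  q <- qc_filter(calls, manifest)
  expect_equal(nrow(q$calls), 2)
  expect_setequal(q$calls$snp_id, c("S1", "S4"))
  expect_equal(q$report$n_snps_pass_gentrain, 4)
  # boundary values are excluded (thresholds are strict)
  expect_false("S2" %in% q$calls$snp_id)  # gc exactly 0.15
  # exact-threshold GenTrain is dropped too
  manifest$gentrain[1] <- 0.7
  expect_false("S1" %in% qc_filter(calls, manifest)$calls$snp_id)
})

test_that("QC is idempotent and monotone in its thresholds", {
  co <- simulate_cohort(cohort_config(n_snps = 300, seed = 41))
  q1 <- qc_filter(co$calls, co$manifest)
  q2 <- qc_filter(q1$calls, co$manifest)
  expect_identical(q1$calls, q2$calls)
  n_prev <- Inf
  for (th in list(c(0.5, 0.05), c(0.7, 0.15), c(0.85, 0.5))) {
    q <- qc_filter(co$calls, co$manifest,
                   analysis_config(gentrain_min = th[1], gc_min = th[2]))
    expect_lte(nrow(q$calls), n_prev)
    n_prev <- nrow(q$calls)
  }
  bad <- make_calls("F1", "NOT_IN_MANIFEST", 1)
  expect_error(qc_filter(bad, co$manifest), "absent from the manifest")
})

test_that("pair concordance counts identical unordered genotypes", {
  a <- make_calls("F1", paste0("S", 1:10), c(0, 1, 2, 1, 0, 2, 1, 0, 1, 2))
  b <- make_calls("F2", paste0("S", 1:10), c(0, 1, 2, 1, 0, 2, 1, 0, 0, 0))
  r <- pair_concordance(a, b)
  expect_equal(r$rate, 0.8)
  expect_equal(r$n_compared, 10)
  # symmetry
  expect_equal(pair_concordance(b, a)$rate, r$rate)
  # identical call sets
  expect_equal(pair_concordance(a, a)$rate, 1.0)
  # missing calls shrink the comparison, not the formula
  b2 <- b; b2$allele1[1] <- "-"; b2$allele2[1] <- "-"
  expect_equal(pair_concordance(a, b2)$n_compared, 9)
  # no co-called SNPs
  c_ <- make_calls("F3", paste0("T", 1:3), c(0, 1, 2))
  expect_error(pair_concordance(a, c_), "undefined concordance")
})

test_that("zygosity is MZ only strictly above the 0.9 threshold", {
  expect_equal(classify_zygosity(0.95), "MZ")
  expect_equal(classify_zygosity(0.83), "DZ")
  expect_equal(classify_zygosity(0.9), "DZ")
  expect_equal(classify_zygosity(c(0.73, 0.91)), c("DZ", "MZ"))
  expect_error(classify_zygosity(1.2), "rate")
})

test_that("zygosity calls on simulated cohorts with call error are exact", {
  hits <- 0; total <- 0
  for (s in 1:5) {
    co <- simulate_cohort(cohort_config(pairs_per_arm = c(4, 3, 3),
                                        n_snps = 1000, mz_fraction = 0.5,
                                        genotype_error_rate = 0.01, seed = 600 + s))
    q <- qc_filter(co$calls, co$manifest)
    z <- zygosity_table(q$calls, co$pairs)
    hits <- hits + sum(z$zygosity == co$truth$zygosity)
    total <- total + nrow(z)
  }
  expect_equal(hits, total)
})
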
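Package: twinans
Title: Antenatal Steroid Responsiveness Analysis for Twin Lamb Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for antenatal steroid (ANS) responsiveness in
    ventilated preterm twin lambs. Provides control-referenced responder
    phenotyping from 30-minute ventilation physiology (PaCO2 cutoff at two
    standard deviations below the steroid-naive control mean, ventilation
    efficacy index), SNP-array quality filtering and twin zygosity calling by
    genotype concordance, a two-stage per-allele association scan (chi-square
    allele-frequency shortlist followed by sex-adjusted logistic regression
    with direction-of-association categorization), pair-level response
    concordance, generalized estimating equation (GEE) prognostic modelling
    with an exchangeable within-ewe working correlation, and
    limit-of-detection aware betamethasone pharmacokinetic summaries. A
    synthetic twin-cohort generator with full-sib Mendelian genotype sharing
    drives the whole pipeline so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
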
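---
title: "Methods: twin-lamb antenatal steroid responsiveness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-lamb antenatal steroid responsiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinans)
```

## The problem and the model

Antenatal steroid (ANS) therapy accelerates fetal lung maturation before
preterm birth, yet a large fraction of exposed fetuses derive little
measurable benefit. A twin design isolates the fetal contribution to that
variability: dizygotic twin lambs share a ewe, a placenta-side drug supply,
gestational age and an identical ventilation protocol, so within-pair
discordance in lung function cannot be explained by maternal or protocol
factors. `twinans` implements the five analysis stages such a study needs —
responder phenotyping, genotype QC and zygosity, allele association, twin
concordance with GEE prognostic modelling, and pharmacokinetic summaries —
plus a synthetic cohort generator that stands in for the (undeposited)
animal data.

### Responder phenotyping

Lung maturation is read out as arterial PaCO2 after 30 minutes of fully
standardized pressure-limited ventilation (PIP 35 cmH2O, PEEP 5 cmH2O, 50
breaths/min, 0.5 s inspiration): a mature lung clears CO2, an immature one
does not. The responsiveness threshold is derived from the steroid-naive
control arm as

$$\mathrm{cutoff} = \bar x_{\mathrm{ctrl}} - k\, s_{\mathrm{ctrl}},
\qquad k = 2,$$

with the sample SD (n − 1 denominator) over all controls of both sexes
pooled. A treated fetus responds iff its PaCO2 is *strictly* below the
cutoff; equality classifies as non-responder, because responders are
defined as more extreme than the 2-SD band. Note the rule, not any
particular printed cutoff value, is normative: the cutoff is always
recomputed from the raw control values supplied, and published
sex-stratified control moments pool to a slightly different constant than a
published cutoff would suggest (pooling 130.7 ± 28.3 (n = 12) and
129.1 ± 19.5 (n = 8) gives ≈ 130.1 − 2·24.6 ≈ 80.9), a discrepancy that
cannot be resolved without the raw data and that we deliberately do not
force. The ventilation efficacy index
`VEI = 3800 / (rate · (PIP − PEEP) · PaCO2)` is carried per fetus as a
secondary maturation measure.

`pooled_moments()` combines per-group summaries exactly as the
concatenated raw data would (within- plus between-group sums of squares
over N − 1), which is how the sex-pooled cohort moments are reproduced from
per-arm tables. Response rates are carried as exact fractions and rounded
only at report time.

### Genotype QC and zygosity

Calls arrive as abstract A/B allele pairs with a per-call GC confidence
score, and SNPs carry a GenTrain clustering-quality score. The filter keeps
SNPs with GenTrain > 0.7 and then calls with GC > 0.15, both strict, in
that order; it is idempotent and monotone in both thresholds. Zygosity is
called from post-QC genotype concordance over co-called SNPs (unordered
pair equality, AB ≡ BA), all chromosomes included: monozygotic iff
concordance > 0.9. Under full-sib sharing the expected concordance at one
SNP is

$$\tfrac14 + \tfrac12 (p^2+q^2) + \tfrac14 (p^4 + 4p^2q^2 + q^4)$$

(conditioning on 0/1/2 alleles IBD), i.e. 0.59375 at MAF 0.5 and 0.83215
at MAF 0.1 — comfortably below 0.9 on any informative panel, which is what
makes the threshold rule reliable; tests verify 100% classification
accuracy at 1000 SNPs under 1% call error. Concordance is computed
post-QC at genotype (not allele) level; the alternative conventions are
unstated in the field's reports, so this choice is documented rather than
configurable.

### Two-stage allele association

Stage 1 screens every SNP with a Pearson chi-square (1 df, no continuity
correction) on the 2×2 allele-by-phenotype table, each called fetus
contributing two alleles; SNPs with p < 0.01 (strict) are shortlisted.
Stage 2 fits, per shortlisted SNP, the additive sex-adjusted logistic model

$$\operatorname{logit} P(\mathrm{responder}) = \alpha + \beta\,d_B +
\gamma\, I(\mathrm{female}),$$

where $d_B$ is B-allele dosage (0/1/2), and declares significance at the
Wald p < 0.05 (strict). Each significant SNP is reported per allele: the
allele with positive log-odds is responder-associated and the opposite
allele non-responder-associated with the mirrored coefficient, so both
direction categories are emitted. Design choices worth flagging:

- **Additive dosage coding** per SNP-allele with sex as the only covariate
  reproduces the per-allele p-value structure of the study's final table;
  SNP×SNP interactions are not fitted.
- **No multiple-testing correction** beyond the two staged raw-p
  thresholds — faithful to the analysis being reimplemented, and the reason
  a null panel still yields a handful of "significant" SNPs (the null
  stage-1 pass rate is property-tested at 0.01).
- **Wald p-values** in stage 2 (the likelihood-ratio alternative would be
  a one-line change); complete separation is flagged and never reported as
  a significant hit.
- **X-linked SNPs in males** are taken as the diploid calls the chip
  format delivers, with no hemizygosity handling.

### Twin statistics

Pair response concordance is the fraction of treated pairs with equal
responder status. The prognostic model is a binary GEE with logit link,
clusters = ewes, exchangeable working correlation and robust (sandwich)
standard errors, on the pooled CS1+CS2 fetuses. No GEE solver is part of
this package's dependency set, so `gee_logit()` implements Fisher scoring
with Liang–Zeger moment estimation of the scale and correlation at each
step; it reduces to ordinary logistic regression for singleton clusters
(tested to 1e-6) and matches an independent reference GEE implementation
to ~1e-6 on a frozen fixture. Covariate coding is fixed and named in the
output: treatment CS2 vs CS1, sex female vs male, twin type MF/FF vs MM,
delivery order first vs second, so every odds ratio's direction is
unambiguous.

Drug concentrations are censored at the assay limits of detection
(plasma 0.5 ng/mL, lung 1 ng/g); a value exactly at the LOD is detected.
Below-LOD values are excluded from means (as "< LOD" reporting implies)
rather than imputed; half-LOD substitution is available behind
`analysis_config(lod_substitute = TRUE)`. The mean absolute within-pair
difference uses only pairs with both values detected and reports the
exclusion count.

## The synthetic cohort generator

The generator emulates the study design so that every stage has realistic,
truth-tagged input: 11/10/10 twin pairs in the CS1 (one maternal 0.25 mg/kg
betamethasone dose), CS2 (two doses) and saline-control arms — 31 ewes, 62
fetuses. Choices and defaults:

- **Genotypes.** Independent SNPs with B-allele frequency Uniform(0.1, 0.5)
  (a post-QC array panel rarely retains rarer variants, and the zygosity
  and association properties are exercised across this range). DZ pairs are
  full sibs: parental genotypes under Hardy–Weinberg, one transmitted
  allele each per sib; MZ pairs are one draw duplicated (`mz_fraction`
  defaults to 0 — sheep MZ twinning is rare and the study cohort was
  all-DZ). No linkage disequilibrium is modelled; this is a stated
  limitation, adequate because no analysis stage uses marker proximity.
- **Quality scores.** GenTrain ~ Beta(20, 4) (≈ 4% of SNPs fail the 0.7
  screen, a realistic array attrition) and GC ~ Beta(25, 3) (essentially
  all calls pass 0.15). Genotype error (symmetric single-allele flip per
  call) and missingness (call deletion) default to 0 and are switched on
  where a property needs them.
- **Response model.** logit P = β0 + βsex·I(female) + βorder·I(second) +
  Σ βk·dk. Defaults plant the study's reported prognostic effects,
  βsex = ln 7.786 and βorder = −ln 0.258, with β0 = −1.35 putting the
  marginal response rate near the observed ≈ 57%; no SNP effects are
  planted by default.
- **PaCO2 laws.** Controls N(130.1, 24.6²) mmHg — the pooled printed
  control moments. Responders N(60, 13²), non-responders N(120, 20²):
  centred on the most nearly status-pure printed strata (the CS2 female
  group, 9/11 responders, at 66.6; the CS2 male group, 3/9, at 114.1) with
  within-status SDs tighter than the printed mixture SDs. These laws sit
  ≈ 1.8–2 SD away from the ≈ 81 mmHg cutoff, so label noise from the
  cutoff rule is small (≈ 4–8%); that noise is what attenuates the
  recovered sex OR from the planted 7.79 toward ≈ 6–7 in the acceptance
  simulations.
- **Sex.** I.i.d. Bernoulli(1/2) per fetus (so MM/MF/FF ≈ 1:2:1, close to
  the observed 65% mixed pairs); `sex_pattern` can force exact pair types.
- **Pharmacokinetics.** One log-normal maternal plasma value per ewe
  (arm-specific laws matched to the printed maternal means/SDs ≈ 14.8/11.4
  and 7.8/2.2 ng/mL), multiplied per fetus by narrow log-normal
  fetal/maternal (≈ 0.17–0.21) and lung/plasma (≈ 13–17) ratios, so twins
  agree closely — as the printed within-twin absolute differences
  (5–15% of the mean) indicate. Controls carry zero drug and are fully
  censored. Only terminal concentrations are modelled; no time courses.
- **Within-pair outcome correlation** beyond shared covariates and shared
  genotype is not simulated (no ewe random intercept): the study's premise
  is precisely that the shared maternal compartment does not guarantee
  concordance, and the GEE is validated for correlated outcomes through a
  dedicated latent-intercept fixture instead.
- **Seeding.** One master seed; subsystem streams (structure, genotypes,
  scores, phenotypes, PK) are derived as
  `(seed·1009 + 97·stream) mod (2^31 − 1)`, so identical configs are
  bit-reproducible and subsystems can be re-run in isolation.

What passing tests on these cohorts do *not* show: robustness to linkage
disequilibrium, allele-frequency spectra with rare variants, non-Normal
PaCO2 physiology, informative missingness, or pedigree errors. The
generator is a design-faithful null/alternative machine, not a physiology
simulator.

## Numerical choices and degenerate inputs

- Thresholds are strict wherever the defining language is exclusive:
  GenTrain > 0.7, GC > 0.15, chi-square p < 0.01, logistic p < 0.05,
  concordance > 0.9 for MZ, PaCO2 < cutoff for responders. A value exactly
  at the LOD is detected (the LOD is the lowest reportable concentration).
- Chi-square tables with a zero marginal are flagged undefined and skipped,
  never tested; logistic fits with complete separation are flagged.
- The GEE clamps fitted probabilities to [1e-10, 1 − 1e-10], bounds the
  exchangeable correlation inside its feasible interval, and aborts with a
  warning (returning the last stable iterate) if a scoring step turns
  singular — which can happen on toy cohorts of a dozen pairs.
- The cutoff needs ≥ 2 control values; concordance needs ≥ 1 co-called
  SNP; pooled moments accept n = 1 groups (zero within-group variance).

## Problem sizes used in the checks

The packaged checks run the default 31-pair design at 5000 SNPs (the full
pipeline finishes in a few seconds), calibration and recovery properties at
250–500 treated pairs with 500–2000 SNPs over 10–20 seeded replicates, and
concordance oracles at 1000–2000 SNPs with 40–60 replicates. These sizes
put Monte-Carlo error well inside each property's tolerance (3 SE bands
where the quantity is stochastic) while keeping a full suite run around
half a minute.

## Known limitations

- No linkage disequilibrium, kinship beyond the sib pair, or
  genome-wide-scale inference machinery (the staged raw-p design is
  reproduced as-is, false positives included).
- The GEE assumes clusters of modest size (it inverts per-cluster
  correlation matrices densely) — ideal for twins, inefficient for very
  large clusters.
- Published group summaries can be reproduced from printed tables (pooled
  moments, response rates), but cohort-level headline numbers (the 52%
  concordance, the specific 13 SNPs) depend on undeposited raw data and are
  therefore covered by property-based recovery tests, not numeric
  reproduction.
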
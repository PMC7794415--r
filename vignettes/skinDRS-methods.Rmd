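---
title: "Composite skin-cancer risk scores: models, generator and design choices"
author: "skinDRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite skin-cancer risk scores: models, generator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinDRS)
```

## The analysis this package implements

skinDRS rebuilds, as reusable and tested R code, the full analysis path of a
case-control survey study of the three major skin cancers — basal cell
carcinoma (BCC), squamous cell carcinoma (SCC) and melanoma — in a cohort
aged 30–90:

1. **Genetics.** A per-variant logistic association scan of imputed dosages
   (age, sex and five ancestry principal components as covariates), the
   genomic-control inflation factor, greedy clumping-and-thresholding
   selection of variants for a polygenic risk score (PRS), and the analytic
   power of the additive association test.
2. **Risk-model building.** Phenotype imputation, a staged selection of
   survey risk factors by binomial GLM (logit link), a conservative scan of
   additional database phenotypes, the final per-cancer 32-factor-style
   models with polynomial age, deviance decomposition, variance-inflation
   and interaction diagnostics, and mixed-variable clustering for redundant
   candidate phenotypes.
3. **Risk scores.** The family-history score; six grouped scores
   (Demographic, Family, Mole, Susceptibility, Exposure, Miscellaneous); the
   global disease risk score DRS (all factors including PRS and age) and
   the age-free DRSA (the same weights with the age polynomial block
   removed, so `DRS − DRSA` is exactly the age contribution).
4. **Evaluation.** ROC/PR AUC, odds ratio per standard deviation,
   percentile binning with fold enrichment against the middle band, per-bin
   age of diagnosis, and score correlation/PCA/age-profile diagnostics.
5. **Trajectories.** DRSA-stratified lifetime risk curves, the
   prevalence-to-incidence transform
   $I_a = (P_a - P_{a-m})/(1 - P_{a-m})$, the survival-weighted expected
   age of diagnosis
   $m = \sum_a S_a I_a a / \sum_a S_a I_a$ with
   $SD = \sqrt{\sum_a S_a I_a (a-m)^2 / \sum_a S_a I_a}$ on the integer
   grid $a = 30..90$, and prospective follow-up validation (incident and
   cancer-free participants).

Because the cohort such a study uses is never public, the package is
exercised end-to-end against its own synthetic cohort generator, which is
first-class, tested code — every stage has ground truth to recover.

## The synthetic cohort generator

`cohortSimConfig()` encodes the study conditions. Defaults were fixed once,
from what such a survey cohort looks like, and are not tuned per analysis:

* **Ages** 30–90, discretized truncated normal centred at 58 (SD 13), so
  roughly half the cohort is 50–70; **sex** 60% female, males carry a
  1.6-fold hazard.
* **27 risk factors** (`defaultFactorCatalog()`) in four groups with sizes
  Mole 4, Susceptibility 8, Exposure 8, Miscellaneous 7. Directions follow
  the skin-cancer literature — dysplastic moles multiply melanoma risk by
  6.7, actinic keratosis before age 40 multiplies BCC/SCC risk by >3, red
  hair is the strongest pigmentation level — and magnitudes are generator
  truth, not estimates. Eleven factors are tagged `source = "database"`:
  they emulate phenotypes outside the baseline survey and reach the model
  only through the conservative additional-phenotype scan. BMI and weight
  are generated with correlation 0.93, which puts their variance inflation
  factors in the classical 7–8 band the collinearity diagnostics should
  tolerate.
* **Ordinal encodings.** Survey response scales are not standardized
  anywhere; ordinal factors use 3–4 plausible ordered levels drawn through
  a latent-logistic cut, and the levels are documented by their marginal
  probabilities in the catalog.
* **Baseline hazards** rise exponentially with age (4% per year) and are
  calibrated so cross-sectional prevalences land near 14% / 7% / 4% for
  BCC / SCC / melanoma — the case fractions of a 30–90 survey cohort.
* **Genotypes** are Hardy–Weinberg `Binomial(2, maf)` dosages, independent
  across variants except for explicitly configured correlated pairs used to
  exercise clumping; ten causal variants per cancer at allelic odds ratios
  near 1.2 by default.
* **Missingness** is completely at random, 5% per factor column (within
  the 2–15% band typical of survey questions). **Follow-up** is two yearly
  waves with a 56% response rate; baseline cases report treatment with
  probability 0.30 per wave.
* **Family history** indicators (father, mother, ≥1 sibling, ≥1 child) are
  drawn with probability increasing in the participant's own summed linear
  predictor — a shared-risk proxy that makes the family-history score
  informative without simulating pedigrees.

### The disease mechanism, and why there are two

Each participant carries a per-cancer linear predictor `lp` (centred factor,
sex and genotype contributions). Disease arises from a yearly diagnosis
process between age 30 and the current age; the first success fixes case
status and the age at diagnosis, giving trajectories, incident cases and
onset ages a common ground truth. Two hazard parameterizations are
available:

* `"logit-cumulative"` (default): the cumulative incidence by age $a$ is
  $P(a \mid lp) = \mathrm{logit}^{-1}\!\big(\mathrm{logit}(P_0(a)) + lp\big)$,
  with $P_0$ the baseline cumulative incidence, and the yearly hazard is
  derived as $(P(a) - P(a-1))/(1 - P(a-1))$.
* `"hazard"`: the yearly hazard is $h_0(a)\,e^{lp}$ clipped to $[0,1]$
  (proportional hazards), with a warning if clipping touches more than 1%
  of person-years.

The two agree closely at low prevalence, and both reduce exactly to
$P(a) = 1-(1-h)^{a-30}$ under a constant baseline hazard with zero effects.
The logit-cumulative form is the default because it is *exactly* consistent
with the model class fitted downstream: a cross-sectional logistic
regression of case status on the factors given age then has true
coefficients equal to the generator's `lp` weights at every age. Under the
multiplicative-hazard form the cross-sectional logistic estimand is inflated
by 5–10% for large effects in a 14%-prevalence outcome (the age-specific
log odds ratios grow with cumulative risk), which is a property of the
estimand, not an estimation error; parameter-recovery checks would then
test the gap between two model classes rather than the implementation. The
multiplicative form remains available and tested for users who want
proportional-hazards truth.

### What the recovery experiment isolates

The end-to-end recovery check (20 seeds, n = 50,000 each) runs generation,
stage-1 selection and the final per-cancer fits, and compares every
coefficient with generator truth. Three default features are switched off
there because each one *changes the estimand* away from the generative
coefficients rather than degrading estimation:

* missingness (imputed values attenuate the coefficient of the imputed
  column toward zero by roughly the missing fraction);
* genotype effects (the fitted factor model omits the per-variant score, and
  logistic regression is non-collapsible over omitted risk);
* the family-history column (family history is generated *from* the
  participant's risk, so conditioning on this descendant of the exposure
  biases the direct factor effects).

Each mechanism is separately exercised by its own tests; the recovery
experiment's job is to certify the selection + fitting machinery, and under
the isolated conditions the 95% Wald intervals cover truth for well over
90% of coefficients, including the planted melanoma dysplastic-mole log
odds ratio $\ln 6.7$.

### What the generator does not emulate

Real linkage disequilibrium (only configured pairwise correlation),
population stratification drift over enrollment time, informative
missingness or informative follow-up non-response, pedigree structure,
survey measurement error and recall bias, and competing mortality during
follow-up. Passing tests therefore certify the statistical machinery under
clean MCAR/random-response conditions, not robustness to those real-data
pathologies.

## Numerical and design choices

* **Stage-1 selection** is at the factor level: a factor survives if any of
  its design columns has Wald p < 0.05, and the kept set is the union over
  the three cancers. Demographics (age, sex, ancestry) and family history
  are never dropped. The additional-phenotype scan uses p < 1e-8 in at
  least one cancer, a Bonferroni-scale guard for several hundred
  candidates.
* **Polynomial bases.** Continuous factors use orthogonal polynomials
  (orthonormal on the training sample), degree 2 by default, raised to 3 or
  4 by sequential likelihood-ratio tests at p < 0.01; age uses degree 3.
  The training basis (and categorical reference levels, chosen as the most
  frequent level) is stored in the design recipe and re-applied verbatim to
  validation participants, so no validation information enters the design.
* **Clumping** defaults: 250 kb window, r² ≤ 0.1, p ≤ 1e-6 — standard
  practice; ties in p break by (chromosome, position) so selection is
  order-invariant.
* **Power.** The additive-test power uses the two-sided Wald
  non-centrality approximation with Woolf variance
  $1/(2 n_{case} \bar p(1-\bar p)) + 1/(2 n_{ctrl} p(1-p))$, where
  $\bar p = \mathrm{OR}\,p/(1-p+\mathrm{OR}\,p)$ is the case allele
  frequency implied by the odds ratio. A 10,000-replicate simulated Wald
  test agrees with it to better than 0.02; against published design-stage
  power figures a tolerance of ±0.05 is documented, since power methods
  differ across tools.
* **Percentile bins** are rank-based with stable tie-breaking by input
  order; bin sizes differ by at most one. Fold enrichment is taken against
  the middle band, bins 48–53 (the 47.5–52.5 percentile band),
  configurable. Any report cell derived from fewer than 5 participants is
  masked.
* **Lifetime risk** uses the retrospective estimator
  $\hat P_a = \#\{\text{cases with } \mathrm{dx} \le a,\ \text{age} \ge a\} /
  \#\{\text{age} \ge a\}$ per stratum — a modelling decision, since
  cross-sectional reports do not fix one estimator — smoothed by weighted
  pool-adjacent-violators isotonic regression (risk-set weights), which
  guarantees the monotonicity a cumulative risk must have and makes the
  derived incidence non-negative by construction; residual numerical
  negatives clamp to zero with a warning.
* **Survival table.** A synthetic Gompertz schedule
  (`defaultSurvivalTable()`, also shipped as
  `inst/extdata/synthetic_survival.tsv`) stands in for a national
  all-cause survival table so nothing needs downloading; any user table is
  accepted through `readSurvivalTable()`.
* **Follow-up concordance** pools person-waves: every answered wave of a
  still-disease-free baseline control contributes one one-year at-risk
  window, and the expected rate averages the trajectory-derived yearly
  incidence over exactly those windows. This keeps the observed rate
  unbiased under random wave non-response; comparing a fixed two-year
  expectation against partially-observed windows would undershoot
  systematically. A consequence worth knowing: if instead the response rate
  is forced to 1, the expected curve's own estimation noise is no longer
  small against the observed binomial interval, and "expected inside the
  observed CI" saturates near 84% no matter how large the cohort — the
  concordance check is run at the default 56% response.
* **Scores** omit the intercept: they are used only through ranks,
  percentiles and z-scales, so location is irrelevant. Standardization
  constants (mean, SD) always come from the training set and are recorded
  in the `ScoreSet`. DRSA removes only the age block; sex and ancestry
  stay.
* **Stage masking and determinism.** All randomness derives from one seed;
  the generator, imputation donors and the random split use fixed named
  offsets of it, so identical configuration + seed reproduces every
  artifact byte for byte.

## Problem sizes used by the test suite

Unit tests run at n = 200–50,000 as each property requires. The
criterion-level suite uses: 20 seeds × n = 50,000 for parameter recovery;
n = 50,000 for the DRSA age-independence check (|Spearman| < 0.05); 120
replicates × 10 noise factors × 3 cancers for stage-1 type-I calibration
and 1,000 null replicates for the interaction LRT; 20 seeds × n = 20,000
with two follow-up waves for incidence concordance; 10,000 simulated Wald
tests for the power oracle; and 100–150 randomized instances for the
AUC/GLM/clumping oracle equivalences. The complete suite runs in about
three minutes on one CPU.

## Known limitations

* The per-variant scan refits a full GLM per variant; it is meant for
  panels of 10²–10⁴ variants, not genome-wide data.
* The mixed-variable clustering is O(k³) in the number of candidate
  variables — intended for the few dozen survivors of the conservative
  scan, not for screening itself.
* `classifyFollowup` trusts self-report: a baseline case reporting a
  "first" diagnosis is flagged contradictory and counted as a persistent
  case rather than adjudicated.
* Competing risks are handled only through the survival weighting of
  expected onset ages; the lifetime-risk curves themselves are
  net-of-mortality cumulative report probabilities.
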
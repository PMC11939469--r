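---
title: "Methods: residual feed intake, repeatability and mixed-model GWAS in rfiflock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residual feed intake, repeatability and mixed-model GWAS in rfiflock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfiflock)
```

## The problem

Feed is the dominant cost of keeping a ewe flock, and animals of the same
size and growth rate can differ substantially in how much they eat.
Residual feed intake (RFI) isolates that difference: it is the residual of
a regression of observed intake on the intake predicted from body size and
growth, so by construction it is uncorrelated with both. A ewe with RFI of
−0.2 kg DM/day eats 200 g less dry matter per day than expected at her
size and gain.

`rfiflock` implements the full analysis for a two-period design in which
the same ewes are measured once as growing lambs and again as yearlings
near maintenance: trait derivation from the longitudinal records, the
within- and between-period correlation structure, repeatability of RFI
across physiological state, and a mixed-model genome-wide association
scan. Because trials like this involve tens, not thousands, of animals,
every statistical choice below is made with small-sample behaviour in
mind.

## Trait derivation

Per animal and period:

* **ADG** (kg/day) is the slope of an ordinary least-squares regression
  of body weight on day. Weekly weighings over a 42-day window give 7
  points; OLS smooths scale error (gut fill, handling) rather than
  differencing first and last weights.
* **MTBW** (kg) is the regression's fitted value at the window midpoint,
  day 21 — more stable than any single weighing.
* **MBW** = MTBW^0.75 (kg^0.75), the allometric scaling of maintenance
  energy demand.
* **DMI** (kg DM/day): as-fed intakes are multiplied by the diet
  dry-matter fraction (0.906 for the growth-period pellet, 0.897 for the
  maintenance hay), regressed on day, and read off at the window
  midpoint. Under a balanced recording schedule this equals the plain
  mean (a `method = "mean"` switch forces the mean); the midpoint form
  is the natural analogue of MTBW and is robust to missing days at one
  end of the window. Days with no recorded feeding are treated as absent
  observations, never zeros — the feeder logs disappearance only when an
  animal eats, so imputing zero would bias DMI down.

Animals with fewer than two weight or intake observations in a period are
excluded from that period with an itemized reason; nothing is dropped
silently.

## The expected-intake model and RFI

Within each period separately,

$$\mathrm{DMI}_i = b_0 + B_1\,\mathrm{MBW}_i + B_2\,\mathrm{ADG}_i + e_i,$$

fitted by multiple OLS with intercept, and RFI is the residual $e_i$. The
cohort mean RFI is exactly 0 and RFI is exactly uncorrelated with MBW and
ADG — these are OLS identities, and the test suite asserts them to 1e-10
on every fit. A useful corollary, also asserted: the sample correlation
between DMI and RFI equals SD(RFI)/SD(DMI).

Metabolic weight, not raw MTBW, is the body-size regressor (the standard
Koch-style choice; the allometric exponent makes the coefficient
interpretable as kg DM per kg^0.75 of metabolic size). A
`size_regressor = "MTBW"` switch exists for sensitivity analysis; with
MTBW and MBW correlated above 0.999 in cohorts this tight, the choice
barely moves the residuals. The two periods are fitted with entirely
separate coefficients: the animals differ in physiological state and the
diets differ in form, so pooling would force one price of metabolic size
on both. No breed term is included by default; the panel's two breeds are
similar, and the GWAS handles structure through the relationship matrix.

## Correlations, period comparison, repeatability

Within- and between-period trait correlations are Pearson coefficients on
pairwise-complete observations with two-sided t-based p-values, flagged at
p < 0.05. Period comparisons use the Welch unequal-variance two-tailed
t-test: the trait SDs differ up to four-fold between periods, where a
pooled test would be miscalibrated.

Repeatability — the fraction of variance attributable to permanent
between-animal differences — comes from the one-way random-intercept
model `value ~ 1 + (1 | animal)` fitted by REML (via `lme4`), with
$R = \sigma^2_{animal} / (\sigma^2_{animal} + \sigma^2_{residual})$.
For balanced two-period data this equals the classical one-way ANOVA
intraclass correlation, and the tests assert agreement with a
mean-squares oracle to 1e-6. Uncertainty is a parametric bootstrap: 1,000
datasets resimulated from the fitted variances on the observed design,
refitted, SE and 95% percentile CI taken from the bootstrap distribution.
Boundary fits ($\sigma^2_{animal} \to 0$) return R = 0 rather than
failing. Raw RFI values enter by default even though the two periods'
variances differ (≈0.24 vs ≈0.97 kg DM/day); that imbalance shrinks R,
so a `standardize = TRUE` option z-scores within period first — the two
options answer different questions, and the default matches how the
estimate is usually reported.

## Genotype QC, GRM, and the mixed-model scan

QC order is fixed and logged: multi-allelic SNPs, then SNP call rate
< 0.90, then individual call rate < 0.90 (over surviving SNPs), then
minor allele frequency < 0.05 recomputed on retained individuals. All
removals are strict inequalities — a SNP at exactly 0.90 call rate or
0.05 MAF is kept. The order matters because removing individuals shifts
borderline MAFs; fixing it makes the report reproducible.

Dosages are minor-allele counts with missing calls imputed at the SNP
mean (which preserves the allele frequency exactly and keeps one spectral
transform valid for all SNPs). The genomic relationship matrix is
VanRaden method 1, $K = ZZ'/(2\sum_j p_j(1-p_j))$ with observed-frequency
centering — the construction standard behind EMMAX-style pipelines; the
builder is a plain function and swappable.

The association model is $y = X\beta + g_j\alpha_j + u + \varepsilon$
with $u \sim (0, \sigma^2_g K)$. Variance components are estimated once
under the null (no SNP) by REML: with $\delta = \sigma^2_e/\sigma^2_g$,
the likelihood profiled over $\beta$ and $\sigma^2_g$ is one-dimensional
in $\log\delta$ and is maximized by a 100-point grid scan refined with
Brent's method on the bracketing interval; the eigendecomposition of K is
computed once. Boundary solutions (no genetic variance) are returned, and
then every per-SNP test reduces exactly to OLS — asserted in the tests.
Each SNP is then tested by generalized least squares under the fixed
covariance (the EMMAX approximation), implemented as one rotation of y, X
and the dosage matrix by $\mathrm{diag}(\lambda_i+\delta)^{-1/2}U'$
followed by vectorized residualization, so a 5,000-SNP scan is a handful
of matrix products. Inference uses the exact t distribution with
$n - \mathrm{rank}([X|g])$ degrees of freedom — at n ≈ 67 the normal
approximation is visibly anticonservative. SNPs collinear with the
covariates get effect 0, p = 1 and a degenerate flag. Significance is
Bonferroni at family-wise 0.05; the headline model uses MTBW as the
fixed covariate. Hits are reported with ±1 Mb candidate windows as
coordinates only — no gene database is queried.

The scan is verified three ways: against a dense-GLS oracle with an
explicit covariance inverse (agreement to 1e-6 in −log10 p), by
parameter-recovery simulations for the variance components, and by a
type-I-error calibration check (empirical rate at α = 0.01 across
thousands of null SNPs within 3 binomial SE).

## What the synthetic flock emulates — and what it does not

The generator is the package's ground truth and its defaults are the
study conditions, chosen once:

* **Panel**: 81 ewes of two breeds, 5,000 SNPs on 26 autosomes (a
  desk-scale stand-in for a 50k chip panel), Balding–Nichols breed
  divergence Fst = 0.05, ancestral MAF uniform on [0.05, 0.5].
* **Design**: 42-day periods, weekly weighings, daily intakes; 74
  animals complete period 1 and 70 of those period 2, attrition uniform
  at random.
* **Growth**: period-1 ADG 0.26 ± 0.12 kg/day and initial weight set so
  mid-test weight is 27.8 ± 4.39 kg; period 2 ADG −0.02 ± 0.16 and
  mid-test weight 42.9 ± 7.10 kg. True initial weights correlate 0.7
  between periods — the same ewes return, ranked much the same.
* **Intake**: true daily DMI follows the expected-intake model with
  coefficients derived in closed form from the trait moments: with
  SD(MBW) ≈ 1.43 kg^0.75 in period 1 and 2.07 in period 2, B1 = 0.18
  and 0.33 (with B2 = 1) make the fitted-intake SD plus the residual SD
  reproduce each period's total DMI SD (0.38 and 1.19 kg DM/day);
  intercepts −0.42 and −3.49 centre mean DMI at 2.01/2.02. Daily intake
  is truncated at zero (an animal cannot eat a negative amount), which
  slightly shrinks realized period-2 variance in the extreme tail.
* **RFI**: per-period SDs 0.24 and 0.97 kg DM/day; a shared fraction
  0.157 of each period's variance — simultaneously the between-period
  correlation of true RFI and the target repeatability — decomposed
  into polygenic (50%, drawn as $K^{1/2}z$ so the GWAS null structure
  is exactly what the mixed model assumes; the symmetric square root
  clips negative eigenvalues at 0), causal-SNP (25%, one random SNP
  with MAF ≥ 0.1) and permanent-environment (25%) parts.
* **Noise**: weighing error SD 0.5 kg and day-to-day intake noise SD
  0.15 kg DM; nothing in the source design states these, and they were
  fixed once at values that leave derived-trait SDs near the trial's,
  exposed in `sim_config()`.
* **Covariates**: the post-weaning-weight EBV is simulated as true
  initial weight plus noise (multiplier 2.05 on the weight SD),
  giving corr(MTBW, EBV) ≈ 0.44 in period 1 and, through the weight
  correlation, ≈ 0.31 in period 2 — while remaining uncorrelated with
  RFI by construction.

Deliberately not emulated: linkage disequilibrium beyond breed structure,
pen and bunk effects, selection, pedigree, and the behavioural
adaptation-failure criterion that removes poorly adapting lambs (the
simulator's attrition is uniform). Passing tests therefore demonstrate
that the estimators recover the truth of *this* generative model at the
study's scale — they cannot certify behaviour under feeder malfunction,
pen competition, or LD-induced multi-SNP signals.

## Numerical choices

* All OLS fits go through QR; the intake model refuses condition numbers
  above 1e12 (singular-fit error) and fewer than 4 animals.
* REML grid for $\log\delta$ spans [−10, 10]; Brent tolerance 1e-10; a
  grid-edge optimum is kept as a boundary solution.
* GRM eigenvalues are clipped at 0 before the square root and the
  spectral transform; PSD is asserted to −1e-8 × max eigenvalue.
* Minor-allele orientation ties at frequency 0.5 break alphabetically;
  the text reader derives orientation from the data while the binary
  reader trusts the accompanying `.bim`, which is what makes the binary
  write/read cycle lossless.
* Repeated-measure bootstraps and the flock simulator consume explicit
  seeds; `repeatability()` touches the RNG stream only when given one.

## Problem sizes

The shipped analysis scripts and test suite run the full pipeline at
n = 81 animals × 5,000 SNPs, the scan oracle at n = 60 × 100, the
calibration check at n = 67 × 3,000 null SNPs, and repeatability recovery
at 100 replicates of 70 × 2 — sizes chosen to exercise the small-n
regime the method targets while keeping a complete run in well under a
minute per stage.

## Known limitations

* The EMMAX approximation holds variance components fixed across SNPs;
  for a SNP explaining a large variance fraction the exact per-SNP REML
  (GEMMA-style) gives slightly different p-values. At trial scale the
  approximation error is far below the Bonferroni margin.
* With n ≈ 70, repeatability estimates have SE ≈ 0.11 near R = 0.157
  and truncation at 0 inflates the mean estimate slightly; the
  parametric bootstrap reflects both.
* The generator's equal-block SNP placement and independent loci make
  the Manhattan layout simpler than a real chip's.
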
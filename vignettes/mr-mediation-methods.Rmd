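---
title: "Methods: two-sample MR with metabolite mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with metabolite mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediation)
```

## The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure (here: a circulating protein or metabolite) on an outcome (here: a
binary disease such as ulcerative colitis) from two independent GWAS
summary-statistic tables, using genetic variants as instrumental variables.
The mediation layer asks how much of an exposure's total effect on the
outcome flows through an intermediate trait: a two-step MR design estimates
the exposure-to-mediator effect $\beta_1$ and the mediator-to-outcome
effect $\beta_2$ with separate instrument sets, and decomposes the total
effect $\beta_t$ into an indirect part $\beta_1\beta_2$ and a direct part
$\beta_t - \beta_1\beta_2$.

This vignette records the modelling choices, defaults and numerical
conventions the package commits to, and what its synthetic validation
studies do and do not demonstrate.

## Harmonization

Exposure and outcome effects must refer to one effect allele per variant.
For each shared variant id the package:

1. keeps rows whose allele pairs match in the same orientation;
2. sign-flips the outcome beta and mirrors its allele frequency
   (`eaf := 1 - eaf`) when the orientation is swapped;
3. applies a strand complement first when the pairs match only after
   complementing (non-palindromic variants; both inputs are assumed
   forward-stranded, complement matching is the fallback);
4. treats palindromic variants (A/T, C/G) by allele frequency alone, since
   their labels cannot resolve strand: a palindrome is dropped when either
   side's effect-allele frequency lies inside the ambiguity window
   `[0.40, 0.60]` (endpoints inclusive - the conservative reading of
   "between") or is missing; otherwise the orientations are chosen so both
   frequencies fall on the same side of 0.5;
5. drops indels, multi-allelic records and irreconcilable pairs as
   incompatible.

Every shared variant receives an audit label
(`kept`/`flipped`/`palindrome_aligned`/`dropped_*`), so
$|\mathrm{retained}| + |\mathrm{dropped}|$ always equals the overlap count.
Missing frequency on a non-palindromic variant is tolerated (alignment uses
alleles alone). No liftover or proxy lookup is attempted: an empty overlap
is an error, because it almost always signals mismatched id schemes or
genome builds rather than genuinely disjoint GWAS.

## Instrument selection

* **p-value threshold** `1e-5`, strict inequality - the conventional
  relaxed threshold for molecular traits, where genome-wide significant
  hits are often too few.
* **Greedy LD clumping** at r² < 0.001 within ±1000 kb: repeatedly take
  the lowest-p unclaimed variant as an index and discard unclaimed
  variants on its chromosome within the window at r² at or above the
  threshold. Ties in p break by (chrom, pos, id) so results are
  reproducible. The LD matrix is an input (square or long TSV); the
  package does not compute LD from reference genotypes.
* **Confounder exclusions** are consumed as a plain variant-id list; the
  upstream lookup (e.g. a PhenoScanner-style scan) is out of scope.
* **Instrument strength**: per-variant variance explained is computed from
  the observed t-statistic, $r^2 = t^2/(t^2 + n - 2)$, because this needs
  only fields guaranteed present (beta, SE, n) and is exact for
  least-squares fits of continuous traits; the F statistic is
  $F = r^2 (n-2) / (1-r^2)$ and instruments with $F < 10$ are removed
  (boundary kept). Weak instruments are filtered, not re-estimated.
* **Steiger directionality**: a variant should explain more variance in
  the exposure than in the outcome. Correlations $r = \sqrt{r^2}$ are
  Fisher-transformed and compared by a z-test with variances $1/(n-3)$; a
  variant is excluded only when the outcome-side $r^2$ is larger *and*
  the difference is significant at $\alpha = 0.05$ - a non-significant
  reversal is retained, reading the exclusion rule literally.

## Estimators

All estimators work on per-variant Wald ratios
$\hat\theta_j = \beta_{out,j} / \beta_{exp,j}$ with first-order delta
standard errors $se_j = se_{out,j}/|\beta_{exp,j}|$ (exposure-side
uncertainty ignored, as is standard in two-sample practice; a second-order
correction is available behind a flag).

* **IVW**: the inverse-variance weighted mean. Fixed effects:
  $\hat\theta = \sum w_j \hat\theta_j / \sum w_j$,
  $se = (\sum w_j)^{-1/2}$, $w_j = 1/se_j^2$. Heterogeneity by Cochran's
  Q with $I^2 = \max(0, (Q - df)/Q) \times 100$. Under the default
  `model = "auto"`, random effects are used when the Q p-value is below
  0.05 *or* $I^2 > 25\%$; the between-variant variance $\tau^2$ is
  estimated by REML (fixed-point iteration from a DerSimonian-Laird
  start, tolerance 1e-10, 100-iteration cap) and enters the weights as
  $1/(se_j^2 + \tau^2)$. A single instrument degrades to a Wald fit.
* **MR-Egger**: weighted least squares of outcome on exposure effects
  *with* intercept, weights $1/se_{out}^2$, after orienting rows so
  $\beta_{exp} \ge 0$; the intercept is the directional-pleiotropy test.
  Standard errors carry a multiplicative residual-variance inflation
  floored at 1.
* **Weighted median**: order ratios, form standardized cumulative weights
  $s_j = (\sum_{i\le j} w_i - w_j/2)/\sum w$, and linearly interpolate the
  ratio at $s = 0.5$; consistent when valid instruments carry at least
  half the weight. Its SE is a parametric bootstrap (default 5000
  replicates, each ratio redrawn from a normal with its own SE) under an
  explicit seed (default 20250912) so results are reproducible. Note a
  boundary subtlety of the interpolation convention: an instrument
  holding just over half the weight pins the estimate to its ratio
  exactly only when the flanking weight is balanced; the estimate is
  otherwise an interpolation toward its neighbour.
* **MR-PRESSO**: the observed residual sum of squares
  $\mathrm{RSS} = \sum_j (\beta_{out,j} - \hat\beta_{(-j)}\beta_{exp,j})^2
  / se_{out,j}^2$ (leave-one-out fixed-effects IVW predictions) is
  compared against parametric simulations that redraw both effect columns
  from their standard errors; the global p-value uses the add-one Monte
  Carlo correction, so it is never exactly zero and is valid at finite
  simulation counts. Per-variant outlier p-values come from the simulated
  distribution of each residual term, Bonferroni-adjusted over the
  instrument count; flagged outliers are removed and the IVW estimate is
  refitted. The distortion test compares the raw-minus-corrected contrast
  against random outlier-sized subsets. It is reported but drives no
  automatic decision; the screening gates use the corrected estimate
  whenever at least one outlier is flagged. The parametric redraw of the
  exposure column makes the global test mildly conservative by
  construction, consistent with the original procedure. Default 10,000
  simulations; all randomness flows through one seeded generator.
* **Leave-one-out**: k IVW refits, model choice re-evaluated per fit;
  flags single-variant-driven signals.
* **Odds ratios**: binary-outcome effects are log-odds, so
  $\mathrm{OR} = e^\beta$ with Wald limits at the exact normal quantile
  (not 1.96 rounded).

## Mediation

With stage fits $(\beta_1, se_1)$, $(\beta_2, se_2)$ and a total effect
$(\beta_t, se_t)$:

* indirect effect $\beta_1\beta_2$, Sobel standard error
  $\sqrt{\beta_1^2 se_2^2 + \beta_2^2 se_1^2}$, two-sided normal test
  ($z$ defined as 0 with $p = 1$ when both coefficients vanish);
* direct effect $\beta_t - \beta_1\beta_2$ (the decomposition is exact by
  construction);
* proportion mediated $\beta_1\beta_2/\beta_t$, with a delta-method SE
  treating product and total as independent - justified because they come
  from different instrument sets, and stated as an approximation.
  Negative proportions are legal (the indirect path opposes the total
  effect) and proportions beyond ±100% are reported untruncated with an
  inconsistent-mediation ("suppression") flag.

$\beta_2$ is deliberately the *univariable* mediator-on-outcome estimate
and $\beta_t$ the forward IVW estimate; multivariable adjustment is out of
scope. When the total-effect SE is unavailable (as when reconstructing
published tables from printed point estimates) the proportion is reported
without a confidence interval.

## Screening cascade

`mr_screen()` runs, per exposure: p-value selection, optional clumping,
exclusions, harmonization, Steiger filtering, weak-instrument removal,
then the full estimator suite. A signal passes when the IVW p-value beats
`screen_alpha` (0.05), the IVW / weighted-median / PRESSO-corrected
estimates agree in sign, and every leave-one-out estimate keeps that sign.
The default leave-one-out gate is lenient (sign stability only), because
demanding retained significance from every subfit would conflate
robustness with power; a strict mode is available. Bonferroni adjustment
over the exposure panel (family size configurable, e.g. 91) is reported
descriptively, not used as a gate. Mediation is attempted for (passing
exposure, passing mediator) pairs whose exposure-to-mediator IVW estimate
is itself significant. `run_pipeline()` writes per-stage TSV reports,
variant-level Wald-ratio tables for external plotting, and a JSON manifest
with counts at every gate; reruns under one seed are byte-identical.

## The synthetic generator

`sim_truth()` fixes the complete ground truth; `simulate_pair()` and
`simulate_mediation()` draw individual-level data and emit only summary
statistics, mimicking the two-sample setting with non-overlapping samples.

* Genotypes are Hardy-Weinberg binomials, independent across variants by
  default; an optional block-LD mode draws alleles from correlated AR(1)
  latent Gaussians and returns the *empirical* r² matrix of the generated
  exposure sample, so the LD input handed to clumping is exactly
  consistent with the data.
* The exposure is standardized; per-variant variance shares are drawn
  uniformly from `r2_range` (default 5e-4 to 2e-3, i.e. per-variant F of
  roughly 25-100 at n = 50,000 - strong but realistic molecular-trait
  instruments under a relaxed selection threshold).
* **Binary outcomes use a logistic liability**: linear predictor plus
  standard-logistic noise, thresholded at the empirical prevalence
  quantile, with per-variant effects estimated by logistic score tests.
  This makes the generator's outcome-effect parameters genuinely log-odds
  per SD, so the estimators' recovery of `theta` can be judged on one
  scale (a normal liability would introduce a scale factor of roughly
  1.6 between the generative parameter and the estimable log-odds
  effect). The marginalization over the remaining genetic variance leaves
  only a sub-percent attenuation at the simulated effect sizes.
* The default outcome sample is a balanced case-control design
  (prevalence 0.5), the desk-scale stand-in for a disease GWAS; a
  population-cohort prevalence (~1.4% for ulcerative colitis) at
  n = 50,000 would leave too few cases for meaningful instrument-level
  power and belongs to much larger cohorts than these studies simulate.
* The mediation generator uses separate instrument blocks for exposure
  and mediator; exposure variants reach the mediator only through the
  causal path, so p-value selection on the mediator GWAS recovers
  (almost) only mediator-specific instruments at the default effect
  sizes. Defaults $\theta_{xm} = 0.3$, $\theta_{my} = 0.4$,
  $\theta_{direct} = 0.08$ give a total effect of 0.2 and a true mediated
  proportion of 0.6.
* Reverse-causal instruments (for directionality studies) affect the
  outcome's genetic component directly and reach the exposure through an
  outcome-to-exposure path (default 0.3); their variance explained
  (default 1e-3 to 3e-3) is drawn larger than the exposure instruments',
  reflecting that reverse contamination in practice comes from the
  outcome GWAS's own hits.

What the generator does **not** emulate: realistic LD from reference
panels, population stratification, sample overlap between the two GWAS,
imputation quality, winner's-curse bias from discovery-replication
asymmetries, and effect heterogeneity across ancestries. Passing
calibration studies on these simulations therefore demonstrates the
estimators' internal correctness and calibration under their stated
assumptions - not robustness to the full messiness of real GWAS.

## Validation study sizes

The packaged studies (mirrored in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) use: 500 replicates of 30 instruments at
n = 50,000/50,000 for IVW bias, coverage and type-I error; 100 seeded
runs of the 29+1 outlier fixture and 400 homogeneous-null replicates at
1,000 Monte-Carlo draws for MR-PRESSO (scaled down from the 10,000-draw
default, which is the analysis-time recommendation); 200 replicates at
n = 100,000 per trait for mediation recovery plus 150 null replicates for
the Sobel level; and one 500-instrument, n = 100,000 directionality study
with 10% reverse-causal variants. The Sobel null check allows two
binomial Monte-Carlo standard errors above the nominal level: with a
strongly significant second stage the Sobel statistic is asymptotically
standard normal, so its true size sits just below 0.05 and a hard cutoff
on a finite-replicate estimate would fail a correct implementation about
half the time.

## Numerical conventions

* P-values are floored at the smallest positive double, never exactly 0,
  keeping every emitted table valid under the (0, 1] contract.
* All Monte-Carlo p-values use the add-one correction.
* Seeds: every stochastic routine takes an explicit seed (package default
  20250912), uses one local RNG stream, and restores the caller's RNG
  state. Derived per-trait seeds are spaced deterministically below
  2^31.
* Clumping tie-breaks, TSV serialization (shortest round-trip floats) and
  manifest JSON are all deterministic, which is what makes the
  byte-identical rerun guarantee testable.

## Limitations

Correlated instruments are not supported (no generalized IVW); mode-based
and robust/penalized estimators are out of scope, as are multivariable MR
and bootstrap mediation intervals. The proportion-mediated CI assumes
independence of the product and total estimates. Real-data idiosyncrasies
listed above are not simulated; results on real GWAS should always be read
alongside the heterogeneity, pleiotropy and directionality diagnostics the
package reports.
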
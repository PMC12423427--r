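---
title: "Structure-function coupling in WMH cohorts: models and methods"
author: "wmhcoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-function coupling in WMH cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhcoupling)
```

## The scientific problem

White matter hyperintensities (WMH) are a hallmark of cerebral small
vessel disease. They damage white-matter tracts, yet many patients with
mild lesion loads keep normal cognition, which suggests a compensatory
reorganization that neither structural nor functional connectivity alone
captures. Structure-function (SC-FC) coupling measures how tightly a
region's functional interactions follow its anatomical wiring, and is the
quantity this package estimates, aggregates, and relates to lesion burden
and cognition.

The inputs are, per subject, a structural connectome (probabilistic
tractography connection probabilities $w_{ij}$: streamlines seeded in
region $i$ that reach region $j$, divided by the number sampled from
$i$), and a functional connectome (Fisher $z$-transformed Pearson
correlations between regional BOLD time series), both on a 400-parcel
cortical scheme grouped into seven canonical resting-state networks
(FPN, DAN, DMN, LMN, SMN, VAN, VIN).

## The coupling statistic

For region $i$ with structural profile $\{w_{ij}\}_{j \ne i}$ and
functional profile $\{z_{ij}\}_{j \ne i}$, ROI-wise coupling is the
Spearman rank correlation over the selected edges,

$$\rho_i \;=\; \mathrm{Spearman}\bigl(w_{i\cdot},\, z_{i\cdot}\bigr)
\quad \text{over } \{j : w_{ij} > 0\},$$

with midranks for ties. Network coupling is the arithmetic mean of the
defined member $\rho_i$. A rank correlation is used because tractography
weights are heavily skewed and the relation between the two profiles is
not assumed linear.

Choices that were genuinely open, and how they were settled:

* **Edge selection.** "Nonzero components of both matrices" is ambiguous
  when FC is continuous: an exact zero in FC is a measure-zero event, so
  selecting on it would make results seed-dependent in simulation. The
  default `sc_nonzero` policy selects on SC only; `both_nonzero` is
  available as an option.
* **SC directionality.** Tractography matrices are directed. The default
  ROI profile is the outgoing row $w_{i\cdot}$, matching the seed-region
  definition of the weights; `sc_mode = "symmetrized"` uses
  $(w_{ij}+w_{ji})/2$. Within-network SC averages ordered pairs, which
  equals the mean of the symmetrized matrix, so no information is lost
  either way.
* **Undefined values.** A correlation needs at least `min_edges = 3`
  selected edges and nonconstant selections; anything else is an `NA`
  sentinel that propagates (network means drop undefined members rather
  than zero-filling, which would bias means toward zero).
* **Fisher transform overflow.** $|r|$ is clamped to $1 - 10^{-7}$
  before `atanh` so perfectly coupled synthetic data stay finite.

## Severity stratification and the statistical battery

Severity derives from the Fazekas scales: severe WMH is a periventricular
score of 3 or a deep score $\ge 2$, otherwise mild; subjects with both
scores zero do not meet inclusion. Head-motion exclusion is strict:
mean framewise displacement $> 0.5$ mm or any rigid-body parameter
$> 3$ mm/degree fails (values exactly at a threshold pass, because the
rule is written with strict inequalities); the threshold is applied to
the maximum absolute excursion per parameter.

The battery mirrors the standard cross-sectional design:

* pooled-variance t-tests for continuous and chi-square tests for binary
  group comparisons. The 2x2 chi-square uses the Yates continuity
  correction by default — with the cohort's published sex counts this is
  the variant that reproduces the published p-value (0.039 rather than
  the uncorrected 0.032) — and is switchable.
* covariate-adjusted ordinary least squares with a standardized
  coefficient $\beta = b \cdot s_x / s_y$ applied uniformly to every
  predictor, binary included, which is how mainstream statistics
  packages print "Beta". Covariate sets are fixed per analysis stage
  (`covariate_sets()`): age and sex for the WMH-volume/coupling models;
  plus education and the five vascular risk factors in the fully
  adjusted variant; age, sex, education and WMH volume for
  coupling-cognition models; plus follow-up duration and the baseline
  score for longitudinal models. Models are complete-case with n
  reported per model; no imputation.
* Benjamini-Hochberg FDR with one family per stratum per analysis table
  (e.g. the seven network models of the mild subgroup). Family
  membership for the cognition analyses is per-table by default and
  configurable, since finer conventions differ between groups.
* education enters as years (continuous): it is listed as a covariate,
  and categorizing it would discard information.

### Repeated-measures ANOVA

The across-network comparison is a one-way within-subject ANOVA on the
subjects x networks coupling matrix. Sphericity is corrected with the
Greenhouse-Geisser $\hat\varepsilon$, applied to both degrees of freedom
($df_1 = \hat\varepsilon (k-1)$) — chosen over Huynh-Feldt because the
non-integer numerator df conventionally reported for such analyses
(e.g. $4.68 \approx 0.78 \times 6$ for $k=7$) follows the GG convention.
Post hoc comparisons are all-pairs paired contrasts on the pooled
within-subject error, reported as $t$ values with Tukey HSD family
adjustment (`ptukey` on $|t|\sqrt{2}$). Under a true null this corrected
test is mildly conservative; the test suite verifies a type-I error near
0.04 at $\alpha = 0.05$ with 60 subjects and 7 conditions.

### Prognosis: quartiles and ROC

Follow-up digit-span-forward scores are split at the inclusive
linear-interpolation quartiles (R type-7): upper quartile ($\ge Q_3$)
versus lower ($\le Q_1$), middle excluded, boundary ties resolved toward
the extreme group. The ROC uses the Mann-Whitney (tie-corrected) area
with the orientation fixed by the hypothesis — higher coupling predicts
the upper quartile — so an AUC below 0.5 is reported as such, never
flipped. The 95% CI is DeLong by default (the published analysis names
no method; a seeded bootstrap is available). The operating cutoff is the
point with the best Youden index among points with sensitivity at or
above a floor (default 0.90): a sensitivity-prioritized rule chosen
because the use case is screening for patients at risk of decline, where
missing a true decliner costs more than a false alarm. This rule is a
documented package choice, not a claim about how any particular
published cutoff was derived.

## The synthetic cohort generator

The study data this design targets are not publicly deposited, so the
generator is the package's test surface: it produces linked connectomes
and clinical tables whose generating parameters are known, making every
stage verifiable by parameter recovery. Its defaults encode the study
conditions: 617 subjects, age 61 (SD 7) years, 46.5% female, vascular
risk prevalences around 0.73/0.22/0.43/0.38/0.44, 123 subjects with
2-year follow-up.

* **Lesion burden.** A latent standard-normal burden $L$ drives
  everything: WMH volume is $\exp(0.61 + 1.2 L)$ mL, calibrated so the
  overall mean is 3.78 mL and, after splitting at the 60.6% quantile of
  $L$, the mild and severe strata have means near 1.1 and 7.9 mL. The
  Fazekas scores are thresholded from the same $L$ with the deep-score
  cut placed exactly at the severity quantile, so severity labels are
  rule-consistent by construction and the mild fraction is 60.6% in
  expectation.
* **Coupling knob $\kappa$.** FC edge values are a mixture
  $a\,t_{ij} + \sqrt{1-a^2}\,\epsilon_{ij}$ of the normal scores
  $t_{ij}$ of the symmetrized SC edge ranks (a global, hence row-wise,
  monotone transform) and independent noise, affinely rescaled into a
  plausible Fisher-z range. Setting $a = 2\sin(\pi\kappa/6)$ makes the
  population Spearman correlation of the latent pair exactly $\kappa$
  (the bivariate-normal rank identity), so the knob is the estimand: at
  $\kappa = 1$ the mixture is noiseless and measured coupling is exactly
  1; at $\kappa = 0$ its expectation is 0. Because FC must be symmetric
  while SC is directed, the exact $\kappa = 1$ guarantee holds for the
  symmetrized SC profile; calibration checks therefore measure coupling
  with `sc_mode = "symmetrized"`. With per-network $\kappa$, an edge's
  mixture weight is the mean of its endpoints' values, so network
  contrast is preserved in order but compressed by between-network
  edges.
* **Effect sizes.** Network coupling, baseline cognition and follow-up
  cognition are generated from standardized linear models with unit
  total variance, carrying the configured effects (defaults 0.136 for
  log-WMH volume on FPN coupling within the mild stratum, 0.110
  cross-sectionally and 0.245 longitudinally for FPN coupling on digit
  span forward, with a baseline-to-follow-up autocorrelation of 0.6 —
  an assumption, the source design reports none). Because volume is
  log-normal, the generating regressor is log-volume; recovery analyses
  use the package's `log_wmh` switch so estimand and generative model
  coincide (regressing raw mL on a log-scale effect would attenuate
  $\beta$). Infeasible combinations (implied $R^2 \ge 1$) are rejected
  at configuration time.
* **Two paths.** The fast path draws network coupling directly from the
  generating model and is what the recovery and null-calibration suites
  use (200-1000 replicates in seconds). The connectome path
  (`connectomes = TRUE`) builds per-subject SC/FC matrices with
  per-subject $\kappa$ and measures coupling with the package's own
  estimator; it is exercised at reduced size (60 ROIs) by the
  monotonicity and pipeline tests. Time series, when requested, come
  from a whitened factor construction whose in-sample correlation equals
  the target FC exactly (after eigenvalue clipping to the nearest
  admissible correlation matrix); it requires more frames than ROIs.

What the generator does *not* emulate: spatial lesion topography and
distance-dependent tractography bias, autocorrelated BOLD noise,
site/scanner effects, floor and ceiling effects in cognitive scores, and
informative follow-up dropout. Passing tests therefore demonstrate that
the estimators recover known effects under the stated statistical
structure — not that the pipeline is robust to those real-data
complications.

## Problem sizes and numerical choices

The test and acceptance simulations use sizes chosen to make Monte Carlo
error small relative to the tolerances they check: 200 replicates of the
full 617-subject cohort for effect recovery (Monte Carlo SE of the mean
$\hat\beta$ about 0.004), 500 replicates for post-FDR false-positive
calibration, 1000 for ANOVA type-I error and DeLong CI coverage, and
60-ROI connectomes for the $\kappa$ sweep. Oracle equivalences
(midrank Spearman, exhaustive-pair AUC, ANOVA sums of squares) are
checked to $10^{-12}$ or $10^{-9}$. Determinism is part of the contract:
every stochastic operation takes an explicit seed, and a run manifest
(config hash, input digests, package version, seeds) accompanies
pipeline and simulation outputs.

## Known limitations

Coupling here is Spearman-based; structural-decoupling (harmonic) and
model-based coupling variants are out of scope. The pipeline consumes
preprocessed inputs: tractography, fMRI preprocessing, lesion
segmentation and registration are upstream. The ROC cutoff rule and the
FDR family conventions are documented choices among reasonable
alternatives, and severity ties to the Fazekas rule only — no volumetric
severity threshold is offered.
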
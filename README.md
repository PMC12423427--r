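# wmhcoupling

Structure–function coupling analysis for white matter hyperintensity
(WMH) cohorts.

## What this package is for

WMH — the bright subcortical lesions of cerebral small vessel disease on
T2-FLAIR MRI — erode cognition, but patients with mild lesion loads often
stay cognitively intact, hinting at network-level compensation. This
package quantifies that candidate mechanism: **structure–function (SC–FC)
coupling**, how tightly a cortical region's functional connectivity
follows its anatomical wiring, and relates it to lesion burden and
cognitive outcomes. It is written for neuroimaging researchers who have
per-subject connectomes (probabilistic tractography + resting-state
fMRI) on a 400-parcel / seven-network cortical parcellation and a
clinical table with Fazekas scores, WMH volume and cognitive testing.

The core statistic, for region $i$ with structural profile
$w_{i\cdot}$ (tractography connection probabilities) and functional
profile $z_{i\cdot}$ (Fisher-z correlations):

$$\rho_i = \mathrm{Spearman}\!\left(w_{i\cdot},\, z_{i\cdot}\right)
\quad\text{over edges with } w_{ij} > 0,$$

with midrank tie handling; network coupling is the mean of the defined
member $\rho_i$. Around that statistic the package provides:

* connectome I/O and validation (delimited SC/FC matrices, ROI time
  series, parcellation lookup tables), Fisher-z FC construction, and the
  strict motion-QC exclusion rule (mean FD > 0.5 mm or any motion
  parameter > 3 mm/deg);
* WMH severity stratification (severe = periventricular Fazekas 3 or
  deep Fazekas ≥ 2);
* the stratified association battery: pooled t / Yates chi-square group
  comparisons, standardized-β OLS with fixed covariate sets,
  Benjamini–Hochberg FDR per stratum, Greenhouse–Geisser
  repeated-measures ANOVA across networks with Tukey post hocs;
* longitudinal models and quartile-outcome ROC risk stratification with
  a sensitivity-targeted cutoff (DeLong 95% CI);
* a fully seeded synthetic cohort generator producing linked connectomes
  and clinical tables with known effect sizes, so every stage is
  verifiable by parameter recovery.

## Worked example

Simulate a 617-subject cohort under the default study conditions and run
the full pipeline:

```r
library(wmhcoupling)

sim <- gen_cohort(sim_config(seed = 42))
res <- run_pipeline(sim$cohort, sim$coupling, wmh_predictor = "log_wmh")

print(res$anova)
#> Repeated-measures ANOVA: F(5.95, 3666) = 434.8, p < 0.001 (GG eps = 0.992)

subset(res$wmh_assoc, stratum == "mild" & outcome == "FPN")[,
       c("stratum", "outcome", "beta_std", "p_raw", "p_fdr", "n")]
#>  stratum outcome beta_std       p_raw      p_fdr   n
#>     mild     FPN  0.16078 0.001717668 0.01202367 379

print(res$roc)
#> AUC = 0.657 (95% CI 0.470-0.845), n = 17 vs 17
#> cutoff = 0.013: sensitivity 1.000, specificity 0.176
```

Reading the output: the ANOVA says network coupling differs strongly
across the seven networks (Greenhouse–Geisser-corrected df). The
association row is the mild stratum's standardized β of frontoparietal
(FPN) coupling on log WMH volume, adjusted for age and sex with BH-FDR
over the seven-network family — a single-cohort draw around the
generating effect of 0.136. The ROC discriminates upper- from
lower-quartile follow-up digit-span performance from baseline FPN
coupling; at this follow-up size (17 vs 17) the AUC is estimated with a
wide CI, and the reported cutoff is the best-Youden point among those
with sensitivity ≥ 0.90.

Real data enter the same way: `read_parcellation()`,
`read_connectome()` (per-subject `sc.tsv`/`fc.tsv`/`ts.tsv`
directories), `cohort_coupling()`, and `read_cohort()` feed
`run_pipeline()` directly.

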
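# dmnalpha

Resting-state EEG source-space analysis of anterior vs. posterior
default-mode-network (DMN) alpha activity, and its moderation by
personality.

## What this package is for

Fronto-posterior differences in resting EEG spectral power relate to
extraversion, and the cortical regions involved overlap the anterior
(medial prefrontal / anterior cingulate) and posterior
(precuneus / posterior cingulate / parietal) hubs of the DMN.
`dmnalpha` implements the full analysis chain needed to study such
effects at the source level, for researchers working with multichannel
resting EEG and questionnaire data:

1. **Forward model** — idealised spherical 10-20/10-10 montages, a
   labelled cortical source grid, and a three-shell spherical-head lead
   field (Legendre series solution).
2. **Spectral analysis** — 1.7 s Hann-tapered epochs, artifact
   rejection, band-limited cross-spectral matrices (delta–gamma).
3. **sLORETA inverse** — standardized current-source-density images
   `Re tr(S_jj^{-1} T_j C T_j^H)` with `T = K'(KK' + aH)^+`,
   regularization fraction 1/100, zero localization error for noiseless
   single sources.
4. **Group spatial ICA** — subject-wise PCA reduction, concatenation,
   Infomax unmixing, MDL order estimation, GICA back-reconstruction of
   per-subject maps, and voxelwise one-sample t-maps with
   Benjamini–Hochberg FDR (q = 0.05) and an 8-voxel cluster filter.
5. **Network scores** — anterior/posterior DMN template matching by
   spatial correlation, per-subject positive-voxel intensity sums, and
   the combined axis `P/ADMN = z(PDMN_IC) − z(ADMN_IC)`.
6. **Statistics** — varimax-PCA questionnaire scale construction with
   Cronbach's alpha, hierarchical moderated regression on z-scored
   variables (`y ~ x + m`, then `+ x·m`), simple slopes at ±0.5 SD of
   the moderator, and subgroup correlations.
7. **Synthetic cohorts** — an EEG + questionnaire generator with known
   ground truth (planted alpha patches with subject-varying amplitudes
   and a planted `amplitude × moderator` interaction on an outcome
   item), so every stage is verifiable by parameter recovery.

The headline statistical object is the moderated regression

```
SRPE ~ b1 * P/ADMN + b2 * Assertiveness + b3 * (P/ADMN x Assertiveness)
```

where SRPE is a self-referential positive-expectations questionnaire
item and P/ADMN the posterior-vs-anterior DMN alpha axis; a positive
interaction means posterior-dominant alpha accompanies high SRPE in
assertive (extraverted) individuals and anterior-dominant alpha does so
in non-assertive ones.

## Worked example

Simulate a 60-subject cohort (40 s of eyes-closed EEG per subject to
keep it quick) and run the pipeline in the alpha band plus two control
bands:

```r
library(dmnalpha)

cfg <- cohort_config(n_subjects = 60, duration_s = 40, seed = 11)
rc  <- run_config(cohort = cfg, bands = c("alpha", "theta", "delta"),
                  n_components = 12, seed = 5, out_dir = "run1")
rep <- run_pipeline(rc)

for (b in names(rep$band_results)) {
  br <- rep$band_results[[b]]
  cat(sprintf("%s: interaction B = %.3f, p = %.2g\n",
              b, br$interaction$B, br$interaction$p))
}
#> alpha: interaction B = 0.785, p = 9.3e-05
#> theta: interaction B = 0.035, p = 0.81
#> delta: interaction B = -0.180, p = 0.14

rep$band_results$alpha$subgroup_correlations
#>   group score          r          p  n
#> 1  high  PDMN  0.2667407 0.20767771 24
#> 2  high  ADMN -0.4538385 0.02590773 24
#> 3   low  PDMN -0.3778099 0.07549928 23
#> 4   low  ADMN  0.3870633 0.06805449 23
```

The planted interaction (`beta3 = 0.7` on the latent amplitude axis) is
detected in the alpha band only; in high-assertiveness subjects the
outcome tracks the posterior component intensity (r = 0.27 > 0) and in
low-assertiveness subjects the anterior one (r = 0.39 > 0) — the
double-dissociation pattern the pipeline is designed to expose.  The
recovered P/ADMN scores correlate with the planted ground truth at
Spearman rho = 0.93 for this configuration:

```r
bundle <- simulate_cohort(cfg, keep_recordings = FALSE)
sc <- read.delim("run1/alpha/scores.tsv")
cor(sc$P_ADMN, bundle$truth$PA_true, method = "spearman")
#> [1] 0.9313698
```

Every run directory also contains per-band score tables, simple-slope
and subgroup TSVs, selected component maps as NIfTI, and a
`report.json`; `make_report("run1")` renders a human-readable summary
with component thumbnails.

A thin command-line wrapper is provided in `exec/`:

```sh
exec/dmnalpha simulate --out fixtures --seed 1
exec/dmnalpha run --fixtures fixtures --out run1 --seed 1
exec/dmnalpha report --run run1
```

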
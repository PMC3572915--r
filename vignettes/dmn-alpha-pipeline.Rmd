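---
title: "From resting EEG to moderated DMN network statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From resting EEG to moderated DMN network statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmnalpha)
```

# The analysis in one paragraph

`dmnalpha` turns multichannel resting eyes-closed EEG into band-limited
cortical source images (sLORETA), decomposes the per-epoch images of a
cohort with group spatial ICA, selects the independent components that
best match anterior and posterior default-mode-network (DMN) templates,
scores each subject's expression of those components, and tests whether
an extraversion facet (assertiveness) moderates the association between
self-referential-thought ratings and the posterior-versus-anterior
balance of DMN alpha activity.  A synthetic-cohort generator with known
ground truth makes every stage verifiable by parameter recovery.

# Forward model

## Geometry

Electrodes are placed on an idealised spherical 10-20/10-10 layout
(19, 32 or 64 channels) with Cz at the vertex; intermediate sites are
great-circle interpolations between lateral ring and midline
electrodes.  Coordinates are right-handed (+x right, +y anterior,
+z superior), millimetres, origin at the sphere centre.  The two lowest
posterior-lateral electrodes (TP9/TP10 in the 32-channel set) serve as
proxies for the linked-mastoid reference.

The source space is a cubic grid clipped to a cortical shell between
55% and 95% of the brain-shell radius (upper hemisphere plus a 20 mm
band below the equator).  Each voxel gets one of six angular-sector
labels that preserve the anterior/posterior DMN topology without any
atlas file: medial/superior frontal (`MF_SF`), anterior cingulate
(`ACC`), posterior parietal (`PPC`), occipito-parietal junction
(`OPJ`), posterior cingulate/precuneus (`PCC_precuneus`), and
`other_cortex`.  The sector bounds are versioned constants
(`dmn_constants$sectors`); at 15 mm spacing the grid has a few hundred
voxels, at 5 mm several thousand.

## Three-shell spherical lead field

Scalp potentials follow the classic Legendre-series solution for a
dipole inside concentric conducting shells (radii 92/85/81 mm,
conductivities 0.33/0.0042/0.33 S/m — standard literature values).
Per spherical degree the interface conditions give a small linear
system; unknowns are rescaled per region so the systems stay well
conditioned at high degree, and the solver reproduces the homogeneous
insulated-sphere closed form to machine precision.

The default truncation is 150 terms.  The series decays like
$(b/R)^n$ with $b/R \le 0.837$ for the shallowest allowed source, so
150 terms bound the truncation error near $10^{-11}$ of the gain-column
norm, comfortably below the $10^{-6}$ accuracy target we impose; 60
terms — a common choice for deeper sources — would only reach about
$5\times10^{-5}$ here, which is why the default is higher.

# Spectral analysis

Recordings are segmented into 1.7 s epochs (510 samples at 300 Hz)
with 50% overlap by default; epochs whose absolute peak exceeds
100 µV on any channel are rejected.  With 3 minutes of eyes-closed
data this yields about 210 epochs per subject, matching the upper end
of the 85–210 epoch range typical of such protocols (the overlap is
configurable precisely because epoch counts in that range cannot be
reached without overlap from a few minutes of data).

Each epoch is Hann-tapered; cross-spectral matrices are averaged over
epochs and over DFT bins whose centre lies in the half-open band
\[low, high): delta 2–4, theta 4–8, alpha 8–12, beta 12–30, gamma
30–45 Hz.  Matrices are Hermitian PSD by construction, with a
PSD-style normalisation (µV²/Hz).

# sLORETA inverse

With $K$ the average-reference-projected lead field and $H$ the
centering projector, the minimum-norm inverse is
$T = K^\top (K K^\top + \alpha H)^{+}$ with
$\alpha = \alpha_{frac}\,\mathrm{tr}(K K^\top)/n_{ch}$; the
regularization fraction defaults to $1/100$ and the trace scaling
makes it dimensionless.  sLORETA standardizes each voxel's 3-vector
estimate by the corresponding $3\times3$ diagonal block of the
resolution matrix $TK$; we store the pre-standardized rows
$S_{jj}^{-1/2} T_j$ so band power is a plain quadratic form
$\mathrm{Re}\,\mathrm{tr}(S_{jj}^{-1} T_j C T_j^{H})$.  In the
noiseless single-source case with $\alpha = 0$ the standardized power
peaks exactly at the true voxel (zero localization error), which the
test suite verifies exhaustively over the grid.

Per-epoch images (the default input to group ICA, since each epoch's
images enter the decomposition) are computed from each epoch's tapered
Fourier vectors; their average equals the image of the epoch-averaged
cross-spectrum exactly.

# Group spatial ICA

Per-epoch source images are stacked subject-contiguously.  Each
subject's block is centred per voxel (removing that subject's mean
image — the common "noise floor" pattern that otherwise couples all
subjects into one confounded component), reduced by PCA over rows to
$r_1 = 1.5\,n_c$ dimensions, concatenated, reduced again to $n_c$, and
unmixed with Infomax (logistic nonlinearity, natural gradient, up to
500 iterations at tolerance $10^{-7}$); a FastICA implementation in
the test helpers serves as an independent cross-check oracle.  PCA
component signs are fixed deterministically, so results are invariant
to subject ordering and bitwise reproducible given the seed.  Group
maps are z-scored over voxels, sign-aligned to positive skewness
(ties by positive maximum), and ordered by explained variance.

The model order defaults to 20 components, with a classic
minimum-description-length estimate (Wax–Kailath form, penalty
$\tfrac12 k (2p-k)\log N$ over the row-covariance eigenvalues with
voxels as samples) available as an alternative; on smooth source-space
images the raw MDL estimate tends to be generous, so the pipeline caps
it at 20.

## Back-reconstruction and subject intensity

Subject maps are obtained GICA-style: the concatenated mixing matrix
is partitioned into subject blocks $G_i$ and
$\hat S_i = G_i^{+} Z_i$.  Any bilinear decomposition leaves a scale
split between maps and time courses undetermined; we resolve it by
normalizing each subject time course to unit RMS, so a subject's
expression *strength* of a component lives in that subject's map.
Subject maps are then standardized with component-pooled mean and SD
across subjects.  This choice is what makes the downstream
positive-voxel summation an intensity measure: per-map z-scoring
would erase between-subject scale entirely and leave only a weak,
support-geometry-dependent shape channel (for two-level patterns the
condition for the positive-voxel sum to *increase* with expression,
$\rho(1-\rho) > 1/2\pi$ over support fraction $\rho$, is almost
exactly complementary to the super-Gaussianity Infomax relies on,
$\rho(1-\rho) < 1/6$).  With pooled standardization a non-expressing
subject has a near-flat map and a strongly expressing subject large
positive values in the component's support, and planted amplitudes are
recovered with correlation above 0.9 in the test conditions.

Component-level inference uses a voxelwise one-sample t-test across
subjects, Benjamini–Hochberg FDR at $q = 0.05$ over voxels
(per component), and removal of surviving face-adjacent
(6-connectivity) clusters smaller than 8 voxels.  Zero-variance voxels
are excluded and flagged.  Only components with a non-empty surviving
mask are eligible for template selection; if none survives the
pipeline falls back to all components with a warning.

# Network scores and the P/ADMN measure

The anterior template is the union of the `MF_SF` and `ACC` sectors,
the posterior template of `PPC`, `OPJ` and `PCC_precuneus`; the two
are disjoint by construction.  Components are ranked by Pearson
correlation between the z-scored group map and the 0/1 mask over *all*
voxels (the usual template-matching convention), ties broken by lower
component id, and the top component selected per template.  A
subject's intensity score is the sum of strictly positive values of
their map of the selected component, over the whole map by default
(restriction to the FDR-surviving mask is available as an option).
Intensity scores are z-scored across subjects and the anterior score
subtracted from the posterior one, giving the P/ADMN axis: negative =
anterior-dominant, positive = posterior-dominant alpha activity.

# Statistics

Questionnaire scales are built by principal components of the item
correlation matrix with varimax rotation: items join the factor of
their largest absolute loading if it exceeds 0.3, negative loadings
mark reverse-scored items (scored as $6 - x$ on the 1–5 range), scale
scores are means of the signed items, and Cronbach's alpha is reported
per scale.

Moderation is tested hierarchically on z-scored variables: step 1
regresses the outcome on the network factor and the moderator, step 2
adds their product (formed from the z-scored variables and *not*
re-standardized, following the usual centering convention for
continuous moderators).  Coefficients are reported with SE, t, df and
two-sided p; degrees of freedom follow the standard OLS convention
$n - p$ (so $n - 4$ in step 2).  Simple slopes at moderator values
$\pm 0.5$ SD are $B_x \pm 0.5 B_{int}$ with delta-method standard
errors.  Subgroup correlations (outcome with each network score) are
computed within the strict-inequality subgroups $z_m > +0.5$ and
$z_m < -0.5$.  No multiplicity correction is applied across bands or
scales; all p-values are nominal.

# The synthetic cohort

The generator's defaults define the reference study conditions:

* 60 subjects, 32 channels, 300 Hz, 180 s eyes-closed each;
* two coherent alpha sources — amplitude-modulated 10 Hz narrowband
  noise (2 Hz bandwidth; pure tones would make cross-spectra
  rank-deficient and unrealistically easy) — placed on all voxels of
  the anterior (`MF_SF`+`ACC`) and posterior (`PPC`+`OPJ`+
  `PCC_precuneus`) sectors with radial orientations, one independent
  time course per patch;
* per-subject patch amplitudes $a_A, a_P$ lognormal with sdlog 0.35;
* 12 background 1/f sources at random voxels plus 1 µV white sensor
  noise; the planted-patch scalp RMS at unit amplitude is `snr` times
  the alpha-band RMS of that noise floor (default `snr = 3`);
* linked-mastoid referencing, as in the emulated recording setup;
* a questionnaire with a planted 4-factor structure (35 Likert items,
  loadings 0.7, discretized at latent thresholds −1.5, −0.5, 0.5,
  1.5), an observed moderator scale with reliability 0.8, and an
  outcome item generated as
  $\beta_1 PA + \beta_2 m + \beta_3\, PA \cdot m + \varepsilon$ with
  $PA = z(a_P) - z(a_A)$, defaults $\beta_3 = 0.7$,
  $\sigma_\varepsilon = 0.7$.

Everything is a pure function of the configuration and master seed;
fixture sets (EDF + TSV + JSON manifest) regenerate identically from
the manifest seed.

What the generator does *not* emulate: ocular and muscle artifacts
(rejection is exercised by amplitude thresholds only), eyes-open
segments, volume-conduction differences of realistic head shapes,
non-alpha oscillatory networks, and item-level response styles.
Passing tests therefore demonstrate correctness of the algorithms and
recoverability under the stated model, not robustness to every
property of real recordings.

# Numerical and design choices worth knowing

* **Series truncation** 150 terms (see above); configurable.
* **Reference handling**: re-referencing only removes channel-common
  signal, so images are identical for average- and linked-mastoid-
  referenced data given the centering in the operator; this is tested
  to $10^{-8}$.
* **Regularization**: spatial blurring (peak/mean of a single-source
  image) decreases monotonically with $\alpha$ from the operating
  value upward; at vanishing $\alpha$ the standardized ratio plateaus
  instead, which is why the blurring property is stated for the
  operating regime.
* **Eigenvalue clipping**: cross-spectra are accepted as PSD down to
  $-10^{-9}$ of their trace (floating-point Hermitian averaging) and
  standardized powers clipped at the same relative tolerance.
* **Determinism**: ICA iteration order is the only stochastic element
  of the analysis path and is seeded explicitly; reports are
  byte-identical across reruns of the same configuration and seed.
* **Problem sizes in the test suite**: the suite runs the full
  pipeline on 15 mm grids (a few hundred voxels) with 32 channels,
  cohorts of 12–60 subjects and up to 3 minutes of synthetic EEG per
  subject, and checks calibration properties (type-I error, CI
  coverage) with 1000-replicate simulations at $n = 60$.  These sizes
  were chosen so the whole suite exercises every stage at full
  fidelity while remaining a desk-scale computation.

# Known limitations

* The spherical head model and parametric sector labels are stand-ins
  for individual anatomy and atlas-based regions; absolute source
  locations should not be over-interpreted.
* MDL order selection on smooth, spatially correlated source images
  overestimates; treat it as an upper bound and prefer the capped
  default.
* The intensity-calibration convention (unit-RMS time courses) is one
  of several defensible resolutions of the ICA scale indeterminacy;
  comparisons with analyses that z-score each subject map separately
  will differ by design.
* Subgroup correlations at $\pm0.5$ SD involve small samples
  (typically 15–20 of 60 subjects) and are reported with nominal
  p-values; they are descriptive follow-ups to the interaction test,
  not independent confirmations.
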
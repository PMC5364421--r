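---
title: "Volumetric Raman imaging by spectral unmixing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric Raman imaging by spectral unmixing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(volraman)
```

## The measurement and the model

A confocal Raman microscope scanned over a z-stack of imaging planes yields,
per voxel, a spectrum of inelastic scattering intensity on a common
wavenumber axis (typically 0–3000 cm⁻¹ at ~10 cm⁻¹ resolution; the package
defaults assume 650 nm lateral steps and 1 µm z increments over 10 planes).
`volraman` models the unfolded dataset `D` (voxels × channels) as a linear
mixture `D ≈ C·S`: every voxel's spectrum is a non-negative combination of a
small number of pure-component spectra. Three assumptions matter:

* **Linear mixing.** Raman intensity is additive over the molecules in the
  focal volume; resonance effects, self-absorption and substrate etaloning
  are ignored.
* **Pure pixels.** For every component, at least one voxel contains
  (almost) only that component. High-resolution confocal imaging of cells
  makes this plausible for organelle-scale structures; it fails when
  structures are smaller than a voxel everywhere.
* **Abundance scale.** Abundances are relative (0–1), not concentrations;
  the per-component rescaling below fixes their scale.

### Endmember extraction

`vca()` implements vertex component analysis: under the assumptions above
the data cloud lies in a simplex whose vertices are the pure voxels. The
algorithm estimates the dataset SNR from the energy split around the
p-dimensional principal subspace; above `15 + 10·log10(p)` dB it projects
the data onto the top-p singular subspace with projective scaling, otherwise
onto p−1 centred principal components lifted with a constant coordinate. It
then repeatedly draws a random direction orthogonal to the span of the
endmembers found so far and takes the voxel with the largest absolute
projection. Returned endmembers are the original spectra at the selected
voxels — real measured spectra, never synthetic averages. The random
directions are seeded (default seed 1); on clean, well-separated data the
selected voxel set is seed-invariant, and a fixed seed makes every run
bit-reproducible.

Throughout the package, "SNR in dB" means `10·log10` of mean per-voxel
signal energy over expected per-voxel noise energy — the convention of the
hyperspectral-unmixing literature.

### Abundance estimation

`nnls_abundances()` solves one small non-negative least-squares problem per
voxel with an active-set method on the normal equations (the gram matrix is
p × p, so the per-voxel cost is independent of the channel count; solutions
satisfy the KKT conditions exactly at convergence). NNLS does not by itself
bound coefficients by one, so each component column is divided by its 99.9th
percentile and clipped to [0, 1]; the percentile, rather than the maximum,
keeps one hot voxel from compressing the whole map, and the factors applied
are recorded. No sum-to-one constraint is imposed: partial-volume voxels and
baseline-corrected background may legitimately sum to less than one, and
constraining the sum would distort abundances when a component is missing
from the basis.

### Labelling

`label_endmembers()` scores each endmember against a band library: the
fraction of an entry's diagnostic wavenumbers at which the spectrum shows a
peak within ±8 cm⁻¹. Peaks are local maxima after light Savitzky–Golay
smoothing, subject to a prominence filter — at least 5% of the spectrum's
range *and* six times the spectrum's own channel-to-channel noise level —
so pure noise earns no diagnostic peaks. Labels are assigned greedily in
decreasing score order (each label and each endmember at most once) above a
0.5 score floor; everything else is "unassigned" and the full score table is
kept for review. The shipped library covers the standard cellular
assignments (phenylalanine 1008 cm⁻¹, DNA O–P–O 789 cm⁻¹, CH₂ stretch
2857 cm⁻¹, glycogen 485 cm⁻¹, TAG ester C=O 1747 cm⁻¹, cholesteryl
1066+1134 cm⁻¹, phospholipid 719+1085 cm⁻¹, PEG 847 cm⁻¹).

The component count `p` is a user decision. `sweep_component_count()` runs
the extraction over a range of `p` and reports how many endmembers earn a
library label at each value; the count that maximises assignable components
is the natural choice, mirroring how an analyst picks `p` by peak
assignment. No automatic selection is made.

## Preprocessing

Order per layer: outlier screening → cosmic-ray repair → baseline
correction (with cropping to the fitting window) → smoothing. Whether
smoothing runs before or after baseline correction is configurable
(`smooth_before_baseline`); the default (after) makes no difference at the
default smoother settings. Dataset normalisation happens later, on the
unfolded matrix, immediately before unmixing.

* **Cosmic rays.** `fit_pca_outliers()` fits a mean-centred PCA retaining
  95% of variance and computes per-spectrum Hotelling T² (F-distribution
  limit) and Q residual (Jackson–Mudholkar limit) at a 99.9% confidence
  level — conservative limits chosen to keep false flags on clean
  shot-noise spectra well under 1%. Flagged spectra are *confirmed* as
  cosmic rays only if they contain a narrow spike: a channel exceeding the
  median of its ±5-channel neighbourhood by more than 8 MADs, in a run of
  at most 2 channels. Confirmed spikes are repaired by linear
  interpolation; broader anomalies are reported but left untouched, and no
  spectrum is ever deleted — the voxel grid must stay complete for
  refolding. Automating the confirmation (rather than reviewing flags by
  hand) is what makes the pipeline deterministic; the full outlier report
  is still exported for manual review.
* **Baseline.** `wls_baseline()` fits a third-order polynomial on the
  700–1800 cm⁻¹ fingerprint window by iteratively reweighted least squares
  with one-sided peak suppression: channels above the current fit are
  clipped to it (their residual pull driven to zero) and the fit repeats
  until the baseline changes by <1e-4 in relative L2 (max 100 iterations).
  Clipping rather than dropping the above-fit channels keeps the
  polynomial anchored across the whole window; an earlier variant that
  removed those channels outright could run away at window edges whenever a
  band sat near 700 cm⁻¹, leaving large spurious humps. On noiseless
  polynomial input the fit is exact; an isolated band's height survives
  within 2%; with noise the baseline settles slightly below the noise mean,
  a standard and harmless bias. Two inherent ambiguities of any
  envelope-following baseline are worth knowing: a band sitting at a window
  edge (719 or 1747 cm⁻¹ against the 700–1800 cm⁻¹ window) leaves the
  polynomial a few percent of freedom under it, and very broad features
  (≳60 cm⁻¹ width, like a watery medium band) are partially absorbed into
  the baseline. Narrow cellular bands in the window interior pass through
  within about 1%. Distinguishing cosmic spikes from real bands additionally
  requires spectral sampling finer than the band width; at 5 cm⁻¹ sampling a
  12 cm⁻¹ band is two channels wide and genuinely spike-like.
* **Smoothing.** `savitzky_golay()` defaults to the acquisition-matched
  second-order, 3-point setting. A quadratic through three points
  interpolates them exactly, so this default is the identity transform —
  it is kept for fidelity to the acquisition convention, and wider windows
  are supported when real smoothing is wanted.
* **Normalisation.** One scalar per sample: the mean over voxels of the
  per-spectrum summed intensity. A per-voxel or per-spectrum normalisation
  would erase exactly the intensity contrast that abundance mapping needs;
  a per-sample scalar removes instrument/throughput differences while
  preserving it. The granularity is exposed as a mode (`dataset_mean`,
  `none`) rather than hard-coded.

## Quantification and statistics

A component's volume is quantified as the percentage of all voxels of the
sample at or above a threshold (`count_voxels()`, inclusive `≥`; for binary
masks this voxel count equals the isosurface-enclosed count). Thresholds
are fixed per experiment and per component: the mean abundance pooled over
the experiment's volumes (`component_threshold()`), which sits well above
the NNLS noise floor as long as the spectral sampling is reasonably fine.
The denominator is always the full sample volume — the only reading that
makes percentages comparable across samples.

`compare_groups()` reports an F test for variance homogeneity and Shapiro–
Wilk normality p-values per group alongside an unpaired two-sided Student's
t-test with pooled variance (df = nA+nB−2); Welch's correction is available
when the F test rejects. Stars follow the * P<0.05, ** P<0.01, *** P<0.001
convention. Degenerate inputs are handled explicitly: identical constant
groups give t = 0, p = 1; constant groups with different means give p = 0.
No multiple-testing correction is applied across components; stars are
per-component, as is conventional for this experiment type.

`z_collapse()` sums a stack over z to emulate a non-confocal acquisition
(dz becomes Z·dz) and feeds the identical downstream pipeline — the control
that measures how much molecular specificity the confocal z-resolution
buys. In the multi-sample pipeline the collapse is applied after per-layer
preprocessing and before unmixing; collapse is linear, so ordering it after
baseline correction only avoids re-fitting baselines on summed spectra.

## The phantom generator

`build_phantom()` realises a `phantom_spec()`: geometric compartments
(spheres, ellipsoids, shells, background) carrying parametric band spectra,
evaluated on a supersampled grid (2× per axis) so boundary voxels get
fractional abundances; per-spectrum random cubic fluorescence baselines;
white Gaussian noise at a requested dataset SNR; and Poisson-count cosmic
spikes (1–2 channels, 20–100× the noise σ) at recorded positions. Fixed
seeds make builds bit-reproducible.

The default macrophage-like phantom places, in a 26 × 26 × 10 µm field of
view (40 × 40 × 10 voxels), an ellipsoidal cytoplasm, a spherical nucleus,
six lipid droplets split between TAG and cholesterol, and a 1-µm
phospholipid membrane shell — thin enough that resolving it is a genuine
test of the method's claim to see membranes. The lipid endmembers share
their CH₂ bands (1300/1303, 1443 cm⁻¹) and differ only in diagnostic bands
(1747; 1066+1134; 719+1085), deliberately making lipid subtyping honest.
Two generator choices deserve comment:

* **The medium is a real component.** The culture medium background has its
  own weak, broad spectrum rather than zero signal. An all-zero background
  would place the origin inside the data simplex as a spurious vertex,
  which is an artefact of simulation (real media and substrates always
  scatter) and destabilises projective unmixing. Default unmixing of this
  phantom therefore targets six endmembers: five cellular plus medium.
* **Lipid intensities are high.** TAG and cholesteryl-ester band amplitudes
  are set well above the protein bands, reflecting the strong Raman
  scattering of dense lipid bodies and the conspicuously intense
  cholesterol spectra seen in practice. With weak lipid amplitudes the
  droplets' few voxels fall below the noise floor of the principal
  subspace and no unmixing method could find them — a regime the method
  does not claim.

Geometry scales with the grid's physical extent, so scaled-down grids keep
their proportions. What the phantom does *not* emulate: optical point-spread
blurring, Poisson (rather than Gaussian) photon statistics, wavenumber
calibration drift, and morphological realism beyond primitives. Passing the
phantom suite therefore demonstrates the correctness of the computation, not
robustness to every artefact of real spectrometers.

## Simulation sizes and the two-group experiment

The package's own validation runs at these sizes, chosen to keep a complete
run on one CPU in minutes:

* **Single-cell end-to-end**: the full acquisition geometry, 40 × 40 × 10
  voxels with a 2 cm⁻¹ axis (~551 fingerprint channels), 25 dB SNR. All
  five cellular components label correctly and their thresholded voxel
  percentages land within ±10% (relative) of the ground-truth thresholded
  fractions.
* **Two-group cholesterol contrast**
  (`cholesterol_contrast_experiment()`): 4 jittered phantoms per group on a
  24 × 24 × 10 grid spanning the same field of view at 30 dB SNR, group B
  carrying cholesterol-rich bodies that group A lacks. The geometry encodes
  the mechanism under test: each cholesterol body sits in the *same xy
  column* as a TAG lipid body, a few micrometres away in z (endosomal
  accumulations stacked with lipid bodies). Confocal z-resolution separates
  the pair into distinct pure voxels, so the 3D pipeline extracts a clean
  cholesterol endmember and detects the group contrast at n = 4
  (p < 0.05). Summing over z merges each pair into one mixed lipid column,
  so the collapsed analysis cannot resolve cholesterol from the TAG signal:
  either no endmember earns the cholesterol label — cholesterol is then
  non-detectable and recorded as 0% in every sample, the usual "n/d"
  convention, giving p = 1 — or a merged lipid component is quantified
  whose voxel counts are dominated by the shared TAG content and its
  cell-to-cell variability (droplet radii vary ±25% between samples), which
  washes out the contrast. Between-sample lipid variability is deliberate:
  it is the realistic noise floor against which the merged collapsed signal
  must compete.

## Numerical and degenerate-input choices

* Unfolding uses the fixed bijection `m = x + X·(y−1) + X·Y·(z−1)`
  (x fastest, 1-based); any fixed bijection is equivalent for unmixing, but
  fixing one makes refolding unambiguous. Spectral crops are inclusive on
  both bounds; axes must match across layers exactly (no resampling).
* Negative intensities are allowed after baseline subtraction everywhere
  except component volumes, which are the only [0, 1]-constrained arrays.
* `vca()` errors when `p` exceeds the numerical rank (relative singular
  value < 1e-12) and special-cases `p = 1` through the projective branch.
* PCA outlier limits fall back gracefully: a perfectly reproduced layer
  gets an infinite Q limit; an all-identical layer warns and flags nothing.
* Min–max scaling of a constant univariate band map is defined as all
  zeros.
* On-disk interchange uses a plain-text container (per-layer TSV matrices
  plus `meta.json`) written with 17 significant digits, making round trips
  bit-exact; component volumes export as multi-page 32-bit float TIFF with
  a JSON sidecar. Vendor formats and spectral resampling are out of scope.

## Known limitations

Linear mixing and the pure-pixel assumption bound the method: components
that never dominate a voxel (sub-voxel structures everywhere) cannot be
extracted, and strongly overlapping fluorophores or resonance effects break
additivity. The mean-abundance threshold is a pragmatic default; very rare
components push it toward the noise floor, and coarse spectral sampling
raises that floor. Endmember labelling depends on the band library:
components without diagnostic bands in the analysed window stay
"unassigned". The t-test operates on per-sample percentages and inherits
their assumptions (approximate normality, similar variances) — both checks
are reported rather than silently assumed, and the "two sample variance
test" is implemented as an F test with an accompanying normality report,
the only self-consistent reading of that check.
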
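# volraman

Quantitative volumetric Raman imaging of cells and 3D cultures by spectral
unmixing.

Confocal Raman microspectroscopy can image a living cell in three dimensions
without labels: scanning the focus over a z-stack of planes yields, at every
voxel, a full Raman spectrum — a vibrational fingerprint of the biomolecules
at that point. `volraman` implements the computational side of that
experiment: it turns a z-stack of hyperspectral Raman images into labelled,
quantified 3D maps of cellular components (cytoplasm, nucleus, lipid
subtypes, hydrogel matrix, ...), and provides the statistics to compare
experimental groups.

## The model

The assembled stack is an `X x Y x Z x w` array. Unfolding it voxel-wise
gives a matrix `D` (`M x w`, `M = X·Y·Z`) that is modelled as a linear
mixture

```
D  ≈  C · S,      C ∈ [0,1]^{M×N},  S ∈ R^{N×w}
```

where the `N` rows of `S` are *endmember* spectra — real spectra taken
verbatim from the dataset at its purest voxels, located by **vertex component
analysis** (VCA): under linear mixing the data cloud is a simplex and its
vertices are the pure voxels. Per-voxel abundances `C` are then estimated by
**non-negative least squares** and mapped to `[0, 1]` per component.
Refolding each column of `C` gives a 3D abundance volume per component, and
each component is quantified as the percentage of voxels at or above a
threshold fixed per experiment (close to the component's mean abundance).
Group differences in these percentages are tested with an unpaired two-sided
Student's t-test (pooled variance, with an F-test variance check).

Before unmixing, every spectrum is preprocessed: PCA-based outlier screening
(Q residuals and Hotelling's T²) with automated cosmic-ray confirmation and
repair, iterative polynomial baseline correction restricted to the
700–1800 cm⁻¹ fingerprint region, Savitzky–Golay smoothing, and a
per-dataset intensity normalisation.

A first-class phantom generator (`build_phantom()`) simulates whole
acquisitions — parametric Raman band spectra, geometric cell compartments
with partial-volume boundaries, fluorescence baselines, shot noise, cosmic
rays — together with the ground truth, so the entire pipeline is testable
without any instrument data.

## Worked example

```r
library(volraman)

# simulate a macrophage-like cell: 40 x 40 x 10 voxels, 0.65 um laterally,
# 1 um z steps, 25 dB SNR, fluorescence baselines and cosmic rays included
ph  <- build_phantom(macrophage_phantom_spec(seed = 1))
vol <- preprocess_volume(ph$volume)          # despike, baseline, smooth, crop
fit <- raman_unmix(vol, p = 6, seed = 1)     # VCA + NNLS + band-library labels
fit
#> Spectral unmixing fit 'macrophage_1': 16000 voxels x 551 channels, 6 endmembers
#>   components: nucleus, cholesterol, cytoplasm, TAG, medium, phospholipid
#>   VCA: seed 1, SNR est. 26.6 dB (projective projection)

cvs <- component_volumes(fit)                # refolded 3D abundance maps
th  <- component_threshold(cvs$cholesterol)  # experiment-wide mean threshold
count_voxels(cvs$cholesterol, th)
#>   sample_id   component   threshold voxels_above total_voxels percent
#> 1    sample cholesterol 0.007259612          168        16000    1.05
```

The printed `percent` is the cholesterol voxel fraction of the whole imaged
volume (here 1.05%, against a ground-truth thresholded fraction of 1.05% for
this phantom). `plot(fit)` draws the labelled endmember spectra as offset
traces; `export_component_tiff()` writes any component volume as a
multi-page float TIFF for 3D rendering.

Multi-sample experiments run through one call:

```r
pipe <- run_pipeline(list(cellA = volA, cellB = volB, ...), p = 6,
                     groups = c("A", "A", "B", "B"), output_dir = "out")
```

which extracts one pooled endmember basis for all samples, quantifies every
component in every sample against shared thresholds, performs the group
tests, and writes endmember tables, component TIFFs, quantification and
comparison CSVs and a JSON run log. `run_pipeline(..., collapse = TRUE)`
first sums each stack over z — a simulated non-confocal acquisition used as
a specificity control. A thin command-line wrapper lives at
`inst/cli/volraman.R`.

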
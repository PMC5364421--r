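test_that("synthetic band spectra place peaks where they belong", {
  wn <- seq(0, 3000, by = 5)
  s <- synth_spectrum(list(peak_band(1008, 15, 1)), wn)
  expect_equal(wn[which.max(s)], 1010)                # nearest channel to 1008
  expect_equal(synth_spectrum(list(), wn), rep(0, length(wn)))
  # linearity: two well-separated bands integrate like the sum of singles
  b1 <- list(peak_band(800, 12, 1)); b2 <- list(peak_band(2000, 20, 0.5))
  both <- synth_spectrum(c(b1, b2), wn)
  expect_equal(sum(both), sum(synth_spectrum(b1, wn)) + sum(synth_spectrum(b2, wn)),
               tolerance = 1e-8)
  # lorentzian profile hits half maximum at half the fwhm
  lor <- synth_spectrum(list(peak_band(1500, 100, 2, "lorentzian")), wn)
  expect_equal(lor[wn == 1550], 1, tolerance = 1e-6)
  expect_error(peak_band(1000, -5, 1), "fwhm")
  expect_error(peak_band(1000, 5, -1), "amplitude")
})

test_that("phantom builds are bit-reproducible for a fixed spec", {
  spec <- macrophage_phantom_spec(seed = 77, wavenumbers = coarse_axis(),
                                  grid = coarse_grid(10, 10, 4))
  ph1 <- build_phantom(spec)
  ph2 <- build_phantom(spec)
  expect_identical(ph1$volume$intensities, ph2$volume$intensities)
  expect_identical(ph1$truth$cosmic, ph2$truth$cosmic)
  # a different seed changes the realisation
  ph3 <- build_phantom(macrophage_phantom_spec(seed = 78, wavenumbers = coarse_axis(),
                                               grid = coarse_grid(10, 10, 4)))
  expect_false(identical(ph1$volume$intensities, ph3$volume$intensities))
})

test_that("true abundances sum to at most 1 per voxel", {
  ph <- build_phantom(macrophage_phantom_spec(
    seed = 79, wavenumbers = coarse_axis(), grid = coarse_grid(14, 14, 6)))
  total <- Reduce(`+`, ph$truth$abundances)
  expect_lte(max(total), 1 + 1e-12)
  expect_gte(min(total), 1 - 1e-12)      # compartments partition the grid
  for (a in ph$truth$abundances) expect_true(all(a >= 0 & a <= 1))
})

test_that("supersampled sphere fractions approach the analytic volume", {
  wn <- seq(700, 1800, by = 50)
  g <- voxel_grid(20, 20, 10, dx = 1, dy = 1, dz = 1)
  comps <- list(
    phantom_compartment("ball", "sphere", c(10, 10, 5), 4,
                        bands = list(peak_band(1000, 20, 1))),
    phantom_compartment("rest", "background", bands = list(peak_band(1500, 20, 1))))
  frac <- function(ss) {
    spec <- phantom_spec(g, wn, comps, baseline_scale = 0, snr_db = Inf,
                         n_cosmic = 0, supersample = ss, seed = 1)
    ph <- build_phantom(spec)
    ph$truth$fractions$fraction_volume[1]
  }
  analytic <- (4 / 3) * pi * 4^3 / (20 * 20 * 10)
  err2 <- abs(frac(2L) - analytic)
  err4 <- abs(frac(4L) - analytic)
  expect_lt(err4, err2)
  expect_lt(err4 / analytic, 0.01)
})

test_that("noiseless phantoms are exact mixtures recovered by the pipeline", {
  ph <- build_phantom(macrophage_phantom_spec(
    seed = 80, wavenumbers = coarse_axis(), grid = coarse_grid(16, 16, 6),
    snr_db = Inf, baseline_scale = 0, n_cosmic = 0))
  A <- sapply(ph$truth$abundances, as.numeric)
  um <- unfold_volume(ph$volume)
  expect_equal(um$D, A %*% ph$truth$endmembers, tolerance = 1e-12,
               ignore_attr = TRUE)
  # unmix without preprocessing: abundances of pure voxels recovered exactly
  fit <- raman_unmix(ph$volume, p = 6, seed = 1, spectral_range = c(700, 1800),
                     rescale_quantile = NULL)
  C <- coef(fit, raw = TRUE)
  pure <- which(apply(A, 1, max) == 1)
  # endmember j's source voxel is pure in exactly one truth component
  truth_of_em <- apply(A[fit$endmembers$source_voxels, , drop = FALSE], 1, which.max)
  expect_setequal(truth_of_em, seq_len(ncol(A)))
  ord <- match(seq_len(ncol(A)), truth_of_em)
  rmse <- sqrt(mean((C[pure, ord] - A[pure, ])^2))
  expect_lt(rmse, 1e-6)
})

test_that("cosmic spikes are injected where the record says", {
  ph <- build_phantom(macrophage_phantom_spec(
    seed = 81, wavenumbers = coarse_axis(), grid = coarse_grid(12, 12, 4),
    n_cosmic = 3))
  cs <- ph$truth$cosmic
  expect_gt(nrow(cs), 0)
  clean <- build_phantom(macrophage_phantom_spec(
    seed = 81, wavenumbers = coarse_axis(), grid = coarse_grid(12, 12, 4),
    n_cosmic = 0))
  for (i in seq_len(nrow(cs))) {
    delta <- ph$volume$intensities[cs$x[i], cs$y[i], cs$layer[i], ] -
      clean$volume$intensities[cs$x[i], cs$y[i], cs$layer[i], ]
    expect_gt(max(delta), 10 * ph$truth$noise_sigma)
  }
})

test_that("two-group experiments produce jittered, seed-stable bundles", {
  mk <- function(seed, jitter) macrophage_phantom_spec(
    seed = seed, wavenumbers = coarse_axis(), grid = coarse_grid(8, 8, 4),
    jitter = jitter)
  ex <- two_group_experiment(mk, mk, n_per_group = 2, seed = 5)
  expect_length(ex$A, 2L)
  expect_length(ex$B, 2L)
  expect_false(identical(ex$A[[1]]$volume$intensities,
                         ex$A[[2]]$volume$intensities))
  ex2 <- two_group_experiment(mk, mk, n_per_group = 2, seed = 5)
  expect_identical(ex$A[[1]]$volume$intensities, ex2$A[[1]]$volume$intensities)
  expect_error(two_group_experiment(mk, mk, n_per_group = 1), "at least 2")
})
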
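test_that("univariate band maps track the underlying component", {
  ph <- build_phantom(macrophage_phantom_spec(
    seed = 12, wavenumbers = coarse_axis(), grid = coarse_grid(16, 16, 6),
    snr_db = 30, baseline_scale = 0, n_cosmic = 0))
  bm <- univariate_band_map(ph$volume, 1008)
  truth <- ph$truth$abundances$cytoplasm
  expect_gt(cor(as.numeric(bm$values), as.numeric(truth)), 0.9)
  expect_true(all(bm$values >= 0 & bm$values <= 1))
  expect_error(univariate_band_map(ph$volume, 5000), "outside")
})

test_that("constant-spectrum volumes map to all-zero band images", {
  g <- voxel_grid(4, 4, 2)
  vol <- hyper_volume(array(2, dim = c(4, 4, 2, 10)),
                      seq(700, 1600, by = 100), g)
  bm <- univariate_band_map(vol, 1000)
  expect_true(all(bm$values == 0))
})

test_that("the PEG 847 band highlights hydrogel, not cell, voxels", {
  ph <- build_phantom(hydrogel_phantom_spec(
    seed = 13, wavenumbers = coarse_axis(), grid = coarse_grid(16, 16, 6),
    snr_db = 30, baseline_scale = 0, n_cosmic = 0))
  bm <- univariate_band_map(ph$volume, 847)
  gel <- ph$truth$abundances$PEG > 0.99
  cell <- ph$truth$abundances$cytoplasm > 0.99
  expect_gt(mean(bm$values[gel]), 3 * mean(bm$values[cell]))
  # gel spectra peak at the PEG band
  gel_vox <- which(gel, arr.ind = TRUE)[1, ]
  spec <- ph$volume$intensities[gel_vox[1], gel_vox[2], gel_vox[3], ]
  expect_lt(abs(ph$volume$wavenumbers[which.max(spec)] - 847), 10)
})

test_that("endmembers earn labels through their diagnostic bands", {
  wn <- seq(600, 1900, by = 2)
  S <- rbind(synth_spectrum(phantom_bands("TAG"), wn),
             synth_spectrum(phantom_bands("cholesterol"), wn),
             rep(0.5, length(wn)))                      # flat spectrum
  em <- structure(list(S = S, labels = paste0("component_", 1:3),
                       source_voxels = 1:3, wavenumbers = wn, p = 3L,
                       snr_db = NA_real_, projective = TRUE),
                  class = "endmember_set")
  lab <- label_endmembers(em)
  expect_identical(lab$labels[1], "TAG")
  expect_identical(lab$labels[2], "cholesterol")
  expect_identical(lab$labels[3], "unassigned")
  expect_equal(unname(lab$score_table[2, "cholesterol"]), 1)  # 1066 and 1134 hit
  expect_equal(unname(lab$score_table[3, "TAG"]), 0)
})

test_that("library bands outside the axis are skipped, not failed", {
  wn <- seq(700, 1800, by = 2)                           # excludes 2857 and 485
  S <- rbind(synth_spectrum(phantom_bands("cytoplasm"), wn))
  em <- structure(list(S = S, labels = "component_1", source_voxels = 1L,
                       wavenumbers = wn, p = 1L, snr_db = NA_real_,
                       projective = TRUE), class = "endmember_set")
  lab <- label_endmembers(em)
  expect_identical(lab$labels, "cytoplasm")
  expect_true(is.na(lab$score_table[1, "lipids"]))
  expect_true(is.na(lab$score_table[1, "glycogen"]))
})

test_that("band library round trips through JSON and ships as extdata", {
  lib <- default_band_library()
  path <- withr::local_tempfile(fileext = ".json")
  write_band_library(lib, path)
  lib2 <- read_band_library(path)
  expect_equal(lib2, lib)
  shipped <- read_band_library(system.file("extdata", "band_library.json",
                                           package = "volraman"))
  expect_equal(vapply(shipped, `[[`, character(1), "label"),
               vapply(lib, `[[`, character(1), "label"))
})

test_that("component-count sweep peaks at the true component number", {
  ph <- build_phantom(macrophage_phantom_spec(
    seed = 14, wavenumbers = coarse_axis(), grid = coarse_grid(20, 20, 8),
    n_cosmic = 0))
  vol <- preprocess_volume(ph$volume)
  nmz <- normalize_dataset(unfold_volume(vol))$D_norm
  sw <- sweep_component_count(nmz, p_range = c(2, 4, 6, 8), seed = 1,
                              wavenumbers = vol$wavenumbers)
  expect_identical(sw$p, c(2L, 4L, 6L, 8L))
  expect_identical(max(sw$n_assigned), max(sw$n_assigned[sw$p >= 6]))
  expect_lte(max(sw$n_assigned), 6L)                     # six real materials
  expect_true(all(diff(sw$n_assigned[sw$p <= 6]) >= 0))
})

test_that("a single-entry sweep returns one row; pure noise assigns nothing", {
  set.seed(15)
  noise <- matrix(rnorm(200 * 60), 200, 60)
  wn <- seq(700, 1790, length.out = 60)
  sw <- sweep_component_count(noise, p_range = 1L, seed = 1, wavenumbers = wn)
  expect_identical(nrow(sw), 1L)
  sw_multi <- sweep_component_count(noise, p_range = c(2, 4), seed = 1,
                                    wavenumbers = wn)
  expect_true(all(sw_multi$n_assigned == 0L))
})
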
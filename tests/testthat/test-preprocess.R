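test_that("Savitzky-Golay with a 3-point window and order 2 is the identity", {
  set.seed(1)
  y <- rnorm(80)
  expect_equal(savitzky_golay(y, 3, 2), y, tolerance = 1e-12)
})

test_that("Savitzky-Golay leaves polynomials of degree <= order invariant", {
  x <- seq_len(120)
  for (ord in c(2L, 3L)) {
    y <- 2 - 0.3 * x + 0.01 * x^2 + if (ord >= 3) 1e-4 * x^3 else 0
    for (win in c(5L, 9L))
      expect_equal(savitzky_golay(y, win, ord), y, tolerance = 1e-8)
  }
})

test_that("Savitzky-Golay matches the brute-force local-fit oracle", {
  set.seed(2)
  y <- cumsum(rnorm(60)) + rnorm(60)
  for (case in list(c(5L, 2L), c(7L, 3L), c(9L, 2L))) {
    got <- savitzky_golay(y, case[1L], case[2L])
    want <- sg_oracle(y, case[1L], case[2L])
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(savitzky_golay(y, 4L, 2L), "odd")
  expect_error(savitzky_golay(y, 5L, 5L), "order")
  expect_error(savitzky_golay(y[1:3], 5L, 2L), "shorter")
})

test_that("baseline correction removes a pure cubic to float precision", {
  wn <- seq(0, 3000, by = 5)
  t <- wn / 3000
  y <- 3 + 1.2 * t - 2 * t^2 + 0.8 * t^3
  bl <- wls_baseline(y, wn)
  expect_true(bl$converged)
  expect_lt(max(abs(bl$corrected)), 1e-8 * max(abs(y)))
  expect_true(all(bl$wavenumbers >= 700 & bl$wavenumbers <= 1800))
})

test_that("baseline correction preserves an isolated band height within 2%", {
  wn <- seq(0, 3000, by = 5)
  t <- wn / 3000
  base <- 2 + 0.9 * t - 1.1 * t^2 + 0.5 * t^3
  for (centre in c(900, 1250, 1700)) {
    band <- 0.7 * exp(-4 * log(2) * ((wn - centre) / 16)^2)
    bl <- wls_baseline(base + band, wn)
    # oracle: fit the cubic with the known peak support masked out
    keep <- bl$channels
    mask <- abs(wn[keep] - centre) > 60
    fit <- lm(yy ~ poly(tt, 3, raw = TRUE),
              data = data.frame(tt = t[keep][mask], yy = (base + band)[keep][mask]))
    oracle_base <- predict(fit, newdata = data.frame(tt = t[keep]))
    oracle_h <- max(((base + band)[keep] - oracle_base)[abs(wn[keep] - centre) < 10])
    got_h <- max(bl$corrected[abs(bl$wavenumbers - centre) < 10])
    expect_lt(abs(got_h - 0.7) / 0.7, 0.02)
    expect_equal(got_h, oracle_h, tolerance = 0.02)
  }
})

test_that("baseline of an all-zero spectrum is zero and converges", {
  wn <- seq(0, 3000, by = 10)
  bl <- wls_baseline(rep(0, length(wn)), wn)
  expect_true(bl$converged)
  expect_equal(max(abs(bl$corrected)), 0)
  expect_equal(max(abs(bl$baseline)), 0)
  expect_error(wls_baseline(rep(1, 301), wn, range = c(700, 712)), "channels")
})

test_that("PCA outlier limits control false flags on clean mixture spectra", {
  dat <- make_simplex_data(p = 3, M = 500, w = 121, seed = 31, snr_db = 20)
  rep_clean <- fit_pca_outliers(dat$D, preprocess_config())
  expect_lte(mean(rep_clean$flagged), 0.01)
  expect_gt(attr(rep_clean, "Q_limit"), 0)
  expect_gt(attr(rep_clean, "T2_limit"), 0)
})

test_that("single-channel spikes are flagged, confirmed and repaired", {
  dat <- make_simplex_data(p = 3, M = 500, w = 121, seed = 32, snr_db = 20)
  # reconstruct the generator's noise sigma from its dataset-SNR definition
  sigma <- sqrt(mean(rowSums((dat$A %*% dat$S)^2)) / (121 * 10^2))
  clean <- dat$D
  spiked_rows <- seq(10, 100, by = 10)
  set.seed(33)
  for (i in spiked_rows) {
    ch <- sample(5:115, 1)
    dat$D[i, ch] <- dat$D[i, ch] + 50 * sigma
  }
  rep_sp <- fit_pca_outliers(dat$D, preprocess_config())
  expect_true(all(rep_sp$flagged[spiked_rows]))
  fixed <- repair_cosmic_rays(dat$D, rep_sp)
  expect_true(all(fixed$report$confirmed[spiked_rows]))
  # repaired channels return close to the clean spectra
  err <- abs(fixed$spectra[spiked_rows, ] - clean[spiked_rows, ])
  expect_lt(max(err), 6 * sigma)
  # unflagged spectra are untouched bit for bit
  untouched <- setdiff(seq_len(500), which(fixed$report$flagged))
  expect_identical(fixed$spectra[untouched, ], dat$D[untouched, ])
})

test_that("broad anomalies are flagged but not confirmed or altered", {
  dat <- make_simplex_data(p = 3, M = 200, w = 121, seed = 34, snr_db = 25)
  dat$D[7, 40:59] <- dat$D[7, 40:59] + 0.5 * max(dat$D)   # 20-channel bump
  rep_b <- fit_pca_outliers(dat$D, preprocess_config())
  expect_true(rep_b$flagged[7])
  fixed <- repair_cosmic_rays(dat$D, rep_b)
  expect_false(fixed$report$confirmed[7])
  expect_identical(fixed$spectra[7, ], dat$D[7, ])
})

test_that("degenerate identical spectra produce no flags and a warning", {
  D <- matrix(rep(c(1, 2, 3, 2, 1), each = 4), nrow = 4)
  expect_warning(rep_d <- fit_pca_outliers(D, preprocess_config()), "degenerate")
  expect_false(any(rep_d$flagged))
})

test_that("dataset normalisation is scale invariant with unit mean sum", {
  set.seed(4)
  D <- matrix(rexp(200, rate = 1 / 40), 20, 10)
  n1 <- normalize_dataset(D)
  expect_equal(mean(rowSums(n1$D_norm)), 1)
  n3 <- normalize_dataset(3 * D)
  expect_equal(n1$D_norm, n3$D_norm)
  expect_equal(n3$scale, 3 * n1$scale)
  # mode none is the identity
  expect_identical(normalize_dataset(D, "none")$D_norm, D)
  expect_error(normalize_dataset(-D), "<= 0")
})

test_that("full preprocessing recovers ground-truth mixtures at 25 dB", {
  # 2 cm^-1 sampling: spike/band discrimination needs sampling finer than the
  # band width, as on the real instrument
  ph <- build_phantom(macrophage_phantom_spec(
    seed = 6, wavenumbers = seq(600, 1900, by = 2), grid = coarse_grid(16, 16, 6),
    snr_db = 25))
  vol <- preprocess_volume(ph$volume)
  expect_identical(dim(vol$intensities)[1:3], c(16L, 16L, 6L))
  expect_true(all(vol$wavenumbers >= 700 & vol$wavenumbers <= 1800))
  # voxel count unchanged by repair (never delete)
  expect_equal(prod(dim(vol$intensities)[1:3]), 16 * 16 * 6)
  # mean spectral angle between processed and ground-truth baseline-free
  # mixtures, over interior cell voxels (medium voxels are noise-on-noise)
  keep <- ph$volume$wavenumbers >= 700 & ph$volume$wavenumbers <= 1800
  A <- sapply(ph$truth$abundances, as.numeric)
  truth_mix <- A %*% ph$truth$endmembers[, keep]
  um <- unfold_volume(vol)
  cellular <- setdiff(colnames(A), "medium")
  cell_vox <- which(rowSums(A[, cellular, drop = FALSE]) >= 0.99)
  angles <- vapply(cell_vox, function(m) spectral_angle(um$D[m, ], truth_mix[m, ]),
                   numeric(1))
  # the white-noise floor alone puts this mean near 0.08 rad at 25 dB dataset
  # SNR; preprocessing must not add materially on top of it
  expect_lt(mean(angles, na.rm = TRUE), 0.1)
  log <- attr(vol, "preprocess_log")
  expect_length(log$flagged_per_layer, 6L)
})

test_that("noise-free, baseline-free phantoms pass through almost unchanged", {
  ph <- build_phantom(macrophage_phantom_spec(
    seed = 8, wavenumbers = seq(600, 1900, by = 2), grid = coarse_grid(12, 12, 4),
    snr_db = Inf, baseline_scale = 0, n_cosmic = 0))
  vol <- preprocess_volume(ph$volume)
  keep <- ph$volume$wavenumbers >= 700 & ph$volume$wavenumbers <= 1800
  orig <- ph$volume$intensities[, , , keep, drop = FALSE]
  # deviations are confined to what an envelope-following baseline cannot
  # distinguish from background: band freedom at the window edges (719 and
  # 1747 cm^-1) and partial absorption of the medium's broad 1640 cm^-1 band;
  # narrow cellular bands in the window interior pass through within ~2%
  # of the peak intensity
  expect_lt(max(abs(vol$intensities - orig)), 0.05 * max(orig))
  A <- sapply(ph$truth$abundances, as.numeric)
  cell <- rowSums(A[, setdiff(colnames(A), "medium"), drop = FALSE]) >= 0.99
  interior <- vol$wavenumbers > 760 & vol$wavenumbers < 1650
  err <- vol$intensities - orig
  dim(err) <- c(length(cell), length(vol$wavenumbers))
  expect_lt(max(abs(err[cell, interior])), 0.02 * max(orig))
})
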
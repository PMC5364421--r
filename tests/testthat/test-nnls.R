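make_endmember_set <- function(S, wn = seq_len(ncol(S))) {
  structure(list(S = S, labels = paste0("component_", seq_len(nrow(S))),
                 source_voxels = seq_len(nrow(S)), wavenumbers = wn,
                 p = nrow(S), snr_db = NA_real_, projective = TRUE),
            class = "endmember_set")
}

test_that("exact convex mixtures are recovered to machine precision", {
  set.seed(40)
  S <- matrix(runif(2 * 50), 2, 50)
  d <- 0.3 * S[1, ] + 0.7 * S[2, ]
  ab <- nnls_abundances(rbind(d), make_endmember_set(S), rescale_quantile = NULL)
  expect_equal(as.numeric(ab$C_raw), c(0.3, 0.7), tolerance = 1e-10)
})

test_that("negative-coefficient directions hit the active constraint at zero", {
  set.seed(41)
  s1 <- runif(40)
  s2 <- rnorm(40)
  s2 <- s2 - s1 * sum(s2 * s1) / sum(s1^2) + 0.05 * s1   # near-orthogonal
  d <- s1 - 0.5 * s2
  A <- cbind(s1, s2)
  ab <- nnls_abundances(rbind(d), make_endmember_set(t(A)), rescale_quantile = NULL)
  oracle <- nnls_oracle(A, d)
  expect_equal(unname(ab$C_raw[1, 2]), 0)
  expect_equal(as.numeric(ab$C_raw), oracle$x, tolerance = 1e-6)
})

test_that("solutions match the exhaustive active-set oracle on random problems", {
  set.seed(42)
  for (rep in 1:25) {
    p <- sample(2:5, 1)
    w <- sample(10:40, 1)
    A <- matrix(rnorm(w * p), w, p)
    b <- rnorm(w)
    ab <- nnls_abundances(rbind(b), make_endmember_set(t(A)),
                          rescale_quantile = NULL)
    got_obj <- sum((A %*% ab$C_raw[1, ] - b)^2)
    oracle <- nnls_oracle(A, b)
    expect_lte(got_obj, oracle$obj + 1e-6)
    expect_equal(got_obj, oracle$obj, tolerance = 1e-6)
    # KKT: zero gradient on the support, non-negative gradient off it
    grad <- drop(crossprod(A, A %*% ab$C_raw[1, ] - b))
    on <- ab$C_raw[1, ] > 1e-10
    if (any(on)) expect_lt(max(abs(grad[on])), 1e-6 * max(1, max(abs(grad))))
    if (any(!on)) expect_gt(min(grad[!on]), -1e-6 * max(1, max(abs(grad))))
  }
})

test_that("batched solutions agree with pracma's reference NNLS", {
  skip_if_not_installed("pracma")
  set.seed(43)
  p <- 5; w <- 60; M <- 50
  S <- matrix(runif(p * w), p, w)
  D <- matrix(rexp(M * p), M, p) %*% S + matrix(rnorm(M * w, sd = 0.02), M, w)
  ab <- nnls_abundances(D, make_endmember_set(S), rescale_quantile = NULL)
  for (m in seq_len(M)) {
    ref <- pracma::lsqnonneg(t(S), D[m, ])
    got_obj <- sum((t(S) %*% ab$C_raw[m, ] - D[m, ])^2)
    expect_equal(got_obj, ref$resid.norm, tolerance = 1e-6)
    expect_equal(unname(ab$C_raw[m, ]), ref$x, tolerance = 1e-5)
  }
})

test_that("rescaled abundances stay in [0,1] and record their factors", {
  set.seed(44)
  dat <- make_simplex_data(3, M = 300, w = 50, seed = 44, snr_db = 25)
  em <- vca(dat$D, 3, seed = 1)
  ab <- nnls_abundances(dat$D, em)
  expect_true(all(ab$C >= 0 & ab$C <= 1))
  expect_length(ab$rescale_factors, 3L)
  expect_true(all(ab$rescale_factors > 0))
  # rescaling is per component: column j equals clipped C_raw * factor
  for (j in 1:3)
    expect_equal(ab$C[, j], pmin(pmax(ab$C_raw[, j] * ab$rescale_factors[j], 0), 1))
})

test_that("permuting endmembers permutes abundance columns identically", {
  set.seed(45)
  dat <- make_simplex_data(4, M = 120, w = 40, seed = 45, snr_db = 30)
  em <- vca(dat$D, 4, seed = 1)
  perm <- c(3L, 1L, 4L, 2L)
  em_p <- em
  em_p$S <- em$S[perm, , drop = FALSE]
  em_p$labels <- em$labels[perm]
  em_p$source_voxels <- em$source_voxels[perm]
  ab <- nnls_abundances(dat$D, em, rescale_quantile = NULL)
  ab_p <- nnls_abundances(dat$D, em_p, rescale_quantile = NULL)
  expect_equal(ab_p$C_raw, ab$C_raw[, perm], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("an all-zero endmember row is rejected", {
  S <- rbind(runif(20), 0)
  expect_error(nnls_abundances(matrix(runif(40), 2, 20), make_endmember_set(S)),
               "zero")
})

test_that("raw objective never exceeds the clipped unconstrained solution", {
  set.seed(46)
  for (rep in 1:10) {
    A <- matrix(rnorm(30 * 4), 30, 4)
    b <- rnorm(30)
    ab <- nnls_abundances(rbind(b), make_endmember_set(t(A)),
                          rescale_quantile = NULL)
    ls_clip <- pmax(qr.solve(A, b), 0)
    expect_lte(sum((A %*% ab$C_raw[1, ] - b)^2),
               sum((A %*% ls_clip - b)^2) + 1e-10)
  }
})
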
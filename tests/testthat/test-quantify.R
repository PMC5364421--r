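cv_of <- function(values, label = "c") {
  d <- dim(values)
  component_volume(values, voxel_grid(d[1], d[2], d[3]), label)
}

test_that("mean thresholds pool the experiment's volumes", {
  const <- cv_of(array(0.5, dim = c(4, 4, 2)))
  expect_equal(component_threshold(const), 0.5)
  half <- array(0, dim = c(10, 10, 1)); half[1:50] <- 0.8
  expect_equal(component_threshold(cv_of(half)), 0.4)
  # pooling two volumes fixes one threshold for both samples
  a <- cv_of(array(0.2, dim = c(2, 2, 2)))
  b <- cv_of(array(0.6, dim = c(2, 2, 2)))
  expect_equal(component_threshold(list(a, b)), 0.4)
  expect_equal(component_threshold(a, mode = "fixed", value = 0.25), 0.25)
  expect_error(component_threshold(a, mode = "fixed"), "fixed")
})

test_that("voxel counting is inclusive at the threshold", {
  const <- cv_of(array(0.5, dim = c(5, 5, 4)))
  rec <- count_voxels(const, 0.5)
  expect_equal(rec$percent, 100)
  expect_equal(rec$total_voxels, 100L)
  onehot <- array(0, dim = c(10, 10, 10)); onehot[3, 4, 5] <- 1
  rec1 <- count_voxels(cv_of(onehot), 0.9)
  expect_equal(rec1$voxels_above, 1L)
  expect_equal(rec1$percent, 0.1)
  expect_error(count_voxels(const, 1.5), "threshold")
})

test_that("percent is non-increasing in the threshold with exact endpoints", {
  set.seed(50)
  vals <- array(runif(8 * 8 * 4, min = 0.01), dim = c(8, 8, 4))
  cv <- cv_of(vals)
  ths <- seq(0, 1, by = 0.05)
  pcts <- vapply(ths, function(t) count_voxels(cv, t)$percent, numeric(1))
  expect_true(all(diff(pcts) <= 0))
  expect_equal(pcts[1], 100)                      # threshold 0, strictly positive
  expect_equal(count_voxels(cv, 1)$percent, 0)    # above the maximum
})

test_that("identical groups give t = 0, p = 1 and no stars", {
  cmp <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)
  expect_identical(cmp$stars, "")
})

test_that("well-separated groups earn three stars", {
  cmp <- compare_groups(c(10, 11, 12, 13), c(30, 31, 32, 33))
  oracle <- ttest_oracle(c(10, 11, 12, 13), c(30, 31, 32, 33))
  expect_equal(cmp$t, oracle$t, tolerance = 1e-12)
  expect_equal(cmp$p, oracle$p, tolerance = 1e-12)
  expect_lt(cmp$p, 0.001)
  expect_identical(cmp$stars, "***")
  expect_equal(cmp$df, 6)
})

test_that("compare_groups matches the closed-form oracle on random pairs", {
  set.seed(51)
  for (rep in 1:50) {
    a <- rnorm(sample(2:8, 1), mean = runif(1, 0, 10), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:8, 1), mean = runif(1, 0, 10), sd = runif(1, 0.5, 3))
    cmp <- compare_groups(a, b)
    oracle <- ttest_oracle(a, b)
    expect_equal(cmp$t, oracle$t, tolerance = 1e-10)
    expect_equal(cmp$p, oracle$p, tolerance = 1e-10)
    expect_equal(cmp$df, oracle$df)
    # symmetry: swapping groups flips t and preserves p
    swap <- compare_groups(b, a)
    expect_equal(swap$t, -cmp$t, tolerance = 1e-10)
    expect_equal(swap$p, cmp$p, tolerance = 1e-10)
  }
})

test_that("degenerate variances and small groups are handled explicitly", {
  expect_error(compare_groups(1, c(2, 3)), "at least 2")
  same <- compare_groups(c(5, 5, 5), c(5, 5))
  expect_equal(same$p, 1)
  diff_const <- compare_groups(c(5, 5, 5), c(7, 7))
  expect_equal(diff_const$p, 0)
  # F statistic and normality report present on regular input
  cmp <- compare_groups(rnorm(5), rnorm(5))
  expect_true(is.finite(cmp$F))
  expect_true(cmp$p_F > 0 && cmp$p_F <= 1)
})

test_that("z-collapse sums over depth and rescales dz", {
  v <- random_volume(4, 3, 5, 6, seed = 52)
  zc <- z_collapse(v)
  expect_identical(zc$grid$Z, 1L)
  expect_equal(zc$grid$dz, 5)
  expect_equal(zc$intensities[2, 3, 1, ], colSums(v$intensities[2, 3, , ]))
  # constant stack: collapse equals Z times one layer
  cv <- hyper_volume(array(2, dim = c(2, 2, 10, 3)), c(1, 2, 3), voxel_grid(2, 2, 10))
  expect_true(all(z_collapse(cv)$intensities == 20))
  # Z = 1 is the identity
  expect_identical(z_collapse(zc), zc)
})

test_that("z-collapse is linear in the input volumes", {
  v1 <- random_volume(3, 3, 4, 5, seed = 53)
  v2 <- random_volume(3, 3, 4, 5, seed = 54)
  mix <- hyper_volume(2 * v1$intensities + 3 * v2$intensities,
                      v1$wavenumbers, v1$grid)
  lhs <- z_collapse(mix)$intensities
  rhs <- 2 * z_collapse(v1)$intensities +
    3 * z_collapse(hyper_volume(v2$intensities, v1$wavenumbers, v1$grid))$intensities
  expect_equal(lhs, rhs, tolerance = 1e-12)
})
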
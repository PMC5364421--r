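# Independent oracles and small fixture builders shared across the suite.
# Each oracle is a deliberately naive, brute-force computation kept separate
# from the implementation path it checks.

# Savitzky-Golay by explicit per-window polynomial fits (interior points) and
# terminal-window polynomial evaluation at the edges.
sg_oracle <- function(y, window, order) {
  w <- length(y)
  half <- (window - 1L) %/% 2L
  out <- numeric(w)
  for (i in seq_len(w)) {
    lo <- max(1L, min(i - half, w - window + 1L))
    idx <- lo:(lo + window - 1L)
    fit <- stats::lm(yy ~ poly(xx, order, raw = TRUE),
                     data = data.frame(xx = idx, yy = y[idx]))
    out[i] <- unname(stats::predict(fit, newdata = data.frame(xx = i)))
  }
  out
}

# NNLS by exhaustive active-set enumeration: try every subset of coefficients
# allowed to be positive, solve the unconstrained LS on that subset, keep the
# best feasible solution.
nnls_oracle <- function(A, b) {
  p <- ncol(A)
  best <- list(x = numeric(p), obj = sum(b^2))
  for (mask in seq_len(2^p - 1L)) {
    on <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
    x <- numeric(p)
    coefs <- tryCatch(qr.solve(A[, on, drop = FALSE], b), error = function(e) NULL)
    if (is.null(coefs) || any(!is.finite(coefs)) || any(coefs < 0)) next
    x[on] <- coefs
    obj <- sum((A %*% x - b)^2)
    if (obj < best$obj - 1e-12) best <- list(x = x, obj = obj)
  }
  best
}

# Pooled-variance two-sided t-test from the textbook formulas.
ttest_oracle <- function(a, b) {
  nA <- length(a); nB <- length(b)
  sp2 <- ((nA - 1) * var(a) + (nB - 1) * var(b)) / (nA + nB - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / nA + 1 / nB))
  df <- nA + nB - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Linear simplex mixtures with planted pure voxels; optional white noise at a
# dataset SNR in dB (mean per-voxel signal energy over per-voxel noise energy).
make_simplex_data <- function(p, M, w, seed, snr_db = Inf, pure_per_comp = 1L) {
  set.seed(seed)
  S <- matrix(0, p, w)
  centers <- seq(0.15, 0.85, length.out = p)
  x <- seq(0, 1, length.out = w)
  for (j in seq_len(p))
    S[j, ] <- exp(-((x - centers[j]) / 0.035)^2) +
      0.4 * exp(-((x - centers[j] * 0.6 - 0.05) / 0.05)^2)
  A <- matrix(stats::rexp(M * p), M, p)
  A <- A / rowSums(A)
  pure <- integer(0)
  for (j in seq_len(p)) {
    rows <- (j - 1L) * pure_per_comp + seq_len(pure_per_comp)
    A[rows, ] <- 0; A[rows, j] <- 1
    pure <- c(pure, rows)
  }
  D <- A %*% S
  if (is.finite(snr_db)) {
    sigma <- sqrt(mean(rowSums(D^2)) / (w * 10^(snr_db / 10)))
    D <- D + matrix(stats::rnorm(M * w, sd = sigma), M, w)
  }
  list(D = D, S = S, A = A, pure_voxels = pure)
}

# Small random hyper-volume for round-trip style tests.
random_volume <- function(X, Y, Z, w, seed = 1) {
  set.seed(seed)
  hyper_volume(array(stats::rnorm(X * Y * Z * w), dim = c(X, Y, Z, w)),
               sort(stats::runif(w, 100, 3000)),
               voxel_grid(X, Y, Z), sprintf("rand_%d", seed))
}

# Shared small phantom settings for fast end-to-end style tests: coarse
# voxels over the full reference field of view.
coarse_grid <- function(X = 24L, Y = 24L, Z = 8L)
  voxel_grid(X, Y, Z, dx = 26 / X, dy = 26 / Y, dz = 10 / Z)

coarse_axis <- function() seq(600, 1900, by = 5)
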
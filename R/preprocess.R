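#' Preprocessing configuration
#'
#' Parameters for the per-spectrum preprocessing chain. The Savitzky-Golay
#' defaults (3-point window, order 2) reproduce the acquisition-matched
#' setting; note that a quadratic fitted through 3 points interpolates them
#' exactly, so this default smoother is the identity transform. Wider windows
#' smooth.
#'
#' @param sg_window Odd Savitzky-Golay window length in points (>= sg_order + 1).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param baseline_order Polynomial order of the baseline model.
#' @param baseline_range Spectral window (cm^-1) the baseline is fitted on and
#'   the analysis is restricted to; default the 700-1800 cm^-1 fingerprint
#'   region.
#' @param baseline_max_iter Maximum reweighting iterations.
#' @param baseline_tol Relative L2 change of the fitted baseline that counts
#'   as convergence.
#' @param cr_variance_kept Fraction of variance the PCA outlier model retains.
#' @param cr_conf_level Confidence level for the Q and Hotelling T-squared
#'   control limits.
#' @param cr_k_mad Spike-confirmation threshold in MADs above the local
#'   rolling median.
#' @param normalize_mode `"dataset_mean"` (divide the whole unfolded matrix by
#'   the mean per-spectrum summed intensity) or `"none"`.
#' @param smooth_before_baseline If `TRUE`, smoothing runs before baseline
#'   correction; default after.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window = 3L, sg_order = 2L,
                              baseline_order = 3L, baseline_range = c(700, 1800),
                              baseline_max_iter = 100L, baseline_tol = 1e-4,
                              cr_variance_kept = 0.95, cr_conf_level = 0.999,
                              cr_k_mad = 8, normalize_mode = "dataset_mean",
                              smooth_before_baseline = FALSE) {
  sg_window <- as.integer(sg_window); sg_order <- as.integer(sg_order)
  if (sg_window %% 2L == 0L || sg_window < sg_order + 1L)
    stop("sg_window must be odd and >= sg_order + 1")
  if (baseline_order < 1L) stop("baseline_order must be >= 1")
  if (cr_conf_level <= 0 || cr_conf_level >= 1) stop("cr_conf_level must lie in (0, 1)")
  normalize_mode <- match.arg(normalize_mode, c("dataset_mean", "none"))
  structure(list(sg_window = sg_window, sg_order = sg_order,
                 baseline_order = as.integer(baseline_order),
                 baseline_range = as.numeric(baseline_range),
                 baseline_max_iter = as.integer(baseline_max_iter),
                 baseline_tol = baseline_tol,
                 cr_variance_kept = cr_variance_kept,
                 cr_conf_level = cr_conf_level, cr_k_mad = cr_k_mad,
                 normalize_mode = normalize_mode,
                 smooth_before_baseline = isTRUE(smooth_before_baseline)),
            class = "preprocess_config")
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the centre value of the least-squares polynomial of
#' the given order fitted over the sliding window; the terminal windows are
#' handled by evaluating the edge-window polynomial fit at the edge points.
#'
#' @param spectrum Numeric vector.
#' @param window Odd window length in points.
#' @param order Polynomial order, `< window`.
#' @return Smoothed vector of the same length.
#' @export
savitzky_golay <- function(spectrum, window = 3L, order = 2L) {
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L) stop("window must be odd")
  if (order >= window) stop("order must be < window")
  if (window >= length(spectrum)) stop("window must be shorter than the spectrum")
  as.numeric(signal::sgolayfilt(spectrum, p = order, n = window))
}

#' Iterative peak-suppressed polynomial baseline correction
#'
#' Fits a polynomial of order `order` to the spectrum restricted to `range`
#' by iteratively reweighted least squares with one-sided peak suppression:
#' after each fit, channels lying above the fitted curve (peaks) are clipped
#' to the fit — driving their residual pull to zero while keeping the
#' polynomial anchored across the whole window — and the fit repeats until
#' the baseline changes by less than `tol` in relative L2 norm (or `max_iter`
#' is reached, which sets `converged = FALSE`). Clipping rather than deleting
#' the above-fit channels is what keeps the fit stable when a peak sits at
#' the window edge. The corrected spectrum is `spectrum - baseline` on the
#' retained window; channels outside the window are dropped, so downstream
#' analysis proceeds on the fingerprint region.
#'
#' @param spectrum Numeric vector on `wavenumbers`.
#' @param wavenumbers Wavenumber axis (cm^-1).
#' @param order Polynomial order (default 3).
#' @param range Fit/crop window in cm^-1.
#' @param max_iter Maximum reweighting iterations.
#' @param tol Relative L2 convergence tolerance on the baseline.
#' @return List with `corrected`, `baseline`, `wavenumbers` (the retained
#'   axis), `channels` (indices retained), `converged`, `iterations`.
#' @export
wls_baseline <- function(spectrum, wavenumbers, order = 3L, range = c(700, 1800),
                         max_iter = 100L, tol = 1e-4) {
  keep <- which(wavenumbers >= range[1L] & wavenumbers <= range[2L])
  if (length(keep) <= order + 1L)
    stop(sprintf("baseline range [%g, %g] retains %d channels; need > order + 1 = %d",
                 range[1L], range[2L], length(keep), order + 1L))
  y <- spectrum[keep]
  B <- poly_basis(wavenumbers[keep], order)
  fit <- wls_baseline_fit(y, B, max_iter, tol)
  list(corrected = y - fit$baseline, baseline = fit$baseline,
       wavenumbers = wavenumbers[keep], channels = keep,
       converged = fit$converged, iterations = fit$iterations)
}

# Scaled monomial basis on [-1, 1] for conditioning.
poly_basis <- function(x, order) {
  t <- 2 * (x - min(x)) / (max(x) - min(x)) - 1
  outer(t, 0:order, `^`)
}

# Core peak-suppression loop on a precomputed basis (shared across spectra,
# so the QR of the basis is factored once per axis, not once per voxel).
wls_baseline_fit <- function(y, B, max_iter, tol, qrB = qr(B)) {
  y_work <- y
  baseline <- rep(0, length(y))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    new_baseline <- qr.fitted(qrB, y_work)
    delta <- sqrt(sum((new_baseline - baseline)^2))
    denom <- sqrt(sum(new_baseline^2))
    baseline <- new_baseline
    if (iter > 1L && delta <= tol * max(denom, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    y_work <- pmin(y_work, baseline)         # peaks stop pulling the fit up
  }
  list(baseline = baseline, converged = converged, iterations = iter)
}

# Same iteration applied to a whole layer at once (spectra in rows); the
# normal-equation solve is batched across spectra, which is what keeps the
# per-voxel baseline affordable on full z-stacks.
wls_baseline_fit_matrix <- function(Y, B, max_iter, tol) {
  BtB <- crossprod(B)
  y_work <- Y
  baseline <- matrix(0, nrow(Y), ncol(Y))
  active <- seq_len(nrow(Y))
  for (iter in seq_len(max_iter)) {
    coefs <- solve(BtB, crossprod(B, t(y_work[active, , drop = FALSE])))
    new_baseline <- t(B %*% coefs)
    delta <- sqrt(rowSums((new_baseline - baseline[active, , drop = FALSE])^2))
    denom <- pmax(sqrt(rowSums(new_baseline^2)), .Machine$double.eps)
    baseline[active, ] <- new_baseline
    if (iter > 1L) {
      done <- delta <= tol * denom            # converged rows freeze here
      if (all(done)) break
      y_work[active, ] <- pmin(y_work[active, , drop = FALSE], new_baseline)
      active <- active[!done]
    } else {
      y_work[active, ] <- pmin(y_work[active, , drop = FALSE], new_baseline)
    }
  }
  baseline
}

#' PCA-based outlier screening (Q residuals and Hotelling T-squared)
#'
#' Fits a mean-centred PCA to a layer's spectra, retaining the smallest number
#' of components that explains at least `cr_variance_kept` of the variance.
#' Each spectrum gets a Hotelling T-squared statistic (Mahalanobis distance in
#' retained score space) and a Q residual (squared norm of its reconstruction
#' residual). Control limits at `cr_conf_level` use the F-distribution form
#' for T-squared and the Jackson-Mudholkar form for Q; a spectrum is flagged
#' when either statistic exceeds its limit. The screen runs two passes:
#' spectra flagged by the first pass are excluded, the PCA model and its
#' limits are refitted on the remainder, and every spectrum is re-scored
#' against the clean model — otherwise strong cosmic rays inflate the
#' residual eigenvalues and raise the Q limit enough to hide weaker ones.
#' Flags mark cosmic-ray candidates which [repair_cosmic_rays()] then
#' confirms and repairs.
#'
#' @param spectra `n x w` matrix, one spectrum per row.
#' @param config A [preprocess_config()] (only the `cr_*` fields are used).
#' @return An object of class `outlier_report`: data frame with columns
#'   `spectrum`, `Q`, `T2`, `flagged`, plus attributes `Q_limit`, `T2_limit`,
#'   `n_components`.
#' @export
fit_pca_outliers <- function(spectra, config = preprocess_config()) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  if (n < 2L) stop("need at least 2 spectra")
  mu <- colMeans(spectra)
  Xc <- sweep(spectra, 2L, mu)
  total_var <- sum(Xc^2) / (n - 1)
  if (total_var <= .Machine$double.eps^0.5 * max(1, sum(mu^2))) {
    warning("degenerate layer: all spectra (nearly) identical; no outliers flagged")
    rep_df <- data.frame(spectrum = seq_len(n), Q = rowSums(Xc^2),
                         T2 = rep(0, n), flagged = rep(FALSE, n))
    return(structure(rep_df, class = c("outlier_report", "data.frame"),
                     Q_limit = Inf, T2_limit = Inf, n_components = 0L,
                     note = "degenerate"))
  }
  pass <- pca_outlier_pass(spectra, seq_len(n), config)
  if (any(pass$flagged)) {
    clean_rows <- which(!pass$flagged)
    if (length(clean_rows) >= max(4L, 0.5 * n)) {
      refit <- pca_outlier_pass(spectra, clean_rows, config)
      if (!is.null(refit)) pass <- refit
    }
  }
  rep_df <- data.frame(spectrum = seq_len(n), Q = pass$Q, T2 = pass$T2,
                       flagged = pass$flagged)
  structure(rep_df, class = c("outlier_report", "data.frame"),
            Q_limit = pass$Q_lim, T2_limit = pass$T2_lim,
            n_components = pass$k)
}

# One PCA screening pass: model fitted on fit_rows, statistics for all rows.
pca_outlier_pass <- function(spectra, fit_rows, config) {
  n_fit <- length(fit_rows)
  w_ch <- ncol(spectra)
  mu <- colMeans(spectra[fit_rows, , drop = FALSE])
  Xc <- sweep(spectra, 2L, mu)
  Xf <- Xc[fit_rows, , drop = FALSE]
  if (n_fit <= w_ch) {
    eg <- eigen(tcrossprod(Xf), symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    load_fun <- function(k) {
      pos <- pmax(ev[seq_len(k)], .Machine$double.eps)
      crossprod(Xf, eg$vectors[, seq_len(k), drop = FALSE]) %*%
        diag(1 / sqrt(pos), k)
    }
  } else {
    eg <- eigen(crossprod(Xf), symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    load_fun <- function(k) eg$vectors[, seq_len(k), drop = FALSE]
  }
  lambda <- ev / (n_fit - 1)
  lambda <- lambda[lambda > .Machine$double.eps * max(lambda, 0)]
  if (length(lambda) == 0L) return(NULL)
  cum <- cumsum(lambda) / sum(lambda)
  k <- which(cum >= config$cr_variance_kept)[1L]
  k <- min(k, n_fit - 2L, length(lambda))    # keep residual df for the limits
  k <- max(k, 1L)
  V <- load_fun(k)                           # w x k orthonormal loadings
  scores <- Xc %*% V
  T2 <- rowSums(sweep(scores^2, 2L, lambda[seq_len(k)], `/`))
  Q <- pmax(rowSums(Xc^2) - rowSums(scores^2), 0)
  alpha <- config$cr_conf_level
  T2_lim <- k * (n_fit - 1) * (n_fit + 1) / (n_fit * (n_fit - k)) *
    stats::qf(alpha, k, n_fit - k)
  rest <- lambda[-seq_len(k)]
  if (length(rest) == 0L || sum(rest) <= .Machine$double.eps * sum(lambda)) {
    Q_lim <- Inf                             # model reproduces the data exactly
  } else {
    th1 <- sum(rest); th2 <- sum(rest^2); th3 <- sum(rest^3)
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (!is.finite(h0) || h0 <= 0) h0 <- 1e-3
    ca <- stats::qnorm(alpha)
    Q_lim <- th1 * (ca * sqrt(2 * th2 * h0^2) / th1 +
                      1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
  }
  list(Q = Q, T2 = T2, Q_lim = Q_lim, T2_lim = T2_lim, k = k,
       flagged = Q > Q_lim | T2 > T2_lim)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier_report: %d spectra, %d flagged (Q limit %.4g, T2 limit %.4g, k = %d)\n",
              nrow(x), sum(x$flagged), attr(x, "Q_limit"), attr(x, "T2_limit"),
              attr(x, "n_components")))
  invisible(x)
}

# Rolling median of the +/- half-width neighbourhood, centre channel excluded.
rolling_median_excl <- function(y, half_width = 5L) {
  w <- length(y)
  out <- numeric(w)
  for (i in seq_len(w)) {
    lo <- max(1L, i - half_width); hi <- min(w, i + half_width)
    out[i] <- stats::median(y[setdiff(lo:hi, i)])
  }
  out
}

#' Confirm and repair cosmic-ray spikes in flagged spectra
#'
#' For each spectrum flagged by [fit_pca_outliers()], a channel is a spike
#' seed when it exceeds the median of its +/- 5-channel neighbourhood by more
#' than `k_mad` times the spectrum's channel-to-channel noise scale (the MAD
#' of second differences scaled by `1/sqrt(6)`; second differencing cancels
#' real band slopes, so dense Raman bands do not inflate the estimate). Each
#' seed's support
#' is grown to all contiguous channels above half the seed's height over its
#' local baseline; supports no wider than `max_width` channels are confirmed
#' cosmic rays and replaced by linear interpolation across the support, while
#' wider features (real bands, broad anomalies) are left untouched and
#' recorded as unconfirmed. Unflagged spectra are returned bit-identical, and
#' no spectrum is ever removed: the voxel grid stays complete.
#'
#' @param spectra `n x w` matrix the report was computed on.
#' @param report The [fit_pca_outliers()] report for `spectra`.
#' @param k_mad Confirmation threshold in MADs (default 8).
#' @param half_width Neighbourhood half-width in channels for the rolling
#'   median (default 5).
#' @param max_width Maximum confirmed spike width in channels (default 2).
#' @return List with `spectra` (repaired matrix) and `report` (the input
#'   report with added columns `confirmed` and `repaired_channels`, a
#'   semicolon-separated channel list).
#' @export
repair_cosmic_rays <- function(spectra, report, k_mad = 8, half_width = 5L,
                               max_width = 2L) {
  spectra <- as.matrix(spectra)
  stopifnot(inherits(report, "outlier_report"), nrow(spectra) == nrow(report))
  confirmed <- rep(FALSE, nrow(spectra))
  repaired <- character(nrow(spectra))
  for (i in which(report$flagged)) {
    y <- spectra[i, ]
    w <- length(y)
    med <- rolling_median_excl(y, half_width)
    dev <- y - med
    scale <- stats::mad(diff(y, differences = 2L)) / sqrt(6)
    if (!is.finite(scale) || scale <= 0) scale <- stats::sd(dev)
    if (!is.finite(scale) || scale <= 0) next
    seeds <- which(dev > k_mad * scale)
    if (length(seeds) == 0L) next
    fixed <- integer(0)
    for (seed in seeds) {
      if (seed %in% fixed) next
      # grow the support to everything above half the seed height over its
      # local baseline; real bands grow wide, cosmic spikes stay narrow
      thr <- med[seed] + (y[seed] - med[seed]) / 2
      lo <- seed
      while (lo > 1L && y[lo - 1L] > thr) lo <- lo - 1L
      hi <- seed
      while (hi < w && y[hi + 1L] > thr) hi <- hi + 1L
      support <- lo:hi
      if (length(support) > max_width) next
      keep <- setdiff(seq_len(w), union(support, fixed))
      y[support] <- stats::approx(keep, y[keep], xout = support, rule = 2)$y
      fixed <- union(fixed, support)
    }
    if (length(fixed) > 0L) {
      spectra[i, ] <- y
      confirmed[i] <- TRUE
      repaired[i] <- paste(sort(fixed), collapse = ";")
    }
  }
  report$confirmed <- confirmed
  report$repaired_channels <- repaired
  list(spectra = spectra, report = report)
}

#' Normalise an unfolded dataset by its mean summed intensity
#'
#' In mode `"dataset_mean"` the whole matrix is divided by a single scalar:
#' the mean over voxels of the per-spectrum summed intensity. One scalar per
#' sample removes instrument/throughput differences between samples while
#' preserving all within-volume contrast (per-voxel normalisation would
#' destroy abundance information). Mode `"none"` is the identity.
#'
#' @param x An `unfolded_matrix` (see [unfold_volume()]) or a plain `M x w`
#'   matrix.
#' @param mode `"dataset_mean"` or `"none"`.
#' @return List with `D_norm` (same type as the input) and `scale` (the
#'   divisor used, 1 for `"none"`).
#' @export
normalize_dataset <- function(x, mode = c("dataset_mean", "none")) {
  mode <- match.arg(mode)
  D <- if (inherits(x, "unfolded_matrix")) x$D else as.matrix(x)
  if (!all(is.finite(D))) stop("dataset must be finite")
  if (mode == "none") return(list(D_norm = x, scale = 1))
  scale <- mean(rowSums(D))
  if (scale <= 0) stop("mean summed intensity is <= 0; cannot normalise")
  if (inherits(x, "unfolded_matrix")) {
    x$D <- D / scale
    list(D_norm = x, scale = scale)
  } else {
    list(D_norm = D / scale, scale = scale)
  }
}

#' Preprocess a z-stack of Raman images into an analysis-ready volume
#'
#' Runs the full per-layer chain on raw layer images: PCA outlier screening
#' ([fit_pca_outliers()]) -> cosmic-ray confirmation and repair
#' ([repair_cosmic_rays()]) -> per-spectrum reweighted polynomial baseline
#' correction with fingerprint cropping ([wls_baseline()]) -> Savitzky-Golay
#' smoothing ([savitzky_golay()]); the cleaned layers are then assembled into
#' a [hyper_volume()]. Dataset normalisation is not applied here: it operates
#' on the unfolded matrix immediately before unmixing (see [raman_unmix()]).
#'
#' @param x A raw [hyper_volume()] or a list of `X x Y x w` layer arrays.
#' @param wavenumbers Axis (cm^-1); taken from `x` when it is a volume.
#' @param grid [voxel_grid()]; taken from `x` when it is a volume.
#' @param config A [preprocess_config()].
#' @param sample_id Sample label; taken from `x` when it is a volume.
#' @return A preprocessed, spectrally cropped [hyper_volume()] with attribute
#'   `"preprocess_log"`: per-layer outlier reports and the config used.
#' @export
preprocess_volume <- function(x, wavenumbers = NULL, grid = NULL,
                              config = preprocess_config(), sample_id = NULL) {
  if (inherits(x, "hyper_volume")) {
    wavenumbers <- x$wavenumbers
    grid <- x$grid
    if (is.null(sample_id)) sample_id <- x$sample_id
    layers <- lapply(seq_len(grid$Z), function(z) x$intensities[, , z, , drop = TRUE])
    layers <- lapply(layers, function(l) array(l, dim = c(grid$X, grid$Y, length(wavenumbers))))
  } else {
    layers <- x
    if (is.null(wavenumbers) || is.null(grid))
      stop("wavenumbers and grid are required when passing a layer list")
    if (is.null(sample_id)) sample_id <- "sample"
  }
  wavenumbers <- check_axis(wavenumbers)
  keep <- which(wavenumbers >= config$baseline_range[1L] &
                  wavenumbers <= config$baseline_range[2L])
  if (length(keep) <= config$baseline_order + 1L)
    stop("baseline_range retains too few channels")
  wn_out <- wavenumbers[keep]
  B <- poly_basis(wn_out, config$baseline_order)
  sg_identity <- config$sg_window == config$sg_order + 1L
  smooth_rows <- function(mat) {
    t(apply(mat, 1L, savitzky_golay, window = config$sg_window,
            order = config$sg_order))
  }
  reports <- vector("list", grid$Z)
  out_layers <- vector("list", grid$Z)
  for (z in seq_len(grid$Z)) {
    mat <- layers[[z]]
    dim(mat) <- c(grid$X * grid$Y, length(wavenumbers))
    rep_z <- fit_pca_outliers(mat, config)
    fixed <- repair_cosmic_rays(mat, rep_z, k_mad = config$cr_k_mad)
    mat <- fixed$spectra
    reports[[z]] <- fixed$report
    if (config$smooth_before_baseline && !sg_identity) mat <- smooth_rows(mat)
    out <- mat[, keep, drop = FALSE]
    out <- out - wls_baseline_fit_matrix(out, B, config$baseline_max_iter,
                                         config$baseline_tol)
    if (!config$smooth_before_baseline && !sg_identity) out <- smooth_rows(out)
    dim(out) <- c(grid$X, grid$Y, length(keep))
    out_layers[[z]] <- out
  }
  vol <- assemble_volume(out_layers, wn_out, grid, sample_id)
  attr(vol, "preprocess_log") <- list(
    outlier_reports = reports,
    flagged_per_layer = vapply(reports, function(r) sum(r$flagged), integer(1)),
    config = config)
  vol
}

#' Write per-layer outlier reports as delimited text
#'
#' @param vol A volume returned by [preprocess_volume()] (or a list of
#'   `outlier_report`s).
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_outlier_reports <- function(vol, path) {
  reports <- if (inherits(vol, "hyper_volume"))
    attr(vol, "preprocess_log")$outlier_reports else vol
  rows <- lapply(seq_along(reports), function(z) {
    r <- as.data.frame(reports[[z]])
    if (is.null(r$confirmed)) { r$confirmed <- FALSE; r$repaired_channels <- "" }
    data.frame(layer = z, pixel = r$spectrum, Q = r$Q, T2 = r$T2,
               Q_limit = attr(reports[[z]], "Q_limit"),
               T2_limit = attr(reports[[z]], "T2_limit"),
               flagged = r$flagged, confirmed = r$confirmed,
               repaired_channels = r$repaired_channels)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
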
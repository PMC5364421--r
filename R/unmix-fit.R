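#' Fit the linear spectral-unmixing model to a volumetric Raman dataset
#'
#' The central model of the package: a preprocessed volumetric hyperspectral
#' dataset, unfolded to `D` (`M x w`), is decomposed as `D ~ C %*% S` where
#' the `p` rows of `S` are "pure" endmember spectra taken verbatim from the
#' dataset by vertex component analysis and `C` holds per-voxel abundances in
#' `[0, 1]` estimated by non-negative least squares. Fitting runs, in order:
#' optional spectral cropping, unfolding, dataset normalisation, [vca()],
#' [label_endmembers()], and [nnls_abundances()].
#'
#' @param x A preprocessed [hyper_volume()] (see [preprocess_volume()]), an
#'   `unfolded_matrix`, or an `M x w` matrix.
#' @param p Number of endmembers.
#' @param band_library A [band_library()] for labelling, or `NULL` to keep
#'   generic component names.
#' @param seed Seed for VCA's random directions.
#' @param spectral_range Optional `c(lo, hi)` crop in cm^-1 applied before
#'   unmixing (volumes only).
#' @param normalize `"dataset_mean"` or `"none"` (see [normalize_dataset()]).
#' @param rescale_quantile Per-component abundance rescale quantile (see
#'   [nnls_abundances()]).
#' @param score_floor Label assignment floor (see [label_endmembers()]).
#' @param wavenumbers Axis, required when `x` is a bare matrix.
#' @return An object of class `raman_unmix` with elements `endmembers`
#'   (labelled `endmember_set`), `abundances` (`abundance_maps`), `D_norm`
#'   (the normalised unfolded matrix), `scale` (normalisation divisor),
#'   `wavenumbers`, `grid`, `sample_id`, `p`, `seed`, `call`.
#' @examples
#' ph <- build_phantom(macrophage_phantom_spec(
#'   seed = 7, wavenumbers = seq(600, 1900, by = 5),
#'   grid = voxel_grid(16, 16, 6), n_cosmic = 0))
#' vol <- preprocess_volume(ph$volume)
#' fit <- raman_unmix(vol, p = 6)
#' fit
#' head(coef(fit))
#' @export
raman_unmix <- function(x, p, band_library = default_band_library(), seed = 1L,
                        spectral_range = NULL, normalize = "dataset_mean",
                        rescale_quantile = 0.999, score_floor = 0.5,
                        wavenumbers = NULL) {
  cl <- match.call()
  if (inherits(x, "hyper_volume")) {
    if (!is.null(spectral_range))
      x <- crop_spectral(x, spectral_range[1L], spectral_range[2L])
    um <- unfold_volume(x)
  } else if (inherits(x, "unfolded_matrix")) {
    um <- x
  } else {
    if (is.null(wavenumbers)) stop("wavenumbers required for a bare matrix")
    um <- structure(list(D = as.matrix(x), wavenumbers = check_axis(wavenumbers),
                         grid = NULL, sample_id = "matrix"),
                    class = "unfolded_matrix")
  }
  norm <- normalize_dataset(um, normalize)
  um_n <- norm$D_norm
  em <- vca(um_n, p, seed = seed)
  if (!is.null(band_library))
    em <- label_endmembers(em, band_library, score_floor)
  ab <- nnls_abundances(um_n, em, rescale_quantile)
  structure(list(endmembers = em, abundances = ab, D_norm = um_n$D,
                 scale = norm$scale, wavenumbers = um_n$wavenumbers,
                 grid = um_n$grid, sample_id = um_n$sample_id, p = em$p,
                 seed = seed, call = cl),
            class = "raman_unmix")
}

#' @export
print.raman_unmix <- function(x, ...) {
  cat(sprintf("Spectral unmixing fit '%s': %d voxels x %d channels, %d endmembers\n",
              x$sample_id, nrow(x$D_norm), ncol(x$D_norm), x$p))
  cat("  components:", paste(x$endmembers$labels, collapse = ", "), "\n")
  cat(sprintf("  VCA: seed %d, SNR est. %.1f dB (%s projection)\n", x$seed,
              x$endmembers$snr_db,
              if (x$endmembers$projective) "projective" else "affine"))
  invisible(x)
}

#' @export
summary.raman_unmix <- function(object, ...) {
  C <- object$abundances$C
  qs <- t(apply(C, 2L, stats::quantile, probs = c(0.5, 0.9, 0.999), names = FALSE))
  res <- object$D_norm - fitted(object)
  r2 <- 1 - sum(res^2) / sum(sweep(object$D_norm, 2L, colMeans(object$D_norm))^2)
  out <- list(fit = object,
              abundance_summary = data.frame(
                component = object$endmembers$labels,
                source_voxel = object$endmembers$source_voxels,
                mean = colMeans(C), q50 = qs[, 1L], q90 = qs[, 2L],
                q999 = qs[, 3L],
                rescale_factor = object$abundances$rescale_factors,
                row.names = NULL),
              score_table = object$endmembers$score_table,
              r_squared = r2)
  class(out) <- "summary.raman_unmix"
  out
}

#' @export
print.summary.raman_unmix <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  reconstruction R-squared: %.4f\n", x$r_squared))
  cat("\nPer-component abundance summary:\n")
  print(x$abundance_summary, digits = 3)
  if (!is.null(x$score_table)) {
    cat("\nBand-library score table:\n")
    print(round(x$score_table, 2))
  }
  invisible(x)
}

#' Abundance coefficients of an unmixing fit
#'
#' @param object A [raman_unmix()] fit.
#' @param raw If `TRUE`, return the unscaled NNLS coefficients instead of the
#'   `[0, 1]` abundances.
#' @param ... Unused.
#' @return The `M x p` coefficient matrix.
#' @export
coef.raman_unmix <- function(object, raw = FALSE, ...) {
  if (raw) object$abundances$C_raw else object$abundances$C
}

#' @export
fitted.raman_unmix <- function(object, ...) {
  object$abundances$C_raw %*% object$endmembers$S
}

#' @export
residuals.raman_unmix <- function(object, ...) {
  object$D_norm - fitted(object)
}

#' Abundances of new spectra under a fitted endmember set
#'
#' Solves the same constrained least-squares problem for new spectra against
#' the fit's endmembers and applies the fit's per-component rescale factors,
#' so new abundances are on the same `[0, 1]` scale as the training voxels.
#'
#' @param object A [raman_unmix()] fit.
#' @param newdata An `n x w` matrix of spectra on the fit's axis, an
#'   `unfolded_matrix`, or a [hyper_volume()] (cropped to the fit's axis).
#'   Spectra are divided by the fit's normalisation scale.
#' @param raw Return unscaled coefficients.
#' @param ... Unused.
#' @return An `n x p` abundance matrix.
#' @export
predict.raman_unmix <- function(object, newdata, raw = FALSE, ...) {
  if (inherits(newdata, "hyper_volume")) newdata <- unfold_volume(newdata)
  D <- if (inherits(newdata, "unfolded_matrix")) newdata$D else as.matrix(newdata)
  if (ncol(D) != ncol(object$endmembers$S))
    stop("newdata is not on the fit's wavenumber axis")
  ab <- nnls_abundances(D / object$scale, object$endmembers, rescale_quantile = NULL)
  C <- ab$C_raw
  if (!raw) {
    C <- pmin(pmax(sweep(C, 2L, object$abundances$rescale_factors, `*`), 0), 1)
  }
  colnames(C) <- object$endmembers$labels
  C
}

#' Plot endmember spectra of an unmixing fit
#'
#' Draws the labelled endmember spectra as vertically offset traces, the
#' conventional presentation of extracted pure-component Raman spectra.
#'
#' @param x A [raman_unmix()] fit.
#' @param offset Vertical spacing between traces (default: the maximum
#'   endmember intensity).
#' @param col Trace colours, recycled.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.raman_unmix <- function(x, offset = NULL,
                             col = c("blue", "red", "darkgreen", "orange",
                                     "magenta", "cyan4", "grey40"), ...) {
  S <- x$endmembers$S
  if (is.null(offset)) offset <- max(S)
  Y <- t(S + offset * (nrow(S) - seq_len(nrow(S))))
  graphics::matplot(x$wavenumbers, Y, type = "l", lty = 1,
                    col = rep_len(col, nrow(S)),
                    xlab = expression(paste("Raman shift (", cm^-1, ")")),
                    ylab = "intensity (offset)", ...)
  graphics::text(x = min(x$wavenumbers), y = apply(Y, 2L, max),
                 labels = x$endmembers$labels, adj = c(0, 0), cex = 0.8,
                 col = rep_len(col, nrow(S)))
  invisible(x)
}

#' Refolded component volumes
#'
#' Turns each abundance column into its 3D [component_volume()].
#'
#' @param x A `raman_unmix` fit or an `abundance_maps` object.
#' @param grid A [voxel_grid()] (defaults to the one carried by `x`).
#' @return Named list of [component_volume()]s.
#' @export
component_volumes <- function(x, grid = NULL) UseMethod("component_volumes")

#' @export
component_volumes.raman_unmix <- function(x, grid = NULL) {
  component_volumes(x$abundances, if (is.null(grid)) x$grid else grid)
}
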
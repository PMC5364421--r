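#' Experiment-wide abundance threshold for a component
#'
#' Mode `"mean"` (default) returns the mean abundance over all voxels of all
#' volumes supplied — values close to the average abundance separate a
#' component from background well in practice, and pooling the experiment's
#' volumes fixes one threshold per component per experiment, so every sample
#' is quantified against the same cut. Mode `"fixed"` returns the
#' user-supplied value.
#'
#' @param volumes A [component_volume()] or a list of them (the experiment's
#'   pooled volumes for one component).
#' @param mode `"mean"` or `"fixed"`.
#' @param value Threshold for mode `"fixed"`.
#' @return A single threshold in `[0, 1]`.
#' @export
component_threshold <- function(volumes, mode = c("mean", "fixed"), value = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(value) || value < 0 || value > 1)
      stop("mode 'fixed' needs a threshold value in [0, 1]")
    return(value)
  }
  if (inherits(volumes, "component_volume")) volumes <- list(volumes)
  if (length(volumes) == 0L) stop("no volumes supplied")
  vals <- unlist(lapply(volumes, function(cv) {
    stopifnot(inherits(cv, "component_volume"))
    as.numeric(cv$values)
  }))
  if (length(vals) == 0L) stop("empty volumes")
  mean(vals)
}

#' Thresholded voxel-count quantification
#'
#' Counts the voxels whose abundance is at or above the threshold (the voxel
#' reading of "inside the isosurface"; for a binary voxel mask the two
#' coincide) and expresses the count as a percentage of all voxels in the
#' sample volume.
#'
#' @param cv A [component_volume()].
#' @param threshold Abundance threshold in `[0, 1]`.
#' @param sample_id Sample label for the record.
#' @return One-row data frame of class `quant_record`: `sample_id`,
#'   `component`, `threshold`, `voxels_above`, `total_voxels`, `percent`.
#' @export
count_voxels <- function(cv, threshold, sample_id = "sample") {
  stopifnot(inherits(cv, "component_volume"))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  total <- length(cv$values)
  above <- sum(cv$values >= threshold)
  structure(data.frame(sample_id = sample_id, component = cv$label,
                       threshold = threshold, voxels_above = above,
                       total_voxels = total, percent = 100 * above / total),
            class = c("quant_record", "data.frame"))
}

#' Unpaired two-group comparison of component percentages
#'
#' The conventional group test for thresholded voxel percentages: an F test
#' for variance homogeneity is reported alongside an unpaired two-sided
#' Student's t-test with pooled variance (`df = nA + nB - 2`); Welch's
#' correction can be requested instead when the F test rejects. Shapiro-Wilk
#' normality p-values per group are reported for review (groups of at least
#' 3). Significance stars follow * P<0.05, ** P<0.01, *** P<0.001.
#'
#' @param a,b Numeric vectors of per-sample percentages (>= 2 each).
#' @param component Component label for the report.
#' @param welch Use Welch's t-test instead of the pooled-variance test.
#' @return An object of class `group_comparison`: list with group summaries,
#'   `F`, `p_F`, `t`, `df`, `p`, `stars`, `shapiro_p_a`, `shapiro_p_b`.
#' @export
compare_groups <- function(a, b, component = "component", welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 samples")
  nA <- length(a); nB <- length(b)
  vA <- stats::var(a); vB <- stats::var(b)
  ftest <- if (vA > 0 && vB > 0) stats::var.test(a, b) else NULL
  pooled <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  if (pooled <= 0) {
    # all observations constant within groups
    if (isTRUE(all.equal(mean(a), mean(b)))) { tstat <- 0; df <- nA + nB - 2; p <- 1 }
    else { tstat <- sign(mean(a) - mean(b)) * Inf; df <- nA + nB - 2; p <- 0 }
  } else {
    tt <- stats::t.test(a, b, var.equal = !welch)
    tstat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  shap <- function(x) {
    if (length(x) >= 3L && stats::var(x) > 0)
      tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
    else NA_real_
  }
  structure(list(component = component,
                 n_a = nA, n_b = nB,
                 mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b),
                 F = if (is.null(ftest)) NA_real_ else unname(ftest$statistic),
                 p_F = if (is.null(ftest)) NA_real_ else ftest$p.value,
                 t = tstat, df = df, p = p, stars = stars, welch = welch,
                 shapiro_p_a = shap(a), shapiro_p_b = shap(b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison '%s': %.3g +/- %.3g (n=%d) vs %.3g +/- %.3g (n=%d)\n",
              x$component, x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  F = %.4g (p = %.3g); t = %.4g, df = %.3g, p = %.3g %s\n",
              x$F, x$p_F, x$t, x$df, x$p, x$stars))
  invisible(x)
}

#' @export
as.data.frame.group_comparison <- function(x, ...) {
  data.frame(component = x$component, mean_A = x$mean_a, sd_A = x$sd_a,
             mean_B = x$mean_b, sd_B = x$sd_b, F = x$F, p_F = x$p_F,
             t = x$t, df = x$df, p = x$p, stars = x$stars)
}

#' Collapse a z-stack to simulate non-confocal acquisition
#'
#' Sums the intensities over the whole z dimension per (x, y, channel),
#' emulating the signal overlap of a non-confocal measurement. The result is
#' a valid single-layer [hyper_volume()] (dz becomes `Z * dz`) and can be fed
#' through the identical unmixing and quantification pipeline to measure how
#' much molecular specificity the confocal z-resolution buys.
#'
#' @param vol A [hyper_volume()].
#' @return A [hyper_volume()] with `Z = 1`.
#' @export
z_collapse <- function(vol) {
  stopifnot(inherits(vol, "hyper_volume"))
  g <- vol$grid
  if (g$Z == 1L) return(vol)
  summed <- apply(vol$intensities, c(1L, 2L, 4L), sum)
  arr <- array(summed, dim = c(g$X, g$Y, 1L, length(vol$wavenumbers)))
  hyper_volume(arr, vol$wavenumbers,
               voxel_grid(g$X, g$Y, 1L, g$dx, g$dy, g$dz * g$Z),
               vol$sample_id)
}
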
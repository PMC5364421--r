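# Lawson-Hanson active-set NNLS on the normal equations (Bro & de Jong's
# fast variant): solves min ||A x - b||_2 s.t. x >= 0 given AtA = A'A and
# Atb = A'b. Working on the p x p gram system lets the per-voxel solve cost
# depend on the number of endmembers, not the number of channels, which is
# what makes solving one NNLS per voxel tractable.
nnls_gram <- function(AtA, Atb, tol = NULL) {
  p <- length(Atb)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(diag(AtA))) * p
  x <- numeric(p)
  passive <- rep(FALSE, p)
  grad <- Atb
  iter_outer <- 0L
  repeat {
    iter_outer <- iter_outer + 1L
    free <- which(!passive)
    if (length(free) == 0L || max(grad[free]) <= tol || iter_outer > 30L * p) break
    passive[free[which.max(grad[free])]] <- TRUE
    repeat {
      Pset <- which(passive)
      s <- numeric(p)
      s[Pset] <- tryCatch(
        drop(solve(AtA[Pset, Pset, drop = FALSE], Atb[Pset])),
        error = function(e)
          drop(MASS::ginv(AtA[Pset, Pset, drop = FALSE]) %*% Atb[Pset]))
      if (all(s[Pset] > tol)) { x <- s; break }
      neg <- Pset[s[Pset] <= tol]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[Pset[x[Pset] <= tol]] <- FALSE
      x[!passive] <- 0
    }
    grad <- Atb - drop(AtA %*% x)
  }
  x
}

#' Non-negative least-squares abundance estimation
#'
#' For every voxel spectrum `d_m`, solves `min || S' c - d_m ||_2` subject to
#' `c >= 0` by an active-set method (exact KKT at convergence), where the rows
#' of `S` are the extracted endmember spectra. The raw coefficients are then
#' mapped to the `[0, 1]` abundance scale per component: column `j` is divided
#' by its 99.9th percentile and clipped to `[0, 1]`. The percentile (rather
#' than the maximum) makes the scaling robust to isolated hot voxels; the
#' factors applied are recorded. No sum-to-one constraint is imposed, so
#' partial-volume voxels may have abundances that do not sum to 1.
#'
#' @param x An `unfolded_matrix` (see [unfold_volume()]) or `M x w` matrix,
#'   on the same axis and intensity scale the endmembers were extracted from.
#' @param endmembers An `endmember_set` from [vca()].
#' @param rescale_quantile Per-component quantile mapped to abundance 1
#'   (default 0.999); `NULL` skips rescaling (raw coefficients returned in
#'   `C` as well).
#' @return An object of class `abundance_maps`: list with `C` (`M x N`
#'   abundances in `[0, 1]`), `C_raw` (unscaled NNLS coefficients),
#'   `rescale_factors` (multipliers applied to each column), `labels`, and
#'   the `grid`/`sample_id` when `x` carries them.
#' @export
nnls_abundances <- function(x, endmembers, rescale_quantile = 0.999) {
  stopifnot(inherits(endmembers, "endmember_set"))
  if (inherits(x, "unfolded_matrix")) {
    D <- x$D; grid <- x$grid; sample_id <- x$sample_id
    if (length(x$wavenumbers) != ncol(endmembers$S))
      stop("data and endmembers are on different wavenumber axes")
  } else {
    D <- as.matrix(x); grid <- NULL; sample_id <- NULL
  }
  S <- endmembers$S
  if (ncol(D) != ncol(S)) stop("channel count mismatch between data and endmembers")
  norms <- sqrt(rowSums(S^2))
  if (any(norms == 0)) stop("endmember set contains an all-zero spectrum")
  AtA <- tcrossprod(S)                      # p x p
  AtB <- S %*% t(D)                         # p x M
  M <- nrow(D); p <- nrow(S)
  C_raw <- matrix(0, M, p)
  for (m in seq_len(M)) C_raw[m, ] <- nnls_gram(AtA, AtB[, m])
  colnames(C_raw) <- endmembers$labels
  if (is.null(rescale_quantile)) {
    C <- C_raw
    factors <- rep(1, p)
  } else {
    q <- apply(C_raw, 2L, stats::quantile, probs = rescale_quantile,
               names = FALSE, type = 7)
    factors <- ifelse(q > 0, 1 / q, 1)
    C <- pmin(pmax(sweep(C_raw, 2L, factors, `*`), 0), 1)
  }
  structure(list(C = C, C_raw = C_raw, rescale_factors = factors,
                 labels = endmembers$labels, grid = grid, sample_id = sample_id),
            class = "abundance_maps")
}

#' @export
print.abundance_maps <- function(x, ...) {
  cat(sprintf("abundance_maps: %d voxels x %d components\n", nrow(x$C), ncol(x$C)))
  cat("  components:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

# Refold every abundance column into component volumes; see the generic in
# unmix-fit.R.
#' @export
component_volumes.abundance_maps <- function(x, grid = NULL) {
  ab <- x
  if (is.null(grid)) grid <- ab$grid
  if (is.null(grid)) stop("no voxel grid available; pass one explicitly")
  out <- lapply(seq_along(ab$labels), function(j)
    refold_component(ab$C[, j], grid, ab$labels[j]))
  names(out) <- ab$labels
  out
}
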
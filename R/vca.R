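#' Vertex component analysis (VCA) endmember extraction
#'
#' Extracts `p` "pure" component spectra (endmembers) from an unfolded
#' dataset under the linear-mixing, pure-pixel assumption: the data cloud is
#' (approximately) a simplex whose vertices are the purest voxels, and VCA
#' locates those vertices by iteratively projecting the data onto random
#' directions orthogonal to the endmembers found so far and taking the voxel
#' with the largest absolute projection.
#'
#' The dataset SNR is first estimated from the energy split between the
#' p-dimensional principal subspace and its complement. Above the threshold
#' `15 + 10*log10(p)` dB the data are projected onto the top-`p` singular
#' subspace of `D'D/M` and scaled projectively onto a hyperplane; otherwise
#' the data are mean-centred, projected onto `p - 1` principal components and
#' lifted with a constant coordinate (affine branch). In both branches the
#' returned endmembers are the original, unprojected spectra at the selected
#' voxels, so every endmember is a real spectrum present verbatim in the
#' dataset.
#'
#' @param x An `unfolded_matrix` (see [unfold_volume()]) or an `M x w` matrix
#'   of spectra (rows = voxels), typically normalised first
#'   ([normalize_dataset()]).
#' @param p Number of endmembers to extract, `1 <= p <= min(M, w)`.
#' @param seed Integer seed for the random direction draws (fixed default for
#'   reproducibility).
#' @param wavenumbers Axis; taken from `x` when it is an `unfolded_matrix`.
#' @return An object of class `endmember_set`: list with `S` (`p x w` matrix,
#'   one endmember spectrum per row), `labels` (placeholders until
#'   [label_endmembers()]), `source_voxels` (row indices into `x`),
#'   `wavenumbers`, `p`, `snr_db`, `projective` (branch taken).
#' @references Nascimento & Bioucas-Dias (2005), IEEE TGRS 43(4), 898-910.
#' @export
vca <- function(x, p, seed = 1L, wavenumbers = NULL) {
  if (inherits(x, "unfolded_matrix")) {
    D <- x$D
    if (is.null(wavenumbers)) wavenumbers <- x$wavenumbers
  } else {
    D <- as.matrix(x)
    if (is.null(wavenumbers)) wavenumbers <- seq_len(ncol(D))
  }
  if (!all(is.finite(D))) stop("data matrix must be finite")
  M <- nrow(D); w <- ncol(D)
  p <- as.integer(p)
  if (p < 1L || p > min(M, w))
    stop(sprintf("p must lie in [1, %d]", min(M, w)))
  R <- t(D)                                  # w x M, pixels in columns

  r_bar <- rowMeans(R)
  R0 <- R - r_bar
  G <- tcrossprod(R) / M                       # shared gram; centred version
  G0 <- G - tcrossprod(r_bar)                  # follows from E[xx'] - mm'
  svG <- svd(G, nu = min(p, w))
  sv0 <- svd(G0, nu = min(p, w))
  rank_num <- sum(svG$d > max(svG$d) * 1e-12)
  if (rank_num < p)
    stop(sprintf("numerical rank %d of the dataset is below p = %d; choose a smaller p",
                 rank_num, p))

  # SNR estimate: energy captured by the p-dim centred principal subspace
  Ud_c <- sv0$u[, seq_len(min(p, ncol(sv0$u))), drop = FALSE]
  xp <- crossprod(Ud_c, R0)
  P_y <- sum(R^2) / M
  P_x <- sum(xp^2) / M + sum(r_bar^2)
  snr_db <- 10 * log10(max(P_x - p / w * P_y, .Machine$double.eps) /
                         max(P_y - P_x, .Machine$double.eps))
  snr_th <- 15 + 10 * log10(p)
  projective <- (snr_db > snr_th) || p == 1L

  if (projective) {
    d <- p
    Ud <- svG$u[, seq_len(d), drop = FALSE]
    Xp <- crossprod(Ud, R)                   # d x M
    u <- rowMeans(Xp)
    denom <- colSums(Xp * u)
    denom[abs(denom) < .Machine$double.eps] <- .Machine$double.eps
    Y <- sweep(Xp, 2L, denom, `/`)           # projective scaling onto a hyperplane
  } else {
    d <- p - 1L
    Ud <- sv0$u[, seq_len(d), drop = FALSE]
    Xp <- crossprod(Ud, R0)
    cmax <- max(sqrt(colSums(Xp^2)))
    Y <- rbind(Xp, cmax)                     # affine lift with a constant coordinate
  }

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  A <- matrix(0, p, p)
  A[p, 1L] <- 1
  idx <- integer(p)
  Ip <- diag(p)
  for (i in seq_len(p)) {
    w_dir <- stats::rnorm(p)
    f <- (Ip - A %*% MASS::ginv(A)) %*% w_dir
    nf <- sqrt(sum(f^2))
    if (nf < .Machine$double.eps) f <- w_dir else f <- f / nf
    v <- crossprod(Y, f)                     # M x 1 projections
    idx[i] <- which.max(abs(v))
    A[, i] <- Y[, idx[i]]
  }

  structure(list(S = D[idx, , drop = FALSE],
                 labels = paste0("component_", seq_len(p)),
                 source_voxels = idx, wavenumbers = wavenumbers,
                 p = p, snr_db = snr_db, projective = projective),
            class = "endmember_set")
}

#' @export
print.endmember_set <- function(x, ...) {
  cat(sprintf("endmember_set: %d components x %d channels (SNR est. %.1f dB, %s branch)\n",
              x$p, ncol(x$S), x$snr_db,
              if (x$projective) "projective" else "affine"))
  cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  cat("  source voxels:", paste(x$source_voxels, collapse = ", "), "\n")
  invisible(x)
}
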
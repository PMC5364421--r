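#' Voxel grid geometry
#'
#' Describes the spatial sampling of a volumetric Raman dataset: the number of
#' pixels per imaging plane (`X`, `Y`), the number of confocal planes (`Z`),
#' and the physical step sizes in micrometres. Defaults match a typical
#' confocal acquisition: 650 nm lateral step and 1 um z increment over 10
#' planes.
#'
#' @param X,Y Pixels per layer in x and y.
#' @param Z Number of z layers.
#' @param dx,dy Lateral step sizes in micrometres.
#' @param dz Axial (z) increment in micrometres.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(X, Y, Z = 10L, dx = 0.65, dy = 0.65, dz = 1.0) {
  X <- as.integer(X); Y <- as.integer(Y); Z <- as.integer(Z)
  if (any(c(X, Y, Z) < 1L)) stop("grid dimensions X, Y, Z must all be >= 1")
  if (any(c(dx, dy, dz) <= 0)) stop("voxel step sizes dx, dy, dz must be > 0")
  structure(list(X = X, Y = Y, Z = Z, dx = dx, dy = dy, dz = dz),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels (%.3g x %.3g x %.3g um steps)\n",
              x$X, x$Y, x$Z, x$dx, x$dy, x$dz))
  invisible(x)
}

n_voxels <- function(grid) grid$X * grid$Y * grid$Z

check_axis <- function(wavenumbers) {
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) < 2L) stop("wavenumber axis needs at least 2 channels")
  if (!all(is.finite(wavenumbers))) stop("wavenumber axis must be finite")
  if (any(diff(wavenumbers) <= 0)) stop("wavenumber axis must be strictly increasing")
  wavenumbers
}

#' Volumetric hyperspectral dataset
#'
#' Container for an assembled z-stack of Raman images: an `X x Y x Z x w`
#' intensity array on a shared, strictly increasing wavenumber axis (cm^-1),
#' with voxel-size metadata. Negative intensities are permitted (they arise
#' after baseline subtraction); only abundance volumes are range-restricted.
#'
#' @param intensities Numeric array of dimension `X x Y x Z x w`.
#' @param wavenumbers Strictly increasing numeric vector, length `w`, in cm^-1.
#' @param grid A [voxel_grid()].
#' @param sample_id Character label for the sample.
#' @return An object of class `hyper_volume`.
#' @export
hyper_volume <- function(intensities, wavenumbers, grid, sample_id = "sample") {
  wavenumbers <- check_axis(wavenumbers)
  if (!inherits(grid, "voxel_grid")) stop("grid must be a voxel_grid")
  d <- dim(intensities)
  if (length(d) != 4L)
    stop("intensities must be a 4-d array (X x Y x Z x w)")
  if (!identical(as.integer(d), c(grid$X, grid$Y, grid$Z, length(wavenumbers))))
    stop(sprintf("intensity array dims [%s] inconsistent with grid %dx%dx%d and %d channels",
                 paste(d, collapse = "x"), grid$X, grid$Y, grid$Z, length(wavenumbers)))
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  structure(list(intensities = intensities, wavenumbers = wavenumbers,
                 grid = grid, sample_id = as.character(sample_id)),
            class = "hyper_volume")
}

#' @export
print.hyper_volume <- function(x, ...) {
  g <- x$grid
  cat(sprintf("hyper_volume '%s': %d x %d x %d voxels, %d channels (%.4g-%.4g cm^-1)\n",
              x$sample_id, g$X, g$Y, g$Z, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Assemble per-layer Raman images into a volumetric dataset
#'
#' Stacks an ordered list of `X x Y x w` hyperspectral layer images (in
#' increasing z order) into a single [hyper_volume()]. All layers must share
#' the same spatial shape and the same wavenumber axis exactly; no spectral
#' resampling is performed.
#'
#' @param layers List of `X x Y x w` numeric arrays, ordered by increasing z.
#' @param wavenumbers Shared wavenumber axis (cm^-1).
#' @param grid A [voxel_grid()] with `Z = length(layers)`.
#' @param sample_id Sample label.
#' @return A [hyper_volume()] with `intensities[x, y, z, ] = layers[[z]][x, y, ]`.
#' @export
assemble_volume <- function(layers, wavenumbers, grid, sample_id = "sample") {
  if (length(layers) == 0L) stop("cannot assemble an empty layer list")
  wavenumbers <- check_axis(wavenumbers)
  d1 <- dim(layers[[1L]])
  if (length(d1) != 3L) stop("each layer must be an X x Y x w array")
  for (z in seq_along(layers)) {
    dz <- dim(layers[[z]])
    if (!identical(dz, d1))
      stop(sprintf("layer %d has shape [%s], expected [%s]", z,
                   paste(dz, collapse = "x"), paste(d1, collapse = "x")))
    if (dz[3L] != length(wavenumbers))
      stop(sprintf("layer %d has %d channels but the axis has %d", z, dz[3L],
                   length(wavenumbers)))
  }
  if (grid$Z != length(layers))
    stop(sprintf("grid declares Z = %d but %d layers were given", grid$Z, length(layers)))
  arr <- array(0, dim = c(d1[1L], d1[2L], length(layers), d1[3L]))
  for (z in seq_along(layers)) arr[, , z, ] <- layers[[z]]
  hyper_volume(arr, wavenumbers, grid, sample_id)
}

#' Restrict a volume to a spectral window
#'
#' Keeps the channels with `lo <= wavenumber <= hi` (inclusive on both ends),
#' e.g. the 700-1800 cm^-1 fingerprint region used for unmixing.
#'
#' @param vol A [hyper_volume()].
#' @param lo,hi Window bounds in cm^-1, `lo < hi`.
#' @return The cropped [hyper_volume()].
#' @export
crop_spectral <- function(vol, lo, hi) {
  stopifnot(inherits(vol, "hyper_volume"))
  if (lo >= hi) stop("need lo < hi")
  keep <- vol$wavenumbers >= lo & vol$wavenumbers <= hi
  if (!any(keep))
    stop(sprintf("no channels in [%g, %g]; axis spans %g-%g cm^-1", lo, hi,
                 min(vol$wavenumbers), max(vol$wavenumbers)))
  if (sum(keep) < 2L) stop(sprintf("window [%g, %g] retains fewer than 2 channels", lo, hi))
  hyper_volume(vol$intensities[, , , keep, drop = FALSE],
               vol$wavenumbers[keep], vol$grid, vol$sample_id)
}

#' Unfold a volume into the voxel-by-channel matrix
#'
#' Reshapes the `X x Y x Z x w` intensity array into the `M x w` matrix `D`
#' (`M = X*Y*Z`) that spectral unmixing operates on. The voxel-to-row
#' bijection is fixed and x-fastest: voxel `(x, y, z)` (1-based) maps to row
#' `m = x + X*((y - 1) + Y*(z - 1))`. [refold_component()] inverts it.
#'
#' @param vol A [hyper_volume()].
#' @return A list of class `unfolded_matrix` with elements `D` (`M x w`
#'   matrix), `wavenumbers`, `grid` and `sample_id`.
#' @seealso [voxel_index()] for the explicit bijection.
#' @export
unfold_volume <- function(vol) {
  stopifnot(inherits(vol, "hyper_volume"))
  g <- vol$grid
  D <- vol$intensities
  dim(D) <- c(n_voxels(g), length(vol$wavenumbers))
  structure(list(D = D, wavenumbers = vol$wavenumbers, grid = g,
                 sample_id = vol$sample_id),
            class = "unfolded_matrix")
}

#' @export
print.unfolded_matrix <- function(x, ...) {
  cat(sprintf("unfolded_matrix '%s': %d voxels x %d channels\n",
              x$sample_id, nrow(x$D), ncol(x$D)))
  invisible(x)
}

#' Row index of a voxel in the unfolded matrix
#'
#' @param x,y,z 1-based voxel coordinates (vectorised).
#' @param grid The [voxel_grid()].
#' @return 1-based row indices `m = x + X*((y-1) + Y*(z-1))`.
#' @export
voxel_index <- function(x, y, z, grid) {
  x + grid$X * ((y - 1L) + grid$Y * (z - 1L))
}

#' Per-component abundance volume
#'
#' A single component's refolded 3D abundance map: values in `[0, 1]` on the
#' voxel grid.
#'
#' @param values Numeric `X x Y x Z` array in `[0, 1]`.
#' @param grid A [voxel_grid()].
#' @param label Component label.
#' @return An object of class `component_volume`.
#' @export
component_volume <- function(values, grid, label = "component") {
  d <- dim(values)
  if (length(d) != 3L || !identical(as.integer(d), c(grid$X, grid$Y, grid$Z)))
    stop("values must be an X x Y x Z array matching the grid")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("component_volume values must be finite and within [0, 1]")
  structure(list(values = values, grid = grid, label = as.character(label)),
            class = "component_volume")
}

#' @export
print.component_volume <- function(x, ...) {
  g <- x$grid
  cat(sprintf("component_volume '%s': %d x %d x %d, abundance range [%.3g, %.3g]\n",
              x$label, g$X, g$Y, g$Z, min(x$values), max(x$values)))
  invisible(x)
}

#' Refold an abundance column back into a 3D component volume
#'
#' Inverts [unfold_volume()]'s voxel-to-row mapping for a single abundance
#' column: value at voxel `(x, y, z)` is `column[x + X*((y-1) + Y*(z-1))]`.
#'
#' @param column Numeric vector of length `M = X*Y*Z`, values in `[0, 1]`.
#' @param grid A [voxel_grid()].
#' @param label Component label.
#' @return A [component_volume()].
#' @export
refold_component <- function(column, grid, label = "component") {
  if (length(column) != n_voxels(grid))
    stop(sprintf("column length %d does not match grid voxel count %d",
                 length(column), n_voxels(grid)))
  if (any(!is.finite(column)) || any(column < 0) || any(column > 1))
    stop("abundance values must be finite and within [0, 1]; clip upstream")
  arr <- array(column, dim = c(grid$X, grid$Y, grid$Z))
  component_volume(arr, grid, label)
}

#' Spectral angle between two spectra
#'
#' arccos of the normalised dot product (SAM), a scale-invariant similarity in
#' radians; 0 means proportional spectra.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Angle in radians in `[0, pi]`.
#' @export
spectral_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  acos(max(-1, min(1, sum(a * b) / (na * nb))))
}
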
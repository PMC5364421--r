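#' Write a volumetric dataset to a plain-text container
#'
#' Serialises a [hyper_volume()] losslessly as a directory holding one
#' delimited-text matrix per z layer (`layer_001.tsv`, ... ; rows are pixels
#' in x-fastest row-major order, columns are spectral channels) plus a
#' `meta.json` file with the grid, the `wavenumbers_cm1` axis and the sample
#' id. Values are written with 17 significant digits so that the round trip
#' through [read_volume()] is bit-exact for doubles.
#'
#' @param vol A [hyper_volume()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "hyper_volume"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- vol$grid
  # non-integer metadata is serialised through %.17g strings: JSON number
  # printing is not guaranteed bit-exact, the 17-digit decimal round trip is
  meta <- list(X = g$X, Y = g$Y, Z = g$Z,
               dx_um = sprintf("%.17g", g$dx), dy_um = sprintf("%.17g", g$dy),
               dz_um = sprintf("%.17g", g$dz),
               sample_id = vol$sample_id,
               wavenumbers_cm1 = sprintf("%.17g", vol$wavenumbers))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  w <- length(vol$wavenumbers)
  for (z in seq_len(g$Z)) {
    layer <- vol$intensities[, , z, ]
    dim(layer) <- c(g$X * g$Y, w)           # pixels x channels, x fastest
    txt <- apply(layer, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(txt, file.path(path, sprintf("layer_%03d.tsv", z)))
  }
  invisible(path)
}

#' Read a volumetric dataset written by [write_volume()]
#'
#' @param path Directory containing `meta.json` and `layer_*.tsv`.
#' @return A [hyper_volume()].
#' @export
read_volume <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop(sprintf("no meta.json under '%s'", path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (key in c("X", "Y", "Z", "dx_um", "dy_um", "dz_um", "wavenumbers_cm1")) {
    if (is.null(meta[[key]]))
      stop(sprintf("meta.json is missing required key '%s'", key))
  }
  grid <- voxel_grid(meta$X, meta$Y, meta$Z, as.numeric(meta$dx_um),
                     as.numeric(meta$dy_um), as.numeric(meta$dz_um))
  wn <- as.numeric(meta$wavenumbers_cm1)
  arr <- array(0, dim = c(grid$X, grid$Y, grid$Z, length(wn)))
  for (z in seq_len(grid$Z)) {
    f <- file.path(path, sprintf("layer_%03d.tsv", z))
    if (!file.exists(f)) stop(sprintf("missing layer file '%s'", f))
    layer <- as.matrix(utils::read.table(f, sep = "\t", header = FALSE,
                                         colClasses = "numeric"))
    if (!identical(dim(layer), c(grid$X * grid$Y, length(wn))))
      stop(sprintf("layer %d has dims [%s], expected [%d x %d]", z,
                   paste(dim(layer), collapse = "x"), grid$X * grid$Y, length(wn)))
    dim(layer) <- c(grid$X, grid$Y, length(wn))
    arr[, , z, ] <- layer
  }
  hyper_volume(arr, wn, grid,
               if (is.null(meta$sample_id)) "sample" else meta$sample_id)
}

#' Export a component volume as a multi-page float TIFF
#'
#' Writes one 32-bit float page per z slice (increasing z), plus a sidecar
#' JSON (`<path>.json`) with the voxel step sizes and the component label, as
#' a portable hand-off to 3D rendering tools.
#'
#' @param cv A [component_volume()].
#' @param path Output TIFF file path.
#' @return `path`, invisibly.
#' @export
export_component_tiff <- function(cv, path) {
  stopifnot(inherits(cv, "component_volume"))
  g <- cv$grid
  pages <- lapply(seq_len(g$Z), function(z) cv$values[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(label = cv$label, dx_um = g$dx, dy_um = g$dy, dz_um = g$dz,
                  X = g$X, Y = g$Y, Z = g$Z)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Re-import a component TIFF written by [export_component_tiff()]
#'
#' @param path TIFF file path (sidecar `<path>.json` must exist).
#' @return A [component_volume()].
#' @export
import_component_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- voxel_grid(meta$X, meta$Y, meta$Z, meta$dx_um, meta$dy_um, meta$dz_um)
  arr <- array(0, dim = c(grid$X, grid$Y, grid$Z))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
  component_volume(arr, grid, meta$label)
}

#' Write endmember spectra as delimited text
#'
#' First column is the wavenumber axis; one column per labelled component.
#'
#' @param endmembers An `endmember_set` (see [vca()]).
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_endmembers <- function(endmembers, path) {
  stopifnot(inherits(endmembers, "endmember_set"))
  tab <- data.frame(wavenumber_cm1 = endmembers$wavenumbers,
                    t(endmembers$S), check.names = FALSE)
  names(tab)[-1L] <- endmembers$labels
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
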
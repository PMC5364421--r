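#' Diagnostic Raman band library
#'
#' A band library maps component names to the diagnostic wavenumbers used to
#' assign extracted endmembers: an endmember earns a label when its spectrum
#' shows local maxima at (enough of) the label's diagnostic bands.
#'
#' @param entries List of entries, each a list with `label` (character),
#'   `bands` (numeric, cm^-1) and optionally `tolerance` (cm^-1, default 8).
#' @return An object of class `band_library`.
#' @export
band_library <- function(entries) {
  entries <- lapply(entries, function(e) {
    if (is.null(e$label) || is.null(e$bands)) stop("each entry needs label and bands")
    list(label = as.character(e$label), bands = as.numeric(e$bands),
         tolerance = if (is.null(e$tolerance)) 8 else as.numeric(e$tolerance))
  })
  labs <- vapply(entries, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("band library labels must be unique")
  structure(entries, class = "band_library")
}

#' Default band library for cell and hydrogel imaging
#'
#' Diagnostic assignments commonly used in cellular Raman microspectroscopy:
#' phenylalanine 1008 cm^-1 (cytoplasm/protein), the DNA O-P-O backbone
#' 789 cm^-1 (nucleus), the CH2 symmetric stretch 2857 cm^-1 (generic
#' lipids), glycogen 485 cm^-1, the triacylglycerol ester C=O stretch
#' 1747 cm^-1, cholesteryl-ester 1066 + 1134 cm^-1, the phospholipid choline
#' and chain C-C stretches 719 + 1085 cm^-1, the PEG C-O-C/C-C stretch
#' 847 cm^-1, and a broad water/amide medium band at 1640 cm^-1.
#'
#' @return A [band_library()].
#' @export
default_band_library <- function() {
  band_library(list(
    list(label = "cytoplasm",    bands = 1008),
    list(label = "nucleus",      bands = 789),
    list(label = "lipids",       bands = 2857),
    list(label = "glycogen",     bands = 485),
    list(label = "TAG",          bands = 1747),
    list(label = "cholesterol",  bands = c(1066, 1134)),
    list(label = "phospholipid", bands = c(719, 1085)),
    list(label = "PEG",          bands = 847),
    list(label = "medium",       bands = 1640)))
}

#' Read / write a band library as JSON
#'
#' @param path JSON file path.
#' @return A [band_library()] (for the reader); `path` invisibly (writer).
#' @export
read_band_library <- function(path) {
  band_library(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' @rdname read_band_library
#' @param lib A [band_library()].
#' @export
write_band_library <- function(lib, path) {
  stopifnot(inherits(lib, "band_library"))
  jsonlite::write_json(lapply(unclass(lib), function(e)
    list(label = jsonlite::unbox(e$label), bands = e$bands,
         tolerance = jsonlite::unbox(e$tolerance))), path, digits = NA)
  invisible(path)
}

# Channel indices of strict local maxima (plateaus and endpoints excluded).
local_maxima <- function(s) {
  w <- length(s)
  if (w < 3L) return(integer(0))
  i <- 2:(w - 1L)
  i[s[i] >= s[i - 1L] & s[i] >= s[i + 1L] & (s[i] > s[i - 1L] | s[i] > s[i + 1L])]
}

# Prominent peaks of a (possibly noisy) spectrum: light smoothing, then local
# maxima whose prominence — height above the higher of the bracketing minima
# before a taller point is reached — exceeds both a fraction of the spectrum
# range and a multiple of the spectrum's own channel-to-channel noise level,
# so that pure noise produces no "diagnostic" peaks.
find_peaks <- function(s, prominence_frac = 0.05, smooth = TRUE) {
  noise_scale <- stats::mad(diff(s)) / sqrt(2)
  if (smooth && length(s) > 9L) s <- savitzky_golay(s, 7L, 2L)
  rng <- diff(range(s))
  if (rng <= 0) return(integer(0))
  prom_min <- max(prominence_frac * rng, 6 * noise_scale)
  cand <- local_maxima(s)
  keep <- vapply(cand, function(i) {
    lo_l <- s[i]
    j <- i
    while (j > 1L && s[j - 1L] <= s[i]) { j <- j - 1L; lo_l <- min(lo_l, s[j]) }
    if (j == 1L) lo_l <- min(lo_l, s[1L])
    lo_r <- s[i]
    j <- i
    while (j < length(s) && s[j + 1L] <= s[i]) { j <- j + 1L; lo_r <- min(lo_r, s[j]) }
    if (j == length(s)) lo_r <- min(lo_r, s[length(s)])
    (s[i] - max(lo_l, lo_r)) >= prom_min
  }, logical(1))
  cand[keep]
}

#' Label endmembers against a band library
#'
#' Scores every endmember against every library entry: the score is the
#' fraction of the entry's diagnostic bands (restricted to bands inside the
#' spectral axis) at which the endmember spectrum has a prominent local
#' maximum within the entry's tolerance. Each endmember's candidate label is
#' its unique best match at or above `score_floor`; an endmember whose top
#' score is shared by several entries (e.g. a merged lipid component showing
#' both the TAG and the cholesteryl diagnostic bands after z-collapse) is
#' ambiguous and stays `"unassigned"`. Conflicts where two endmembers want
#' the same label go to the higher score, then to the spectrum in which the
#' diagnostic bands are the more dominant feature. The full score table is
#' kept for manual review.
#'
#' @param endmembers An `endmember_set` from [vca()].
#' @param lib A [band_library()].
#' @param score_floor Minimum score for an assignment (default 0.5).
#' @param prominence Minimum peak prominence as a fraction of the spectrum
#'   range; spectra are lightly smoothed before peak finding so that noise
#'   maxima do not count as diagnostic peaks.
#' @return The `endmember_set` with `labels` replaced and a `score_table`
#'   element added (endmembers x library entries matrix).
#' @export
label_endmembers <- function(endmembers, lib = default_band_library(),
                             score_floor = 0.5, prominence = 0.05) {
  stopifnot(inherits(endmembers, "endmember_set"), inherits(lib, "band_library"))
  wn <- endmembers$wavenumbers
  p <- endmembers$p
  labs <- vapply(lib, `[[`, character(1), "label")
  scores <- matrix(NA_real_, p, length(lib), dimnames = list(NULL, labs))
  heights <- matrix(0, p, length(lib))         # tie-break: relative peak height
  for (i in seq_len(p)) {
    s <- endmembers$S[i, ]
    peak_idx <- find_peaks(s, prominence_frac = prominence)
    peaks <- wn[peak_idx]
    smax <- max(abs(s), .Machine$double.eps)
    for (e in seq_along(lib)) {
      bands <- lib[[e]]$bands
      bands <- bands[bands >= min(wn) & bands <= max(wn)]
      if (length(bands) == 0L) next            # entry inapplicable on this axis
      hit <- vapply(bands, function(b) {
        if (length(peaks) == 0L) return(0)
        d <- abs(peaks - b)
        if (min(d) > lib[[e]]$tolerance) return(0)
        s[peak_idx[which.min(d)]] / smax
      }, numeric(1))
      scores[i, e] <- mean(hit > 0)
      heights[i, e] <- mean(hit)
    }
  }
  # each endmember may carry at most one candidate label: its unique best
  # match. A spectrum matching two entries' diagnostic bands equally well
  # (e.g. a merged lipid component showing both the TAG and the cholesteryl
  # markers) is ambiguous and stays unassigned rather than being guessed.
  cand_entry <- rep(NA_integer_, p)
  for (i in seq_len(p)) {
    ok <- which(!is.na(scores[i, ]) & scores[i, ] >= score_floor)
    if (length(ok) == 0L) next
    top <- max(scores[i, ok])
    tied <- ok[scores[i, ok] == top]
    if (length(tied) == 1L) cand_entry[i] <- tied
  }
  assigned <- rep(NA_character_, p)
  cand <- which(!is.na(cand_entry))
  if (length(cand) > 0L) {
    # label conflicts between endmembers resolved by score, then by how
    # dominant the diagnostic bands are in the spectrum
    ord <- cand[order(scores[cbind(cand, cand_entry[cand])],
                      heights[cbind(cand, cand_entry[cand])],
                      decreasing = TRUE)]
    for (i in ord) {
      lab <- labs[cand_entry[i]]
      if (!(lab %in% assigned)) assigned[i] <- lab
    }
  }
  assigned[is.na(assigned)] <- "unassigned"
  endmembers$labels <- make.unique(assigned, sep = "_")
  endmembers$score_table <- scores
  endmembers
}

#' Univariate band-intensity volume
#'
#' Classic single-band reconstruction: per voxel, the maximum intensity
#' within `band +/- half_width` cm^-1 (the local maximum is robust to small
#' calibration shifts), min-max scaled to `[0, 1]` over the whole volume. A
#' constant volume scales to all zeros.
#'
#' @param vol A [hyper_volume()].
#' @param band Band centre in cm^-1 (must lie on the axis range).
#' @param half_width Window half-width in cm^-1 (default 5, about half a
#'   typical 10 cm^-1 spectral resolution).
#' @return A [component_volume()] labelled `"band_<band>"`.
#' @export
univariate_band_map <- function(vol, band, half_width = 5) {
  stopifnot(inherits(vol, "hyper_volume"))
  wn <- vol$wavenumbers
  if (band < min(wn) || band > max(wn))
    stop(sprintf("band %g cm^-1 is outside the axis range %g-%g", band, min(wn), max(wn)))
  idx <- which(wn >= band - half_width & wn <= band + half_width)
  if (length(idx) == 0L) stop("empty band window; widen half_width")
  sub <- vol$intensities[, , , idx, drop = FALSE]
  vals <- apply(sub, c(1L, 2L, 3L), max)
  rng <- range(vals)
  vals <- if (rng[2L] > rng[1L]) (vals - rng[1L]) / (rng[2L] - rng[1L])
          else array(0, dim = dim(vals))
  component_volume(vals, vol$grid, sprintf("band_%g", band))
}

#' Sweep the endmember count and report label assignments
#'
#' Runs [vca()] + [label_endmembers()] for each candidate component count and
#' reports how many endmembers earn a library label, to assist the analyst's
#' choice of `p`. No automatic selection is made: the final count is a user
#' decision based on peak assignment.
#'
#' @param x An `unfolded_matrix` or `M x w` matrix (normalised).
#' @param p_range Integer vector of candidate component counts.
#' @param lib A [band_library()].
#' @param seed Seed forwarded to [vca()].
#' @param wavenumbers Axis; required when `x` is a bare matrix.
#' @param score_floor Forwarded to [label_endmembers()].
#' @return Data frame with columns `p`, `n_assigned`, and `labels`
#'   (semicolon-separated assigned labels).
#' @export
sweep_component_count <- function(x, p_range, lib = default_band_library(),
                                  seed = 1L, wavenumbers = NULL,
                                  score_floor = 0.5) {
  rows <- lapply(as.integer(p_range), function(p) {
    em <- label_endmembers(vca(x, p, seed = seed, wavenumbers = wavenumbers),
                           lib, score_floor)
    hit <- !startsWith(em$labels, "unassigned")
    data.frame(p = p, n_assigned = sum(hit),
               labels = paste(em$labels[hit], collapse = ";"))
  })
  do.call(rbind, rows)
}
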
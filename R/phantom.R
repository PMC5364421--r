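#' Parametric Raman band
#'
#' @param center Band centre in cm^-1.
#' @param fwhm Full width at half maximum in cm^-1 (> 0).
#' @param amplitude Peak amplitude in arbitrary units (>= 0).
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return An object of class `peak_band`.
#' @export
peak_band <- function(center, fwhm, amplitude = 1, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape = shape), class = "peak_band")
}

#' Evaluate a sum of parametric bands on a wavenumber axis
#'
#' @param bands List of [peak_band()]s (empty list gives a zero spectrum).
#' @param wavenumbers Axis in cm^-1.
#' @return Non-negative numeric vector, one value per channel.
#' @export
synth_spectrum <- function(bands, wavenumbers) {
  s <- numeric(length(wavenumbers))
  for (b in bands) {
    if (b$shape == "gaussian") {
      s <- s + b$amplitude * exp(-4 * log(2) * ((wavenumbers - b$center) / b$fwhm)^2)
    } else {
      s <- s + b$amplitude / (1 + (2 * (wavenumbers - b$center) / b$fwhm)^2)
    }
  }
  s
}

# Convenience: build a band list from a matrix-like spec of (center, fwhm, amp).
bands_from_table <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i)
    peak_band(tab[i, 1L], tab[i, 2L], tab[i, 3L]))
}

#' Reference endmember band sets for the phantom components
#'
#' Parametric band models for the components the phantoms are built from.
#' Band centres follow standard cellular Raman assignments (phenylalanine
#' 1008, DNA O-P-O 789, ester C=O 1747, cholesteryl 1066/1134, choline 719,
#' PEG 847, CH2 twist 1300/1303 and deformation 1443, CH stretches near
#' 2850-2950 cm^-1); widths of 12-40 cm^-1 are consistent with a ~10 cm^-1
#' instrument resolution. The lipid subtypes deliberately share the CH2
#' 1300/1303 and 1443 cm^-1 bands and differ only in their diagnostic bands,
#' so that separating them is a genuine test of spectral specificity.
#'
#' @param component One of `"cytoplasm"`, `"nucleus"`, `"TAG"`,
#'   `"phospholipid"`, `"cholesterol"`, `"PEG"`, `"medium"`, `"glycogen"`.
#' @return A list of [peak_band()]s.
#' @export
phantom_bands <- function(component) {
  tabs <- list(
    cytoplasm    = rbind(c(1008, 12, 1.00), c(1450, 18, 0.55), c(1660, 22, 0.70),
                         c(2935, 40, 0.90)),
    nucleus      = rbind(c(789, 14, 1.00), c(1095, 18, 0.55), c(1578, 16, 0.60),
                         c(1660, 22, 0.30), c(2950, 40, 0.50)),
    TAG          = rbind(c(870, 18, 0.35), c(1303, 16, 1.25), c(1443, 16, 1.60),
                         c(1660, 18, 0.60), c(1747, 14, 1.45), c(2857, 30, 2.20)),
    phospholipid = rbind(c(719, 12, 0.60), c(1085, 18, 0.45), c(1300, 16, 0.70),
                         c(1443, 16, 0.85), c(2857, 30, 1.00)),
    cholesterol  = rbind(c(1066, 12, 1.50), c(1134, 12, 1.45), c(1300, 16, 0.90),
                         c(1443, 16, 2.00), c(2857, 30, 2.00)),
    PEG          = rbind(c(847, 14, 1.00), c(1240, 18, 0.45), c(1470, 16, 0.65),
                         c(2890, 35, 0.80)),
    medium       = rbind(c(1640, 80, 0.40), c(2930, 90, 0.30)),
    glycogen     = rbind(c(485, 16, 1.00), c(940, 18, 0.50), c(1083, 18, 0.40),
                         c(1340, 20, 0.35)))
  tab <- tabs[[component]]
  if (is.null(tab)) stop(sprintf("unknown phantom component '%s'", component))
  bands_from_table(tab)
}

#' Phantom compartment
#'
#' A geometric primitive carrying one endmember spectrum. Geometry parameters
#' are in micrometres. When compartments overlap, the one listed first in the
#' [phantom_spec()] claims the voxel (priority by listing order).
#'
#' @param label Component label.
#' @param shape `"sphere"`, `"ellipsoid"`, `"shell"` (an ellipsoidal shell of
#'   the given `thickness` outside `radii`), or `"background"` (everything
#'   not claimed by an earlier compartment).
#' @param center Centre in um (length 3), unused for `"background"`.
#' @param radii Radius (sphere) or semi-axes in um (ellipsoid/shell inner
#'   surface).
#' @param thickness Shell thickness in um.
#' @param bands List of [peak_band()]s (the compartment's endmember).
#' @param level Abundance level of a fully interior voxel (default 1).
#' @return An object of class `phantom_compartment`.
#' @export
phantom_compartment <- function(label, shape, center = c(0, 0, 0), radii = 1,
                                thickness = 1, bands = list(), level = 1) {
  shape <- match.arg(shape, c("sphere", "ellipsoid", "shell", "background"))
  if (shape == "sphere") radii <- rep(radii[1L], 3L)
  structure(list(label = label, shape = shape, center = center, radii = radii,
                 thickness = thickness, bands = bands, level = level),
            class = "phantom_compartment")
}

# Membership test for supersampled points (n x 3 matrix of um coordinates).
compartment_inside <- function(comp, pts) {
  if (comp$shape == "background") return(rep(TRUE, nrow(pts)))
  q <- sweep(pts, 2L, comp$center)
  r2 <- function(radii) (q[, 1L] / radii[1L])^2 + (q[, 2L] / radii[2L])^2 +
    (q[, 3L] / radii[3L])^2
  if (comp$shape %in% c("sphere", "ellipsoid")) return(r2(comp$radii) <= 1)
  r2(comp$radii + comp$thickness) <= 1 & r2(comp$radii) > 1   # shell
}

#' Phantom specification
#'
#' Everything needed to simulate one z-stack acquisition: grid, wavenumber
#' axis, compartments (priority by listing order), per-spectrum random cubic
#' fluorescence baseline, dataset SNR, expected cosmic-ray count per layer,
#' sub-voxel supersampling for partial-volume boundaries, and the seed.
#'
#' @param grid A [voxel_grid()].
#' @param wavenumbers Axis in cm^-1.
#' @param compartments List of [phantom_compartment()]s (non-empty).
#' @param baseline_scale Amplitude of the random cubic baseline relative to
#'   the maximum endmember intensity (0 disables baselines).
#' @param snr_db Dataset signal-to-noise ratio in dB: 10*log10 of mean
#'   per-voxel signal energy over expected per-voxel noise energy
#'   (`Inf` disables noise).
#' @param n_cosmic Expected (Poisson) cosmic-ray spikes per layer.
#' @param supersample Sub-voxel sampling factor per axis (default 2).
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid, wavenumbers, compartments, baseline_scale = 1,
                         snr_db = 25, n_cosmic = 2, supersample = 2L,
                         seed = 1L, sample_id = "phantom") {
  if (length(compartments) == 0L) stop("need at least one compartment")
  structure(list(grid = grid, wavenumbers = check_axis(wavenumbers),
                 compartments = compartments, baseline_scale = baseline_scale,
                 snr_db = snr_db, n_cosmic = n_cosmic,
                 supersample = as.integer(supersample), seed = as.integer(seed),
                 sample_id = sample_id),
            class = "phantom_spec")
}

#' Default macrophage-like cell phantom
#'
#' A 40 x 40 x 10 voxel z-stack (0.65 um lateral, 1 um axial) holding one
#' cell built from five cellular components — ellipsoidal cytoplasm,
#' spherical nucleus, six lipid droplets split between triacylglycerols and
#' cholesterol, and a 1-um phospholipid membrane shell — immersed in a
#' culture-medium background with its own weak broad spectrum. The medium
#' carries real (if dim) signal so that the data simplex has no degenerate
#' all-zero vertex; unmixing this phantom therefore targets six endmembers
#' (five cellular + medium).
#'
#' @param seed Seed for the stochastic parts (baseline, noise, cosmic rays).
#' @param wavenumbers Axis; default 0-3000 cm^-1 in 2 cm^-1 steps.
#' @param grid Grid; default `voxel_grid(40, 40, 10)`.
#' @param snr_db,baseline_scale,n_cosmic See [phantom_spec()].
#' @param cholesterol Include the cholesterol droplets (set `FALSE` for an
#'   undifferentiated-monocyte-like phantom).
#' @param chol_radius Cholesterol droplet radius in um at the reference field
#'   of view (cholesterol-rich regions are smaller than TAG lipid bodies;
#'   default 1.5).
#' @param jitter Geometry jitter magnitude in um applied to droplet centres
#'   and proportionally to radii (0 = the reference geometry); jitter draws
#'   use the spec seed at build time.
#' @return A [phantom_spec()].
#' @export
macrophage_phantom_spec <- function(seed = 1L,
                                    wavenumbers = seq(0, 3000, by = 2),
                                    grid = voxel_grid(40, 40, 10),
                                    snr_db = 25, baseline_scale = 1,
                                    n_cosmic = 2, cholesterol = TRUE,
                                    chol_radius = 1.5, jitter = 0) {
  # geometry scales with the grid's physical extent; the reference design is
  # a 26 x 26 x 10 um field of view (40 x 40 x 10 voxels at default steps)
  Lx <- grid$X * grid$dx; Ly <- grid$Y * grid$dy; Lz <- grid$Z * grid$dz
  s <- min(Lx, Ly) / 26; sz <- Lz / 10
  centre <- c(Lx / 2, Ly / 2, 0.45 * Lz)
  frac <- function(fx, fy, fz) c(fx * Lx, fy * Ly, fz * Lz)
  # cholesterol-rich bodies sit in the same xy columns as TAG lipid bodies
  # but at other depths (endosomal accumulations stacked with lipid bodies):
  # resolvable confocally, merged by z-overlap
  pair_xy <- list(c(0.673, 0.500), c(0.600, 0.662), c(0.440, 0.660))
  tag_z <- c(0.33, 0.58, 0.32)
  chol_z <- c(0.64, 0.265, 0.64)
  droplets <- list(
    TAG = lapply(1:3, function(i) frac(pair_xy[[i]][1], pair_xy[[i]][2], tag_z[i])),
    cholesterol = lapply(1:3, function(i) frac(pair_xy[[i]][1], pair_xy[[i]][2],
                                               chol_z[i])))
  r_tag <- rep(1.6 * s, 3L)
  r_chol <- rep(chol_radius * s, 3L)
  if (jitter > 0) {
    # each TAG/cholesterol pair moves laterally as one cluster; radii vary
    # per droplet by +/-25% — lipid content differs markedly from cell to cell
    jseed <- seed + 7919L
    set.seed(jseed)
    for (i in 1:3) {
      lat <- stats::runif(2, -jitter * s, jitter * s)
      dz_t <- stats::runif(1, -jitter * s / 2, jitter * s / 2)
      dz_c <- stats::runif(1, -jitter * s / 2, jitter * s / 2)
      droplets$TAG[[i]] <- droplets$TAG[[i]] + c(lat, dz_t)
      droplets$cholesterol[[i]] <- droplets$cholesterol[[i]] + c(lat, dz_c)
    }
    r_tag <- r_tag * stats::runif(3L, 0.75, 1.25)
    r_chol <- r_chol * stats::runif(3L, 0.75, 1.25)
  }
  comps <- list(
    phantom_compartment("nucleus", "sphere", frac(0.375, 0.5, 0.45), 3.2 * s,
                        bands = phantom_bands("nucleus")))
  for (i in seq_along(droplets$TAG))
    comps <- c(comps, list(phantom_compartment("TAG", "sphere", droplets$TAG[[i]],
                                               r_tag[i], bands = phantom_bands("TAG"))))
  if (cholesterol)
    for (i in seq_along(droplets$cholesterol))
      comps <- c(comps, list(phantom_compartment("cholesterol", "sphere",
                                                 droplets$cholesterol[[i]], r_chol[i],
                                                 bands = phantom_bands("cholesterol"))))
  cyto_radii <- c(0.404 * Lx, 0.365 * Ly, 0.39 * Lz)
  comps <- c(comps, list(
    phantom_compartment("phospholipid", "shell", centre, cyto_radii,
                        thickness = 1.0 * sz, bands = phantom_bands("phospholipid")),
    phantom_compartment("cytoplasm", "ellipsoid", centre, cyto_radii,
                        bands = phantom_bands("cytoplasm")),
    phantom_compartment("medium", "background", bands = phantom_bands("medium"))))
  phantom_spec(grid, wavenumbers, comps, baseline_scale = baseline_scale,
               snr_db = snr_db, n_cosmic = n_cosmic, seed = seed,
               sample_id = sprintf("macrophage_%d", seed))
}

#' Cell-in-hydrogel phantom
#'
#' A smaller spherical cell (cytoplasm + nucleus + TAG droplet + membrane)
#' embedded in a PEG hydrogel background whose spectrum carries the PEG
#' 847 cm^-1 marker band.
#'
#' @inheritParams macrophage_phantom_spec
#' @return A [phantom_spec()].
#' @export
hydrogel_phantom_spec <- function(seed = 1L, wavenumbers = seq(0, 3000, by = 2),
                                  grid = voxel_grid(40, 40, 10), snr_db = 25,
                                  baseline_scale = 1, n_cosmic = 2) {
  Lx <- grid$X * grid$dx; Ly <- grid$Y * grid$dy; Lz <- grid$Z * grid$dz
  s <- min(Lx, Ly) / 26; sz <- Lz / 10
  centre <- c(Lx / 2, Ly / 2, 0.45 * Lz)
  cell_radii <- c(0.3 * Lx, 0.277 * Ly, 0.36 * Lz)
  comps <- list(
    phantom_compartment("nucleus", "sphere", centre + c(-2.0 * s, 0, 0), 2.6 * s,
                        bands = phantom_bands("nucleus")),
    phantom_compartment("TAG", "sphere", centre + c(3.9 * s, 2.6 * s, 1.0 * sz), 1.6 * s,
                        bands = phantom_bands("TAG")),
    phantom_compartment("phospholipid", "shell", centre, cell_radii,
                        thickness = 1.0 * sz, bands = phantom_bands("phospholipid")),
    phantom_compartment("cytoplasm", "ellipsoid", centre, cell_radii,
                        bands = phantom_bands("cytoplasm")),
    phantom_compartment("PEG", "background", bands = phantom_bands("PEG")))
  phantom_spec(grid, wavenumbers, comps, baseline_scale = baseline_scale,
               snr_db = snr_db, n_cosmic = n_cosmic, seed = seed,
               sample_id = sprintf("hydrogel_%d", seed))
}

#' Build a phantom z-stack with ground truth
#'
#' Realises a [phantom_spec()]: true per-component abundance volumes come
#' from the compartment geometry with partial-volume boundary voxels
#' estimated by sub-voxel supersampling; each voxel's raw spectrum is the
#' abundance-weighted sum of the endmember spectra plus a random per-spectrum
#' cubic baseline and iid Gaussian noise at the requested dataset SNR; sparse
#' cosmic-ray spikes (1-2 channels wide, 20-100 times the noise sigma) are
#' injected per layer at Poisson-distributed counts and recorded. The build
#' is bit-reproducible for a fixed spec.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (the raw [hyper_volume()]) and `truth` (class
#'   `phantom_truth`): `abundances` (named list of X x Y x Z arrays in
#'   `[0, 1]`), `endmembers` (component x channel matrix), `fractions` (per
#'   component: `fraction_volume`, the abundance integral over the grid, and
#'   `fraction_thresholded`, the voxel fraction at/above the component's own
#'   mean true abundance), `cosmic` (injected spike table), `noise_sigma`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid; wn <- spec$wavenumbers; ss <- spec$supersample
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  # supersampled grid coordinates (um), x fastest then y then z
  sub <- function(n, step) (rep(seq_len(n), each = ss) - 1 +
                              (rep(seq_len(ss), n) - 0.5) / ss) * step
  xs <- sub(g$X, g$dx); ys <- sub(g$Y, g$dy); zs <- sub(g$Z, g$dz)
  pts <- cbind(rep(xs, times = ss * g$Y * ss * g$Z),
               rep(rep(ys, each = ss * g$X), times = ss * g$Z),
               rep(zs, each = ss * g$X * ss * g$Y))

  labels <- vapply(spec$compartments, `[[`, character(1), "label")
  ulabels <- unique(labels)
  claimed <- rep(FALSE, nrow(pts))
  sub_ab <- matrix(0, nrow(pts), length(ulabels))
  colnames(sub_ab) <- ulabels
  for (i in seq_along(spec$compartments)) {
    comp <- spec$compartments[[i]]
    inside <- compartment_inside(comp, pts) & !claimed
    sub_ab[inside, comp$label] <- sub_ab[inside, comp$label] + comp$level
    claimed <- claimed | inside
  }
  # aggregate ss^3 subsamples per voxel
  M <- g$X * g$Y * g$Z
  abund <- lapply(ulabels, function(lab) {
    a <- array(sub_ab[, lab], dim = c(ss, g$X, ss, g$Y, ss, g$Z))
    a <- aperm(a, c(1L, 3L, 5L, 2L, 4L, 6L))
    dim(a) <- c(ss^3, M)
    array(colMeans(a), dim = c(g$X, g$Y, g$Z))
  })
  names(abund) <- ulabels

  # endmember spectra and the clean linear mixture
  E <- t(vapply(spec$compartments[match(ulabels, labels)],
                function(comp) synth_spectrum(comp$bands, wn),
                numeric(length(wn))))
  rownames(E) <- ulabels
  A <- vapply(abund, as.numeric, numeric(M))        # M x ncomp
  signal <- A %*% E

  # random per-spectrum cubic fluorescence baseline
  amp <- max(E)
  if (spec$baseline_scale > 0 && amp > 0) {
    tt <- (wn - min(wn)) / (max(wn) - min(wn))
    Tb <- cbind(1, tt, tt^2, tt^3)
    coefs <- cbind(stats::runif(M, 0.3, 1.0), stats::runif(M, -0.8, 0.1),
                   stats::runif(M, -0.3, 0.3), stats::runif(M, -0.2, 0.2))
    baseline <- (spec$baseline_scale * amp) * (coefs %*% t(Tb))
  } else baseline <- 0

  sig_energy <- mean(rowSums(signal^2))
  sigma <- if (is.finite(spec$snr_db) && sig_energy > 0)
    sqrt(sig_energy / (length(wn) * 10^(spec$snr_db / 10))) else 0
  noise <- if (sigma > 0) matrix(stats::rnorm(M * length(wn), sd = sigma),
                                 M, length(wn)) else 0
  raw <- signal + baseline + noise

  # cosmic-ray spikes, Poisson count per layer, width 1-2 channels
  cosmic <- NULL
  if (spec$n_cosmic > 0 && sigma > 0) {
    recs <- list()
    for (z in seq_len(g$Z)) {
      n_spk <- stats::rpois(1L, spec$n_cosmic)
      if (n_spk == 0L) next
      for (s in seq_len(n_spk)) {
        x <- sample.int(g$X, 1L); y <- sample.int(g$Y, 1L)
        ch <- sample.int(length(wn) - 1L, 1L)
        width <- sample.int(2L, 1L)
        ampl <- stats::runif(1L, 20, 100) * sigma
        m <- voxel_index(x, y, z, g)
        chs <- ch:min(ch + width - 1L, length(wn))
        raw[m, chs] <- raw[m, chs] + ampl
        recs[[length(recs) + 1L]] <- data.frame(layer = z, x = x, y = y,
                                                channel = ch, width = width,
                                                amplitude = ampl)
      }
    }
    cosmic <- if (length(recs)) do.call(rbind, recs) else NULL
  }
  if (is.null(cosmic))
    cosmic <- data.frame(layer = integer(0), x = integer(0), y = integer(0),
                         channel = integer(0), width = integer(0),
                         amplitude = numeric(0))

  dim(raw) <- c(g$X, g$Y, g$Z, length(wn))
  vol <- hyper_volume(raw, wn, g, spec$sample_id)
  fractions <- data.frame(
    component = ulabels,
    fraction_volume = vapply(abund, function(a) sum(a) / M, numeric(1)),
    fraction_thresholded = vapply(abund, function(a)
      if (max(a) > 0) mean(a >= mean(a)) else 0, numeric(1)),
    row.names = NULL)
  truth <- structure(list(abundances = abund, endmembers = E,
                          fractions = fractions, cosmic = cosmic,
                          noise_sigma = sigma, seed = spec$seed),
                     class = "phantom_truth")
  list(volume = vol, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom_truth components:\n")
  print(x$fractions)
  cat(sprintf("  noise sigma %.4g, %d cosmic spikes\n", x$noise_sigma, nrow(x$cosmic)))
  invisible(x)
}

#' Simulate a seeded two-group phantom experiment
#'
#' Builds `n_per_group` phantoms per group with per-sample geometry jitter
#' and per-sample noise seeds, emulating a differentiation experiment where
#' the effect is known (e.g. group B carries cholesterol droplets that group
#' A lacks). The output feeds [run_pipeline()] for power or type-I studies.
#'
#' @param spec_fn_a,spec_fn_b Functions `(seed, jitter) -> phantom_spec` for
#'   the two groups; see [macrophage_phantom_spec()].
#' @param n_per_group Samples per group (>= 2).
#' @param seed Experiment seed; per-sample seeds are derived from it.
#' @param jitter Geometry jitter in um passed to the spec functions.
#' @return List with `A` and `B`: lists of [build_phantom()] results.
#' @export
two_group_experiment <- function(spec_fn_a, spec_fn_b, n_per_group = 4L,
                                 seed = 1L, jitter = 0.5) {
  if (n_per_group < 2L) stop("need at least 2 samples per group")
  build_group <- function(fn, offset) {
    lapply(seq_len(n_per_group), function(i)
      build_phantom(fn(seed = seed * 1000L + offset + i, jitter = jitter)))
  }
  list(A = build_group(spec_fn_a, 0L), B = build_group(spec_fn_b, 500L))
}
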
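# Synthetic data generation: toy atomic models in a monoclinic P2(1) cell,
# ground-truth diffuse volumes from the LLM/RBT forward models, and full
# artificial rotation series (crystal + paired background frames) with
# controllable physical artifacts, so every pipeline stage is testable
# without experimental data.
#
# The renderer emulates data collection: each frame is the Ewald-sphere
# slice of the ground-truth volume (trilinear interpolation), plus an
# isotropic water-ring-like background, a detector-fixed anisotropic
# background component (emulating mount scatter), Bragg spikes at
# reciprocal-lattice points, polarization and solid-angle modulation (which
# the pipeline must undo), per-frame radial drift of the illuminated
# volume, Poisson counting noise, and randomly dead/hot pixels. Background
# frames carry the background-only signal at a longer exposure.

#' Specification of a synthetic rotation series
#'
#' Defaults emulate a desk-scale version of a synchrotron diffuse
#' scattering experiment: 0.5 degree rotation per frame, 0.3 s crystal and
#' 1 s background exposures, strong horizontal polarization, a water-ring
#' background hump, and weak Poisson noise on a small (512^2) detector.
#'
#' @param n_frames number of frames (default 180).
#' @param step_deg rotation per frame (degrees, default 0.5).
#' @param exposure_s crystal exposure (seconds, default 0.3).
#' @param background_exposure_s background exposure (seconds, default 1).
#' @param diffuse_scale mean diffuse signal (photons/s) at the truth
#'   volume's mean intensity.
#' @param background_scale peak isotropic background rate (photons/s).
#' @param background_aniso_frac amplitude of the detector-fixed anisotropic
#'   background component, as a fraction of the isotropic peak.
#' @param radial_drift_sd per-frame fractional amplitude of the radial
#'   profile drift of the crystal signal (emulates illuminated-volume and
#'   beam variation; 0 disables).
#' @param bragg_rate Bragg spike rate (photons/s) at reciprocal-lattice
#'   points.
#' @param bad_pixel_rate fraction of dead/hot pixels per frame.
#' @param poisson_noise apply Poisson counting noise? (FALSE gives exact
#'   expected counts, for identity tests).
#' @param mount_rotation_deg random crystal mounting rotation bound: each
#'   dataset gets a random orientation offset drawn within this bound
#'   (degrees), so replicate datasets sample reciprocal space differently.
#' @param seed integer seed; fully determines the series.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_frames = 180, step_deg = 0.5,
                           exposure_s = 0.3, background_exposure_s = 1,
                           diffuse_scale = 500, background_scale = 600,
                           background_aniso_frac = 0.25,
                           radial_drift_sd = 0.08,
                           bragg_rate = 2e4, bad_pixel_rate = 1e-3,
                           mount_rotation_deg = 360, poisson_noise = TRUE,
                           seed = 1L) {
  stopifnot(n_frames >= 1, step_deg > 0, exposure_s > 0,
            background_exposure_s > 0, bad_pixel_rate >= 0,
            bad_pixel_rate <= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Default desk-scale synthetic geometry
#'
#' A small 512^2 detector at 16 keV (0.7749 Angstrom), placed so the
#' detector edge reaches about 1.35 Angstrom resolution; the short
#' wavelength keeps the Ewald blind cusp around the spindle axis small, as
#' at a synchrotron beamline.
#'
#' @param detector_px detector edge length in pixels (default 512).
#' @param polarization_fraction see [experiment_geometry()].
#' @return an [experiment_geometry()].
#' @export
synthetic_geometry <- function(detector_px = 512,
                               polarization_fraction = 0.99) {
  experiment_geometry(
    wavelength = 0.7749, distance_mm = 70, pixel_mm = 0.172,
    beam_center = c((detector_px - 1) / 2, (detector_px - 1) / 2),
    detector_shape = c(detector_px, detector_px),
    polarization_fraction = polarization_fraction
  )
}

#' Generate a toy atomic model
#'
#' Pseudo-atoms at uniform random positions in the asymmetric unit of a
#' monoclinic P2(1) cell, with isotropic-equivalent B values in a plausible
#' protein range and anisotropic U tensors whose anisotropy ratios
#' (smallest/largest eigenvalue) are drawn from a bell-shaped distribution
#' centered near 0.45. Optionally includes a few two-conformer (altloc
#' A/B) atoms to exercise conformer filtering.
#'
#' @param n_atoms number of atoms in the asymmetric unit (default 40).
#' @param cell unit cell (default monoclinic 25, 30, 20, 90, 105, 90).
#' @param b_range range of B_eq values (Angstrom^2).
#' @param anisotropy_center center of the anisotropy-ratio distribution.
#' @param n_altloc number of atoms duplicated as B conformers (default 0).
#' @param seed integer seed.
#' @return an [atomic_model()] (space group P21).
#' @export
make_toy_model <- function(n_atoms = 40,
                           cell = c(25, 30, 20, 90, 105, 90),
                           b_range = c(8, 20), anisotropy_center = 0.45,
                           n_altloc = 0, seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  elements <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE,
                     prob = c(0.6, 0.17, 0.2, 0.03))
  pos <- cbind(stats::runif(n_atoms), stats::runif(n_atoms) / 2,
               stats::runif(n_atoms))
  beq <- stats::runif(n_atoms, b_range[1], b_range[2])
  # anisotropy ratio ~ Beta with mean anisotropy_center, sd ~ 0.1
  ab <- anisotropy_center * (1 - anisotropy_center) / 0.1^2 - 1
  r <- stats::rbeta(n_atoms, anisotropy_center * ab,
                    (1 - anisotropy_center) * ab)
  U <- matrix(NA_real_, n_atoms, 6)
  for (i in seq_len(n_atoms)) {
    ueq <- beq[i] / (8 * pi^2)
    # eigenvalues (l1 >= l2 >= l3) with l3/l1 = r and trace = 3 ueq
    l1 <- 3 * ueq / (1 + (1 + r[i]) / 2 + r[i])
    ev <- c(l1, l1 * (1 + r[i]) / 2, l1 * r[i])
    # random rotation via QR of a Gaussian matrix
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Um <- Q %*% diag(ev) %*% t(Q)
    U[i, ] <- c(Um[1, 1], Um[2, 2], Um[3, 3], Um[1, 2], Um[1, 3], Um[2, 3])
  }
  atoms <- data.frame(element = elements, x = pos[, 1], y = pos[, 2],
                      z = pos[, 3], occupancy = 1, altloc = "",
                      b = beq, u11 = U[, 1], u22 = U[, 2], u33 = U[, 3],
                      u12 = U[, 4], u13 = U[, 5], u23 = U[, 6])
  if (n_altloc > 0) {
    pick <- seq_len(min(n_altloc, n_atoms))
    a <- atoms[pick, , drop = FALSE]
    atoms$altloc[pick] <- "A"
    atoms$occupancy[pick] <- 0.7
    a$altloc <- "B"
    a$occupancy <- 0.3
    a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * nrow(a), sd = 0.01), nrow(a))
    atoms <- rbind(atoms, a)
  }
  atomic_model(atoms, cell, "P21")
}

#' Ground-truth diffuse volume from a toy model
#'
#' Forward-computes the noiseless LLM or RBT diffuse intensity on the
#' integer-Miller grid.
#'
#' @param model an [atomic_model()].
#' @param sigma,gamma ground-truth LLM parameters (Angstrom); `gamma` is
#'   ignored for `kind = "rbt"`.
#' @param hmax grid half-width in Miller indices (default 60, the standard
#'   121^3 grid).
#' @param kind `"llm"` or `"rbt"`.
#' @param adp_mode ADP treatment of the reference intensity.
#' @param dw overall Debye-Waller factor (defaults to `adp_mode == "zero"`).
#' @param oversample samples per Miller index (>1 reduces the renderer's
#'   interpolation smoothing).
#' @return a [diffuse_volume()].
#' @export
make_truth_volume <- function(model, sigma = 0.4, gamma = 7, hmax = 60,
                              kind = c("llm", "rbt"),
                              adp_mode = c("zero", "isotropic",
                                           "anisotropic"),
                              dw = NULL, oversample = 1L) {
  kind <- match.arg(kind)
  adp_mode <- match.arg(adp_mode)
  if (is.null(dw)) dw <- adp_mode == "zero"
  ref <- reference_intensity(select_conformer(model), hmax, adp_mode,
                             oversample = oversample)
  if (kind == "llm") llm_intensity(ref, sigma, gamma, dw)
  else rbt_intensity(ref, sigma)
}

# Trilinear interpolation of a centered cubic volume at fractional Miller
# indices; returns 0 outside the grid. `hmax` is in grid steps and
# `oversample` converts Miller units to grid steps.
trilinear <- function(values, hmax, hkl, oversample = 1L) {
  n <- 2L * hmax + 1L
  g <- hkl * oversample + hmax + 1   # 1-based grid coordinates
  i0 <- floor(g)
  f <- g - i0
  out <- numeric(nrow(hkl))
  v <- values
  v[is.na(v)] <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- i0[, 1] + dx; iy <- i0[, 2] + dy; iz <- i0[, 3] + dz
    w <- (if (dx == 1) f[, 1] else 1 - f[, 1]) *
      (if (dy == 1) f[, 2] else 1 - f[, 2]) *
      (if (dz == 1) f[, 3] else 1 - f[, 3])
    ok <- ix >= 1 & ix <= n & iy >= 1 & iy <= n & iz >= 1 & iz <= n
    idx <- (ix - 1) + (iy - 1) * n + (iz - 1) * n^2 + 1
    out[ok] <- out[ok] + w[ok] * v[idx[ok]]
  }
  out
}

# Smooth water-ring-like isotropic background profile: broad hump peaking
# near d = 3.3 A on a decaying base; returns rate per |q|.
background_profile <- function(qmag, scale) {
  scale * (0.35 * exp(-(qmag / 0.25)^2) +
             exp(-((qmag - 1 / 3.3) / 0.09)^2) +
             0.25 * exp(-((qmag - 1 / 2.0) / 0.12)^2))
}

#' Render a synthetic rotation series
#'
#' Produces paired crystal and background frames for every spindle angle,
#' plus the orientation (A matrix, spindle angles) ground truth, from a
#' noiseless truth volume. See the module comment for the physical effects
#' included; the generator applies polarization and solid-angle modulation
#' so the processing pipeline must undo them.
#'
#' @param truth ground-truth [diffuse_volume()].
#' @param spec a [synthetic_spec()].
#' @param geometry an [experiment_geometry()].
#' @return list with `frames`, `backgrounds` (lists of
#'   [detector_frame()]s), `A` (the lab-frame reciprocal-cell matrix at
#'   spindle angle zero), `angles_deg`, `cell`, `geometry`, `spec`.
#' @export
render_frames <- function(truth, spec, geometry = synthetic_geometry()) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(spec$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  nx <- geometry$detector_shape[1]; ny <- geometry$detector_shape[2]
  px <- pixel_grid(geometry)
  q <- pixel_to_q(geometry, px)
  qmag <- sqrt(rowSums(q^2))
  cf <- correction_factors(geometry, px)
  modulation <- cf$polarization * cf$solid_angle
  iso_bg <- background_profile(qmag, spec$background_scale)
  # detector-fixed anisotropic background: an off-center broad blob
  blob <- spec$background_aniso_frac * spec$background_scale *
    exp(-(((px[, 1] - 0.72 * nx) / (0.18 * nx))^2 +
            ((px[, 2] - 0.35 * ny) / (0.30 * ny))^2))
  bg_rate <- (iso_bg + blob) * modulation
  # random mounting orientation for this dataset
  mount_axis <- stats::rnorm(3)
  mount <- rotation_matrix(mount_axis, stats::runif(1) *
                             spec$mount_rotation_deg)
  A <- mount %*% reciprocal_basis(truth$cell)
  angles <- (seq_len(spec$n_frames) - 1L) * spec$step_deg
  drift <- stats::rnorm(spec$n_frames, 0, spec$radial_drift_sd)
  frames <- vector("list", spec$n_frames)
  backgrounds <- vector("list", spec$n_frames)
  n_bad <- round(spec$bad_pixel_rate * nx * ny)
  for (i in seq_len(spec$n_frames)) {
    hkl <- q_to_hkl(A, angles[i], q, geometry$rotation_axis)
    diffuse <- trilinear(truth$values, truth$hmax, hkl,
                         truth$oversample) /
      mean(truth$values, na.rm = TRUE) * spec$diffuse_scale
    off <- abs(hkl - round(hkl))
    spike <- (off[, 1] < 0.08 & off[, 2] < 0.08 & off[, 3] < 0.08 &
                qmag > 0.02) * spec$bragg_rate
    # per-frame radial drift: a smooth |q|-dependent multiplicative ripple
    drift_mult <- 1 + drift[i] * sin(2 * pi * qmag / 0.35)
    rate_c <- pmax(0, (diffuse + spike) * drift_mult) * modulation + bg_rate
    if (spec$poisson_noise) {
      counts_c <- matrix(stats::rpois(nx * ny, rate_c * spec$exposure_s),
                         nx, ny)
      counts_b <- matrix(stats::rpois(nx * ny,
                                      bg_rate * spec$background_exposure_s),
                         nx, ny)
    } else {
      counts_c <- matrix(rate_c * spec$exposure_s, nx, ny)
      counts_b <- matrix(bg_rate * spec$background_exposure_s, nx, ny)
    }
    if (n_bad > 0) {
      bad <- sample.int(nx * ny, n_bad)
      counts_c[bad] <- ifelse(stats::runif(n_bad) < 0.5, 0L, 60000L)
    }
    frames[[i]] <- detector_frame(counts_c, spec$exposure_s, i, angles[i])
    backgrounds[[i]] <- detector_frame(counts_b,
                                       spec$background_exposure_s, i,
                                       angles[i])
  }
  list(frames = frames, backgrounds = backgrounds, A = A,
       angles_deg = angles, cell = truth$cell, geometry = geometry,
       spec = spec)
}

#' Write a rendered series to disk
#'
#' Frames go to TIFF (32-bit float, one file per frame) when the `tiff`
#' package is available, orientation and geometry to plain text/YAML, so
#' the synthetic fixtures double as format-conformance tests for the I/O
#' layer.
#'
#' @param series output of [render_frames()].
#' @param dir output directory (created if needed).
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(frame = seq_along(series$angles_deg),
               angle_deg = series$angles_deg),
    file.path(dir, "angles.txt"), row.names = FALSE, quote = FALSE)
  writeLines(apply(format(series$A, digits = 10), 1, paste, collapse = " "),
             file.path(dir, "A_matrix.txt"))
  if (requireNamespace("tiff", quietly = TRUE)) {
    for (i in seq_along(series$frames)) {
      tiff::writeTIFF(series$frames[[i]]$counts / 65535,
                      file.path(dir, sprintf("frame_%04d.tif", i)),
                      bits.per.sample = 32)
      tiff::writeTIFF(series$backgrounds[[i]]$counts / 65535,
                      file.path(dir, sprintf("background_%04d.tif", i)),
                      bits.per.sample = 32)
    }
  }
  invisible(dir)
}
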
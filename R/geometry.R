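# Detector geometry: pixel -> scattering vector -> fractional Miller index
# mapping, plus the per-pixel geometric correction factors.
#
# Conventions (documented once, used everywhere):
#  * the incident beam travels along +z; the detector is a flat panel
#    perpendicular to the beam at distance `distance_mm`;
#  * pixel indices are 0-based, fast axis = detector x (horizontal),
#    slow axis = detector y;
#  * the synchrotron polarization axis is x, the spindle rotation axis y
#    (both configurable);
#  * scattering vectors use the crystallographic convention |q| = 2 sin(theta)
#    / lambda = 1/d (inverse Angstrom, no 2*pi). Where the liquid-like-motions
#    formulas need the physics convention, q_rad = 2*pi*|q| is formed
#    explicitly at the point of use.

#' Experiment geometry
#'
#' Bundles the beam and detector parameters needed to map detector pixels to
#' scattering vectors and to evaluate the per-pixel geometric corrections.
#'
#' @param wavelength x-ray wavelength (Angstrom).
#' @param distance_mm crystal-to-detector distance z_d (mm).
#' @param pixel_mm pixel edge length (mm).
#' @param beam_center numeric(2), beam center in 0-based pixel units
#'   (fast x, slow y).
#' @param detector_shape integer(2), number of pixels along (fast, slow).
#' @param polarization_fraction fraction of horizontally (x-) polarized
#'   intensity, in [0, 1]; 0.5 is the unpolarized limit. Default 0.99,
#'   typical of a synchrotron bending-magnet/undulator beam.
#' @param sensor_thickness_mm silicon sensor thickness (mm).
#' @param sensor_attenuation_mm attenuation length of the sensor material at
#'   the experiment energy (mm).
#' @param rotation_axis numeric(3), spindle axis in the lab frame.
#' @param polarization_axis numeric(3), polarization axis in the lab frame.
#' @return object of class `experiment_geometry`.
#' @export
experiment_geometry <- function(wavelength, distance_mm, pixel_mm,
                                beam_center, detector_shape,
                                polarization_fraction = 0.99,
                                sensor_thickness_mm = 0.32,
                                sensor_attenuation_mm = 0.257,
                                rotation_axis = c(0, 1, 0),
                                polarization_axis = c(1, 0, 0)) {
  stopifnot(wavelength > 0, distance_mm > 0, pixel_mm > 0,
            length(beam_center) == 2, length(detector_shape) == 2,
            polarization_fraction >= 0, polarization_fraction <= 1,
            sensor_thickness_mm >= 0, sensor_attenuation_mm > 0)
  structure(list(
    wavelength = wavelength, distance_mm = distance_mm, pixel_mm = pixel_mm,
    beam_center = as.numeric(beam_center),
    detector_shape = as.integer(detector_shape),
    polarization_fraction = polarization_fraction,
    sensor_thickness_mm = sensor_thickness_mm,
    sensor_attenuation_mm = sensor_attenuation_mm,
    rotation_axis = rotation_axis / sqrt(sum(rotation_axis^2)),
    polarization_axis = polarization_axis / sqrt(sum(polarization_axis^2))
  ), class = "experiment_geometry")
}

#' @export
print.experiment_geometry <- function(x, ...) {
  cat("Experiment geometry\n")
  cat(sprintf("  wavelength     %.4f A\n", x$wavelength))
  cat(sprintf("  distance       %.2f mm, pixel %.4f mm\n",
              x$distance_mm, x$pixel_mm))
  cat(sprintf("  detector       %d x %d px, beam center (%.1f, %.1f)\n",
              x$detector_shape[1], x$detector_shape[2],
              x$beam_center[1], x$beam_center[2]))
  cat(sprintf("  polarization   fraction %.3f\n", x$polarization_fraction))
  cat(sprintf("  sensor         t = %.3f mm, attenuation length %.3f mm\n",
              x$sensor_thickness_mm, x$sensor_attenuation_mm))
  invisible(x)
}

# n x 2 matrix of 0-based pixel coordinates for every pixel of the detector,
# fast axis varying fastest (matches `as.vector` of an (nx, ny) matrix).
pixel_grid <- function(geometry) {
  nx <- geometry$detector_shape[1]; ny <- geometry$detector_shape[2]
  cbind(rep(seq_len(nx) - 1L, times = ny),
        rep(seq_len(ny) - 1L, each = nx))
}

# Lab-frame positions (mm) of pixel centers; n x 3.
pixel_positions_mm <- function(geometry, pixels) {
  cbind((pixels[, 1] - geometry$beam_center[1]) * geometry$pixel_mm,
        (pixels[, 2] - geometry$beam_center[2]) * geometry$pixel_mm,
        geometry$distance_mm)
}

#' Map detector pixels to scattering vectors
#'
#' Computes q = (s - s0)/lambda for each pixel, with s the unit vector from
#' the crystal to the pixel and s0 the unit incident-beam vector, so that
#' |q| = 2 sin(theta)/lambda = 1/d.
#'
#' @param geometry an [experiment_geometry()].
#' @param pixels n x 2 matrix of 0-based pixel coordinates (fast, slow);
#'   fractional values are allowed (parallax-shifted positions).
#' @return n x 3 matrix of scattering vectors (inverse Angstrom).
#' @export
pixel_to_q <- function(geometry, pixels) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2)
  bad <- pixels[, 1] < -0.5 | pixels[, 1] > geometry$detector_shape[1] - 0.5 |
         pixels[, 2] < -0.5 | pixels[, 2] > geometry$detector_shape[2] - 0.5
  if (any(bad)) stop("pixel coordinates outside detector bounds")
  pos <- pixel_positions_mm(geometry, pixels)
  r <- sqrt(rowSums(pos^2))
  s <- pos / r
  q <- s
  q[, 3] <- q[, 3] - 1
  q / geometry$wavelength
}

#' Convert scattering vectors to fractional Miller indices
#'
#' Inverts q = R(phi) A h, where A is the indexing matrix (columns a*, b*,
#' c* in the lab frame at spindle angle zero) and R(phi) the spindle
#' rotation for the frame.
#'
#' @param A 3x3 reciprocal-cell matrix in the lab frame (inverse Angstrom).
#' @param angle_deg spindle angle of the frame (degrees).
#' @param q n x 3 matrix of scattering vectors.
#' @param rotation_axis spindle axis (lab frame).
#' @return n x 3 matrix of fractional Miller indices.
#' @export
q_to_hkl <- function(A, angle_deg, q, rotation_axis = c(0, 1, 0)) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 3)
  if (abs(det(A)) < 1e-12) stop("singular A matrix")
  R <- rotation_matrix(rotation_axis, angle_deg)
  t(solve(R %*% A, t(q)))
}

#' Inverse of [q_to_hkl()]
#'
#' @inheritParams q_to_hkl
#' @param hkl n x 3 matrix of (fractional) Miller indices.
#' @return n x 3 matrix of scattering vectors.
#' @export
hkl_to_q <- function(A, angle_deg, hkl, rotation_axis = c(0, 1, 0)) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  R <- rotation_matrix(rotation_axis, angle_deg)
  t((R %*% A) %*% t(hkl))
}

#' Per-pixel geometric correction factors
#'
#' Returns the polarization, solid-angle and detector-absorption factors by
#' which raw pixel intensities are divided, plus the parallax-shifted pixel
#' positions at which the reciprocal-space mapping should be evaluated.
#'
#' Polarization: for polarized fraction f along the x axis,
#' P = f (1 - (s.x)^2) + (1 - f) (1 - (s.y)^2), which reduces to the
#' unpolarized Thomson form (1 + cos^2 2theta)/2 at f = 0.5 and equals 1 at
#' the beam center. Solid angle: cos^3(theta_pix) of the pixel incidence
#' angle from the detector normal (flat panel, equal pixel areas),
#' normalized to 1 at the beam center. Detector absorption: relative sensor
#' efficiency (1 - exp(-t/(l cos theta))) / (1 - exp(-t/l)), normalized to
#' normal incidence (>= 1 off-normal: the oblique path through the sensor is
#' longer, so more photons are captured). Parallax: detection occurs at a
#' mean depth t_eff inside the sensor, displacing the recorded position
#' radially outward by t_eff tan(theta_pix); the corrected (entry-point)
#' position subtracts this shift.
#'
#' @inheritParams pixel_to_q
#' @param polarization_floor pixels whose polarization factor falls below
#'   this floor are flagged unusable rather than divided (grazing
#'   extinction).
#' @return list with numeric vectors `polarization`, `solid_angle`,
#'   `absorption`, logical `usable`, and `shifted_pixels` (n x 2, 0-based
#'   fractional pixel coordinates after the parallax correction).
#' @export
correction_factors <- function(geometry, pixels,
                               polarization_floor = 1e-3) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2)
  pos <- pixel_positions_mm(geometry, pixels)
  r <- sqrt(rowSums(pos^2))
  s <- pos / r
  f <- geometry$polarization_fraction
  xhat <- geometry$polarization_axis
  # second transverse axis, beam (z) cross polarization axis
  zhat <- c(0, 0, 1)
  yhat <- c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
            zhat[3] * xhat[1] - zhat[1] * xhat[3],
            zhat[1] * xhat[2] - zhat[2] * xhat[1])
  pol <- f * (1 - (s %*% xhat)[, 1]^2) + (1 - f) * (1 - (s %*% yhat)[, 1]^2)
  cos_t <- geometry$distance_mm / r
  sa <- cos_t^3
  t <- geometry$sensor_thickness_mm; l <- geometry$sensor_attenuation_mm
  if (t > 0) {
    eff0 <- 1 - exp(-t / l)
    absn <- (1 - exp(-t / (l * cos_t))) / eff0
    t_eff <- l * (1 - (1 + t / l) * exp(-t / l)) / eff0
  } else {
    absn <- rep(1, length(r))
    t_eff <- 0
  }
  # in-plane radial unit vector (direction of beam penetration in the plane)
  rho <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  tan_t <- rho / geometry$distance_mm
  shift_mm <- t_eff * tan_t
  ux <- ifelse(rho > 0, pos[, 1] / rho, 0)
  uy <- ifelse(rho > 0, pos[, 2] / rho, 0)
  shifted <- cbind(pixels[, 1] - shift_mm * ux / geometry$pixel_mm,
                   pixels[, 2] - shift_mm * uy / geometry$pixel_mm)
  list(polarization = pol, solid_angle = sa, absorption = absn,
       usable = pol > polarization_floor,
       shifted_pixels = shifted)
}
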
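# The 3D reciprocal-space diffuse volume: merging of corrected frames onto
# an integer-Miller voxel grid, Friedel/Laue symmetrization, isotropic
# (radially averaged) component subtraction, completeness, and plain-text /
# CCP4-MRC export.

#' Diffuse volume
#'
#' A 3D grid over integer Miller indices H, K, L in [-hmax, hmax] holding
#' per-voxel mean intensities and observation counts. `values` is NA where
#' `count` is zero. The grid edge is 2*hmax + 1 (odd, so the origin voxel
#' exists).
#'
#' @param values numeric 3D array of per-voxel mean intensities.
#' @param count numeric 3D array of observation counts.
#' @param cell numeric(6) unit-cell parameters (a, b, c in Angstrom; alpha,
#'   beta, gamma in degrees).
#' @param laue Laue group label, `"-1"` or `"2/m"` (unique axis b).
#' @param oversample sampling factor per Miller index (1 for production
#'   metrics; >1 only for visualization).
#' @return object of class `diffuse_volume`.
#' @export
diffuse_volume <- function(values, count, cell, laue = "2/m",
                           oversample = 1L) {
  stopifnot(length(dim(values)) == 3, identical(dim(values), dim(count)),
            dim(values)[1] %% 2 == 1,
            dim(values)[1] == dim(values)[2], dim(values)[2] == dim(values)[3])
  values[count == 0] <- NA_real_
  structure(list(values = values, count = count, cell = as.numeric(cell),
                 laue = laue, hmax = (dim(values)[1] - 1L) %/% 2L,
                 oversample = as.integer(oversample)),
            class = "diffuse_volume")
}

#' @export
print.diffuse_volume <- function(x, ...) {
  n <- dim(x$values)[1]
  cat(sprintf("Diffuse volume: %d x %d x %d voxels (|H| <= %d, oversample %d)\n",
              n, n, n, x$hmax, x$oversample))
  cat(sprintf("  cell %.2f %.2f %.2f  %.1f %.1f %.1f, Laue %s\n",
              x$cell[1], x$cell[2], x$cell[3], x$cell[4], x$cell[5],
              x$cell[6], x$laue))
  cat(sprintf("  observed voxels: %d (%.1f%%)\n", sum(x$count > 0),
              100 * mean(x$count > 0)))
  invisible(x)
}

# Integer Miller indices of every voxel, n^3 x 3, in array order.
volume_hkl <- function(vol) {
  h <- seq(-vol$hmax, vol$hmax) / vol$oversample
  as.matrix(expand.grid(H = h, K = h, L = h))
}

#' |q| of every voxel of a diffuse volume
#'
#' Uses the reciprocal metric tensor of the unit cell (exact for any
#' crystal system, including monoclinic).
#'
#' @param vol a [diffuse_volume()].
#' @return 3D array of |q| (inverse Angstrom).
#' @export
volume_qmag <- function(vol) {
  n <- 2L * vol$hmax + 1L
  array(hkl_qmag(volume_hkl(vol), vol$cell), dim = c(n, n, n))
}

#' Merge preprocessed frames into a diffuse volume
#'
#' Every usable pixel whose fractional Miller indices fall outside the
#' Bragg rejection box (all three indices within `bragg_delta` of an
#' integer) contributes its intensity to the voxel at the rounded indices;
#' the voxel value is the mean of its contributions. Pixels mapping outside
#' the grid are dropped (counted in the `n_outside` attribute).
#'
#' @param frames list of preprocessed [detector_frame()]s.
#' @param hkl_fun function(frame) returning the n_pixel x 3 matrix of
#'   fractional Miller indices for that frame (encapsulates orientation and
#'   geometry).
#' @param hmax grid half-width in Miller indices.
#' @param cell unit-cell parameters.
#' @param laue Laue group label.
#' @param bragg_delta Bragg rejection half-width (default 0.25; offsets
#'   equal to the boundary are rejected).
#' @return a [diffuse_volume()].
#' @export
merge_frames <- function(frames, hkl_fun, hmax, cell, laue = "2/m",
                         bragg_delta = 0.25) {
  n <- 2L * hmax + 1L
  sums <- numeric(n^3)
  cnts <- numeric(n^3)
  outside <- 0L
  for (fr in frames) {
    hkl <- hkl_fun(fr)
    use <- as.vector(fr$mask) & !flag_bragg_pixels(hkl, bragg_delta)
    hkl <- round(hkl[use, , drop = FALSE])
    vals <- as.vector(fr$counts)[use]
    inside <- abs(hkl[, 1]) <= hmax & abs(hkl[, 2]) <= hmax &
      abs(hkl[, 3]) <= hmax
    outside <- outside + sum(!inside)
    hkl <- hkl[inside, , drop = FALSE]
    vals <- vals[inside]
    if (!length(vals)) next
    idx <- (hkl[, 1] + hmax + 1) +
      (hkl[, 2] + hmax) * n + (hkl[, 3] + hmax) * n^2
    rs <- rowsum(cbind(vals, 1), idx)
    ii <- as.integer(rownames(rs))
    sums[ii] <- sums[ii] + rs[, 1]
    cnts[ii] <- cnts[ii] + rs[, 2]
  }
  vals <- ifelse(cnts > 0, sums / cnts, NA_real_)
  out <- diffuse_volume(array(vals, c(n, n, n)), array(cnts, c(n, n, n)),
                        cell, laue)
  attr(out, "n_outside") <- outside
  out
}

# Index-map transforms of a centered cubic array for the supported Laue
# operations; each is an involution on the grid.
flip_all <- function(a) a[rev(seq_len(dim(a)[1])), rev(seq_len(dim(a)[2])),
                          rev(seq_len(dim(a)[3])), drop = FALSE]
flip_hl <- function(a) a[rev(seq_len(dim(a)[1])), , rev(seq_len(dim(a)[3])),
                         drop = FALSE]

laue_operations <- function(laue, mode = c("laue", "friedel")) {
  mode <- match.arg(mode)
  if (mode == "friedel") return(list(identity, flip_all))
  if (laue == "-1") return(list(identity, flip_all))
  if (laue == "2/m")
    return(list(identity, flip_hl, flip_all,
                function(a) flip_hl(flip_all(a))))
  stop("unsupported Laue group: ", laue)
}

#' Symmetrize a diffuse volume
#'
#' Replaces every voxel by the count-weighted mean over its symmetry orbit:
#' the Friedel pair {(h,k,l), (-h,-k,-l)} or the 2/m (unique axis b) orbit
#' {(h,k,l), (-h,k,-l), (-h,-k,-l), (h,-k,l)}. Unobserved orbit members are
#' ignored; output counts are the orbit count sums, so symmetrization is
#' idempotent on the voxel values.
#'
#' @param vol a [diffuse_volume()].
#' @param mode `"laue"` (default; uses `vol$laue`) or `"friedel"`.
#' @return the symmetrized [diffuse_volume()].
#' @export
symmetrize <- function(vol, mode = c("laue", "friedel")) {
  mode <- match.arg(mode)
  ops <- laue_operations(vol$laue, mode)
  S <- vol$values * vol$count
  S[is.na(S)] <- 0
  sums <- 0; cnts <- 0
  for (op in ops) {
    sums <- sums + op(S)
    cnts <- cnts + op(vol$count)
  }
  vals <- ifelse(cnts > 0, sums / cnts, NA_real_)
  diffuse_volume(vals, cnts, vol$cell, vol$laue, vol$oversample)
}

#' Resolution shell scheme
#'
#' Equal-volume shells in |q|^3 from `d_max` down to `d_min`.
#'
#' @param d_min high-resolution cutoff (Angstrom, default 1.4).
#' @param n_shells number of shells (default 15).
#' @param d_max low-resolution limit (Angstrom; Inf starts at q = 0).
#' @return numeric vector of shell boundaries in |q| (increasing).
#' @export
shell_scheme <- function(d_min = 1.4, n_shells = 15, d_max = Inf) {
  q0 <- if (is.finite(d_max)) 1 / d_max else 0
  (seq(q0^3, (1 / d_min)^3, length.out = n_shells + 1))^(1 / 3)
}

#' Subtract the isotropic (radially averaged) component
#'
#' Estimates the count-weighted radial average on fine |q| shells,
#' interpolates it linearly to every voxel's |q|, subtracts it, and then
#' removes the residual per-shell weighted means exactly, so that every
#' shell's observation-weighted mean is zero to machine precision.
#'
#' @param vol a [diffuse_volume()].
#' @param n_shells number of averaging shells spanning the observed |q|
#'   range (default 100).
#' @return the anisotropic [diffuse_volume()].
#' @export
subtract_isotropic <- function(vol, n_shells = 100) {
  q <- as.vector(volume_qmag(vol))
  v <- as.vector(vol$values)
  w <- as.vector(vol$count)
  obs <- w > 0
  qmaxo <- max(q[obs])
  br <- seq(0, qmaxo * (1 + 1e-9), length.out = n_shells + 1)
  bin <- findInterval(q[obs], br, rightmost.closed = TRUE)
  sw <- rowsum(w[obs], bin)
  swv <- rowsum((w * v)[obs], bin)
  swq <- rowsum((w * q)[obs], bin)
  centers <- swq[, 1] / sw[, 1]
  means <- swv[, 1] / sw[, 1]
  # interpolate the radial average at each observed voxel's |q|
  if (length(centers) >= 2) {
    rad <- stats::approx(centers, means, xout = q[obs], rule = 2)$y
  } else {
    rad <- rep(means[1], sum(obs))
  }
  v[obs] <- v[obs] - rad
  # exact centering pass: kill the residual weighted mean of every shell
  res <- rowsum((w * v)[obs], bin)[, 1] / sw[, 1]
  v[obs] <- v[obs] - res[match(bin, as.integer(rownames(sw)))]
  n <- 2L * vol$hmax + 1L
  diffuse_volume(array(v, c(n, n, n)), vol$count, vol$cell, vol$laue,
                 vol$oversample)
}

#' Completeness of a diffuse volume
#'
#' Fraction of symmetry-unique voxels (under the volume's Laue group) with
#' at least one observation, per resolution shell and overall, within the
#' resolution cutoff implied by the shell boundaries.
#'
#' @param vol a [diffuse_volume()].
#' @param shells shell boundaries in |q| from [shell_scheme()].
#' @return data.frame with one row per shell plus an `"overall"` row:
#'   d-spacing range, unique voxel count and completeness fraction.
#' @export
completeness <- function(vol, shells = shell_scheme()) {
  # a unique voxel is observed if any of its orbit members is
  csym <- 0
  for (op in laue_operations(vol$laue, "laue")) csym <- csym + op(vol$count)
  q <- as.vector(volume_qmag(vol))
  obs <- as.vector(csym) > 0
  # unique-orbit representatives: lexicographically smallest index tuple
  n <- 2L * vol$hmax + 1L
  idx <- array(seq_len(n^3), c(n, n, n))
  rep_idx <- idx
  for (op in laue_operations(vol$laue, "laue")) rep_idx <- pmin(rep_idx, op(idx))
  is_rep <- as.vector(rep_idx) == seq_len(n^3)
  rows <- lapply(seq_len(length(shells) - 1L), function(i) {
    sel <- is_rep & q > shells[i] & q <= shells[i + 1]
    data.frame(q_lo = shells[i], q_hi = shells[i + 1],
               d_hi = ifelse(shells[i] > 0, 1 / shells[i], Inf),
               d_lo = 1 / shells[i + 1],
               n_unique = sum(sel),
               completeness = if (any(sel)) mean(obs[sel]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  sel <- is_rep & q > shells[1] & q <= shells[length(shells)]
  rbind(out, data.frame(q_lo = shells[1], q_hi = shells[length(shells)],
                        d_hi = ifelse(shells[1] > 0, 1 / shells[1], Inf),
                        d_lo = 1 / shells[length(shells)],
                        n_unique = sum(sel),
                        completeness = mean(obs[sel])))
}

#' Crop a diffuse volume to a smaller grid half-width
#'
#' @param vol a [diffuse_volume()].
#' @param hmax target half-width (<= `vol$hmax`).
#' @return the cropped [diffuse_volume()].
#' @export
crop_volume <- function(vol, hmax) {
  stopifnot(hmax <= vol$hmax)
  s <- (vol$hmax - hmax + 1):(vol$hmax + hmax + 1)
  diffuse_volume(vol$values[s, s, s], vol$count[s, s, s], vol$cell,
                 vol$laue, vol$oversample)
}

#' Write a diffuse volume as a plain HKL table
#'
#' Tab-separated columns H, K, L, mean intensity, observation count; one
#' row per observed voxel.
#'
#' @param vol a [diffuse_volume()].
#' @param path output file path.
#' @export
write_hkl_table <- function(vol, path) {
  hkl <- volume_hkl(vol)
  obs <- as.vector(vol$count) > 0
  tab <- data.frame(H = hkl[obs, 1], K = hkl[obs, 2], L = hkl[obs, 3],
                    intensity = as.vector(vol$values)[obs],
                    count = as.vector(vol$count)[obs])
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a diffuse volume from an HKL table
#'
#' @param path file written by [write_hkl_table()].
#' @param cell,laue volume metadata (not stored in the table).
#' @param hmax grid half-width; defaults to the largest index present.
#' @return a [diffuse_volume()].
#' @export
read_hkl_table <- function(path, cell, laue = "2/m", hmax = NULL) {
  tab <- utils::read.table(path, header = TRUE)
  if (is.null(hmax)) hmax <- max(abs(as.matrix(tab[, 1:3])))
  n <- 2L * as.integer(hmax) + 1L
  vals <- array(NA_real_, c(n, n, n))
  cnts <- array(0, c(n, n, n))
  ii <- cbind(tab$H + hmax + 1, tab$K + hmax + 1, tab$L + hmax + 1)
  vals[ii] <- tab$intensity
  cnts[ii] <- tab$count
  diffuse_volume(vals, cnts, cell, laue)
}

#' Write a diffuse volume as a CCP4/MRC map
#'
#' Minimal mode-2 (32-bit float) MRC writer for interoperability with
#' crystallographic visualization tools; unobserved voxels are written as
#' zero. The grid is written in Miller-index order with the cell scaled so
#' one voxel corresponds to one index step.
#'
#' @param vol a [diffuse_volume()].
#' @param path output file path.
#' @export
write_mrc <- function(vol, path) {
  n <- 2L * vol$hmax + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- vol$values
  v[is.na(v)] <- 0
  wi(c(n, n, n))           # NX NY NZ
  wi(2)                    # MODE 2: float32
  wi(c(-vol$hmax, -vol$hmax, -vol$hmax))  # NXSTART...
  wi(c(n, n, n))           # MX MY MZ
  wf(vol$cell[1:3] * n / (2 * vol$hmax + 1))  # cell lengths
  wf(vol$cell[4:6])        # cell angles
  wi(c(1, 2, 3))           # axis order
  wf(c(min(v), max(v), mean(v)))
  wi(0)                    # ISPG
  wi(0)                    # NSYMBT
  wi(rep(0, 25))           # extra
  wf(c(0, 0, 0))           # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(v)))
  wi(0)                    # NLABL
  writeBin(raw(800), con)  # labels
  wf(as.vector(v))
  invisible(path)
}
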
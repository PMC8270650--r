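# Per-frame intensity scaling and residual isotropic variation removal.
#
# Four alternative per-frame scale factors are supported: the radial-profile
# least-squares factor against a fixed reference frame (the series default),
# the water-ring and overall mean-intensity ratios, and externally computed
# Bragg scale factors imported from a two-column table. After scaling, the
# remaining frame-to-frame variation of the radial intensity profiles is
# removed by principal-component analysis of the frames x bins profile
# matrix (top components subtracted per frame).

#' Radial intensity profile of a frame
#'
#' Mean usable-pixel intensity in bins of the scattering-vector length |q|.
#'
#' @param frame a [detector_frame()].
#' @param qmag numeric matrix (same shape as the frame) of per-pixel |q|
#'   (inverse Angstrom).
#' @param breaks bin boundaries in |q|; see [radial_breaks()].
#' @return object of class `radial_profile`: list with `centers` (bin
#'   midpoints), `mean` (NA where a bin holds no usable pixel) and `count`.
#' @export
radial_profile <- function(frame, qmag, breaks) {
  sel <- frame$mask & qmag >= breaks[1] & qmag <= breaks[length(breaks)]
  bin <- findInterval(qmag[sel], breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  cnt <- tabulate(bin, nb)
  s <- rep(0, nb)
  if (any(sel)) {
    rs <- rowsum(frame$counts[sel], bin)
    s[as.integer(rownames(rs))] <- rs[, 1]
  }
  structure(list(centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 mean = ifelse(cnt > 0, s / cnt, NA_real_),
                 count = cnt),
            class = "radial_profile")
}

#' Uniform |q| bin boundaries up to a resolution cutoff
#'
#' @param d_min resolution cutoff in Angstrom (default 1.4).
#' @param n_bins number of bins (default 200).
#' @return numeric vector of length `n_bins + 1`.
#' @export
radial_breaks <- function(d_min = 1.4, n_bins = 200) {
  seq(0, 1 / d_min, length.out = n_bins + 1)
}

#' Per-frame scale factor
#'
#' Computes the multiplicative factor `s` applied to a frame so that it
#' matches the fixed reference frame of the series (the first frame by
#' convention). Methods: `radial_profile` minimizes the L2 distance between
#' the two radial profiles, giving the closed form
#' s = <p_frame, p_ref> / <p_frame, p_frame>; `water_ring` and `overall`
#' take the ratio of mean usable-pixel intensities over the water-ring
#' region (5-1.82 Angstrom by default) or the full resolution range;
#' `bragg` looks the factor up in an imported table of externally computed
#' Bragg scale factors.
#'
#' @param frame a [detector_frame()].
#' @param reference the reference [detector_frame()] (ignored for `bragg`).
#' @param qmag per-pixel |q| matrix shared by both frames.
#' @param method one of `"radial_profile"`, `"water_ring"`, `"overall"`,
#'   `"bragg"`.
#' @param d_min resolution cutoff in Angstrom (default 1.4).
#' @param water_ring_d water-ring d-spacing range, Angstrom (default
#'   c(5, 1.82)).
#' @param n_bins radial-profile bin count (default 200).
#' @param bragg_factors data.frame with columns `frame_index`, `factor`, as
#'   read by [read_bragg_scale_factors()] (required for `method = "bragg"`).
#' @return positive scalar.
#' @export
scale_factor <- function(frame, reference, qmag,
                         method = c("radial_profile", "water_ring",
                                    "overall", "bragg"),
                         d_min = 1.4, water_ring_d = c(5, 1.82),
                         n_bins = 200, bragg_factors = NULL) {
  method <- match.arg(method)
  if (method == "bragg") {
    if (is.null(bragg_factors)) stop("method 'bragg' needs an imported factor table")
    s <- bragg_factors$factor[match(frame$frame_index,
                                    bragg_factors$frame_index)]
    if (is.na(s)) stop("no Bragg scale factor for frame ", frame$frame_index)
    return(s)
  }
  if (method == "radial_profile") {
    br <- radial_breaks(d_min, n_bins)
    pf <- radial_profile(frame, qmag, br)$mean
    pr <- radial_profile(reference, qmag, br)$mean
    ok <- !is.na(pf) & !is.na(pr)
    den <- sum(pf[ok]^2)
    if (den <= 0) stop("degenerate frame profile; cannot scale")
    return(sum(pf[ok] * pr[ok]) / den)
  }
  rng <- if (method == "water_ring") sort(1 / water_ring_d) else c(0, 1 / d_min)
  sel_f <- frame$mask & qmag >= rng[1] & qmag <= rng[2]
  sel_r <- reference$mask & qmag >= rng[1] & qmag <= rng[2]
  mf <- mean(frame$counts[sel_f]); mr <- mean(reference$counts[sel_r])
  if (!is.finite(mf) || mf <= 0) stop("non-positive frame mean; cannot scale")
  mr / mf
}

#' Read externally computed Bragg scale factors
#'
#' Plain-text table with two whitespace-separated columns: frame index and
#' scale factor.
#'
#' @param path file path.
#' @return data.frame with columns `frame_index`, `factor`.
#' @export
read_bragg_scale_factors <- function(path) {
  tab <- utils::read.table(path, col.names = c("frame_index", "factor"))
  stopifnot(all(tab$factor > 0))
  tab
}

#' Remove residual radial variance across frames
#'
#' Builds the frames x bins matrix of (already scaled) radial profiles,
#' mean-centers it across frames, and removes each frame's projection onto
#' the leading principal components. The returned correction curves (one
#' per frame, on the profile bin centers) are subtracted from every pixel
#' of the corresponding frame by interpolation in |q|; the frame-average
#' (mean) profile is untouched, since the isotropic component is removed
#' later in reciprocal space.
#'
#' @param profiles numeric matrix, frames x bins, of scaled radial profiles
#'   (NA bins allowed; they are ignored and get zero correction).
#' @param n_components number of leading components to remove (default 3;
#'   0 returns zero corrections).
#' @return matrix of the same shape: the per-frame radial corrections.
#' @export
radial_variance_correction <- function(profiles, n_components = 3) {
  stopifnot(is.matrix(profiles))
  if (n_components == 0) return(profiles * 0)
  if (nrow(profiles) < n_components + 1)
    stop("need more frames than components to estimate the subspace")
  ok_bin <- colSums(is.na(profiles)) == 0
  M <- profiles[, ok_bin, drop = FALSE]
  mu <- colMeans(M)
  X <- sweep(M, 2, mu)
  sv <- svd(X, nu = min(n_components, nrow(X)), nv = min(n_components, ncol(X)))
  k <- min(n_components, length(sv$d))
  recon <- sv$u[, seq_len(k), drop = FALSE] %*%
    (sv$d[seq_len(k)] * t(sv$v[, seq_len(k), drop = FALSE]))
  out <- profiles * 0
  out[is.na(out)] <- 0
  out[, ok_bin] <- recon
  out
}

#' Apply a radial correction curve to a frame
#'
#' Subtracts, from every usable pixel, the correction value interpolated
#' linearly between profile bin centers at the pixel's |q| (constant
#' extrapolation beyond the outermost centers).
#'
#' @param frame a [detector_frame()].
#' @param qmag per-pixel |q| matrix.
#' @param centers profile bin centers.
#' @param correction correction values on the bin centers.
#' @return the corrected frame.
#' @export
apply_radial_correction <- function(frame, qmag, centers, correction) {
  v <- stats::approx(centers, correction, xout = qmag[frame$mask],
                     rule = 2)$y
  frame$counts[frame$mask] <- frame$counts[frame$mask] - v
  frame
}
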
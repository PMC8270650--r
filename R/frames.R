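# Per-frame image cleaning: static masking, windowed outlier rejection,
# exposure-scaled background subtraction, Bragg-pixel flagging and median
# replacement. A frame's mask is TRUE where the pixel is usable; every
# cleaning step only shrinks the usable set (median replacement preserves
# it). Masked pixels are excluded from every downstream statistic.

#' Detector frame
#'
#' One exposure's photon-count grid with its usability mask and metadata.
#' The count matrix is indexed `[fast + 1, slow + 1]` for 0-based pixel
#' coordinates (fast, slow).
#'
#' @param counts numeric matrix of photon counts (fast axis = rows).
#' @param exposure_s exposure time in seconds.
#' @param frame_index integer frame number within the series (1-based).
#' @param spindle_angle_deg spindle angle of this frame (degrees).
#' @param mask logical matrix, TRUE = usable; defaults to all usable.
#' @return object of class `detector_frame`.
#' @export
detector_frame <- function(counts, exposure_s, frame_index = 1L,
                           spindle_angle_deg = 0, mask = NULL) {
  stopifnot(is.matrix(counts), exposure_s > 0)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(counts), ncol(counts))
  stopifnot(identical(dim(mask), dim(counts)))
  structure(list(counts = counts, mask = mask, exposure_s = exposure_s,
                 frame_index = as.integer(frame_index),
                 spindle_angle_deg = spindle_angle_deg),
            class = "detector_frame")
}

#' @export
print.detector_frame <- function(x, ...) {
  cat(sprintf("Detector frame %d: %d x %d px, %.3g s, phi = %.2f deg, %.1f%% usable\n",
              x$frame_index, nrow(x$counts), ncol(x$counts), x$exposure_s,
              x$spindle_angle_deg, 100 * mean(x$mask)))
  invisible(x)
}

#' Static pixel mask
#'
#' Masks user-defined detector regions (panel gaps, beamstop, shadows) plus
#' pixels whose raw counts are non-positive or exceed the saturation
#' threshold.
#'
#' @param frame a [detector_frame()].
#' @param saturation saturation threshold in photons (default 10000).
#' @param user_mask optional logical matrix of additional usable pixels
#'   (FALSE = reject).
#' @return the frame with its mask shrunk.
#' @export
static_mask <- function(frame, saturation = 10000, user_mask = NULL) {
  m <- frame$mask & frame$counts > 0 & frame$counts <= saturation
  if (!is.null(user_mask)) m <- m & user_mask
  if (!any(m)) stop("static mask rejected every pixel")
  frame$mask <- m
  frame
}

#' Windowed outlier mask
#'
#' Masks pixels that deviate from their local neighborhood by more than
#' `nsigma` standard deviations, with local statistics computed over the
#' currently unmasked pixels of a square window centered on the pixel
#' (window truncated at frame borders; the center pixel is included in its
#' own window). Windows with zero standard deviation mask nothing; windows
#' with fewer than two usable pixels leave the pixel unmasked.
#'
#' @param frame a [detector_frame()].
#' @param window odd window edge length (default 11).
#' @param nsigma rejection threshold in standard deviations (default 5).
#' @return the frame with its mask shrunk.
#' @export
windowed_outlier_mask <- function(frame, window = 11, nsigma = 5) {
  stopifnot(window >= 3, window %% 2 == 1)
  w <- (window - 1L) %/% 2L
  M <- frame$mask
  I <- frame$counts
  Iu <- ifelse(M, I, 0)
  n <- box_sum(M * 1, w)
  s1 <- box_sum(Iu, w)
  s2 <- box_sum(Iu^2, w)
  mu <- ifelse(n > 0, s1 / n, 0)
  varw <- pmax(0, (s2 - n * mu^2) / pmax(n - 1, 1))
  sdw <- sqrt(varw)
  out <- M & n >= 2 & sdw > 0 & abs(I - mu) > nsigma * sdw
  frame$mask <- M & !out
  frame
}

#' Exposure-scaled background subtraction
#'
#' Subtracts the paired non-crystal background frame, scaled by the ratio of
#' exposure times; the masks of the two frames are combined (union of
#' rejections). Negative differences are retained (the merge stage averages
#' them without bias).
#'
#' @param frame crystal [detector_frame()].
#' @param background paired background [detector_frame()] of the same shape.
#' @return the background-subtracted crystal frame.
#' @export
subtract_background <- function(frame, background) {
  if (is.null(background)) stop("background subtraction enabled but no paired background frame")
  stopifnot(identical(dim(frame$counts), dim(background$counts)))
  ratio <- frame$exposure_s / background$exposure_s
  frame$counts <- frame$counts - ratio * background$counts
  frame$mask <- frame$mask & background$mask
  frame
}

#' Flag pixels inside the Bragg rejection box
#'
#' A pixel belongs to a Bragg peak when each of its fractional Miller
#' indices lies within `delta` of the nearest integer (a 2*delta box around
#' every reciprocal-lattice point; the boundary is flagged).
#'
#' @param fractional_hkl n x 3 matrix of fractional Miller indices.
#' @param delta half-width of the rejection box (default 0.25).
#' @return logical vector of length n.
#' @export
flag_bragg_pixels <- function(fractional_hkl, delta = 0.25) {
  off <- abs(fractional_hkl - round(fractional_hkl))
  off[, 1] <= delta & off[, 2] <= delta & off[, 3] <= delta
}

#' Replace flagged Bragg pixels with the local median
#'
#' Each flagged pixel's intensity is replaced by the median of the
#' unflagged, usable pixels inside a square window centered on it; if the
#' window holds no usable unflagged pixel, the pixel is masked instead.
#'
#' @param frame a [detector_frame()].
#' @param bragg_flags logical matrix of Bragg flags, same shape as the
#'   frame.
#' @param window odd window edge length (default 11).
#' @return the frame with flagged intensities replaced (mask preserved
#'   except where no replacement value exists).
#' @export
replace_bragg_with_median <- function(frame, bragg_flags, window = 11) {
  stopifnot(window %% 2 == 1, identical(dim(bragg_flags), dim(frame$counts)))
  w <- (window - 1L) %/% 2L
  n1 <- nrow(frame$counts); n2 <- ncol(frame$counts)
  ok <- frame$mask & !bragg_flags
  idx <- which(bragg_flags & frame$mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(frame)
  vals <- numeric(nrow(idx))
  drop <- logical(nrow(idx))
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1]; j <- idx[p, 2]
    ri <- max(1, i - w):min(n1, i + w)
    rj <- max(1, j - w):min(n2, j + w)
    sel <- ok[ri, rj]
    if (any(sel)) vals[p] <- stats::median(frame$counts[ri, rj][sel])
    else drop[p] <- TRUE
  }
  frame$counts[idx[!drop, , drop = FALSE]] <- vals[!drop]
  if (any(drop)) frame$mask[idx[drop, , drop = FALSE]] <- FALSE
  frame
}
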
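# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle_deg` degrees about the (normalized) `axis`.
#' Used for the spindle rotation applied to the indexing A matrix.
#'
#' @param axis numeric(3) rotation axis (need not be unit length).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Reciprocal-basis matrix of a unit cell
#'
#' Columns are the reciprocal basis vectors a*, b*, c* in a Cartesian frame
#' (x along a, z along c*), in inverse Angstrom without the 2*pi factor, so
#' that q = B %*% h has |q| = 1/d.
#'
#' @param cell numeric(6): a, b, c (Angstrom), alpha, beta, gamma (degrees).
#' @return 3x3 matrix.
#' @export
reciprocal_basis <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  ca <- cos(al); cb <- cos(be); cg <- cos(ga); sg <- sin(ga)
  # direct-basis orthogonalization (PDB convention), columns a, b, c
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  M <- matrix(c(
    a, 0, 0,
    b * cg, b * sg, 0,
    c * cb, c * (ca - cb * cg) / sg, c * v / sg
  ), 3, 3)
  t(solve(M))
}

#' Orthogonalization matrix of a unit cell
#'
#' Columns are the direct basis vectors in Cartesian coordinates (Angstrom);
#' x_cart = orthogonalization_matrix(cell) %*% x_frac.
#'
#' @inheritParams reciprocal_basis
#' @return 3x3 matrix.
#' @export
orthogonalization_matrix <- function(cell) {
  solve(t(reciprocal_basis(cell)))
}

# |q| (1/d, inverse Angstrom) for an n x 3 matrix of (possibly fractional)
# Miller indices under a given cell.
hkl_qmag <- function(hkl, cell) {
  B <- reciprocal_basis(cell)
  G <- crossprod(B)             # reciprocal metric tensor
  sqrt(rowSums((hkl %*% G) * hkl))
}

# Truncated-window box sum of a matrix: S[i,j] = sum of M over the
# intersection of the (2w+1)x(2w+1) window with the matrix. O(n) via cumsum.
box_sum <- function(M, w) {
  n1 <- nrow(M); n2 <- ncol(M)
  C <- apply(M, 2, cumsum)
  C <- rbind(0, C)
  hi <- pmin(seq_len(n1) + w, n1) + 1L
  lo <- pmax(seq_len(n1) - w - 1L, 0L) + 1L
  S <- C[hi, , drop = FALSE] - C[lo, , drop = FALSE]
  C2 <- t(apply(S, 1, cumsum))
  C2 <- cbind(0, C2)
  hj <- pmin(seq_len(n2) + w, n2) + 1L
  lj <- pmax(seq_len(n2) - w - 1L, 0L) + 1L
  C2[, hj, drop = FALSE] - C2[, lj, drop = FALSE]
}

# fftshift-style index vector that moves the centered origin of an
# odd-length axis (index (n+1)/2) to position 1, for kernel arrays.
ifftshift_index <- function(n) {
  ctr <- if (n %% 2L == 1L) (n + 1L) %/% 2L else n %/% 2L + 1L
  c(ctr:n, seq_len(ctr - 1L))
}

# Circular convolution of two equally-sized 3D arrays via FFT.
convolve3d <- function(x, kernel_centered) {
  d <- dim(x)
  k <- kernel_centered[ifftshift_index(d[1]),
                       ifftshift_index(d[2]),
                       ifftshift_index(d[3])]
  Re(stats::fft(stats::fft(x) * stats::fft(k), inverse = TRUE)) / prod(d)
}
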
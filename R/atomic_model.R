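# Atomic models: a data.frame of atoms (element, fractional coordinates,
# occupancy, altloc, isotropic B, Cartesian anisotropic U) plus cell and
# space group. PDB ATOM/HETATM parsing is delegated to bio3d; ANISOU
# records (which bio3d does not expose) are read by a supplemental
# fixed-column scan. U tensors are stored in the Cartesian convention of
# PDB ANISOU records (Angstrom^2), with B = 8 pi^2 U.

U_COLS <- c("u11", "u22", "u33", "u12", "u13", "u23")

#' Atomic model
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`
#'   (fractional coordinates), `occupancy`, `altloc`, `b` (isotropic B,
#'   Angstrom^2) and optionally `u11`, `u22`, `u33`, `u12`, `u13`, `u23`
#'   (Cartesian anisotropic U, Angstrom^2).
#' @param cell numeric(6) unit-cell parameters.
#' @param spacegroup space-group symbol (`"P1"` and `"P21"` supported for
#'   symmetry expansion).
#' @return object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, cell, spacegroup = "P1") {
  stopifnot(all(c("element", "x", "y", "z", "occupancy", "altloc", "b")
                %in% names(atoms)),
            all(atoms$occupancy >= 0 & atoms$occupancy <= 1))
  structure(list(atoms = atoms, cell = as.numeric(cell),
                 spacegroup = spacegroup),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("Atomic model: %d atoms, %s, cell %.2f %.2f %.2f  %.1f %.1f %.1f\n",
              nrow(x$atoms), x$spacegroup, x$cell[1], x$cell[2], x$cell[3],
              x$cell[4], x$cell[5], x$cell[6]))
  cat(sprintf("  anisotropic U present: %s\n", has_anisou(x)))
  invisible(x)
}

has_anisou <- function(model) all(U_COLS %in% names(model$atoms)) &&
  !all(is.na(model$atoms$u11))

# Fractional rotation+translation operators of the supported space groups.
spacegroup_symops <- function(symbol) {
  sym <- toupper(gsub("[ _()]", "", symbol))
  if (sym %in% c("P1")) {
    list(list(R = diag(3), t = c(0, 0, 0)))
  } else if (sym %in% c("P21", "P1211", "P21(B)")) {
    # 2-fold screw along b: (-x, y + 1/2, -z)
    list(list(R = diag(3), t = c(0, 0, 0)),
         list(R = diag(c(-1, 1, -1)), t = c(0, 0.5, 0)))
  } else {
    stop("unsupported space group: ", symbol)
  }
}

#' Read an atomic model from a PDB file
#'
#' ATOM/HETATM records are parsed with bio3d; ANISOU records are collected
#' by a fixed-column scan and attached as Cartesian U (Angstrom^2, the
#' stored integers divided by 1e4). Coordinates are converted to fractional
#' using the CRYST1 cell.
#'
#' @param path PDB file path.
#' @return an [atomic_model()].
#' @export
read_pdb_model <- function(path) {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE)
  at <- pdb$atom
  lines <- readLines(path)
  cr <- lines[startsWith(lines, "CRYST1")][1]
  if (is.na(cr)) stop("PDB file has no CRYST1 record")
  cell <- as.numeric(c(substr(cr, 7, 15), substr(cr, 16, 24),
                       substr(cr, 25, 33), substr(cr, 34, 40),
                       substr(cr, 41, 47), substr(cr, 48, 54)))
  sg <- trimws(substr(cr, 56, 66))
  Minv <- solve(orthogonalization_matrix(cell))
  frac <- t(Minv %*% rbind(at$x, at$y, at$z))
  atoms <- data.frame(
    element = trimws(at$elesy),
    x = frac[, 1], y = frac[, 2], z = frac[, 3],
    occupancy = at$o, altloc = ifelse(is.na(at$alt), "", at$alt),
    b = at$b, serial = at$eleno,
    u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
    u12 = NA_real_, u13 = NA_real_, u23 = NA_real_
  )
  an <- lines[startsWith(lines, "ANISOU")]
  if (length(an)) {
    serial <- as.integer(substr(an, 7, 11))
    u <- vapply(c(29, 36, 43, 50, 57, 64), function(p)
      as.numeric(substr(an, p, p + 6)) / 1e4, numeric(length(an)))
    if (is.null(dim(u))) u <- matrix(u, nrow = 1)
    i <- match(serial, atoms$serial)
    ok <- !is.na(i)
    atoms[i[ok], U_COLS] <- u[ok, , drop = FALSE]
  }
  atoms$serial <- NULL
  atomic_model(atoms, cell, sg)
}

#' Write an atomic model as a PDB file
#'
#' Emits CRYST1, ATOM and (where anisotropic U is present) ANISOU records.
#'
#' @param model an [atomic_model()].
#' @param path output path.
#' @export
write_pdb_model <- function(model, path) {
  M <- orthogonalization_matrix(model$cell)
  at <- model$atoms
  xyz <- t(M %*% t(as.matrix(at[, c("x", "y", "z")])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                     model$cell[1], model$cell[2], model$cell[3],
                     model$cell[4], model$cell[5], model$cell[6],
                     model$spacegroup), con)
  for (i in seq_len(nrow(at))) {
    el <- at$element[i]
    name <- sprintf(" %-3s", el)
    writeLines(sprintf(
      "ATOM  %5d %4s%1sALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, name, substr(paste0(at$altloc[i], " "), 1, 1), i,
      xyz[i, 1], xyz[i, 2], xyz[i, 3], at$occupancy[i], at$b[i],
      toupper(el)), con)
    if (has_anisou(model) && !is.na(at$u11[i])) {
      u <- round(as.numeric(at[i, U_COLS]) * 1e4)
      writeLines(sprintf(
        "ANISOU%5d %4s%1sALA A%4d  %7d%7d%7d%7d%7d%7d      %2s",
        i, name, substr(paste0(at$altloc[i], " "), 1, 1), i,
        u[1], u[2], u[3], u[4], u[5], u[6], toupper(el)), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Select the A conformer and reset occupancies
#'
#' Keeps atoms whose altloc is blank or `"A"` and sets all occupancies to
#' unity, the standard preparation before structure-factor calculation for
#' diffuse modeling.
#'
#' @param model an [atomic_model()].
#' @return the filtered model.
#' @export
select_conformer <- function(model) {
  keep <- model$atoms$altloc %in% c("", "A")
  model$atoms <- model$atoms[keep, , drop = FALSE]
  model$atoms$occupancy <- 1
  model
}

# Symmetric 3x3 from the six packed components.
u_matrix <- function(u) {
  matrix(c(u[1], u[4], u[5], u[4], u[2], u[6], u[5], u[6], u[3]), 3, 3)
}

#' Equivalent isotropic B from an anisotropic U
#'
#' B_eq = (8 pi^2 / 3) trace(U).
#'
#' @param U symmetric 3x3 Cartesian U (Angstrom^2), or numeric(6) packed as
#'   (u11, u22, u33, u12, u13, u23).
#' @return B_eq in Angstrom^2.
#' @export
beq_from_u <- function(U) {
  if (length(U) == 6) U <- u_matrix(U)
  (8 * pi^2 / 3) * sum(diag(U))
}

#' Anisotropy ratio of an ADP tensor
#'
#' Ratio of the smallest to the largest eigenvalue of U; 1 means isotropic.
#' Indefinite tensors are flagged with a warning and evaluated on
#' eigenvalues clipped at zero.
#'
#' @inheritParams beq_from_u
#' @return ratio in [0, 1].
#' @export
anisotropy_ratio <- function(U) {
  if (length(U) == 6) U <- u_matrix(U)
  ev <- eigen(U, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12) {
    warning("non-positive-semidefinite U; clipping eigenvalues at zero")
    ev <- pmax(ev, 0)
  }
  min(ev) / max(ev)
}

#' Traceless part of a symmetric matrix
#'
#' @param delta symmetric 3x3 matrix (any units).
#' @return delta minus trace(delta)/3 on the diagonal.
#' @export
traceless <- function(delta) {
  delta - diag(rep(sum(diag(delta)) / 3, 3))
}

#' Rescale anisotropic ADPs with a traceless difference scale matrix
#'
#' Adds the traceless part of an overall anisotropic difference scale
#' matrix (B-convention, Angstrom^2) to every atom's Cartesian U
#' (converting with B = 8 pi^2 U), leaving every B_eq unchanged. Atoms
#' whose updated U is not positive semidefinite are flagged in the
#' `n_non_psd` attribute.
#'
#' @param model an [atomic_model()] carrying anisotropic U.
#' @param delta_b symmetric 3x3 difference scale matrix in B units.
#' @return the rescaled model.
#' @export
rescale_adps <- function(model, delta_b) {
  stopifnot(has_anisou(model), isTRUE(all.equal(delta_b, t(delta_b))))
  dU <- traceless(delta_b) / (8 * pi^2)
  at <- model$atoms
  at$u11 <- at$u11 + dU[1, 1]; at$u22 <- at$u22 + dU[2, 2]
  at$u33 <- at$u33 + dU[3, 3]; at$u12 <- at$u12 + dU[1, 2]
  at$u13 <- at$u13 + dU[1, 3]; at$u23 <- at$u23 + dU[2, 3]
  n_bad <- 0L
  for (i in seq_len(nrow(at))) {
    ev <- eigen(u_matrix(as.numeric(at[i, U_COLS])), symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-12) n_bad <- n_bad + 1L
  }
  model$atoms <- at
  attr(model, "n_non_psd") <- n_bad
  model
}
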
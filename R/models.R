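# Model diffuse intensity on the voxel grid: reference (Bragg) intensities
# from an atomic model under zero / isotropic / anisotropic ADP treatments,
# the liquid-like motions (LLM) model with an exponential displacement
# correlation function, the independent rigid-body translation (RBT) model,
# and correlation-maximizing parameter fits by a Powell direction-set
# search.
#
# Two q conventions meet here: voxel coordinates use the crystallographic
# |q| = 1/d, while the LLM/RBT closed forms are written in the physics
# convention q_rad = 2 pi / d; q_rad is formed explicitly wherever
# sigma^2 q^2 appears.

#' Reference squared-structure-factor volume
#'
#' Computes I(hkl) = |sum_j f_j(|q|) o_j T_j(q) exp(2 pi i (hkl) . x_j)|^2
#' over every integer grid point, where T_j is the atomic Debye-Waller
#' factor under the chosen ADP treatment: 1 (`zero`), exp(-B_eq |q|^2 / 4)
#' (`isotropic`), or exp(-2 pi^2 q' U q) with Cartesian q and U
#' (`anisotropic`). Crystallographic symmetry mates of the model's space
#' group are included, so the map carries the full unit-cell (and hence
#' Laue) symmetry. Atoms lacking an anisotropic U under `anisotropic` fall
#' back to their isotropic B (with a message).
#'
#' @param model an [atomic_model()] (apply [select_conformer()] first for
#'   multi-conformer models).
#' @param hmax grid half-width in Miller indices.
#' @param adp_mode `"zero"`, `"isotropic"` or `"anisotropic"`.
#' @param laue Laue group label stored on the output volume.
#' @param oversample samples per Miller index (1 for production; >1 for
#'   finely sampled volumes used by the synthetic renderer and for
#'   visualization).
#' @return a [diffuse_volume()] of reference intensities (all voxels
#'   observed).
#' @export
reference_intensity <- function(model, hmax,
                                adp_mode = c("zero", "isotropic",
                                             "anisotropic"),
                                laue = "2/m", oversample = 1L) {
  adp_mode <- match.arg(adp_mode)
  n <- 2L * hmax * oversample + 1L
  h <- seq(-hmax, hmax, by = 1 / oversample)
  H <- as.matrix(expand.grid(H = h, K = h, L = h))
  B <- reciprocal_basis(model$cell)
  qc <- H %*% t(B)                       # Cartesian q, |q| = 1/d
  q2 <- rowSums(qc^2)
  M <- orthogonalization_matrix(model$cell)
  Minv <- solve(M)
  ops <- spacegroup_symops(model$spacegroup)
  at <- model$atoms
  if (adp_mode == "anisotropic" && !has_anisou(model)) {
    message("no anisotropic U in model; using isotropic B for all atoms")
  }
  # unique elements: evaluate the form factor once per element
  ff <- lapply(unique(at$element), function(el) form_factor(el, sqrt(q2)))
  names(ff) <- unique(at$element)
  re <- numeric(nrow(H)); im <- numeric(nrow(H))
  for (op in ops) {
    Rcart <- M %*% op$R %*% Minv
    for (j in seq_len(nrow(at))) {
      xj <- op$R %*% c(at$x[j], at$y[j], at$z[j]) + op$t
      Tj <- if (adp_mode == "zero") {
        1
      } else if (adp_mode == "isotropic" ||
                 (adp_mode == "anisotropic" && is.na(at$u11[j]))) {
        beq <- if (!is.na(at$u11[j])) beq_from_u(as.numeric(at[j, U_COLS]))
               else at$b[j]
        exp(-beq * q2 / 4)
      } else {
        U <- Rcart %*% u_matrix(as.numeric(at[j, U_COLS])) %*% t(Rcart)
        expo <- U[1, 1] * qc[, 1]^2 + U[2, 2] * qc[, 2]^2 +
          U[3, 3] * qc[, 3]^2 +
          2 * (U[1, 2] * qc[, 1] * qc[, 2] + U[1, 3] * qc[, 1] * qc[, 3] +
                 U[2, 3] * qc[, 2] * qc[, 3])
        exp(-2 * pi^2 * expo)
      }
      amp <- ff[[at$element[j]]] * at$occupancy[j] * Tj
      ph <- 2 * pi * (H %*% xj)[, 1]
      re <- re + amp * cos(ph)
      im <- im + amp * sin(ph)
    }
  }
  vals <- array(re^2 + im^2, c(n, n, n))
  diffuse_volume(vals, array(1, c(n, n, n)), model$cell, laue,
                 oversample = oversample)
}

#' Liquid-like-motions displacement correlation kernel
#'
#' The 3D Fourier transform of the exponential correlation function
#' exp(-r/gamma): Gamma_gamma(q) = 8 pi gamma^3 / (1 + gamma^2 q_rad^2)^2
#' with q_rad = 2 pi |q|, evaluated at every voxel offset of the grid
#' (centered array). For convolution the kernel is normalized to unit grid
#' sum so total intensity is preserved.
#'
#' @param gamma correlation length (Angstrom, > 0).
#' @param hmax grid half-width in Miller indices.
#' @param cell unit-cell parameters (defines the q of each voxel offset).
#' @param normalize if TRUE (default) scale to unit sum (convolution
#'   weights); if FALSE return the closed-form values.
#' @param oversample samples per Miller index.
#' @return centered 3D array.
#' @export
llm_kernel <- function(gamma, hmax, cell, normalize = TRUE,
                       oversample = 1L) {
  if (gamma <= 0) stop("gamma must be positive")
  n <- 2L * hmax * oversample + 1L
  h <- seq(-hmax, hmax, by = 1 / oversample)
  qrad <- 2 * pi * array(hkl_qmag(as.matrix(expand.grid(h, h, h)), cell),
                         c(n, n, n))
  k <- 8 * pi * gamma^3 / (1 + gamma^2 * qrad^2)^2
  if (normalize) k / sum(k) else k
}

#' LLM model diffuse intensity
#'
#' With the overall Debye-Waller factor (`dw = TRUE`):
#' I_d(q) = sigma^2 q_rad^2 exp(-sigma^2 q_rad^2) (I_ref * Gamma_gamma);
#' without it (`dw = FALSE`, the form used when individual ADPs are kept in
#' the reference): I_d(q) = sigma^2 q_rad^2 (I_ref * Gamma_gamma). The
#' convolution is circular on the periodic index grid via FFT.
#'
#' @param reference reference-intensity [diffuse_volume()] (zero-ADP I0 for
#'   the standard model; IB with individual ADPs otherwise).
#' @param sigma displacement amplitude (Angstrom, >= 0).
#' @param gamma correlation length (Angstrom, > 0).
#' @param dw keep the overall Debye-Waller factor exp(-sigma^2 q_rad^2)?
#' @return a [diffuse_volume()] of model diffuse intensities.
#' @export
llm_intensity <- function(reference, sigma, gamma, dw = TRUE) {
  stopifnot(sigma >= 0)
  k <- llm_kernel(gamma, reference$hmax / reference$oversample,
                  reference$cell, oversample = reference$oversample)
  conv <- convolve3d(reference$values, k)
  qrad2 <- (2 * pi * volume_qmag(reference))^2
  pref <- sigma^2 * qrad2
  if (dw) pref <- pref * exp(-sigma^2 * qrad2)
  diffuse_volume(pref * conv, reference$count, reference$cell,
                 reference$laue, reference$oversample)
}

#' RBT model diffuse intensity
#'
#' Independent rigid translation of the asymmetric unit with amplitude
#' sigma: I_d(q) = I0(q) (1 - exp(-sigma^2 q_rad^2)); no correlation
#' kernel.
#'
#' @param reference zero-ADP reference-intensity [diffuse_volume()].
#' @param sigma translational displacement amplitude (Angstrom, >= 0).
#' @return a [diffuse_volume()].
#' @export
rbt_intensity <- function(reference, sigma) {
  stopifnot(sigma >= 0)
  qrad2 <- (2 * pi * volume_qmag(reference))^2
  diffuse_volume(reference$values * (1 - exp(-sigma^2 * qrad2)),
                 reference$count, reference$cell, reference$laue,
                 reference$oversample)
}

#' Process a model map like the data
#'
#' Laue-symmetrizes and isotropic-subtracts a model volume so model and
#' data maps are compared after identical processing.
#'
#' @param vol a [diffuse_volume()].
#' @return the anisotropic symmetrized volume.
#' @export
process_like_data <- function(vol) {
  subtract_isotropic(symmetrize(vol, "laue"))
}

# Powell direction-set minimizer with Brent line searches, box constraints
# enforced by restricting each line search to the feasible segment.
powell_minimize <- function(par, fn, lower, upper, tol = 1e-4,
                            maxit = 25) {
  np <- length(par)
  dirs <- diag(np)
  f <- fn(par)
  trace <- list(list(par = par, value = f))
  line_min <- function(par, d, f0) {
    # feasible t range of par + t d within [lower, upper]
    tlo <- -Inf; thi <- Inf
    for (i in seq_len(np)) {
      if (d[i] > 0) {
        tlo <- max(tlo, (lower[i] - par[i]) / d[i])
        thi <- min(thi, (upper[i] - par[i]) / d[i])
      } else if (d[i] < 0) {
        tlo <- max(tlo, (upper[i] - par[i]) / d[i])
        thi <- min(thi, (lower[i] - par[i]) / d[i])
      }
    }
    if (!is.finite(tlo) || !is.finite(thi) || thi <= tlo)
      return(list(par = par, value = f0))
    o <- stats::optimize(function(t) fn(par + t * d), c(tlo, thi),
                         tol = max(1e-4, tol) * max(1, thi - tlo) / 50)
    if (o$objective < f0) list(par = par + o$minimum * d, value = o$objective)
    else list(par = par, value = f0)
  }
  for (it in seq_len(maxit)) {
    par0 <- par; f0 <- f
    biggest <- 0; ibig <- 1L
    for (i in seq_len(np)) {
      res <- line_min(par, dirs[, i], f)
      if (f - res$value > biggest) { biggest <- f - res$value; ibig <- i }
      par <- res$par; f <- res$value
    }
    dnew <- par - par0
    if (sqrt(sum(dnew^2)) > 1e-12) {
      res <- line_min(par, dnew, f)
      par <- res$par; f <- res$value
      dirs[, ibig] <- dnew / sqrt(sum(dnew^2))
    }
    trace[[length(trace) + 1L]] <- list(par = par, value = f)
    if (f0 - f < tol * (abs(f0) + tol)) break
  }
  list(par = par, value = f, iterations = it, trace = trace)
}

#' Fit an LLM or RBT motion model to an anisotropic diffuse map
#'
#' Maximizes the Pearson correlation between the data map and the
#' symmetrized, isotropic-subtracted model map over the model parameters
#' (sigma and, for the LLM, gamma) using a Powell direction-set search
#' seeded from a coarse (sigma, gamma) screening grid. The correlation is
#' evaluated over voxels observed in the data within the resolution window
#' `[d_max, d_min]` (the low-resolution exclusion reflects the absence of a
#' bulk-solvent model in the reference intensities).
#'
#' @param data Laue-symmetrized anisotropic data [diffuse_volume()].
#' @param model an [atomic_model()]; multi-conformer models are reduced to
#'   the A conformer automatically. Alternatively supply `reference`.
#' @param kind `"llm"` or `"rbt"`.
#' @param adp_mode ADP treatment for the reference intensity: `"zero"`
#'   (standard LLM), `"isotropic"` or `"anisotropic"`.
#' @param dw keep the overall Debye-Waller factor? Defaults to TRUE for
#'   `adp_mode = "zero"` and FALSE otherwise (where the individual ADPs
#'   already carry the damping); setting `dw = TRUE` with individual ADPs
#'   is the diagnostic probe of whether sigma refines toward zero.
#' @param reference optional precomputed reference-intensity volume
#'   (bypasses `model`).
#' @param d_min high-resolution cutoff (Angstrom, default 1.4).
#' @param d_max low-resolution exclusion (Angstrom, default 10).
#' @param sigma_bounds,gamma_bounds box constraints (Angstrom).
#' @param sigma_starts,gamma_starts screening grid values.
#' @param n_refine number of best screening points refined by Powell
#'   (default 2).
#' @param tol convergence tolerance on the correlation (default 1e-4).
#' @return object of class `diffuse_fit` with elements `kind`, `adp_mode`,
#'   `dw`, `sigma`, `gamma` (LLM only), `cc`, `n_voxels`,
#'   `resolution_range`, `trace`.
#' @export
fit_diffuse_model <- function(data, model = NULL,
                              kind = c("llm", "rbt"),
                              adp_mode = c("zero", "isotropic",
                                           "anisotropic"),
                              dw = NULL, reference = NULL,
                              d_min = 1.4, d_max = 10,
                              sigma_bounds = c(0, 3),
                              gamma_bounds = c(0.5, 100),
                              sigma_starts = c(0.2, 0.4, 0.8),
                              gamma_starts = c(4, 8, 16),
                              n_refine = 2, tol = 1e-4) {
  kind <- match.arg(kind)
  adp_mode <- match.arg(adp_mode)
  if (is.null(dw)) dw <- adp_mode == "zero"
  if (is.null(reference)) {
    if (is.null(model)) stop("supply either a model or a reference volume")
    model <- select_conformer(model)
    reference <- reference_intensity(model, data$hmax, adp_mode, data$laue)
  }
  stopifnot(identical(dim(reference$values), dim(data$values)))
  qmag <- volume_qmag(data)
  inres <- qmag > 1 / d_max & qmag <= 1 / d_min & is.finite(data$values)
  if (sum(inres) < 10) stop("too few observed voxels in the resolution window")
  dvec <- data$values[inres]
  n <- 2L * data$hmax + 1L
  Fref <- stats::fft(reference$values)
  qrad2 <- (2 * pi * qmag)^2
  kernel_cache <- new.env(parent = emptyenv())
  conv_for <- function(gamma) {
    key <- sprintf("%.12g", gamma)
    got <- kernel_cache[[key]]
    if (!is.null(got)) return(got)
    k <- llm_kernel(gamma, data$hmax, data$cell)
    k <- k[ifftshift_index(n), ifftshift_index(n), ifftshift_index(n)]
    cv <- Re(stats::fft(Fref * stats::fft(k), inverse = TRUE)) / n^3
    if (length(ls(kernel_cache)) > 8) rm(list = ls(kernel_cache)[1],
                                         envir = kernel_cache)
    kernel_cache[[key]] <- cv
    cv
  }
  evals <- new.env(parent = emptyenv()); evals$log <- list()
  objective <- function(par) {
    raw <- if (kind == "llm") {
      pref <- par[1]^2 * qrad2
      if (dw) pref <- pref * exp(-par[1]^2 * qrad2)
      pref * conv_for(par[2])
    } else {
      reference$values * (1 - exp(-par[1]^2 * qrad2))
    }
    m <- process_like_data(diffuse_volume(raw, reference$count,
                                          data$cell, data$laue))
    cc <- pearson_cc(dvec, m$values[inres])
    if (!is.finite(cc)) cc <- -1
    evals$log[[length(evals$log) + 1L]] <- c(par, cc)
    -cc
  }
  if (kind == "llm") {
    grid <- as.matrix(expand.grid(sigma = sigma_starts,
                                  gamma = gamma_starts))
    fg <- apply(grid, 1, objective)
    ord <- order(fg)[seq_len(min(n_refine, nrow(grid)))]
    best <- NULL
    for (i in ord) {
      res <- powell_minimize(grid[i, ], objective,
                             lower = c(sigma_bounds[1], gamma_bounds[1]),
                             upper = c(sigma_bounds[2], gamma_bounds[2]),
                             tol = tol)
      if (is.null(best) || res$value < best$value) best <- res
    }
    sigma <- unname(best$par[1]); gamma <- unname(best$par[2])
    cc <- -best$value
  } else {
    o <- stats::optimize(function(s) objective(s), sigma_bounds,
                         tol = 1e-5 * diff(sigma_bounds))
    sigma <- o$minimum; gamma <- NA_real_; cc <- -o$objective
  }
  tr <- do.call(rbind, evals$log)
  colnames(tr) <- if (kind == "llm") c("sigma", "gamma", "cc") else
    c("sigma", "cc")
  structure(list(kind = kind, adp_mode = adp_mode, dw = dw,
                 sigma = sigma, gamma = gamma, cc = cc,
                 n_voxels = sum(inres),
                 resolution_range = c(d_max, d_min),
                 trace = as.data.frame(tr),
                 reference = reference, data = data),
            class = "diffuse_fit")
}

#' @export
print.diffuse_fit <- function(x, ...) {
  lab <- if (x$kind == "llm") "LLM" else "RBT"
  cat(sprintf("%s fit (%s ADPs%s)\n", lab, x$adp_mode,
              if (x$kind == "llm" && !x$dw) ", no overall DW factor" else ""))
  cat(sprintf("  sigma = %.3f A", x$sigma))
  if (x$kind == "llm") cat(sprintf(", gamma = %.2f A", x$gamma))
  cat(sprintf("\n  CC_%s = %.4f over %d voxels (%.1f-%.2f A)\n", lab,
              x$cc, x$n_voxels, x$resolution_range[1],
              x$resolution_range[2]))
  invisible(x)
}

#' @export
coef.diffuse_fit <- function(object, ...) {
  if (object$kind == "llm") c(sigma = object$sigma, gamma = object$gamma)
  else c(sigma = object$sigma)
}

#' @export
summary.diffuse_fit <- function(object, ...) {
  out <- list(fit = object, n_evaluations = nrow(object$trace),
              cc = object$cc)
  class(out) <- "summary.diffuse_fit"
  out
}

#' @export
print.summary.diffuse_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d objective evaluations\n", x$n_evaluations))
  invisible(x)
}

#' Model map at the fitted parameters
#'
#' @param object a `diffuse_fit`.
#' @param processed return the symmetrized, isotropic-subtracted map (as
#'   compared against the data) rather than the raw model intensity.
#' @param ... unused.
#' @return a [diffuse_volume()].
#' @export
predict.diffuse_fit <- function(object, processed = TRUE, ...) {
  raw <- if (object$kind == "llm") {
    llm_intensity(object$reference, object$sigma, object$gamma, object$dw)
  } else {
    rbt_intensity(object$reference, object$sigma)
  }
  if (processed) process_like_data(raw) else raw
}

#' Residual map of a fit
#'
#' Data minus the least-squares-scaled model map over the fit's resolution
#' window (NA elsewhere).
#'
#' @param object a `diffuse_fit`.
#' @param ... unused.
#' @return a [diffuse_volume()].
#' @export
residuals.diffuse_fit <- function(object, ...) {
  m <- predict(object)
  qmag <- volume_qmag(object$data)
  inres <- qmag > 1 / object$resolution_range[1] &
    qmag <= 1 / object$resolution_range[2]
  d <- object$data$values; mv <- m$values
  ok <- inres & is.finite(d) & is.finite(mv)
  b <- stats::cov(d[ok], mv[ok]) / stats::var(mv[ok])
  out <- d * NA_real_
  out[ok] <- d[ok] - b * mv[ok]
  diffuse_volume(out, (object$data$count > 0) * ok, object$data$cell,
                 object$data$laue)
}

#' Trace plot of a fit's objective evaluations
#'
#' @param x a `diffuse_fit`.
#' @param ... passed to [plot()].
#' @export
plot.diffuse_fit <- function(x, ...) {
  plot(seq_len(nrow(x$trace)), x$trace$cc, type = "b", xlab = "evaluation",
       ylab = "CC", main = sprintf("%s fit objective trace", toupper(x$kind)),
       ...)
  invisible(x)
}
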
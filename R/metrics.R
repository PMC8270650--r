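# Correlation-based quality metrics for diffuse maps: the symmetry metrics
# CC_Friedel and CC_Laue (correlation of the unsymmetrized anisotropic map
# with its own symmetrized version), the internal-consistency metric CC_1/2
# (half-splits of symmetry-related observations), and the inter-dataset
# metrics CC_Rep and CC_Cross. All metrics operate on anisotropic
# (isotropic-subtracted) maps and report overall and per-resolution-shell
# values over the voxels observed in both operands.

#' Pearson correlation over common observed voxels
#'
#' The standard centered Pearson correlation coefficient between two voxel
#' vectors restricted to positions where both are finite. At least three
#' common voxels are required; zero variance in either operand yields NA.
#'
#' @param x,y numeric vectors (or 3D arrays) of voxel values; NA marks an
#'   unobserved voxel.
#' @return correlation in [-1, 1], or NA when undefined.
#' @export
pearson_cc <- function(x, y) {
  x <- as.vector(x); y <- as.vector(y)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

# Shared shell-resolved CC report builder.
cc_report <- function(name, x, y, q, shells, companions = NULL) {
  x <- as.vector(x); y <- as.vector(y); q <- as.vector(q)
  rows <- lapply(seq_len(length(shells) - 1L), function(i) {
    sel <- q > shells[i] & q <= shells[i + 1]
    ok <- sel & is.finite(x) & is.finite(y)
    data.frame(d_hi = ifelse(shells[i] > 0, 1 / shells[i], Inf),
               d_lo = 1 / shells[i + 1],
               n = sum(ok),
               cc = pearson_cc(x[sel], y[sel]))
  })
  inr <- q > shells[1] & q <= shells[length(shells)]
  structure(list(metric = name,
                 overall = pearson_cc(x[inr], y[inr]),
                 n = sum(inr & is.finite(x) & is.finite(y)),
                 shells = do.call(rbind, rows),
                 companions = companions),
            class = "cc_report")
}

#' @export
print.cc_report <- function(x, ...) {
  cat(sprintf("%s: overall CC = %.4f over %d voxels\n", x$metric,
              x$overall, x$n))
  sh <- x$shells
  cat(sprintf("  %d shells, CC range %.3f .. %.3f\n", nrow(sh),
              suppressWarnings(min(sh$cc, na.rm = TRUE)),
              suppressWarnings(max(sh$cc, na.rm = TRUE))))
  if (!is.null(x$companions))
    cat("  companions:", paste(x$companions, collapse = ", "), "\n")
  invisible(x)
}

#' Symmetry correlation (CC_Friedel / CC_Laue)
#'
#' Correlates an unsymmetrized anisotropic map with its own Friedel- or
#' Laue-symmetrized version over their common observed voxels. On an
#' independent random map this converges to 1/sqrt(orbit size) (about 0.71
#' for a Friedel pair, 0.50 for a 2/m orbit of four), so values are
#' inflated relative to chance; the metric is reported for comparability
#' with earlier work.
#'
#' @param vol unsymmetrized anisotropic [diffuse_volume()].
#' @param mode `"friedel"` or `"laue"`.
#' @param shells shell boundaries in |q| ([shell_scheme()]).
#' @return a `cc_report`.
#' @export
cc_symmetry <- function(vol, mode = c("friedel", "laue"),
                        shells = shell_scheme()) {
  mode <- match.arg(mode)
  sym <- symmetrize(vol, mode)
  name <- if (mode == "friedel") "CC_Friedel" else "CC_Laue"
  cc_report(name, vol$values, sym$values, volume_qmag(vol), shells)
}

#' Half-dataset correlation CC_1/2
#'
#' For every symmetry-unique voxel with at least two observed
#' symmetry-related grid observations, the orbit members are randomly
#' partitioned into two halves; the count-weighted half means are then
#' correlated over unique voxels, per shell and overall. Voxels with fewer
#' than two observed orbit members are excluded.
#'
#' @param vol unsymmetrized anisotropic [diffuse_volume()].
#' @param shells shell boundaries in |q|.
#' @param seed integer seed for the random half-split.
#' @return a `cc_report`.
#' @export
cc_half <- function(vol, shells = shell_scheme(), seed = 1L) {
  ops <- laue_operations(vol$laue, "laue")
  m <- length(ops)
  nvox <- length(vol$values)
  V <- matrix(NA_real_, nvox, m)
  W <- matrix(0, nvox, m)
  for (i in seq_along(ops)) {
    V[, i] <- as.vector(ops[[i]](vol$values))
    W[, i] <- as.vector(ops[[i]](vol$count))
  }
  obs <- is.finite(V) & W > 0
  # orbit representatives only, to avoid counting each orbit m times; on
  # symmetry-special positions coinciding orbit members are deduplicated so
  # a voxel is not split against itself
  n <- 2L * vol$hmax + 1L
  idx <- array(seq_len(n^3), c(n, n, n))
  IDX <- matrix(0L, nvox, m)
  for (i in seq_along(ops)) IDX[, i] <- as.vector(ops[[i]](idx))
  rep_idx <- do.call(pmin, lapply(seq_len(m), function(i) IDX[, i]))
  dup <- matrix(FALSE, nvox, m)
  for (i in seq_len(m)[-1]) for (j in seq_len(i - 1L))
    dup[, i] <- dup[, i] | IDX[, i] == IDX[, j]
  obs <- obs & !dup
  nobs <- rowSums(obs)
  use <- which(rep_idx == seq_len(nvox) & nobs >= 2)
  h1 <- rep(NA_real_, nvox); h2 <- rep(NA_real_, nvox)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (v in use) {
    mem <- which(obs[v, ])
    mem <- sample(mem)
    k <- length(mem) %/% 2L
    a <- mem[seq_len(k)]; b <- mem[-seq_len(k)]
    h1[v] <- sum(V[v, a] * W[v, a]) / sum(W[v, a])
    h2[v] <- sum(V[v, b] * W[v, b]) / sum(W[v, b])
  }
  cc_report("CC_1/2", h1, h2, volume_qmag(vol), shells)
}

#' Reproducibility correlation CC_Rep
#'
#' Mean pairwise correlation between the Laue-symmetrized anisotropic map
#' of a dataset and those of independent replicate datasets measured from
#' different crystals of the same protein.
#'
#' @param target Laue-symmetrized anisotropic [diffuse_volume()].
#' @param replicates list of replicate maps on the same grid.
#' @param shells shell boundaries in |q|.
#' @param labels optional companion dataset labels.
#' @return a `cc_report` whose overall/shell values are the means of the
#'   pairwise reports.
#' @export
cc_rep <- function(target, replicates, shells = shell_scheme(),
                   labels = NULL) {
  stopifnot(length(replicates) >= 1)
  reports <- lapply(replicates, function(r) {
    if (!identical(dim(r$values), dim(target$values)))
      stop("replicate grids are incompatible")
    cc_report("CC", target$values, r$values, volume_qmag(target), shells)
  })
  sh <- reports[[1]]$shells
  sh$cc <- rowMeans(do.call(cbind, lapply(reports, function(r) r$shells$cc)))
  sh$n <- rowMeans(do.call(cbind, lapply(reports, function(r) r$shells$n)))
  structure(list(metric = "CC_Rep",
                 overall = mean(vapply(reports, `[[`, 0, "overall")),
                 n = reports[[1]]$n,
                 shells = sh,
                 companions = labels,
                 pairwise = vapply(reports, `[[`, 0, "overall")),
            class = "cc_report")
}

#' Cross-form correlation CC_Cross
#'
#' Mean pairwise correlation against maps of a different sample form (same
#' grid and Laue group); definitionally identical to [cc_rep()] with a
#' different companion set.
#'
#' @inheritParams cc_rep
#' @param other_form list of maps of the other sample form.
#' @return a `cc_report`.
#' @export
cc_cross <- function(target, other_form, shells = shell_scheme(),
                     labels = NULL) {
  out <- cc_rep(target, other_form, shells, labels)
  out$metric <- "CC_Cross"
  out
}

#' Table-style summary of map quality metrics
#'
#' Computes completeness, CC_Friedel, CC_Laue, CC_1/2 and, when replicate
#' or cross-form maps are supplied, CC_Rep and CC_Cross for one dataset.
#'
#' @param raw_anisotropic unsymmetrized anisotropic map.
#' @param laue_anisotropic Laue-symmetrized anisotropic map.
#' @param replicates optional list of replicate Laue anisotropic maps.
#' @param cross optional list of cross-form maps.
#' @param shells shell boundaries in |q|.
#' @param seed seed for the CC_1/2 half split.
#' @return named list of metric values plus the underlying reports.
#' @export
quality_summary <- function(raw_anisotropic, laue_anisotropic,
                            replicates = NULL, cross = NULL,
                            shells = shell_scheme(), seed = 1L) {
  rep_friedel <- cc_symmetry(raw_anisotropic, "friedel", shells)
  rep_laue <- cc_symmetry(raw_anisotropic, "laue", shells)
  rep_half <- cc_half(raw_anisotropic, shells, seed)
  compl <- completeness(raw_anisotropic, shells)
  out <- list(
    completeness = 100 * compl$completeness[nrow(compl)],
    cc_friedel = rep_friedel$overall,
    cc_laue = rep_laue$overall,
    cc_half = rep_half$overall,
    reports = list(friedel = rep_friedel, laue = rep_laue, half = rep_half)
  )
  if (!is.null(replicates) && length(replicates)) {
    r <- cc_rep(laue_anisotropic, replicates, shells)
    out$cc_rep <- r$overall
    out$reports$rep <- r
  }
  if (!is.null(cross) && length(cross)) {
    r <- cc_cross(laue_anisotropic, cross, shells)
    out$cc_cross <- r$overall
    out$reports$cross <- r
  }
  out
}
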
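# Pipeline orchestration: configuration, the standard frames-to-map run,
# and the ablation / scale-factor study driver.
#
# Step order follows the standard protocol: (1) static masking, (2)
# windowed outlier masking, (3) exposure-scaled background subtraction,
# (4) pixel position (parallax) and intensity (polarization, solid-angle,
# absorption) corrections, (5) Bragg cleaning, (6) per-frame scaling and
# radial-profile variance removal; then 3D merging, symmetrization and
# isotropic subtraction. Bragg cleaning always precedes scaling and
# variance removal.

#' Pipeline configuration
#'
#' Every switch corresponds to one named processing step; the serialized
#' configuration plus the inputs fully determines every deterministic
#' output.
#'
#' @param background_subtraction,polarization,solid_angle,absorption,parallax,outlier_mask,scaling,variance_removal
#'   step toggles.
#' @param bragg_mode Bragg-pixel treatment in image space: `"reject"`
#'   (mask) or `"replace"` (median replacement); merging additionally
#'   rejects the reciprocal-space Bragg box either way.
#' @param scale_method per-frame scale factor method (see
#'   [scale_factor()]).
#' @param saturation static-mask saturation threshold (photons).
#' @param window,nsigma windowed outlier-mask parameters.
#' @param bragg_delta Bragg-box half width.
#' @param pca_components number of radial-profile principal components to
#'   remove.
#' @param n_bins radial-profile bin count.
#' @param d_min high-resolution cutoff (Angstrom) for scaling, metrics and
#'   shells.
#' @param n_shells metric resolution shells.
#' @param hmax merge-grid half-width in Miller indices.
#' @param laue Laue group label.
#' @param seed seed for the CC_1/2 half split.
#' @param bragg_factors optional imported Bragg scale-factor table.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(background_subtraction = TRUE,
                            polarization = TRUE, solid_angle = TRUE,
                            absorption = TRUE, parallax = TRUE,
                            outlier_mask = TRUE, scaling = TRUE,
                            variance_removal = TRUE,
                            bragg_mode = c("reject", "replace"),
                            scale_method = "radial_profile",
                            saturation = 10000, window = 11, nsigma = 5,
                            bragg_delta = 0.25, pca_components = 3,
                            n_bins = 200, d_min = 1.4, n_shells = 15,
                            hmax = 25, laue = "2/m", seed = 1L,
                            bragg_factors = NULL) {
  bragg_mode <- match.arg(bragg_mode)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# MD5 of the serialized configuration, for provenance.
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(config[order(names(config))], NULL,
                     xdr = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Run the frames-to-map pipeline
#'
#' Applies the preprocessing steps enabled in the configuration to every
#' crystal/background frame pair, merges onto the voxel grid, and returns
#' the raw unsymmetrized map, its anisotropic version, Friedel- and
#' Laue-symmetrized anisotropic maps, per-frame scale factors, quality
#' metrics and a provenance record.
#'
#' @param frames list of crystal [detector_frame()]s.
#' @param backgrounds list of paired background frames (may be NULL when
#'   background subtraction is off).
#' @param A lab-frame reciprocal-cell matrix at spindle angle zero.
#' @param angles_deg per-frame spindle angles.
#' @param geometry an [experiment_geometry()].
#' @param cell unit-cell parameters.
#' @param config a [pipeline_config()].
#' @return list with maps, metrics and provenance.
#' @export
run_pipeline <- function(frames, backgrounds, A, angles_deg, geometry,
                         cell, config = pipeline_config()) {
  stopifnot(length(frames) == length(angles_deg))
  px <- pixel_grid(geometry)
  cf <- correction_factors(geometry, px)
  pos_px <- if (config$parallax) cf$shifted_pixels else px
  q <- pixel_to_q(geometry, pos_px)
  nx <- geometry$detector_shape[1]; ny <- geometry$detector_shape[2]
  qmag <- matrix(sqrt(rowSums(q^2)), nx, ny)
  divisor <- rep(1, nrow(px))
  if (config$polarization) divisor <- divisor * cf$polarization
  if (config$solid_angle) divisor <- divisor * cf$solid_angle
  if (config$absorption) divisor <- divisor * cf$absorption
  divisor <- matrix(divisor, nx, ny)
  usable0 <- matrix(cf$usable, nx, ny)
  breaks <- radial_breaks(config$d_min, config$n_bins)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2

  preprocess <- function(fr, bg) {
    fr <- static_mask(fr, config$saturation, usable0)
    if (config$outlier_mask) fr <- windowed_outlier_mask(fr, config$window,
                                                         config$nsigma)
    if (config$background_subtraction) {
      bg <- static_mask(bg, config$saturation, usable0)
      if (config$outlier_mask) bg <- windowed_outlier_mask(bg, config$window,
                                                           config$nsigma)
      fr <- subtract_background(fr, bg)
    }
    fr$counts <- fr$counts / divisor
    hkl <- q_to_hkl(A, fr$spindle_angle_deg, q, geometry$rotation_axis)
    flags <- matrix(flag_bragg_pixels(hkl, config$bragg_delta), nx, ny)
    if (config$bragg_mode == "replace") {
      fr <- replace_bragg_with_median(fr, flags, config$window)
    } else {
      fr$mask <- fr$mask & !flags
    }
    fr
  }

  nfr <- length(frames)
  processed <- vector("list", nfr)
  scale_factors <- numeric(nfr)
  profiles <- matrix(NA_real_, nfr, config$n_bins)
  reference <- NULL
  for (i in seq_len(nfr)) {
    fr <- preprocess(frames[[i]],
                     if (config$background_subtraction) backgrounds[[i]]
                     else NULL)
    if (i == 1) reference <- fr
    s <- if (config$scaling) {
      scale_factor(fr, reference, qmag, config$scale_method,
                   d_min = config$d_min, n_bins = config$n_bins,
                   bragg_factors = config$bragg_factors)
    } else 1
    fr$counts <- fr$counts * s
    scale_factors[i] <- s
    profiles[i, ] <- radial_profile(fr, qmag, breaks)$mean
    processed[[i]] <- fr
  }
  if (config$variance_removal) {
    corr <- radial_variance_correction(profiles, config$pca_components)
    for (i in seq_len(nfr)) {
      processed[[i]] <- apply_radial_correction(processed[[i]], qmag,
                                                centers, corr[i, ])
    }
  }
  hkl_fun <- function(fr) q_to_hkl(A, fr$spindle_angle_deg, q,
                                   geometry$rotation_axis)
  raw <- merge_frames(processed, hkl_fun, config$hmax, cell, config$laue,
                      config$bragg_delta)
  raw_aniso <- subtract_isotropic(raw)
  laue_aniso <- subtract_isotropic(symmetrize(raw, "laue"))
  friedel_aniso <- subtract_isotropic(symmetrize(raw, "friedel"))
  shells <- shell_scheme(config$d_min, config$n_shells)
  metrics <- quality_summary(raw_aniso, laue_aniso, shells = shells,
                             seed = config$seed)
  list(raw = raw, raw_anisotropic = raw_aniso,
       friedel_anisotropic = friedel_aniso,
       laue_anisotropic = laue_aniso,
       scale_factors = scale_factors, metrics = metrics,
       provenance = list(config = config, hash = config_hash(config),
                         n_frames = nfr,
                         package_version =
                           as.character(utils::packageVersion("diffusemap")),
                         timestamp = format(Sys.time(), tz = "UTC")))
}

#' Run a rendered synthetic series through the pipeline
#'
#' Convenience wrapper around [run_pipeline()] for the output of
#' [render_frames()].
#'
#' @param series output of [render_frames()].
#' @param config a [pipeline_config()].
#' @return see [run_pipeline()].
#' @export
run_pipeline_series <- function(series, config = pipeline_config()) {
  run_pipeline(series$frames, series$backgrounds, series$A,
               series$angles_deg, series$geometry, series$cell, config)
}

#' Named step-omission variants of a configuration
#'
#' @param config the standard [pipeline_config()].
#' @param which variant names among `"standard"`, `"no_background"`,
#'   `"no_polarization"`, `"no_variance_removal"`, `"no_solid_angle"`,
#'   `"no_absorption"`, `"no_parallax"`, or `"scale_<method>"`.
#' @return named list of configurations.
#' @export
pipeline_variants <- function(config = pipeline_config(),
                              which = c("standard", "no_background",
                                        "no_polarization",
                                        "no_variance_removal")) {
  make <- function(nm) {
    cfg <- config
    if (nm == "standard") {
    } else if (nm == "no_background") cfg$background_subtraction <- FALSE
    else if (nm == "no_polarization") cfg$polarization <- FALSE
    else if (nm == "no_variance_removal") cfg$variance_removal <- FALSE
    else if (nm == "no_solid_angle") cfg$solid_angle <- FALSE
    else if (nm == "no_absorption") cfg$absorption <- FALSE
    else if (nm == "no_parallax") cfg$parallax <- FALSE
    else if (startsWith(nm, "scale_"))
      cfg$scale_method <- sub("^scale_", "", nm)
    else stop("unknown pipeline variant: ", nm)
    cfg
  }
  stats::setNames(lapply(which, make), which)
}

#' Ablation / scale-factor study
#'
#' Runs every configuration variant on every dataset, computes
#' CC_Friedel, CC_Laue, CC_1/2 per dataset and CC_Rep across datasets, and
#' tabulates values for the standard pipeline with deltas for each
#' variant.
#'
#' @param series_list list of rendered datasets ([render_frames()]
#'   outputs); at least two for CC_Rep.
#' @param config the standard configuration.
#' @param which variant names (see [pipeline_variants()]).
#' @return data.frame with columns `variant`, `dataset`, the metric
#'   values, and their deltas relative to the standard pipeline.
#' @export
ablation_matrix <- function(series_list, config = pipeline_config(),
                            which = c("standard", "no_background",
                                      "no_polarization",
                                      "no_variance_removal")) {
  stopifnot(length(series_list) >= 2)
  variants <- pipeline_variants(config, which)
  shells <- shell_scheme(config$d_min, config$n_shells)
  rows <- list()
  for (vn in names(variants)) {
    runs <- lapply(series_list, run_pipeline_series,
                   config = variants[[vn]])
    for (i in seq_along(runs)) {
      reps <- lapply(runs[-i], function(r) r$laue_anisotropic)
      rep_cc <- cc_rep(runs[[i]]$laue_anisotropic, reps, shells)$overall
      m <- runs[[i]]$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        variant = vn, dataset = i, cc_friedel = m$cc_friedel,
        cc_laue = m$cc_laue, cc_half = m$cc_half, cc_rep = rep_cc)
    }
  }
  out <- do.call(rbind, rows)
  std <- out[out$variant == "standard", ]
  for (col in c("cc_friedel", "cc_laue", "cc_half", "cc_rep")) {
    out[[paste0("d_", col)]] <-
      out[[col]] - std[[col]][match(out$dataset, std$dataset)]
  }
  out
}
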
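#' Simulation configuration for synthetic BOLD cohorts
#'
#' Defines the study conditions the generator emulates: two groups of 27
#' subjects, 240 volumes at TR = 2 s on a 24x24x24 grid of 3 mm voxels,
#' band-limited (0.01-0.1 Hz) network signals shared within regions of
#' interest (producing long-range connectivity), spatially smoothed local
#' noise (producing short-range connectivity), AR(1) noise plus a linear
#' drift, random-walk motion traces, and clinical scores linearly linked to
#' each patient's planted effect magnitude.
#'
#' Planted group effects: patients receive reduced network coupling inside
#' one ROI (a long-range FCD decrease), reduced local gain in one spherical
#' region (a short-range FCD decrease) and raised local gain in another (a
#' short-range FCD increase). Per-patient severity scales all three and
#' drives the clinical scores.
#'
#' @param grid_shape voxels per axis (length 3)
#' @param voxel_size mm, isotropic
#' @param n_volumes number of volumes acquired (before any discarding)
#' @param tr repetition time, seconds
#' @param n_per_group subjects per group
#' @param network_rois list of ROIs: `list(center = c(i,j,k), radius = mm,
#'   network = id)` with 1-based voxel centers
#' @param lfcd_decrease_roi index into `network_rois` of the ROI where
#'   patients lose network coupling
#' @param sfcd_regions list with `decrease` and `increase` spheres
#'   (`center`, `radius` in mm) where patients' local gain is altered
#' @param local_smoothing_fwhm mm; spatial smoothing of the local noise
#'   field, controls how fast short-range correlation decays with distance
#' @param coupling_strength named vector (control, patient): baseline
#'   correlation-scale coupling of ROI voxels to their network signal
#' @param local_gain named vector (control, patient): baseline amplitude of
#'   the smoothed local field relative to unit-variance signals
#' @param effects list: `lfcd_deficit`, `sfcd_deficit`, `sfcd_boost`
#'   (fractional changes applied to patients inside the planted regions),
#'   `severity_mean`, `severity_sd` (per-patient severity distribution)
#' @param noise_ar1 lag-1 autocorrelation of the voxel noise, in \[0, 1)
#' @param drift_slope linear drift, signal units per volume
#' @param snr amplitude ratio of unit-variance signal to the white-noise
#'   innovation (noise sd = 1/snr)
#' @param band passband in Hz for the network signals
#' @param n_sinusoids sinusoids summed per network signal
#' @param motion_scale baseline random-walk step scale for motion traces
#' @param clinical_model per-metric linear models
#'   `list(metric = list(patient = list(intercept, slope, noise), control =
#'   ..., range = c(lo, hi)))`; `slope` multiplies the subject's planted
#'   severity
#' @param seed integer RNG seed
#' @return an object of class `sim_config`
#' @export
sim_config <- function(grid_shape = c(24, 24, 24),
                       voxel_size = 3,
                       n_volumes = 240,
                       tr = 2,
                       n_per_group = 27,
                       network_rois = NULL,
                       lfcd_decrease_roi = 1L,
                       sfcd_regions = NULL,
                       local_smoothing_fwhm = 8,
                       coupling_strength = c(control = 0.7, patient = 0.7),
                       local_gain = c(control = 0.6, patient = 0.6),
                       effects = list(lfcd_deficit = 0.8, sfcd_deficit = 0.6,
                                      sfcd_boost = 1.0,
                                      severity_mean = 1, severity_sd = 0.15),
                       noise_ar1 = 0.3,
                       drift_slope = 0.02,
                       snr = 1.4,
                       band = c(0.01, 0.1),
                       n_sinusoids = 8L,
                       motion_scale = 0.02,
                       clinical_model = NULL,
                       seed = 1L) {
  grid_shape <- as.integer(rep(grid_shape, length.out = 3))
  stopifnot(all(grid_shape > 0), voxel_size > 0, tr > 0,
            n_volumes > 10, n_per_group >= 1,
            noise_ar1 >= 0, noise_ar1 < 1, snr > 0,
            all(coupling_strength >= 0), all(coupling_strength <= 1),
            band[1] >= 0, band[1] < band[2], band[2] <= 1 / (2 * tr))
  if (is.null(network_rois)) {
    sc <- grid_shape / 24  # scale default ROI layout with the grid
    network_rois <- list(
      list(center = round(c(7, 12, 12) * sc), radius = 6, network = 1L),
      list(center = round(c(18, 12, 12) * sc), radius = 6, network = 1L),
      list(center = round(c(12, 7, 16) * sc), radius = 6, network = 2L),
      list(center = round(c(12, 18, 16) * sc), radius = 6, network = 2L)
    )
  }
  if (is.null(sfcd_regions)) {
    sc <- grid_shape / 24
    sfcd_regions <- list(
      decrease = list(center = round(c(12, 12, 7) * sc), radius = 7.5),
      increase = list(center = round(c(12, 12, 18) * sc), radius = 7.5)
    )
  }
  if (is.null(clinical_model)) clinical_model <- default_clinical_model()
  structure(list(
    grid_shape = grid_shape, voxel_size = voxel_size,
    n_volumes = as.integer(n_volumes), tr = tr,
    n_per_group = as.integer(n_per_group),
    network_rois = network_rois,
    lfcd_decrease_roi = as.integer(lfcd_decrease_roi),
    sfcd_regions = sfcd_regions,
    local_smoothing_fwhm = local_smoothing_fwhm,
    coupling_strength = coupling_strength,
    local_gain = local_gain,
    effects = effects,
    noise_ar1 = noise_ar1, drift_slope = drift_slope, snr = snr,
    band = band, n_sinusoids = as.integer(n_sinusoids),
    motion_scale = motion_scale,
    clinical_model = clinical_model,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Cohort-level score models. Intercepts/noise emulate a chronic-insomnia
# cohort and matched good-sleeper controls; slopes tie patient scores to the
# planted severity so correlation recovery is testable.
default_clinical_model <- function() {
  list(
    PSQI   = list(patient = list(intercept = 0,    slope = 13.3, noise = 1.5),
                  control = list(intercept = 0.9,  slope = 0,    noise = 1.0),
                  range = c(0, 21)),
    STAI_s = list(patient = list(intercept = 28.1, slope = 0,    noise = 4.2),
                  control = list(intercept = 26.2, slope = 0,    noise = 8.1),
                  range = c(20, 80)),
    STAI_t = list(patient = list(intercept = 32.3, slope = 0,    noise = 4.8),
                  control = list(intercept = 29.1, slope = 0,    noise = 10.0),
                  range = c(20, 80)),
    BDI_II = list(patient = list(intercept = 6.2,  slope = 0,    noise = 5.3),
                  control = list(intercept = 4.9,  slope = 0,    noise = 1.6),
                  range = c(0, 63)),
    duration = list(patient = list(intercept = 2.5, slope = 8.5, noise = 4.0),
                    control = NULL,
                    range = c(0.25, 40))
  )
}

#' Ellipsoidal gray-matter mask inscribed in the grid
#'
#' A compact, brain-like mask used for synthetic cohorts: the axis-aligned
#' ellipsoid with semi-axes (shape - 1)/2 voxels, centered in the grid.
#'
#' @param grid_shape voxels per axis
#' @return 3D logical array
#' @export
gm_ellipsoid_mask <- function(grid_shape) {
  grid_shape <- rep(grid_shape, length.out = 3)
  ctr <- (grid_shape + 1) / 2
  semi <- pmax((grid_shape - 1) / 2, 0.5)
  i <- slice.index(array(0, grid_shape), 1)
  j <- slice.index(array(0, grid_shape), 2)
  k <- slice.index(array(0, grid_shape), 3)
  ((i - ctr[1]) / semi[1])^2 + ((j - ctr[2]) / semi[2])^2 +
    ((k - ctr[3]) / semi[3])^2 <= 1
}

#' Spherical ROI mask in voxel space
#' @param grid_shape voxels per axis
#' @param center 1-based voxel center (length 3)
#' @param radius_mm sphere radius in mm
#' @param voxel_size mm per voxel
#' @return 3D logical array
#' @export
roi_sphere_mask <- function(grid_shape, center, radius_mm, voxel_size = 3) {
  grid_shape <- rep(grid_shape, length.out = 3)
  i <- slice.index(array(0, grid_shape), 1)
  j <- slice.index(array(0, grid_shape), 2)
  k <- slice.index(array(0, grid_shape), 3)
  d2 <- ((i - center[1])^2 + (j - center[2])^2 + (k - center[3])^2) *
    voxel_size^2
  d2 <= radius_mm^2
}

#' Band-limited network signal
#'
#' Sum of `n_sinusoids` sinusoids with frequencies drawn uniformly in the
#' passband and uniform random phases, standardized to zero mean and unit
#' variance. Exactly band-limited by construction.
#'
#' @param n_volumes length of the series
#' @param tr sampling interval, seconds
#' @param band passband in Hz
#' @param n_sinusoids number of summed sinusoids
#' @return numeric vector of length `n_volumes`
#' @export
bandlimited_signal <- function(n_volumes, tr, band = c(0.01, 0.1),
                               n_sinusoids = 8L) {
  t_sec <- (seq_len(n_volumes) - 1) * tr
  f <- stats::runif(n_sinusoids, band[1], band[2])
  ph <- stats::runif(n_sinusoids, 0, 2 * pi)
  s <- rowSums(sapply(seq_len(n_sinusoids),
                      function(m) sin(2 * pi * f[m] * t_sec + ph[m])))
  (s - mean(s)) / stats::sd(s)
}

#' Random-walk head-motion trace
#'
#' Six rigid-body parameters (3 translations in mm, 3 rotations in radians)
#' as independent random walks whose step scale is proportional to
#' `severity`; severity 0 yields the all-zero trace.
#'
#' @param config a [sim_config()]
#' @param severity nonnegative scalar scaling the walk
#' @return numeric matrix (volumes x 6), columns tx, ty, tz, rx, ry, rz
#' @export
generate_motion <- function(config, severity = 1) {
  stopifnot(severity >= 0)
  n <- config$n_volumes
  step_t <- config$motion_scale * severity
  step_r <- config$motion_scale / 50 * severity  # radians: ~mm/50 at R=80mm
  m <- cbind(
    matrix(stats::rnorm(n * 3, 0, 1), n, 3) * step_t,
    matrix(stats::rnorm(n * 3, 0, 1), n, 3) * step_r
  )
  m <- apply(m, 2, cumsum)
  m <- matrix(m, n, 6)
  if (severity == 0) m[] <- 0
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

clip <- function(x, range) pmin(pmax(x, range[1]), range[2])

draw_clinical <- function(model, group, magnitude) {
  sapply(names(model), function(metric) {
    spec <- model[[metric]][[group]]
    if (is.null(spec)) return(rep(NA_real_, length(magnitude)))
    v <- spec$intercept + spec$slope * magnitude +
      stats::rnorm(length(magnitude), 0, spec$noise)
    round(clip(v, model[[metric]]$range), 2)
  })
}

#' Generate a synthetic two-group BOLD cohort
#'
#' Produces, deterministically for a given config and seed, a full cohort:
#' per-subject 4D BOLD series and motion traces, a cohort table with group
#' labels, demographics and clinical scores, the ground-truth planted-effect
#' masks, and the gray-matter mask. See [sim_config()] for the signal model.
#'
#' @param config a [sim_config()]
#' @return list with elements `subjects` (list of `list(bold, motion)`),
#'   `cohort` (data.frame), `truth` (planted masks, effect sizes and
#'   per-subject severities), `mask` (3D logical), `affine` (4x4) and
#'   `config`
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gs <- config$grid_shape
  affine <- default_affine(gs, config$voxel_size)
  mask <- gm_ellipsoid_mask(gs)

  for (r in seq_along(config$network_rois)) {
    ctr <- config$network_rois[[r]]$center
    if (any(ctr < 1) || any(ctr > gs))
      stop(sprintf("network ROI %d center (%s) lies outside the %s grid",
                   r, paste(ctr, collapse = ","),
                   paste(gs, collapse = "x")))
  }

  roi_masks <- lapply(config$network_rois, function(roi)
    roi_sphere_mask(gs, roi$center, roi$radius, config$voxel_size) & mask)
  truth_masks <- list(
    lfcd_decrease = roi_masks[[config$lfcd_decrease_roi]],
    sfcd_decrease = roi_sphere_mask(gs, config$sfcd_regions$decrease$center,
                                    config$sfcd_regions$decrease$radius,
                                    config$voxel_size) & mask,
    sfcd_increase = roi_sphere_mask(gs, config$sfcd_regions$increase$center,
                                    config$sfcd_regions$increase$radius,
                                    config$voxel_size) & mask
  )

  n <- config$n_per_group
  groups <- rep(c("patient", "control"), each = n)
  n_total <- 2L * n

  # cohort-level draws on the base stream
  set.seed(subject_seed(config$seed, 0L))
  severity <- ifelse(
    groups == "patient",
    pmax(stats::rnorm(n_total, config$effects$severity_mean,
                      config$effects$severity_sd), 0),
    0
  )
  age <- round(ifelse(groups == "patient",
                      stats::rnorm(n_total, 42.6, 11.6),
                      stats::rnorm(n_total, 40.9, 11.5)))
  age <- clip(age, c(18, 70))
  n_f <- round(17 / 27 * n)
  gender <- unlist(lapply(1:2, function(g)
    sample(c(rep("F", n_f), rep("M", n - n_f)))))
  clin <- draw_clinical(config$clinical_model, "patient", severity)
  clin_c <- draw_clinical(config$clinical_model, "control", severity)
  clin[groups == "control", ] <- clin_c[groups == "control", ]
  motion_sev <- stats::rlnorm(n_total, meanlog = 0, sdlog = 0.3)

  cohort <- data.frame(
    subject = sprintf("sub-%03d", seq_len(n_total)),
    group = groups, age = age, gender = gender,
    clin, mean_fd = NA_real_,
    stringsAsFactors = FALSE
  )
  cohort$duration[groups == "control"] <- NA_real_

  subjects <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    set.seed(subject_seed(config$seed, i))
    subjects[[i]] <- list(
      bold = simulate_subject(config, groups[i], severity[i], roi_masks,
                              truth_masks, affine),
      motion = generate_motion(config, motion_sev[i])
    )
  }

  list(
    subjects = subjects,
    cohort = cohort,
    truth = list(masks = truth_masks,
                 effects = config$effects[c("lfcd_deficit", "sfcd_deficit",
                                            "sfcd_boost")],
                 severity = stats::setNames(severity, cohort$subject)),
    mask = mask, affine = affine, config = config
  )
}

# One subject's 4D series: network signals mixed into ROI voxels at the
# group's coupling, a spatially smoothed local field at the group's local
# gain, AR(1) noise, linear drift and a constant baseline.
simulate_subject <- function(config, group, severity, roi_masks, truth_masks,
                             affine) {
  gs <- config$grid_shape
  nt <- config$n_volumes
  nv <- prod(gs)

  net_ids <- sort(unique(vapply(config$network_rois, `[[`, 1L, "network")))
  net <- sapply(net_ids, function(id)
    bandlimited_signal(nt, config$tr, config$band, config$n_sinusoids))
  colnames(net) <- as.character(net_ids)

  coupling <- numeric(nv)
  base_c <- unname(config$coupling_strength[group])
  for (r in seq_along(config$network_rois)) {
    cc <- base_c
    if (group == "patient" && r == config$lfcd_decrease_roi)
      cc <- base_c * max(0, 1 - config$effects$lfcd_deficit * severity)
    vox <- which(roi_masks[[r]])
    coupling[vox] <- cc
  }
  net_of <- integer(nv)
  for (r in seq_along(config$network_rois))
    net_of[which(roi_masks[[r]])] <-
      match(config$network_rois[[r]]$network, net_ids)

  gain <- rep(unname(config$local_gain[group]), nv)
  if (group == "patient") {
    gain[which(truth_masks$sfcd_decrease)] <-
      gain[which(truth_masks$sfcd_decrease)] *
      max(0, 1 - config$effects$sfcd_deficit * severity)
    gain[which(truth_masks$sfcd_increase)] <-
      gain[which(truth_masks$sfcd_increase)] *
      (1 + config$effects$sfcd_boost * severity)
  }

  # smoothed local field, standardized to unit global sd
  local <- array(stats::rnorm(nv * nt), c(gs, nt))
  if (config$local_smoothing_fwhm > 0) {
    sigma <- config$local_smoothing_fwhm / FWHM_TO_SIGMA
    for (t in seq_len(nt))
      local[, , , t] <- smooth3d_raw(local[, , , t], sigma, affine)
  }
  local <- local / stats::sd(local)
  lm_mat <- matrix(local, nv, nt)  # voxels x time

  innov <- matrix(stats::rnorm(nt * nv), nt, nv)
  if (config$noise_ar1 > 0) {
    e <- stats::filter(innov, config$noise_ar1, method = "recursive")
    innov <- matrix(as.numeric(e), nt, nv) * sqrt(1 - config$noise_ar1^2)
  }

  y <- t(lm_mat) * rep(gain, each = nt) + innov / config$snr
  has_net <- which(coupling > 0 & net_of > 0)
  if (length(has_net))
    y[, has_net] <- y[, has_net] +
      net[, net_of[has_net], drop = FALSE] *
      rep(coupling[has_net], each = nt)
  y <- y + config$drift_slope * (seq_len(nt) - 1) + 100

  bold_series(array(t(y), c(gs, nt)), affine, config$tr)
}

#' Write a generated cohort to disk
#'
#' BOLD as 4D NIfTI-1, gray-matter and ground-truth masks as 3D NIfTI-1,
#' motion as 6-column whitespace-delimited text, the cohort table as TSV,
#' and the planted effect sizes as a JSON manifest.
#'
#' @param cohort_obj result of [generate_cohort()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort_obj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti(array(as.numeric(cohort_obj$mask), dim(cohort_obj$mask)),
              cohort_obj$affine, file.path(dir, "gm_mask.nii"))
  for (nm in names(cohort_obj$truth$masks))
    write_nifti(array(as.numeric(cohort_obj$truth$masks[[nm]]),
                      dim(cohort_obj$mask)),
                cohort_obj$affine,
                file.path(dir, sprintf("truth_%s.nii", nm)))
  jsonlite::write_json(
    list(effects = cohort_obj$truth$effects,
         severity = as.list(cohort_obj$truth$severity)),
    file.path(dir, "truth_effects.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(cohort_obj$cohort, file.path(dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_along(cohort_obj$subjects)) {
    id <- cohort_obj$cohort$subject[i]
    write_bold(cohort_obj$subjects[[i]]$bold,
               file.path(dir, sprintf("%s_bold.nii", id)))
    utils::write.table(cohort_obj$subjects[[i]]$motion,
                       file.path(dir, sprintf("%s_motion.txt", id)),
                       sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
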
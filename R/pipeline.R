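#' Pipeline configuration
#'
#' Bundles the per-stage configurations of a full run: simulation, temporal
#' preprocessing, FCD mapping, group inference and seed-based connectivity,
#' plus stage skip flags and the global seed. Every stage writes a JSON
#' sidecar with its resolved parameters when an output directory is given.
#'
#' @param sim a [sim_config()]
#' @param n_discard leading volumes to drop
#' @param band band-pass edges, Hz
#' @param fcd an [fcd_config()]
#' @param alphasim an [alphasim_config()]
#' @param seed_p_thresh adjusted-p threshold for the one-sample seed maps
#' @param skip named logical flags: `group`, `seed` (simulation,
#'   preprocessing and FCD always run unless inputs are supplied)
#' @param seed global RNG seed; per-stage streams are derived from it
#' @return object of class `run_config`
#' @export
run_config <- function(sim = sim_config(),
                       n_discard = 10,
                       band = c(0.01, 0.1),
                       fcd = fcd_config(),
                       alphasim = alphasim_config(),
                       seed_p_thresh = 0.001,
                       skip = c(group = FALSE, seed = FALSE),
                       seed = 1L) {
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, n_discard = n_discard, band = band,
                 fcd = fcd, alphasim = alphasim,
                 seed_p_thresh = seed_p_thresh, skip = skip,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Cohort summary table (demographics and clinical scores by group)
#'
#' Per metric: group means and SDs with the pooled two-sample t and its p
#' value; gender as F/M counts with a chi-square test. Reproduces the
#' layout of a standard demographics table.
#'
#' @param cohort cohort data.frame (group, age, gender, clinical columns,
#'   mean_fd)
#' @return data.frame with one row per metric
#' @export
cohort_summary <- function(cohort) {
  pat <- cohort$group == "patient"
  metrics <- intersect(c("age", "PSQI", "STAI_s", "STAI_t", "BDI_II",
                         "duration", "mean_fd"), names(cohort))
  rows <- lapply(metrics, function(m) {
    x <- cohort[[m]][pat]; y <- cohort[[m]][!pat]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(y) < 2 || length(x) < 2) {
      return(data.frame(metric = m, patient_mean = mean(x),
                        patient_sd = stats::sd(x),
                        control_mean = NA_real_, control_sd = NA_real_,
                        t = NA_real_, p = NA_real_))
    }
    tt <- two_sample_t_summary(mean(x), stats::sd(x), length(x),
                               mean(y), stats::sd(y), length(y))
    data.frame(metric = m, patient_mean = mean(x), patient_sd = stats::sd(x),
               control_mean = mean(y), control_sd = stats::sd(y),
               t = tt$t, p = tt$p)
  })
  out <- do.call(rbind, rows)
  tab <- table(factor(cohort$gender, c("F", "M")), cohort$group)
  chi <- chi_square_2x2(matrix(as.numeric(tab), 2, 2))
  attr(out, "gender") <- list(counts = tab, statistic = chi$statistic,
                              p = chi$p)
  out
}

#' Run the full synthetic-cohort pipeline
#'
#' simulate -> preprocess -> FCD -> group inference (sFCD and lFCD) ->
#' clinical correlations -> seed-based connectivity from the surviving
#' long-range clusters. Deterministic for a fixed config: identical seeds
#' give identical reports.
#'
#' @param config a [run_config()]
#' @param out_dir optional directory for NIfTI/TSV/JSON outputs; NULL
#'   keeps everything in memory
#' @param verbose print stage progress
#' @return a `run_report` list: `cohort` (with mean FD filled in),
#'   `summary` (cohort summary), `fcd_tables` (cluster tables for sFCD and
#'   lFCD), `correlations` (region x metric partial correlations),
#'   `seed_tables` (per-seed difference cluster tables), `extent`
#'   (AlphaSim result), `dice` (overlap of surviving clusters with the
#'   planted ground-truth regions), `truth`, `provenance`
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("simulate: %d+%d subjects", config$sim$n_per_group,
      config$sim$n_per_group)
  cohort_obj <- generate_cohort(config$sim)
  mask <- cohort_obj$mask
  affine <- cohort_obj$affine
  cohort <- cohort_obj$cohort
  n_sub <- nrow(cohort)

  say("preprocess + fcd")
  pre <- vector("list", n_sub)
  fcd_list <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    p <- preprocess_bold(cohort_obj$subjects[[i]]$bold,
                         cohort_obj$subjects[[i]]$motion,
                         n_discard = config$n_discard,
                         low = config$band[1], high = config$band[2])
    cohort$mean_fd[i] <- p$fd$mean_fd
    pre[[i]] <- p$series
    fcd_list[[i]] <- fcd_products(compute_fcd(p$series, mask, config$fcd))
  }

  report <- list(cohort = cohort, summary = cohort_summary(cohort),
                 truth = cohort_obj$truth,
                 provenance = list(seed = config$seed,
                                   grid = config$sim$grid_shape,
                                   n_volumes = config$sim$n_volumes,
                                   n_per_group = config$sim$n_per_group,
                                   r0 = config$fcd$r0,
                                   cutoff_mm = config$fcd$cutoff_mm,
                                   started = format(t0)))

  if (!isTRUE(config$skip["group"])) {
    say("group inference")
    design <- build_design(cohort)
    set.seed(subject_seed(config$seed, 900000L))
    extent <- alphasim_extent(mask, affine, config$alphasim)
    groups <- cohort$group
    fcd_tables <- list()
    statmaps <- list()
    region_values <- list()
    surv <- list()  # union of surviving cluster voxels per measure/sign
    for (measure in c("sfcd", "lfcd")) {
      zfield <- if (measure == "sfcd") "z_short_sm" else "z_long_sm"
      nfield <- if (measure == "sfcd") "norm_short" else "norm_long"
      zmaps <- lapply(fcd_list, `[[`, zfield)
      nmaps <- lapply(fcd_list, `[[`, nfield)
      statmap <- fit_voxel_glm(zmaps, design, mask)
      clusters <- label_clusters(statmap, config$alphasim$voxel_p,
                                 config$alphasim$rmm, affine)
      tab <- cluster_report(clusters, statmap, nmaps, groups, affine,
                            extent$k_min)
      fcd_tables[[measure]] <- tab
      statmaps[[measure]] <- statmap
      keep <- Filter(function(cl) cl$size >= extent$k_min, clusters)
      for (j in seq_along(keep))
        region_values[[sprintf("%s_%s", measure, tab$label[j])]] <-
          vapply(nmaps, function(m) mean(m[keep[[j]]$voxels]), 1.0)
      for (sgn in c(1L, -1L)) {
        vox <- unlist(lapply(Filter(function(cl) cl$sign == sgn, keep),
                             `[[`, "voxels"))
        surv[[sprintf("%s_%s", measure, if (sgn > 0) "pos" else "neg")]] <-
          vox %||% integer(0)
      }
    }
    report$fcd_tables <- fcd_tables
    report$extent <- extent
    # overlap of surviving clusters with the planted ground-truth regions
    dice_with <- function(vox, truth_mask) {
      m <- array(FALSE, dim(mask)); m[vox] <- TRUE
      2 * sum(m & truth_mask) / max(sum(m) + sum(truth_mask), 1)
    }
    report$dice <- list(
      lfcd_decrease = dice_with(surv$lfcd_neg,
                                cohort_obj$truth$masks$lfcd_decrease),
      sfcd_decrease = dice_with(surv$sfcd_neg,
                                cohort_obj$truth$masks$sfcd_decrease),
      sfcd_increase = dice_with(surv$sfcd_pos,
                                cohort_obj$truth$masks$sfcd_increase))

    metrics <- intersect(c("PSQI", "STAI_s", "STAI_t", "BDI_II", "duration"),
                         names(cohort))
    if (length(region_values)) {
      pat <- cohort$group == "patient"
      rv <- as.data.frame(region_values)[pat, , drop = FALSE]
      mt <- cohort[pat, metrics, drop = FALSE]
      cv <- data.frame(age = cohort$age[pat],
                       gender = as.numeric(cohort$gender[pat] == "M"))
      report$correlations <- clinical_correlations(rv, mt, cv)
    } else {
      report$correlations <- NULL
    }

    if (!isTRUE(config$skip["seed"])) {
      say("seed connectivity")
      lkeep <- Filter(function(cl) cl$size >= extent$k_min,
                      label_clusters(statmaps$lfcd, config$alphasim$voxel_p,
                                     config$alphasim$rmm, affine))
      seed_tables <- list()
      for (j in seq_along(lkeep)) {
        seed_mask <- array(FALSE, dim(mask))
        seed_mask[lkeep[[j]]$voxels] <- TRUE
        zmaps <- lapply(pre, function(s)
          ifc_map(s, seed_timecourse(s, seed_mask), mask)$z)
        gd <- group_difference_ifc(zmaps, design, mask, affine,
                                   config$alphasim, extent = extent)
        seed_tables[[sprintf("lfcd_seed_%02d", j)]] <- gd$table
      }
      report$seed_tables <- seed_tables
    }
  }

  report$provenance$wall_seconds <-
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "run_report"

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  cohort: %d subjects\n", nrow(x$cohort)))
  if (!is.null(x$fcd_tables))
    for (m in names(x$fcd_tables))
      cat(sprintf("  %s clusters: %d\n", m, nrow(x$fcd_tables[[m]])))
  invisible(x)
}

#' Write a run report to disk
#' @param report a `run_report`
#' @param dir output directory
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$cohort, file.path(dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$summary, file.path(dir, "cohort_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$fcd_tables))
    for (m in names(report$fcd_tables))
      utils::write.table(report$fcd_tables[[m]],
                         file.path(dir, sprintf("clusters_%s.tsv", m)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$correlations))
    utils::write.table(report$correlations,
                       file.path(dir, "clinical_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$seed_tables))
    for (m in names(report$seed_tables))
      utils::write.table(report$seed_tables[[m]],
                         file.path(dir, sprintf("ifc_%s.tsv", m)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$extent))
    jsonlite::write_json(
      list(k_min = report$extent$k_min,
           null_max_sizes = report$extent$null_max_sizes,
           config = unclass(report$extent$config)),
      file.path(dir, "alphasim.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
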
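#' Build the group-comparison design matrix
#'
#' Intercept, a patient-vs-control indicator, and mean-centered covariates
#' (age, gender coded 0/1, mean frame-wise displacement). The group
#' coefficient then estimates the adjusted patient - control difference.
#'
#' @param cohort data.frame with columns `group` ("patient"/"control") and
#'   optionally `age`, `gender` ("F"/"M"), `mean_fd`
#' @param covariates character vector of covariate columns to include
#' @return numeric matrix (subjects x columns) with attribute
#'   `"group_col"` naming the contrast column
#' @export
build_design <- function(cohort,
                         covariates = c("age", "gender", "mean_fd")) {
  stopifnot(all(cohort$group %in% c("patient", "control")))
  g <- as.numeric(cohort$group == "patient")
  X <- cbind(intercept = 1, group = g)
  for (cv in covariates) {
    if (!cv %in% names(cohort)) next
    v <- cohort[[cv]]
    if (cv == "gender") v <- as.numeric(v == "M")
    v <- as.numeric(v)
    X <- cbind(X, scale(v, scale = FALSE)[, 1])
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop(sprintf("design matrix is rank deficient (collinear: %s)",
                 paste(bad, collapse = ", ")))
  }
  attr(X, "group_col") <- "group"
  X
}

#' Voxel-wise general linear model for a group contrast
#'
#' Ordinary least squares at every mask voxel of the per-subject maps on
#' the design matrix; returns the t statistic and two-tailed p-value of
#' the group coefficient at df = n - rank(design). With no covariates this
#' reduces exactly to the two-sample pooled-variance t test.
#'
#' @param maps list of per-subject 3D arrays (one per design row), or a
#'   subjects x voxels matrix over the mask
#' @param design matrix from [build_design()]
#' @param mask 3D logical mask
#' @return object of class `stat_map`: `t` and `p` 3D arrays (0 / 1
#'   outside the mask), `beta` (group-coefficient array), `df`, `mask`
#' @export
fit_voxel_glm <- function(maps, design, mask) {
  vox <- which(mask != 0)
  Y <- if (is.matrix(maps)) maps
       else t(vapply(maps, function(m) m[vox], numeric(length(vox))))
  n <- nrow(design)
  stopifnot(nrow(Y) == n, n >= 4)
  gcol <- which(colnames(design) == (attr(design, "group_col") %||% "group"))
  XtXi <- solve(crossprod(design))
  beta <- XtXi %*% crossprod(design, Y)
  res <- Y - design %*% beta
  df <- n - qr(design)$rank
  rss <- colSums(res^2)
  rss[rss < 1e-12 * pmax(colSums(Y^2), 1)] <- 0  # numerically exact fits
  sigma2 <- rss / df
  se <- sqrt(sigma2 * XtXi[gcol, gcol])
  tstat <- ifelse(se > 0, beta[gcol, ] / se, 0)
  pval <- 2 * stats::pt(-abs(tstat), df)
  tm <- array(0, dim(mask)); tm[vox] <- tstat
  pm <- array(1, dim(mask)); pm[vox] <- pval
  bm <- array(0, dim(mask)); bm[vox] <- beta[gcol, ]
  structure(list(t = tm, p = pm, beta = bm, df = df, mask = mask != 0),
            class = "stat_map")
}

#' AlphaSim configuration
#'
#' Parameters of the Monte-Carlo cluster-extent estimation: cluster
#' connectivity radius `rmm` (mm), the smoothness of the simulated noise
#' (`fwhm`, mm -- taken as the smoothing actually applied to the data),
#' iteration count, the voxel-level two-tailed threshold and the corrected
#' alpha level.
#'
#' @param rmm mm; voxels with center distance <= rmm are cluster neighbors
#' @param fwhm mm Gaussian smoothness of the simulated null noise
#' @param iterations Monte-Carlo iterations
#' @param voxel_p two-tailed voxel-level p threshold
#' @param alpha corrected family-wise level
#' @return object of class `alphasim_config`
#' @export
alphasim_config <- function(rmm = 5, fwhm = 6, iterations = 1000L,
                            voxel_p = 0.001, alpha = 0.05) {
  stopifnot(iterations >= 1, voxel_p > 0, voxel_p < 1,
            alpha > 0, alpha < 1, rmm > 0, fwhm >= 0)
  structure(list(rmm = rmm, fwhm = fwhm, iterations = as.integer(iterations),
                 voxel_p = voxel_p, alpha = alpha),
            class = "alphasim_config")
}

#' Estimate the Gaussian smoothness (FWHM) of statistical maps
#'
#' Estimates, from neighboring-voxel correlations within the mask, the
#' FWHM of the Gaussian kernel that would give white noise the observed
#' spatial autocorrelation (the classical difference-variance estimator).
#' Useful when maps carry intrinsic smoothness beyond the applied kernel,
#' so the cluster-extent null can be simulated at the smoothness the data
#' actually have.
#'
#' @param maps list of 3D maps (e.g. per-subject standardized maps or GLM
#'   residual maps)
#' @param mask 3D logical mask
#' @param affine 4x4 voxel-to-world matrix
#' @return estimated FWHM in mm (average over the three axes)
#' @export
estimate_fwhm <- function(maps, mask, affine) {
  vs <- voxel_sizes(affine)
  d <- dim(mask)
  per_axis <- vapply(1:3, function(ax) {
    shift <- c(0, 0, 0); shift[ax] <- 1
    idx <- which(mask != 0, arr.ind = TRUE)
    nb <- sweep(idx, 2, shift, "+")
    ok <- nb[, ax] <= d[ax]
    idx <- idx[ok, , drop = FALSE]; nb <- nb[ok, , drop = FALSE]
    lin_a <- idx[, 1] + (idx[, 2] - 1) * d[1] + (idx[, 3] - 1) * d[1] * d[2]
    lin_b <- nb[, 1] + (nb[, 2] - 1) * d[1] + (nb[, 3] - 1) * d[1] * d[2]
    keep <- mask[lin_b] != 0
    lin_a <- lin_a[keep]; lin_b <- lin_b[keep]
    rho <- mean(vapply(maps, function(m) {
      a <- m[lin_a]; b <- m[lin_b]
      stats::cor(a, b)
    }, 1.0))
    rho <- min(max(rho, 1e-6), 1 - 1e-6)
    sigma_k <- vs[ax] / (2 * sqrt(-log(rho)))
    sigma_k * FWHM_TO_SIGMA
  }, 1.0)
  mean(per_axis)
}

#' Monte-Carlo cluster-extent threshold (AlphaSim)
#'
#' Each iteration fills the grid with unit Gaussian noise, smooths it to
#' `fwhm`, re-standardizes within the mask, thresholds two-tailed at
#' `voxel_p`, labels positive and negative suprathreshold clusters
#' separately under the `rmm` connectivity rule, and records the maximum
#' cluster size over both signs. The extent threshold `k_min` is the
#' smallest size k with P(max cluster >= k) <= alpha under this null.
#'
#' @param mask 3D logical mask
#' @param affine 4x4 voxel-to-world matrix
#' @param config an [alphasim_config()]
#' @return list with `k_min`, `null_max_sizes` (length `iterations`) and
#'   `config`
#' @export
alphasim_extent <- function(mask, affine, config = alphasim_config()) {
  vox <- which(mask != 0)
  stopifnot(length(vox) > 0)
  zcrit <- stats::qnorm(1 - config$voxel_p / 2)
  offsets <- neighbor_offsets(config$rmm, voxel_sizes(affine))
  d <- dim(mask)
  sigma <- config$fwhm / FWHM_TO_SIGMA
  max_sizes <- integer(config$iterations)
  for (it in seq_len(config$iterations)) {
    noise <- array(stats::rnorm(prod(d)), d)
    if (config$fwhm > 0) noise <- smooth3d_raw(noise, sigma, affine)
    v <- noise[vox]
    z <- (v - mean(v)) / stats::sd(v)
    zm <- array(0, d); zm[vox] <- z
    mx <- 0L
    for (sgn in c(1, -1)) {
      flag <- array(FALSE, d)
      flag[vox] <- sgn * z > zcrit
      if (!any(flag)) next
      lab <- label_components(flag, offsets)
      if (max(lab) > 0) mx <- max(mx, max(tabulate(lab[lab > 0])))
    }
    max_sizes[it] <- mx
  }
  tail_p <- vapply(seq_len(max(max_sizes, 1L) + 1L),
                   function(k) mean(max_sizes >= k), 1.0)
  k_min <- which(tail_p <= config$alpha)[1]
  if (is.na(k_min)) k_min <- max(max_sizes) + 1L
  list(k_min = as.integer(k_min), null_max_sizes = max_sizes,
       config = config)
}

#' Label suprathreshold clusters of a statistic map
#'
#' Thresholds |t| at the two-tailed `voxel_p` quantile of the t
#' distribution (df from the map), then groups suprathreshold voxels whose
#' centers lie within `rmm` mm of each other; positive and negative
#' clusters are labeled separately.
#'
#' @param statmap a `stat_map` from [fit_voxel_glm()]
#' @param voxel_p two-tailed voxel-level threshold
#' @param rmm connectivity radius in mm
#' @param affine 4x4 voxel-to-world matrix
#' @return list of clusters, each `list(voxels, size, sign, peak_ijk,
#'   peak_t)`; empty list when nothing survives
#' @export
label_clusters <- function(statmap, voxel_p = 0.001, rmm = 5, affine) {
  tcrit <- stats::qt(1 - voxel_p / 2, statmap$df)
  offsets <- neighbor_offsets(rmm, voxel_sizes(affine))
  out <- list()
  for (sgn in c(1, -1)) {
    flag <- statmap$mask & (sgn * statmap$t > tcrit)
    if (!any(flag)) next
    lab <- label_components(flag, offsets)
    for (l in seq_len(max(lab))) {
      vox <- which(lab == l)
      tv <- statmap$t[vox]
      pk <- vox[which.max(abs(tv))]
      out[[length(out) + 1L]] <- list(
        voxels = vox, size = length(vox), sign = as.integer(sgn),
        peak_ijk = as.integer(arrayInd(pk, dim(statmap$t))),
        peak_t = tv[which.max(abs(tv))])
    }
  }
  out[order(-vapply(out, `[[`, 1L, "size"))]
}

#' Cohen's d standardized mean difference
#'
#' (mean1 - mean2) / pooled SD, pooling variances with the n1 + n2 - 2
#' denominator.
#'
#' @param x,y numeric vectors (>= 2 values each)
#' @return scalar d
#' @export
cohen_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance: effect size undefined")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Pooled two-sample t test from summary statistics
#'
#' Student's pooled-variance t and its two-tailed p-value computed from
#' group means, SDs and sizes, as needed to reproduce demographic
#' comparisons from printed tables.
#'
#' @param mean1,sd1,n1 first group summary
#' @param mean2,sd2,n2 second group summary
#' @return list with `t`, `p`, `df`
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    tval <- if (mean1 == mean2) 0 else stop("zero pooled SD, unequal means")
  } else {
    tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = tval, p = 2 * stats::pt(-abs(tval), df), df = df)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, 1 degree of freedom.
#'
#' @param tab 2x2 matrix of nonnegative counts
#' @return list with `statistic` and `p`
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square undefined: zero margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of x and y after least-squares
#' removal of the covariates (with intercept); the p-value comes from
#' t = rho * sqrt(df / (1 - rho^2)) with df = n - 2 - #covariates.
#'
#' @param x,y numeric vectors
#' @param covariates numeric matrix/data.frame (n rows), or NULL for a
#'   plain Pearson correlation
#' @return list with `rho`, `p`, `df`
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  ok <- stats::complete.cases(x, y,
                              if (is.null(covariates)) rep(TRUE, length(x))
                              else covariates)
  x <- x[ok]; y <- y[ok]
  ncov <- 0L
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)[ok, , drop = FALSE]
    Z <- cbind(1, Z)
    ncov <- ncol(Z) - 1L
    if (length(x) < ncov + 3) stop("too few observations for the covariates")
    x <- stats::lm.fit(Z, x)$residuals
    y <- stats::lm.fit(Z, y)$residuals
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate residuals: zero variance")
  rho <- stats::cor(x, y)
  df <- length(x) - 2L - ncov
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), df), df = df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, capped at 1; invariant to input order.
#'
#' @param pvalues numeric vector of p-values in (0, 1]
#' @return q-values in the input order
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Report surviving clusters
#'
#' Keeps the clusters at or above the extent threshold and summarizes each:
#' size, peak world-mm coordinate, peak t, sign, and Cohen's d computed on
#' the per-subject mean of the normalized (k/k0) map within the cluster
#' (patients vs controls).
#'
#' @param clusters output of [label_clusters()]
#' @param statmap the `stat_map` the clusters came from
#' @param norm_maps list of per-subject 3D normalized maps (k/k0 or Fisher
#'   z), one per cohort row
#' @param groups character vector, "patient"/"control" per subject
#' @param affine 4x4 voxel-to-world matrix
#' @param k_min extent threshold in voxels (from [alphasim_extent()])
#' @return data.frame with one row per surviving cluster (zero rows when
#'   none survive): label, size, peak_x/y/z (mm), peak_t, sign, cohen_d
#' @export
cluster_report <- function(clusters, statmap, norm_maps, groups, affine,
                           k_min) {
  keep <- Filter(function(cl) cl$size >= k_min, clusters)
  empty <- data.frame(label = character(), size = integer(),
                      peak_x = numeric(), peak_y = numeric(),
                      peak_z = numeric(), peak_t = numeric(),
                      sign = integer(), cohen_d = numeric(),
                      stringsAsFactors = FALSE)
  if (length(keep) == 0) return(empty)
  pat <- groups == "patient"
  rows <- lapply(seq_along(keep), function(i) {
    cl <- keep[[i]]
    mm <- voxel_to_mm(matrix(cl$peak_ijk, 1), affine)
    vals <- vapply(norm_maps, function(m) mean(m[cl$voxels]), 1.0)
    d <- if (stats::var(vals[pat]) + stats::var(vals[!pat]) > 0)
      cohen_d(vals[pat], vals[!pat]) else 0
    data.frame(label = sprintf("cluster_%02d", i), size = cl$size,
               peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
               peak_t = cl$peak_t, sign = cl$sign, cohen_d = d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Region-by-metric partial correlations with FDR
#'
#' For each region (a column of `region_values`) and each clinical metric,
#' the partial correlation controlling for the given covariates, with
#' Benjamini-Hochberg q-values computed over the whole region x metric
#' family.
#'
#' @param region_values data.frame/matrix, subjects x regions (e.g. mean
#'   k/k0 per surviving cluster)
#' @param metrics data.frame, subjects x clinical metrics
#' @param covariates data.frame/matrix of covariates (e.g. age, gender
#'   coded numerically)
#' @return data.frame with columns region, metric, rho, p, q
#' @export
clinical_correlations <- function(region_values, metrics, covariates) {
  region_values <- as.data.frame(region_values)
  metrics <- as.data.frame(metrics)
  grid <- expand.grid(region = names(region_values),
                      metric = names(metrics),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- region_values[[grid$region[i]]]
    y <- metrics[[grid$metric[i]]]
    pc <- tryCatch(partial_correlation(x, y, covariates),
                   error = function(e) list(rho = NA_real_, p = NA_real_))
    data.frame(region = grid$region[i], metric = grid$metric[i],
               rho = pc$rho, p = pc$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  out
}
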
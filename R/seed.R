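#' Mean time course of a seed region
#'
#' Unweighted mean across the seed voxels at each volume.
#'
#' @param series a [bold_series()]
#' @param seed 3D logical/0-1 mask
#' @return numeric vector of length n_volumes
#' @export
seed_timecourse <- function(series, seed) {
  stopifnot(inherits(series, "bold_series"))
  vox <- which(seed != 0)
  if (length(vox) == 0) stop("seed mask is empty")
  d <- dim(series$data)
  y <- matrix(series$data, prod(d[1:3]), d[4])[vox, , drop = FALSE]
  colMeans(y)
}

#' Fisher r-to-z transform
#'
#' atanh with |r| clamped to 1 - 1e-7 so seed voxels (r ~ 1) stay finite.
#' Odd and strictly increasing in r.
#'
#' @param r correlations
#' @param clamp bound on |r| before the transform
#' @return z values
#' @export
fisher_z <- function(r, clamp = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clamp), clamp))
}

#' Seed-based intrinsic functional connectivity map
#'
#' Pearson correlation between the seed's mean time course and every mask
#' voxel, plus the Fisher r-to-z transformed map used for group-level
#' statistics.
#'
#' @param series a [bold_series()] (preprocessed)
#' @param seed_series numeric vector (e.g. from [seed_timecourse()])
#' @param mask 3D logical mask
#' @return list with `r` and `z` 3D arrays (0 outside mask)
#' @export
ifc_map <- function(series, seed_series, mask) {
  stopifnot(inherits(series, "bold_series"))
  if (stats::sd(seed_series) == 0) stop("constant seed time course")
  d <- dim(series$data)
  stopifnot(length(seed_series) == d[4])
  vox <- which(mask != 0)
  y <- matrix(series$data, prod(d[1:3]), d[4])[vox, , drop = FALSE]
  y <- y - rowMeans(y)
  nrm <- sqrt(rowSums(y^2))
  s <- seed_series - mean(seed_series)
  s <- s / sqrt(sum(s^2))
  r <- as.numeric(y %*% s)
  r <- ifelse(nrm > 1e-12, r / pmax(nrm, 1e-12), 0)
  rmap <- array(0, d[1:3]); rmap[vox] <- r
  zmap <- array(0, d[1:3]); zmap[vox] <- fisher_z(r)
  list(r = rmap, z = zmap)
}

#' Group-level positive connectivity mask from Fisher z maps
#'
#' One-sample t test across subjects at every mask voxel, two-tailed
#' p-values adjusted by Benjamini-Hochberg FDR over the mask; a voxel
#' enters the mask when its adjusted p falls below `p_thresh` AND the
#' group mean z is positive (negative correlations never define the
#' connectivity pattern).
#'
#' @param z_maps list of per-subject 3D Fisher z arrays
#' @param mask 3D logical mask
#' @param p_thresh adjusted-p threshold
#' @return list with `mask` (3D logical), `t` and `q` arrays
#' @export
group_onesample_map <- function(z_maps, mask, p_thresh = 0.001) {
  stopifnot(length(z_maps) >= 3)
  vox <- which(mask != 0)
  Y <- t(vapply(z_maps, function(m) m[vox], numeric(length(vox))))
  n <- nrow(Y)
  mu <- colMeans(Y)
  se <- sqrt(apply(Y, 2, stats::var) / n)
  tval <- ifelse(se > 0, mu / se, 0)
  p <- 2 * stats::pt(-abs(tval), n - 1)
  q <- bh_fdr(pmax(p, .Machine$double.xmin))
  sel <- q < p_thresh & mu > 0
  out <- array(FALSE, dim(mask)); out[vox] <- sel
  tm <- array(0, dim(mask)); tm[vox] <- tval
  qm <- array(1, dim(mask)); qm[vox] <- q
  list(mask = out, t = tm, q = qm)
}

#' Group difference in seed connectivity
#'
#' Runs the same GLM + Monte-Carlo cluster-extent machinery used for the
#' FCD group comparison on per-subject Fisher z maps: voxel-wise t for the
#' group coefficient (age, gender, mean FD as covariates), cluster labeling
#' at the voxel threshold, AlphaSim extent correction, and a cluster table
#' with Cohen's d of the extracted mean z values.
#'
#' @param z_maps list of per-subject 3D Fisher z arrays
#' @param design matrix from [build_design()]
#' @param mask 3D logical mask
#' @param affine 4x4 voxel-to-world matrix
#' @param alphasim an [alphasim_config()]
#' @param extent optional precomputed [alphasim_extent()] result (reused
#'   across seeds; computed here when NULL)
#' @return list with `statmap`, `clusters`, `extent`, `table` (the
#'   cluster report data.frame)
#' @export
group_difference_ifc <- function(z_maps, design, mask, affine,
                                 alphasim = alphasim_config(),
                                 extent = NULL) {
  statmap <- fit_voxel_glm(z_maps, design, mask)
  if (is.null(extent)) extent <- alphasim_extent(mask, affine, alphasim)
  clusters <- label_clusters(statmap, alphasim$voxel_p, alphasim$rmm, affine)
  groups <- ifelse(design[, "group"] == 1, "patient", "control")
  tab <- cluster_report(clusters, statmap, z_maps, groups, affine,
                        extent$k_min)
  list(statmap = statmap, clusters = clusters, extent = extent, table = tab)
}
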
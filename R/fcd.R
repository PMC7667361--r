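#' FCD configuration
#'
#' Parameters of the thresholded voxel correlation graph: the Pearson
#' correlation threshold defining an edge (strictly greater, positive
#' correlations only), the anatomical distance (mm) separating short-range
#' from long-range connections, and the smoothing kernel applied to the
#' standardized maps.
#'
#' @param r0 correlation threshold; an edge requires r > r0
#' @param cutoff_mm distance cutoff: pairs at center-to-center distance
#'   <= cutoff_mm are short-range, > cutoff_mm long-range
#' @param smooth_fwhm mm FWHM of the Gaussian kernel for Z maps
#' @param block_size voxels per block in the blocked correlation pass
#' @return object of class `fcd_config`
#' @export
fcd_config <- function(r0 = 0.25, cutoff_mm = 12, smooth_fwhm = 6,
                       block_size = 512L) {
  stopifnot(r0 > -1, r0 < 1, cutoff_mm > 0, smooth_fwhm >= 0, block_size >= 1)
  structure(list(r0 = r0, cutoff_mm = cutoff_mm, smooth_fwhm = smooth_fwhm,
                 block_size = as.integer(block_size)),
            class = "fcd_config")
}

#' Voxel-wise short- and long-range FCD counts
#'
#' For every gray-matter voxel i, counts the other mask voxels j whose full
#' time-course Pearson correlation with i exceeds `r0`, split by
#' center-to-center anatomical distance (through the affine) at
#' `cutoff_mm`: `k_short` counts suprathreshold neighbors within the
#' cutoff sphere, `k_long` those beyond it. Only positive correlations
#' above the threshold count as edges. The correlation matrix is evaluated
#' in blocks of `config$block_size` index voxels, so memory stays bounded;
#' the counts are exactly independent of the block size.
#'
#' Voxels with zero temporal variance have undefined correlations; they
#' contribute no edges, stay in the mask with counts of 0, and their number
#' is reported in the result (`n_zero_variance`).
#'
#' @param series a [bold_series()] (preprocessed)
#' @param mask 3D logical/0-1 gray-matter mask on the same grid
#' @param config an [fcd_config()]
#' @return object of class `fcd_maps`: 3D arrays `k_short`, `k_long`
#'   (integer counts, 0 outside the mask), the `mask`, `affine`, `config`,
#'   `n_volumes` and `n_zero_variance`
#' @export
compute_fcd <- function(series, mask, config = fcd_config()) {
  stopifnot(inherits(series, "bold_series"), inherits(config, "fcd_config"))
  d <- dim(series$data)
  stopifnot(all(dim(mask) == d[1:3]))
  if (d[4] < 3) stop("need at least 3 volumes to correlate")
  vox <- which(mask != 0)
  if (length(vox) == 0) stop("mask is empty")
  nv <- length(vox)

  # unit-normalized time courses: correlation becomes a cross product
  y <- matrix(series$data, prod(d[1:3]), d[4])[vox, , drop = FALSE]
  y <- y - rowMeans(y)
  nrm <- sqrt(rowSums(y^2))
  zero_var <- nrm < 1e-12
  nrm[zero_var] <- 1
  y <- y / nrm
  y[zero_var, ] <- 0  # undefined correlations count no edges

  xyz <- voxel_to_mm(arrayInd(vox, d[1:3]), series$affine)
  cut2 <- config$cutoff_mm^2
  ks <- integer(nv)
  kl <- integer(nv)
  starts <- seq(1L, nv, by = config$block_size)
  for (s in starts) {
    idx <- s:min(s + config$block_size - 1L, nv)
    r <- y[idx, , drop = FALSE] %*% t(y)          # block x all correlations
    edge <- r > config$r0
    edge[cbind(seq_along(idx), idx)] <- FALSE     # no self edges
    d2 <- outer(rowSums(xyz[idx, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[idx, , drop = FALSE] %*% t(xyz)
    short <- edge & d2 <= cut2
    ks[idx] <- as.integer(rowSums(short))
    kl[idx] <- as.integer(rowSums(edge & !(d2 <= cut2)))
  }

  k_short <- array(0L, d[1:3]); k_short[vox] <- ks
  k_long <- array(0L, d[1:3]); k_long[vox] <- kl
  structure(list(k_short = k_short, k_long = k_long,
                 mask = mask != 0, affine = series$affine, config = config,
                 n_volumes = d[4], n_zero_variance = sum(zero_var)),
            class = "fcd_maps")
}

#' @export
print.fcd_maps <- function(x, ...) {
  cat(sprintf(
    "<fcd_maps> %d mask voxels, r0 = %g, cutoff = %g mm; mean k_short = %.2f, mean k_long = %.2f\n",
    sum(x$mask), x$config$r0, x$config$cutoff_mm,
    mean(x$k_short[x$mask]), mean(x$k_long[x$mask])))
  invisible(x)
}

#' Z-standardize a count map within a mask
#'
#' z = (k - mean) / sd over mask voxels, with the population (n
#' denominator) standard deviation; voxels outside the mask are set to 0.
#'
#' @param k_map 3D numeric array
#' @param mask 3D logical mask
#' @return 3D array with mask mean 0 and mask SD 1
#' @export
zscore_map <- function(k_map, mask) {
  v <- k_map[mask != 0]
  mu <- mean(v)
  sdev <- sqrt(mean((v - mu)^2))
  if (sdev <= 0) stop("degenerate map: zero variance within the mask")
  out <- array(0, dim(k_map))
  out[mask != 0] <- (v - mu) / sdev
  out
}

#' Normalize a count map by its whole-mask mean
#'
#' Returns k/k0 where k0 is the mean count over the mask; the normalized
#' map has mask mean exactly 1. Used for ROI extraction, effect sizes and
#' clinical correlations.
#'
#' @param k_map 3D numeric array
#' @param mask 3D logical mask
#' @return list with `norm` (3D array) and `k0` (scalar)
#' @export
normalize_k <- function(k_map, mask) {
  v <- k_map[mask != 0]
  k0 <- mean(v)
  if (k0 <= 0) stop("k0 = 0: no edges anywhere in the mask")
  out <- array(0, dim(k_map))
  out[mask != 0] <- v / k0
  list(norm = out, k0 = k0)
}

#' Full per-subject FCD product set
#'
#' From raw counts to the maps the group analysis consumes: Z-standardized
#' then smoothed maps (`z_short_sm`, `z_long_sm`) for voxel-wise
#' statistics, and k/k0-normalized unsmoothed maps (`norm_short`,
#' `norm_long`) for ROI extraction and correlations. Standardization
#' precedes smoothing.
#'
#' @param fcd an `fcd_maps` object from [compute_fcd()]
#' @return the input with added fields `z_short`, `z_long`, `z_short_sm`,
#'   `z_long_sm`, `norm_short`, `norm_long`, `k0_short`, `k0_long`
#' @export
fcd_products <- function(fcd) {
  stopifnot(inherits(fcd, "fcd_maps"))
  fwhm <- fcd$config$smooth_fwhm
  fcd$z_short <- zscore_map(fcd$k_short, fcd$mask)
  fcd$z_long <- zscore_map(fcd$k_long, fcd$mask)
  fcd$z_short_sm <- smooth_map(fcd$z_short, fwhm, fcd$affine, fcd$mask)
  fcd$z_long_sm <- smooth_map(fcd$z_long, fwhm, fcd$affine, fcd$mask)
  ns <- normalize_k(fcd$k_short, fcd$mask)
  nl <- normalize_k(fcd$k_long, fcd$mask)
  fcd$norm_short <- ns$norm; fcd$k0_short <- ns$k0
  fcd$norm_long <- nl$norm; fcd$k0_long <- nl$k0
  fcd
}

#' Write per-subject FCD maps to disk
#'
#' Six NIfTI maps (raw counts, smoothed Z, k/k0 for each range) and a JSON
#' sidecar with the parameters and normalization constants.
#'
#' @param fcd result of [fcd_products()]
#' @param dir output directory
#' @param prefix file-name prefix (e.g. the subject id)
#' @export
write_fcd <- function(fcd, dir, prefix) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maps <- list(k_short = fcd$k_short, k_long = fcd$k_long,
               z_short_sm = fcd$z_short_sm, z_long_sm = fcd$z_long_sm,
               norm_short = fcd$norm_short, norm_long = fcd$norm_long)
  for (nm in names(maps))
    write_nifti(maps[[nm]], fcd$affine,
                file.path(dir, sprintf("%s_%s.nii", prefix, nm)))
  jsonlite::write_json(
    list(r0 = fcd$config$r0, cutoff_mm = fcd$config$cutoff_mm,
         fwhm = fcd$config$smooth_fwhm,
         k0_short = fcd$k0_short, k0_long = fcd$k0_long,
         n_mask_voxels = sum(fcd$mask), n_volumes = fcd$n_volumes,
         n_zero_variance = fcd$n_zero_variance),
    file.path(dir, sprintf("%s_fcd.json", prefix)),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
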
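# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

FWHM_TO_SIGMA <- 2 * sqrt(2 * log(2))

#' Voxel sizes (mm) along each axis from a voxel-to-world affine
#' @param affine 4x4 matrix
#' @return numeric length-3 vector of mm per voxel step
#' @keywords internal
voxel_sizes <- function(affine) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' World (mm) coordinates of voxel centers
#'
#' Indices are 1-based array indices; the affine follows the NIfTI
#' convention of mapping 0-based indices to world mm.
#'
#' @param ijk n x 3 matrix of 1-based voxel indices
#' @param affine 4x4 voxel-to-world matrix
#' @return n x 3 matrix of mm coordinates
#' @keywords internal
voxel_to_mm <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  xyz1 <- cbind(ijk - 1, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

#' Default centered affine for an isotropic grid
#' @keywords internal
default_affine <- function(grid_shape, voxel_size = 3) {
  aff <- diag(c(rep(voxel_size, 3), 1))
  aff[1:3, 4] <- -(grid_shape - 1) / 2 * voxel_size
  aff
}

# 1D Gaussian kernel (normalized to sum 1) for sigma in voxel units
gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-half):half)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolve a 3D array along one axis with a symmetric kernel (zero padding),
# implemented as a banded-matrix multiply so the whole volume is one BLAS call.
conv_axis <- function(a, kern, axis) {
  if (length(kern) == 1L) return(a)
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- d[axis]
  half <- (length(kern) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - half):(j + half)
    ok <- idx >= 1 & idx <= n
    K[j, idx[ok]] <- kern[ok]
  }
  out <- K %*% matrix(ap, nrow = n)
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

# Separable Gaussian smoothing of a 3D array, sigma given in mm per axis.
smooth3d_raw <- function(a, sigma_mm, affine) {
  vs <- voxel_sizes(affine)
  for (ax in 1:3) a <- conv_axis(a, gauss_kernel(sigma_mm / vs[ax]), ax)
  a
}

#' Gaussian smoothing of a 3D map with boundary renormalization
#'
#' Smooths with a separable Gaussian kernel of the requested full width at
#' half maximum (in mm, converted to voxels through the affine). The map is
#' smoothed embedded in zeros and divided by the smoothed support indicator
#' (the mask if supplied, otherwise the full grid), so constants are
#' preserved up to the mask boundary and edge voxels are not attenuated.
#'
#' @param map3d 3D numeric array
#' @param fwhm full width at half maximum in mm; 0 returns the input
#' @param affine 4x4 voxel-to-world matrix (used for voxel sizes)
#' @param mask optional 3D logical/0-1 array restricting the support
#' @return smoothed 3D array (zero outside the mask when a mask is given)
#' @export
smooth_map <- function(map3d, fwhm, affine, mask = NULL) {
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(map3d)
  sigma <- fwhm / FWHM_TO_SIGMA
  if (!is.null(mask)) {
    m <- array(as.numeric(mask != 0), dim(map3d))
    num <- smooth3d_raw(map3d * m, sigma, affine)
    den <- smooth3d_raw(m, sigma, affine)
    out <- array(0, dim(map3d))
    inside <- m > 0 & den > 0
    out[inside] <- num[inside] / den[inside]
    out
  } else {
    num <- smooth3d_raw(map3d, sigma, affine)
    den <- smooth3d_raw(array(1, dim(map3d)), sigma, affine)
    num / den
  }
}

# Integer neighbor offsets whose center-to-center distance is <= rmm,
# derived from the voxel sizes at run time (self excluded).
neighbor_offsets <- function(rmm, voxel_size) {
  voxel_size <- rep(voxel_size, length.out = 3)
  r <- floor(rmm / voxel_size)
  g <- as.matrix(expand.grid(di = -r[1]:r[1], dj = -r[2]:r[2], dk = -r[3]:r[3]))
  d <- sqrt(colSums((t(g) * voxel_size)^2))
  g[d <= rmm & d > 0, , drop = FALSE]
}

# Label connected components of a logical 3D array under a given offset
# neighborhood. Returns an integer array (0 = background); label order
# follows array (column-major) order of the first voxel of each component,
# making labels independent of traversal details.
label_components <- function(flag, offsets) {
  d <- dim(flag)
  lab <- array(0L, d)
  vox <- which(flag)
  if (length(vox) == 0L) return(lab)
  mark <- array(FALSE, d)
  mark[vox] <- TRUE
  ijk_of <- function(lin) arrayInd(lin, d)
  current <- 0L
  for (v in vox) {
    if (lab[v] != 0L) next
    current <- current + 1L
    stack <- v
    lab[v] <- current
    while (length(stack)) {
      s <- stack[length(stack)]
      stack <- stack[-length(stack)]
      sijk <- ijk_of(s)
      nb <- sweep(offsets, 2, as.integer(sijk), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
        nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      if (!any(ok)) next
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      lin <- lin[mark[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- current
        stack <- c(stack, lin)
      }
    }
  }
  lab
}

# Deterministic per-subject seed derived from a global seed.
# Counter scheme: seed * 1009 + subject index, folded into 32-bit range.
subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i) %% 2147483647)
}
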
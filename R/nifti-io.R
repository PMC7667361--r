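#' BOLD series container
#'
#' A 4D (x, y, z, t) BOLD array together with its voxel-to-world affine and
#' repetition time. All temporal operations in the package act on this type.
#'
#' @param data 4D numeric array (x, y, z, t); a 3D array is promoted to a
#'   single-volume series
#' @param affine 4x4 voxel-to-world matrix (NIfTI convention, 0-based indices)
#' @param tr repetition time in seconds
#' @return an object of class `bold_series`
#' @export
bold_series <- function(data, affine, tr) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L, dim(data)[4] >= 1L)
  stopifnot(all(is.finite(data)))
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)),
            abs(det(affine)) > .Machine$double.eps)
  stopifnot(is.numeric(tr), tr > 0)
  structure(list(data = data, affine = affine, tr = tr),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d voxels, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' @export
dim.bold_series <- function(x) dim(x$data)

n_volumes <- function(series) dim(series$data)[4]

#' Read a NIfTI-1 volume
#'
#' @param path file path (.nii or .nii.gz)
#' @return list with `data` (3D or 4D array), `affine` (4x4), `tr` (seconds,
#'   from pixdim\[4\]; NA when absent)
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  pd <- attr(img, "pixdim")
  tr <- if (length(pd) >= 4) pd[4] else NA_real_
  list(data = as.array(img), affine = aff, tr = tr)
}

#' Write a NIfTI-1 volume
#'
#' The affine is stored in the sform (code 2) and the qform; 4D data carry
#' `tr` in pixdim\[4\].
#'
#' @param data 3D or 4D numeric array
#' @param affine 4x4 voxel-to-world matrix
#' @param path output path (.nii or .nii.gz)
#' @param tr repetition time in seconds for 4D data
#' @return `path`, invisibly
#' @export
write_nifti <- function(data, affine, path, tr = NULL) {
  vs <- voxel_sizes(affine)
  d <- dim(data)
  nd <- length(d)
  stopifnot(nd %in% c(3L, 4L))
  hdr <- RNifti::niftiHeader(list(
    dim = c(nd, d, rep(1, 7 - nd)),
    pixdim = c(1, vs, if (nd == 4L) tr %||% 1 else 0, 0, 0, 0),
    srow_x = affine[1, ], srow_y = affine[2, ], srow_z = affine[3, ],
    sform_code = 2, qform_code = 0, xyzt_units = 10))
  img <- RNifti::asNifti(data, reference = hdr, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a bold_series to NIfTI
#' @param series a [bold_series()]
#' @param path output path
#' @export
write_bold <- function(series, path) {
  write_nifti(series$data, series$affine, path, tr = series$tr)
}

#' Read a NIfTI file as a bold_series
#' @param path input path
#' @param tr repetition time override (seconds); defaults to pixdim\[4\]
#' @export
read_bold <- function(path, tr = NULL) {
  x <- read_nifti(path)
  bold_series(x$data, x$affine, tr %||% x$tr)
}
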
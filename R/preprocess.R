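#' Discard initial volumes
#'
#' Removes the first `n_discard` volumes of a BOLD series (scanner
#' saturation period). With the defaults of 240 acquired volumes and 10
#' discarded, 230 volumes remain.
#'
#' @param series a [bold_series()]
#' @param n_discard number of leading volumes to drop
#' @return the shortened [bold_series()]
#' @export
discard_initial <- function(series, n_discard = 10) {
  stopifnot(inherits(series, "bold_series"), n_discard >= 0)
  nt <- n_volumes(series)
  if (nt <= n_discard)
    stop(sprintf("cannot discard %d volumes from a series of %d",
                 n_discard, nt))
  if (n_discard == 0) return(series)
  bold_series(series$data[, , , (n_discard + 1):nt, drop = FALSE],
              series$affine, series$tr)
}

# Frequency response of the band-pass mask: 1 inside [low, high], raised
# cosine roll-off of half-width taper_hz at each edge, 0 outside.
bandpass_weights <- function(freqs, low, high, taper_hz) {
  w <- numeric(length(freqs))
  f <- abs(freqs)
  w[f >= low & f <= high] <- 1
  if (taper_hz > 0) {
    lo_edge <- f > low - taper_hz & f < low
    w[lo_edge] <- 0.5 * (1 + cos(pi * (low - f[lo_edge]) / taper_hz))
    hi_edge <- f > high & f < high + taper_hz
    w[hi_edge] <- 0.5 * (1 + cos(pi * (f[hi_edge] - high) / taper_hz))
  }
  w
}

# Detrend (linear) then band-pass filter the columns of a time x series
# matrix with a zero-phase frequency-domain mask.
bandpass_matrix <- function(y, tr, low, high, taper_hz = 0.002) {
  nt <- nrow(y)
  tt <- seq_len(nt)
  x <- cbind(1, tt - mean(tt))
  beta <- solve(crossprod(x), crossprod(x, y))
  y <- y - x %*% beta
  freqs <- c(0:(nt %/% 2), -((nt - nt %/% 2 - 1):1)) / (nt * tr)
  if (nt %% 2 == 0) freqs <- c(0:(nt %/% 2 - 1), -(nt %/% 2):-1) / (nt * tr)
  w <- bandpass_weights(freqs, low, high, taper_hz)
  Re(stats::mvfft(stats::mvfft(y) * w, inverse = TRUE)) / nt
}

#' Detrend and band-pass filter a BOLD series
#'
#' Per voxel: removes the linear trend, then applies a zero-phase
#' frequency-domain band-pass (rectangular passband with a raised-cosine
#' taper of half-width `taper_hz` at each edge). The default band of
#' 0.01-0.1 Hz retains the low-frequency fluctuations of interest while
#' suppressing drift and high-frequency physiological noise.
#'
#' @param series a [bold_series()]
#' @param low,high passband edges in Hz
#' @param taper_hz raised-cosine transition half-width in Hz
#' @return the filtered [bold_series()] (each voxel has mean ~0)
#' @export
bandpass_detrend <- function(series, low = 0.01, high = 0.1,
                             taper_hz = 0.002) {
  stopifnot(inherits(series, "bold_series"))
  nyq <- 1 / (2 * series$tr)
  if (!(low >= 0 && low < high && high < nyq))
    stop(sprintf("need 0 <= low < high < Nyquist (%.3f Hz); got [%g, %g]",
                 nyq, low, high))
  d <- dim(series$data)
  y <- t(matrix(series$data, prod(d[1:3]), d[4]))
  y <- bandpass_matrix(y, series$tr, low, high, taper_hz)
  bold_series(array(t(y), d), series$affine, series$tr)
}

#' Friston 24-parameter motion regressor matrix
#'
#' Expands a 6-parameter rigid-body trace into the 24-regressor model:
#' the parameters, their one-volume lags, and the squares of both. The
#' lagged row at the first volume is zero-padded (set `lag_pad = "drop"`
#' to instead duplicate the first observed row, keeping the design full
#' length without an artificial zero).
#'
#' @param motion volumes x 6 matrix (tx, ty, tz, rx, ry, rz)
#' @param lag_pad `"zero"` (default) or `"drop"`; how to fill the lag at
#'   the first volume
#' @return volumes x 24 matrix
#' @export
build_friston24 <- function(motion, lag_pad = c("zero", "drop")) {
  lag_pad <- match.arg(lag_pad)
  motion <- as.matrix(motion)
  if (ncol(motion) != 6)
    stop(sprintf("motion trace must have 6 columns, got %d", ncol(motion)))
  stopifnot(nrow(motion) >= 2)
  lagged <- rbind(if (lag_pad == "zero") rep(0, 6) else motion[1, ],
                  motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lagged, motion^2, lagged^2)
  colnames(out) <- c(paste0(colnames(motion) %||% paste0("p", 1:6)),
                     paste0("lag_", 1:6), paste0("sq_", 1:6),
                     paste0("lagsq_", 1:6))
  out
}

#' Nuisance model container
#'
#' @param friston24 volumes x 24 motion regressor matrix (or NULL)
#' @param tissue_signals volumes x k matrix of mean tissue series (white
#'   matter, CSF), optional
#' @return object of class `nuisance_model`
#' @export
nuisance_model <- function(friston24 = NULL, tissue_signals = NULL) {
  parts <- list()
  if (!is.null(friston24)) parts$friston24 <- as.matrix(friston24)
  if (!is.null(tissue_signals)) parts$tissue <- as.matrix(tissue_signals)
  n <- unique(vapply(parts, nrow, 1L))
  if (length(parts) && length(n) != 1)
    stop("nuisance components disagree on volume count")
  structure(list(parts = parts, n = if (length(parts)) n else NA_integer_),
            class = "nuisance_model")
}

#' Regress nuisance signals out of a BOLD series
#'
#' Per voxel, returns the residual of an ordinary least-squares fit on an
#' intercept plus the nuisance columns. Degenerate columns (constant after
#' centering, or linearly dependent) are dropped with a warning. Residuals
#' are orthogonal to every retained regressor.
#'
#' @param series a [bold_series()]
#' @param model a [nuisance_model()]
#' @return residual [bold_series()]
#' @export
regress_nuisance <- function(series, model) {
  stopifnot(inherits(series, "bold_series"), inherits(model, "nuisance_model"))
  nt <- n_volumes(series)
  X <- do.call(cbind, model$parts)
  d <- dim(series$data)
  y <- t(matrix(series$data, prod(d[1:3]), d[4]))
  if (is.null(X) || ncol(X) == 0) {
    res <- y - matrix(colMeans(y), nt, ncol(y), byrow = TRUE)
  } else {
    if (nrow(X) != nt)
      stop(sprintf("nuisance model has %d rows but series has %d volumes",
                   nrow(X), nt))
    Xc <- scale(X, center = TRUE, scale = FALSE)
    keep <- apply(Xc, 2, function(col) stats::sd(col) > 1e-12)
    Xc <- Xc[, keep, drop = FALSE]
    if (ncol(Xc) < ncol(X))
      warning(sprintf("dropped %d degenerate nuisance column(s)",
                      ncol(X) - ncol(Xc)))
    if (ncol(Xc)) {
      qrX <- qr(Xc)
      if (qrX$rank < ncol(Xc)) {
        warning(sprintf("dropped %d collinear nuisance column(s)",
                        ncol(Xc) - qrX$rank))
        Xc <- Xc[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
        qrX <- qr(Xc)
      }
      y <- scale(y, center = TRUE, scale = FALSE)
      res <- y - Xc %*% qr.coef(qrX, y)
    } else {
      res <- y - matrix(colMeans(y), nt, ncol(y), byrow = TRUE)
    }
  }
  bold_series(array(t(res), d), series$affine, series$tr)
}

# Rigid-body transform (4x4) from 6 parameters: translations mm, rotations
# radians applied as Rx %*% Ry %*% Rz.
rigid_transform <- function(p) {
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  out <- diag(4)
  out[1:3, 1:3] <- Rx %*% Ry %*% Rz
  out[1:3, 4] <- p[1:3]
  out
}

#' Jenkinson frame-wise displacement
#'
#' For each adjacent volume pair, the root-mean-square displacement of the
#' relative rigid-body transform over a sphere of radius `head_radius`:
#' with the relative transform written as identity + \[A | b\],
#' FD = sqrt(R^2/5 * trace(A'A) + b'b). Rotations enter through the full
#' rotation matrix, not a small-angle approximation.
#'
#' @param motion volumes x 6 matrix (tx, ty, tz in mm; rx, ry, rz in rad)
#' @param head_radius sphere radius in mm
#' @return list with `fd` (length volumes - 1) and `mean_fd`
#' @export
framewise_displacement <- function(motion, head_radius = 80) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6, nrow(motion) >= 2)
  n <- nrow(motion)
  Ts <- lapply(seq_len(n), function(i) rigid_transform(motion[i, ]))
  fd <- vapply(2:n, function(i) {
    M <- Ts[[i]] %*% solve(Ts[[i - 1]])
    A <- M[1:3, 1:3] - diag(3)
    b <- M[1:3, 4]
    sqrt(head_radius^2 / 5 * sum(A^2) + sum(b^2))
  }, 1.0)
  list(fd = fd, mean_fd = mean(fd))
}

#' Motion-based subject exclusion
#'
#' A subject passes only if, relative to the first retained volume, every
#' translation stays strictly below `trans_limit` (mm) and every rotation
#' strictly below `rot_limit` (degrees) on all three axes.
#'
#' @param motion volumes x 6 matrix
#' @param trans_limit mm
#' @param rot_limit degrees
#' @return list with `pass` (logical) and `reason` (string, "" on pass)
#' @export
motion_exclusion <- function(motion, trans_limit = 2, rot_limit = 2) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6)
  rel <- sweep(motion, 2, motion[1, ])
  trans <- abs(rel[, 1:3, drop = FALSE])
  rot <- abs(rel[, 4:6, drop = FALSE]) * 180 / pi
  axes <- c("x", "y", "z")
  if (any(trans >= trans_limit)) {
    w <- which(trans >= trans_limit, arr.ind = TRUE)[1, ]
    return(list(pass = FALSE,
                reason = sprintf(
                  "translation %.2f mm on %s at volume %d exceeds %g mm",
                  trans[w[1], w[2]], axes[w[2]], w[1], trans_limit)))
  }
  if (any(rot >= rot_limit)) {
    w <- which(rot >= rot_limit, arr.ind = TRUE)[1, ]
    return(list(pass = FALSE,
                reason = sprintf(
                  "rotation %.2f deg on %s at volume %d exceeds %g deg",
                  rot[w[1], w[2]], axes[w[2]], w[1], rot_limit)))
  }
  list(pass = TRUE, reason = "")
}

#' Full temporal preprocessing of one subject
#'
#' Fixed stage order: discard initial volumes, detrend + band-pass, then
#' nuisance regression (Friston-24 from the retained motion rows, plus any
#' tissue signals). Nuisance regressors are passed through the same
#' band-pass as the data before regression so no out-of-band variance is
#' reintroduced (set `filter_regressors = FALSE` to regress the raw
#' regressors instead). Frame-wise displacement is computed on the retained
#' motion trace.
#'
#' @param series a [bold_series()] (raw, full length)
#' @param motion volumes x 6 motion trace matching the raw series
#' @param n_discard leading volumes to drop
#' @param low,high band-pass edges, Hz
#' @param tissue_signals optional volumes x k tissue series (retained
#'   volumes only, or full length to be trimmed)
#' @param filter_regressors band-pass the nuisance columns before
#'   regression
#' @return list with `series` (preprocessed [bold_series()]), `fd`
#'   ([framewise_displacement()] output), `exclusion`
#'   ([motion_exclusion()] output) and `n_volumes`
#' @export
preprocess_bold <- function(series, motion, n_discard = 10,
                            low = 0.01, high = 0.1,
                            tissue_signals = NULL,
                            filter_regressors = TRUE) {
  stopifnot(inherits(series, "bold_series"))
  motion <- as.matrix(motion)
  if (nrow(motion) != n_volumes(series))
    stop("motion trace and series disagree on volume count")
  series <- discard_initial(series, n_discard)
  motion_ret <- motion[(n_discard + 1):nrow(motion), , drop = FALSE]
  series <- bandpass_detrend(series, low, high)
  f24 <- build_friston24(motion_ret)
  if (!is.null(tissue_signals)) {
    tissue_signals <- as.matrix(tissue_signals)
    if (nrow(tissue_signals) == nrow(motion))
      tissue_signals <- tissue_signals[(n_discard + 1):nrow(motion), ,
                                       drop = FALSE]
  }
  if (filter_regressors) {
    if (stats::sd(as.numeric(f24)) > 0)
      f24 <- bandpass_matrix(f24, series$tr, low, high)
    if (!is.null(tissue_signals))
      tissue_signals <- bandpass_matrix(tissue_signals, series$tr, low, high)
  }
  model <- nuisance_model(friston24 = f24, tissue_signals = tissue_signals)
  series <- suppressWarnings(regress_nuisance(series, model))
  fd <- framewise_displacement(motion_ret)
  list(series = series, fd = fd,
       exclusion = motion_exclusion(motion_ret),
       n_volumes = n_volumes(series))
}
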
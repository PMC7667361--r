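# FCD mapping: thresholded correlation graph, standardization, smoothing

test_that("constructed identical/orthogonal series give exact counts", {
  grid <- c(10, 10, 10); nt <- 16
  dat <- array(0, c(grid, nt))
  mask <- array(FALSE, grid)
  # five voxels: A,B adjacent (3 mm) and identical; C,D,E distant and
  # mutually orthogonal series (no chance edges by construction)
  set.seed(1)
  # columns orthogonal to the constant (zero mean) and to each other, so
  # all cross-correlations are exactly 0
  M <- qr.Q(qr(cbind(1, matrix(rnorm(nt * 4), nt, 4))))[, 2:5]
  pos <- list(A = c(2, 2, 2), B = c(3, 2, 2), C = c(9, 9, 9),
              D = c(2, 9, 9), E = c(9, 2, 9))
  series <- list(A = M[, 1], B = M[, 1], C = M[, 2], D = M[, 3], E = M[, 4])
  for (nm in names(pos)) {
    p <- pos[[nm]]
    dat[p[1], p[2], p[3], ] <- series[[nm]]
    mask[p[1], p[2], p[3]] <- TRUE
  }
  s <- bold_series(dat, fcdmap:::default_affine(grid, 3), 2)
  f <- compute_fcd(s, mask, fcd_config())
  a <- pos$A
  expect_identical(f$k_short[a[1], a[2], a[3]], 1L)
  expect_identical(f$k_long[a[1], a[2], a[3]], 0L)
  expect_identical(f$k_long[9, 9, 9], 0L)
})

test_that("anti-correlated pairs contribute no edge", {
  grid <- c(6, 6, 6); nt <- 20
  dat <- array(rnorm(prod(grid) * nt) * 0, c(grid, nt))
  s0 <- sin(2 * pi * 0.05 * (0:(nt - 1)))
  dat[2, 2, 2, ] <- s0
  dat[2, 2, 3, ] <- -s0
  mask <- array(FALSE, grid); mask[2, 2, 2] <- mask[2, 2, 3] <- TRUE
  s <- bold_series(dat, fcdmap:::default_affine(grid, 3), 2)
  f <- compute_fcd(s, mask, fcd_config())
  expect_identical(f$k_short[2, 2, 2], 0L)
  expect_identical(f$k_long[2, 2, 2], 0L)
})

test_that("blocked counts equal the exhaustive pairwise oracle", {
  set.seed(7)
  for (rep in 1:3) {
    grid <- c(8, 8, 8)
    s <- random_bold(grid, nt = 40)
    # add local structure so edges actually occur
    for (t in 1:40)
      s$data[, , , t] <- s$data[, , , t] +
        2 * fcdmap:::smooth3d_raw(array(rnorm(prod(grid)), grid), 3,
                                  s$affine)
    mask <- gm_ellipsoid_mask(grid)
    f <- compute_fcd(s, mask, fcd_config(block_size = 37))
    o <- fcd_oracle(s, mask)
    expect_identical(f$k_short[o$vox], o$k_short)
    expect_identical(f$k_long[o$vox], o$k_long)
  }
})

test_that("counts are exactly independent of the block size", {
  set.seed(9)
  s <- random_bold(c(7, 7, 7), nt = 30)
  mask <- gm_ellipsoid_mask(c(7, 7, 7))
  ref <- compute_fcd(s, mask, fcd_config(block_size = 100000))
  for (bs in c(1, 13, 64)) {
    f <- compute_fcd(s, mask, fcd_config(block_size = bs))
    expect_identical(f$k_short, ref$k_short)
    expect_identical(f$k_long, ref$k_long)
  }
})

test_that("short + long conserves total degree and the graph is symmetric", {
  set.seed(11)
  s <- random_bold(c(8, 8, 8), nt = 24)
  mask <- gm_ellipsoid_mask(c(8, 8, 8))
  f <- compute_fcd(s, mask, fcd_config())
  total <- compute_fcd(s, mask, fcd_config(cutoff_mm = 1e6))
  expect_identical(f$k_short + f$k_long, total$k_short)
  expect_identical(sum(total$k_short) %% 2L, 0L)
})

test_that("degree is monotone in r0 and the partition monotone in cutoff", {
  set.seed(13)
  s <- random_bold(c(8, 8, 8), nt = 24)
  mask <- gm_ellipsoid_mask(c(8, 8, 8))
  grid_r0 <- c(0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4)
  prev <- NULL
  for (r0 in grid_r0) {
    f <- compute_fcd(s, mask, fcd_config(r0 = r0))
    tot <- f$k_short + f$k_long
    if (!is.null(prev)) expect_true(all(tot <= prev))
    prev <- tot
  }
  prev_s <- NULL
  for (cut in c(3, 6, 12, 24)) {
    f <- compute_fcd(s, mask, fcd_config(cutoff_mm = cut))
    if (!is.null(prev_s)) {
      expect_true(all(f$k_short >= prev_s$k_short))
      expect_true(all(f$k_long <= prev_s$k_long))
    }
    prev_s <- f
  }
})

test_that("zero-variance voxels carry no edges but stay in the mask", {
  grid <- c(6, 6, 6)
  s <- random_bold(grid, nt = 20)
  s$data[3, 3, 3, ] <- 42
  mask <- array(TRUE, grid)
  f <- compute_fcd(s, mask, fcd_config())
  expect_identical(f$n_zero_variance, 1L)
  expect_identical(f$k_short[3, 3, 3] + f$k_long[3, 3, 3], 0L)
})

test_that("zscore_map standardizes with the population SD", {
  mask <- array(TRUE, c(2, 1, 1))
  k <- array(c(0, 2), c(2, 1, 1))
  expect_equal(as.numeric(zscore_map(k, mask)), c(-1, 1))
  set.seed(2)
  km <- array(rpois(125, 20), c(5, 5, 5))
  m2 <- array(TRUE, c(5, 5, 5))
  z <- zscore_map(km, m2)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-12)
  expect_error(zscore_map(array(3, c(2, 2, 2)), array(TRUE, c(2, 2, 2))),
               "zero variance")
})

test_that("normalize_k divides by the whole-mask mean", {
  mask <- array(TRUE, c(2, 1, 1))
  out <- normalize_k(array(c(1, 3), c(2, 1, 1)), mask)
  expect_equal(out$k0, 2)
  expect_equal(as.numeric(out$norm), c(0.5, 1.5))
  nc <- normalize_k(array(c(7, 7), c(2, 1, 1)), mask)
  expect_equal(as.numeric(nc$norm), c(1, 1))
  set.seed(3)
  km <- array(rpois(64, 10) + 1, c(4, 4, 4))
  m2 <- array(TRUE, c(4, 4, 4))
  expect_lt(abs(mean(normalize_k(km, m2)$norm) - 1), 1e-12)
  expect_error(normalize_k(array(0, c(2, 2, 2)), array(TRUE, c(2, 2, 2))),
               "k0")
})

test_that("Gaussian smoothing has the closed-form impulse response", {
  grid <- c(15, 15, 15)
  aff <- fcdmap:::default_affine(grid, 3)
  imp <- array(0, grid); imp[8, 8, 8] <- 1
  sm <- smooth_map(imp, 6, aff)
  sigma <- 6 / (2 * sqrt(2 * log(2)))
  expect_equal(sm[9, 8, 8] / sm[8, 8, 8], exp(-9 / (2 * sigma^2)),
               tolerance = 1e-10)
  # FWHM is literal: value at half the kernel width is half the peak
  expect_equal(sm[9, 8, 8] / sm[8, 8, 8], 0.5, tolerance = 1e-10)
  expect_identical(smooth_map(imp, 0, aff), imp)
  cst <- array(3.5, grid)
  mask <- gm_ellipsoid_mask(grid)
  smc <- smooth_map(cst, 6, aff, mask)
  expect_equal(max(abs(smc[mask] - 3.5)), 0, tolerance = 1e-10)
})

test_that("fcd_products emits standardized and normalized maps together", {
  set.seed(15)
  s <- random_bold(c(8, 8, 8), nt = 40)
  for (t in 1:40)
    s$data[, , , t] <- s$data[, , , t] +
      2 * fcdmap:::smooth3d_raw(array(rnorm(512), c(8, 8, 8)), 3, s$affine)
  mask <- gm_ellipsoid_mask(c(8, 8, 8))
  fp <- fcd_products(compute_fcd(s, mask, fcd_config()))
  expect_lt(abs(mean(fp$z_short[mask])), 1e-10)
  expect_lt(abs(mean(fp$norm_long[mask]) - 1), 1e-10)
  expect_equal(fp$k0_short, mean(fp$k_short[mask]))
  expect_true(all(c("z_short_sm", "z_long_sm") %in% names(fp)))
})
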
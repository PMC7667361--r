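# Group inference: voxel GLM, cluster-extent correction, summary statistics

make_maps <- function(n, grid, f = function() array(rnorm(prod(grid)), grid)) {
  lapply(seq_len(n), function(i) f())
}

test_that("the GLM without covariates equals the two-sample pooled t", {
  set.seed(1)
  grid <- c(4, 4, 4)
  maps <- make_maps(20, grid)
  cohort <- data.frame(group = rep(c("patient", "control"), each = 10))
  design <- build_design(cohort, covariates = character(0))
  mask <- array(TRUE, grid)
  sm <- fit_voxel_glm(maps, design, mask)
  Y <- sapply(maps, function(m) as.numeric(m))
  direct <- apply(Y, 1, function(v) {
    g1 <- v[1:10]; g2 <- v[11:20]
    sp2 <- (9 * var(g1) + 9 * var(g2)) / 18
    (mean(g1) - mean(g2)) / sqrt(sp2 * (2 / 10))
  })
  expect_equal(as.numeric(sm$t), direct, tolerance = 1e-10)
  expect_equal(sm$df, 18)
})

test_that("identical maps across subjects give t = 0 everywhere", {
  grid <- c(3, 3, 3)
  m0 <- array(rnorm(27), grid)
  maps <- lapply(1:8, function(i) m0)
  cohort <- data.frame(group = rep(c("patient", "control"), each = 4))
  sm <- fit_voxel_glm(maps, build_design(cohort, character(0)),
                      array(TRUE, grid))
  expect_true(all(sm$t == 0))
})

test_that("a planted mean shift is recovered within its standard error", {
  set.seed(3)
  grid <- c(5, 5, 5)
  delta <- 0.8
  n <- 27
  cohort <- data.frame(group = rep(c("patient", "control"), each = n),
                       age = rnorm(2 * n, 40, 10),
                       gender = sample(c("F", "M"), 2 * n, TRUE),
                       mean_fd = runif(2 * n, 0.02, 0.2))
  region <- array(FALSE, grid); region[2:3, 2:3, 2:3] <- TRUE
  maps <- lapply(seq_len(2 * n), function(i) {
    m <- array(rnorm(prod(grid)), grid)
    if (cohort$group[i] == "patient") m[region] <- m[region] + delta
    m
  })
  sm <- fit_voxel_glm(maps, build_design(cohort), array(TRUE, grid))
  est <- mean(sm$beta[region])
  se_mean <- sqrt(2 / n) / sqrt(sum(region))  # analytic SE of the average
  expect_lt(abs(est - delta), 4 * se_mean)
})

test_that("collinear designs are rejected by name", {
  cohort <- data.frame(group = rep(c("patient", "control"), each = 5),
                       age = rep(1, 10))
  cohort$mean_fd <- as.numeric(cohort$group == "patient")
  expect_error(build_design(cohort, c("age", "mean_fd")), "rank deficient")
})

test_that("rmm = 5 on a 3 mm grid connects faces and edges, not corners", {
  grid <- c(8, 8, 8)
  aff <- fcdmap:::default_affine(grid, 3)
  tmap <- array(0, grid)
  tmap[2, 2, 2] <- 10
  tmap[3, 3, 3] <- 10   # corner neighbor (~5.196 mm): separate cluster
  tmap[5, 5, 5] <- 10
  tmap[6, 6, 5] <- 10   # edge neighbor (~4.243 mm): same cluster
  tmap[7, 6, 5] <- 10   # face neighbor of the former
  sm <- structure(list(t = tmap, p = array(1, grid), df = 50,
                       mask = array(TRUE, grid)), class = "stat_map")
  cl <- label_clusters(sm, voxel_p = 0.001, rmm = 5, affine = aff)
  expect_equal(length(cl), 3)
  expect_equal(sort(vapply(cl, `[[`, 1L, "size")), c(1L, 1L, 3L))
  line <- cl[[which(vapply(cl, `[[`, 1L, "size") == 3L)]]
  expect_equal(line$peak_t, 10)
  empty <- structure(list(t = array(0, grid), p = array(1, grid), df = 50,
                          mask = array(TRUE, grid)), class = "stat_map")
  expect_equal(length(label_clusters(empty, 0.001, 5, aff)), 0)
})

test_that("cluster labeling separates signs and is order-invariant", {
  grid <- c(6, 6, 6)
  aff <- fcdmap:::default_affine(grid, 3)
  tmap <- array(0, grid)
  tmap[2, 2, 2] <- 8
  tmap[2, 2, 3] <- -8  # face neighbor of opposite sign: separate clusters
  sm <- structure(list(t = tmap, p = array(1, grid), df = 30,
                       mask = array(TRUE, grid)), class = "stat_map")
  cl <- label_clusters(sm, 0.001, 5, aff)
  expect_equal(length(cl), 2)
  expect_setequal(vapply(cl, `[[`, 1L, "sign"), c(1L, -1L))
})

test_that("AlphaSim extent rises with noise smoothness", {
  mask <- gm_ellipsoid_mask(c(10, 10, 10))
  aff <- fcdmap:::default_affine(c(10, 10, 10), 3)
  set.seed(5)
  e0 <- alphasim_extent(mask, aff,
                        alphasim_config(fwhm = 0, voxel_p = 0.05,
                                        iterations = 300))
  set.seed(5)
  e6 <- alphasim_extent(mask, aff,
                        alphasim_config(fwhm = 6, voxel_p = 0.05,
                                        iterations = 300))
  expect_gte(e6$k_min, e0$k_min)
  expect_equal(length(e0$null_max_sizes), 300)
})

test_that("smoothness estimation recovers the applied kernel width", {
  grid <- c(20, 20, 20)
  aff <- fcdmap:::default_affine(grid, 3)
  mask <- gm_ellipsoid_mask(grid)
  set.seed(21)
  for (fwhm_true in c(6, 9)) {
    sigma <- fwhm_true / fcdmap:::FWHM_TO_SIGMA
    maps <- lapply(1:10, function(i)
      fcdmap:::smooth3d_raw(array(rnorm(prod(grid)), grid), sigma, aff))
    est <- estimate_fwhm(maps, mask, aff)
    expect_lt(abs(est - fwhm_true) / fwhm_true, 0.15)
  }
})

test_that("a near-unity voxel threshold lets no finite cluster pass", {
  mask <- gm_ellipsoid_mask(c(8, 8, 8))
  aff <- fcdmap:::default_affine(c(8, 8, 8), 3)
  set.seed(6)
  e <- alphasim_extent(mask, aff,
                       alphasim_config(fwhm = 0, voxel_p = 0.999,
                                       iterations = 50))
  # almost every voxel survives every iteration; with signs labeled
  # separately each sign holds ~half the mask, and the extent threshold
  # must exceed the clusters that same process produces
  expect_gt(e$k_min, 0.4 * sum(mask))
  expect_gte(e$k_min, max(e$null_max_sizes))
})

test_that("Cohen's d matches the textbook formula", {
  expect_equal(cohen_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(7)
  x <- rnorm(30, 1, 1); y <- rnorm(25, 0, 1)
  sp <- sqrt((29 * var(x) + 24 * var(y)) / 53)
  expect_equal(cohen_d(x, y), (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  expect_error(cohen_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("summary t test and chi-square reproduce hand computations", {
  tt <- two_sample_t_summary(1, 1, 10, 0, 1, 10)
  direct <- 1 / sqrt(1 * (2 / 10))
  expect_equal(tt$t, direct, tolerance = 1e-12)
  eq <- two_sample_t_summary(5, 2, 10, 5, 2, 10)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_equal(two_sample_t_summary(3, 0, 5, 3, 0, 5)$t, 0)
  expect_equal(chi_square_2x2(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  expect_equal(chi_square_2x2(matrix(c(6, 3, 12, 6), 2))$statistic, 0,
               tolerance = 1e-12)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("partial correlation removes covariates and reduces to Pearson", {
  set.seed(9)
  z <- rnorm(500)
  x <- 2 * z + rnorm(500)
  y <- -3 * z + rnorm(500)
  pc <- partial_correlation(x, y, cbind(z))
  expect_lt(abs(pc$rho), 0.1)
  expect_gt(abs(cor(x, y)), 0.5)  # confounded without partialling
  x2 <- rnorm(40); cov2 <- cbind(rnorm(40))
  exact <- partial_correlation(x2, x2 + 0.5 * cov2[, 1], NULL)
  expect_equal(exact$rho, cor(x2, x2 + 0.5 * cov2[, 1]), tolerance = 1e-12)
  perfect <- partial_correlation(x2, x2, cov2)
  expect_equal(perfect$rho, 1, tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up rule and ignores order", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(11)
  p <- runif(50)
  o <- sample(50)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
})

test_that("cluster_report summarizes surviving clusters with effect size", {
  grid <- c(6, 6, 6)
  aff <- fcdmap:::default_affine(grid, 3)
  tmap <- array(0, grid)
  tmap[2:4, 3, 3] <- c(5, 9, 6)
  sm <- structure(list(t = tmap, p = array(1, grid), df = 20,
                       mask = array(TRUE, grid)), class = "stat_map")
  cl <- label_clusters(sm, 0.001, 5, aff)
  groups <- rep(c("patient", "control"), each = 6)
  set.seed(13)
  nmaps <- lapply(seq_along(groups), function(i) {
    m <- array(1, grid) + rnorm(prod(grid), sd = 0.05)
    if (groups[i] == "patient") m <- m + 0.5
    m
  })
  tab <- cluster_report(cl, sm, nmaps, groups, aff, k_min = 2)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$size, 3L)
  expect_equal(tab$peak_t, 9)
  expect_equal(tab$peak_x, (3 - 1) * 3 + aff[1, 4])
  expect_gt(tab$cohen_d, 2)
  none <- cluster_report(cl, sm, nmaps, groups, aff, k_min = 10)
  expect_equal(nrow(none), 0)
  expect_true(all(c("label", "size", "peak_t", "cohen_d") %in% names(none)))
})
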
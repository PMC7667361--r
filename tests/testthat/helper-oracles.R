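# Independent oracles and small fixture builders, written against different
# code paths than the implementations they check.

# Exhaustive pairwise FCD oracle: full correlation matrix from stats::cor,
# explicit per-voxel loop over all partners, distances recomputed directly.
fcd_oracle <- function(series, mask, r0 = 0.25, cutoff = 12) {
  d <- dim(series$data)
  vox <- which(mask != 0)
  ts <- t(matrix(series$data, prod(d[1:3]), d[4])[vox, , drop = FALSE])
  suppressWarnings(R <- stats::cor(ts))
  R[is.na(R)] <- 0
  ijk <- arrayInd(vox, d[1:3])
  xyz <- (ijk - 1) %*% t(series$affine[1:3, 1:3])
  xyz <- sweep(xyz, 2, series$affine[1:3, 4], "+")
  nv <- length(vox)
  ks <- integer(nv); kl <- integer(nv)
  for (i in seq_len(nv)) {
    dist <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    edge <- R[i, ] > r0
    edge[i] <- FALSE
    ks[i] <- sum(edge & dist <= cutoff)
    kl[i] <- sum(edge & dist > cutoff)
  }
  list(k_short = ks, k_long = kl, vox = vox)
}

# Random bold series on a small grid (white noise unless given structure).
random_bold <- function(grid = c(8, 8, 8), nt = 40, voxel = 3, tr = 2) {
  bold_series(array(rnorm(prod(grid) * nt), c(grid, nt)),
              fcdmap:::default_affine(grid, voxel), tr)
}

# Brute-force null max-cluster-size simulation for fwhm = 0 using igraph
# components over an explicitly built neighbor graph.
alphasim_bruteforce <- function(mask, affine, voxel_p, rmm, iterations) {
  vox <- which(mask != 0)
  d <- dim(mask)
  ijk <- arrayInd(vox, d)
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  xyz <- sweep(ijk, 2, vs, "*")
  nv <- length(vox)
  dd <- as.matrix(stats::dist(xyz))
  adj <- which(dd <= rmm & dd > 0, arr.ind = TRUE)
  adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
  zcrit <- qnorm(1 - voxel_p / 2)
  vapply(seq_len(iterations), function(it) {
    z <- rnorm(nv)
    z <- (z - mean(z)) / sd(z)
    mx <- 0L
    for (sgn in c(1, -1)) {
      sel <- which(sgn * z > zcrit)
      if (length(sel) == 0) next
      keep <- adj[adj[, 1] %in% sel & adj[, 2] %in% sel, , drop = FALSE]
      g <- igraph::graph_from_data_frame(
        data.frame(from = as.character(keep[, 1]),
                   to = as.character(keep[, 2])),
        directed = FALSE,
        vertices = data.frame(name = as.character(sel)))
      mx <- max(mx, max(igraph::components(g)$csize))
    }
    as.integer(mx)
  }, 1L)
}

# Dice overlap of two logical arrays
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
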
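# Shared test helpers: random sphere draws, truth interpolation, and a small
# Euclidean sparse-FPCA oracle used by the small-curvature equivalence test.

random_sphere_point <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_composition <- function() {
  v <- stats::rgamma(3, shape = 2)
  v / sum(v)
}

# random tangent vector at p with given norm
random_tangent <- function(p, norm = stats::runif(1, 0, 1)) {
  v <- stats::rnorm(3)
  v <- v - sum(v * p) * p
  v / sqrt(sum(v^2)) * norm
}

# interpolate a dense-grid truth matrix (ng x 3) onto another grid
interp_truth <- function(grid_from, M, grid_to) {
  apply(M, 2, function(col) stats::approx(grid_from, col, xout = grid_to)$y)
}

quad_align <- function(grid, A, B) {
  w <- rep(grid[2] - grid[1], length(grid))
  w[c(1, length(grid))] <- w[1] / 2
  abs(sum(w * rowSums(A * B)))
}

# Euclidean sparse FPCA on ambient coordinates, built from the package's
# smoothers but with flat-space centering (independent route from the
# tangent-space pipeline).
euclidean_sparse_fpca <- function(sample, bw_mean, bw_cov, n_grid = 31) {
  pool <- comptraj:::.pool_sample(sample)
  grid <- seq(min(pool$times), max(pool$times), length.out = n_grid)
  mu <- sapply(1:3, function(d)
    local_linear_1d(pool$times, pool$obs[, d], grid, bw_mean))
  mu_at <- function(t) sapply(1:3, function(d)
    stats::approx(grid, mu[, d], xout = t, rule = 2)$y)
  R <- pool$obs - t(vapply(pool$times, mu_at, numeric(3)))
  s_all <- c(); t_all <- c(); V <- NULL
  for (ix in split(seq_along(pool$subject), pool$subject)) {
    m <- length(ix)
    if (m < 2) next
    for (j in 1:m) for (l in 1:m) {
      if (j == l) next
      s_all <- c(s_all, pool$times[ix[j]]); t_all <- c(t_all, pool$times[ix[l]])
      V <- rbind(V, as.vector(outer(R[ix[j], ], R[ix[l], ])))
    }
  }
  sm <- local_linear_2d(s_all, t_all, V, grid, bw_cov, symmetrize = FALSE)
  ng <- n_grid
  B <- matrix(NA_real_, 3 * ng, 3 * ng)
  for (q in 1:ng) for (r in 1:ng) {
    blk <- matrix(sm[q, r, ], 3, 3)
    B[(3 * (q - 1) + 1):(3 * q), (3 * (r - 1) + 1):(3 * r)] <- blk
  }
  B <- (B + t(B)) / 2
  dt <- grid[2] - grid[1]
  w <- rep(dt, ng); w[c(1, ng)] <- dt / 2
  sw <- sqrt(rep(w, each = 3))
  ev <- eigen(B * outer(sw, sw), symmetric = TRUE)$values
  list(grid = grid, lambda = pmax(ev, 0))
}
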
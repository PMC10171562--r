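# Sparse Riemannian FPCA: mean, log-data, covariance, eigenstructure, noise,
# scores, reconstruction, prediction.

# small cohort whose observations all equal a fixed sphere point
constant_sample <- function(p, n = 20, seed = 5) {
  set.seed(seed)
  ids <- sprintf("s%02d", 1:n)
  times <- lapply(1:n, function(i) sort(runif(sample(1:3, 1), 0, 10)))
  obs <- lapply(times, function(tt) matrix(rep(p, length(tt)), ncol = 3, byrow = TRUE))
  longitudinal_sample(ids, times, obs)
}

test_that("mean function of constant data is that constant", {
  p <- comp_to_sphere(c(0.2, 0.5, 0.3))
  s <- constant_sample(p)
  grid <- seq(0, 10, length.out = 21)
  mu <- estimate_mean_function(s, bandwidth = 1.5, grid = grid)
  for (q in 1:21) expect_equal(mu[q, ], p, tolerance = 1e-9)
})

test_that("mean function recovers a smooth truth from dense noiseless data", {
  params <- default_scenario()
  grid <- seq(1.5, 8, length.out = 51)
  mu_true <- make_mean_curve(params$mean_anchors, grid)
  set.seed(8)
  n <- 200
  ids <- sprintf("s%03d", 1:n)
  times <- rep(list(grid), n)
  obs <- rep(list(mu_true), n)
  s <- longitudinal_sample(ids, times, obs)
  mu <- estimate_mean_function(s, bandwidth = 0.65, grid = grid)
  errs <- vapply(1:51, function(q) geodesic_distance(mu[q, ], mu_true[q, ]), numeric(1))
  expect_lt(max(errs), 0.02)
})

test_that("log-data satisfies the log-map identities", {
  params <- default_scenario()
  params$n_subjects <- c(60, 0); params$seed <- 13L
  gen <- generate_sample(params, groups = 1)
  s <- gen$sample
  grid <- seq(min(unlist(s$times)), max(unlist(s$times)), length.out = 31)
  mu <- estimate_mean_function(s, 0.65, grid)
  ld <- compute_log_data(s, mu, grid, 0.65)
  pool <- comptraj:::.pool_sample(s)
  for (j in seq_along(ld$times)) {
    expect_equal(sum(ld$L[j, ] * ld$mu_obs[j, ]), 0, tolerance = 1e-10)
    expect_equal(sqrt(sum(ld$L[j, ]^2)),
                 geodesic_distance(ld$mu_obs[j, ], pool$obs[j, ]), tolerance = 1e-10)
    expect_equal(exp_map(ld$mu_obs[j, ], ld$L[j, ]), pool$obs[j, ], tolerance = 1e-10)
  }
  # observations exactly on the mean give zero logs
  p <- comp_to_sphere(c(0.3, 0.4, 0.3))
  sc <- constant_sample(p, n = 15)
  gc <- seq(0, 10, length.out = 11)
  muc <- estimate_mean_function(sc, 2, gc)
  ldc <- compute_log_data(sc, muc, gc, 2)
  expect_lt(max(abs(ldc$L)), 1e-8)
})

test_that("covariance surface is zero for on-mean data and transpose-symmetric", {
  p <- comp_to_sphere(c(0.3, 0.4, 0.3))
  s <- constant_sample(p, n = 25, seed = 6)
  grid <- seq(0, 10, length.out = 15)
  mu <- estimate_mean_function(s, 2, grid)
  ld <- compute_log_data(s, mu, grid, 2)
  G <- estimate_covariance(ld, 3, grid)
  expect_lt(max(abs(G)), 1e-12)

  params <- default_scenario(); params$n_subjects <- c(80, 0); params$seed <- 17L
  gen <- generate_sample(params, groups = 1)
  sg <- gen$sample
  g2 <- seq(min(unlist(sg$times)), max(unlist(sg$times)), length.out = 15)
  mu2 <- estimate_mean_function(sg, 0.65, g2)
  ld2 <- compute_log_data(sg, mu2, g2, 0.65)
  G2 <- estimate_covariance(ld2, 1.6, g2)
  for (q in 1:15) for (r in 1:15)
    expect_equal(G2[q, r, , ], t(G2[r, q, , ]), tolerance = 1e-12)
})

test_that("covariance recovers a rank-1 tangent structure from dense data", {
  grid <- seq(0, 1, length.out = 21)
  mu <- matrix(rep(comp_to_sphere(c(0.2, 0.3, 0.5)), 21), ncol = 3, byrow = TRUE)
  phi <- make_eigenfunctions(mu, grid, k = 1)
  lam <- 0.02
  set.seed(23)
  n <- 60
  ids <- sprintf("s%03d", 1:n)
  times <- rep(list(grid), n)  # dense noiseless design
  xi <- rnorm(n, 0, sqrt(lam))
  xi <- xi * sqrt(lam / mean(xi^2))  # exact empirical second moment
  obs <- lapply(1:n, function(i) {
    t(vapply(grid, function(tt) {
      v <- xi[i] * comptraj:::.interp_rows(grid, phi[, , 1], tt)
      exp_map(mu[1, ], v)
    }, numeric(3)))
  })
  s <- longitudinal_sample(ids, times, obs)
  mu_hat <- estimate_mean_function(s, 0.1, grid)
  ld <- compute_log_data(s, mu_hat, grid, 0.1)
  G <- estimate_covariance(ld, 0.08, grid)
  for (q in seq(1, 21, by = 5)) for (r in seq(1, 21, by = 5)) {
    truth <- lam * outer(phi[q, , 1], phi[r, , 1])
    expect_lt(max(abs(G[q, r, , ] - truth)), 0.1 * lam)
  }
})

test_that("eigendecomposition recovers an analytic rank-1 surface", {
  grid <- seq(0, 2, length.out = 26)
  mu <- make_mean_curve(list(ages = c(0, 2),
                             comps = rbind(c(0.2, 0.5, 0.3), c(0.3, 0.4, 0.3))), grid)
  phi <- make_eigenfunctions(mu, grid, k = 2)
  lam <- 0.5
  G <- array(0, c(26, 26, 3, 3))
  for (q in 1:26) for (r in 1:26)
    G[q, r, , ] <- lam * outer(phi[q, , 1], phi[r, , 1])
  eg <- eigendecompose(G, grid, mu)
  expect_equal(eg$lambda[1], lam, tolerance = 1e-6)
  expect_true(length(eg$lambda) == 1 || eg$lambda[2] < 1e-8)
  al <- quad_align(grid, eg$phi[, , 1], phi[, , 1])
  expect_equal(al, 1, tolerance = 1e-6)
  # trace conservation: positive spectrum sums to the integrated trace
  expect_equal(sum(eg$lambda_all), eg$total_var, tolerance = 1e-6)

  # zero surface has an empty positive spectrum
  eg0 <- eigendecompose(array(0, c(26, 26, 3, 3)), grid, mu)
  expect_length(eg0$lambda, 0)

  # fitted-model invariants: orthonormality, tangency, ordering
  w <- comptraj:::.quad_weights(grid)
  for (k in seq_len(eg$n_kept))
    expect_equal(sum(w * rowSums(eg$phi[, , k]^2)), 1, tolerance = 1e-6)
  expect_lt(max(abs(rowSums(eg$phi[, , 1] * mu))), 1e-6)
})

test_that("noise variance estimation brackets the truth", {
  # pure tangent noise around a constant mean, sigma2 = 0.04
  set.seed(29)
  p <- comp_to_sphere(c(0.25, 0.35, 0.4))
  n <- 500
  ids <- sprintf("s%03d", 1:n)
  times <- lapply(1:n, function(i) sort(runif(2, 0, 4)))
  obs <- lapply(times, function(tt) {
    t(vapply(tt, function(x) {
      b <- comptraj:::.tangent_basis(p)
      e <- rnorm(2, 0, sqrt(0.04 / 2))
      exp_map(p, e[1] * b$u + e[2] * b$v)
    }, numeric(3)))
  })
  s <- longitudinal_sample(ids, times, obs)
  grid <- seq(0, 4, length.out = 21)
  mu <- estimate_mean_function(s, 0.5, grid)
  ld <- compute_log_data(s, mu, grid, 0.5)
  G <- estimate_covariance(ld, 1, grid)
  s2 <- estimate_noise_variance(ld, G, 0.6, grid)
  expect_gt(s2, 0.03); expect_lt(s2, 0.05)

  # noiseless signal: estimate near zero relative to the signal size
  # (richer 5-visit design supports the smaller bandwidths used here)
  params <- default_scenario(); params$sigma <- 0
  params$n_subjects <- c(200, 0); params$seed <- 31L
  params$visit_probs <- c(0, 0, 0, 0, 1, 0)
  gen <- generate_sample(params, groups = 1)
  fit <- fit_rfpca(gen$sample,
                   rfpca_options(bw_mean = 0.45, bw_cov = 0.6, bw_noise = 0.7))
  tr_mean <- mean(vapply(seq_along(fit$grid), function(q)
    sum(diag(fit$Gamma[q, q, , ])), numeric(1)))
  expect_lte(fit$sigma2, 0.01 * tr_mean)
})

test_that("select_K follows the fraction-of-variance rule", {
  expect_equal(select_K(c(9, 1), 0.9), 1)
  expect_equal(select_K(c(5, 4, 1), 0.9), 2)
  expect_equal(select_K(c(7), 0.99), 1)
  expect_equal(select_K(c(5, 4, 1), 0.9, total = 20), 3)  # explicit denominator
  expect_error(select_K(c(0, 0)), "zero")
})

test_that("BLUP scores: zero on the mean, quadrature oracle when dense, shrinkage with noise", {
  params <- default_scenario(); params$n_subjects <- c(150, 0); params$seed <- 37L
  gen <- generate_sample(params, groups = 1)
  fit <- fit_rfpca(gen$sample)

  # subject observed exactly on the mean has zero scores
  tt <- c(2.5, 4.0, 6.0)
  mu_t <- comptraj:::.mean_at_times(fit$pool, fit$grid, fit$mu, tt, fit$bandwidths["mean"])
  expect_equal(conditional_scores(fit, tt, mu_t), rep(0, fit$K), tolerance = 1e-8)

  # dense noiseless subject: BLUP matches the Karhunen-Loeve integral scores
  xi_true <- c(0.15, -0.08)
  Y <- t(vapply(seq_along(fit$grid), function(q) {
    v <- xi_true[1] * fit$phi[q, , 1] + xi_true[2] * fit$phi[q, , 2]
    exp_map(fit$mu[q, ], v)
  }, numeric(3)))
  sc <- conditional_scores(fit, fit$grid, Y)
  L <- t(vapply(seq_along(fit$grid), function(q)
    log_map(fit$mu[q, ], Y[q, ]), numeric(3)))
  w <- comptraj:::.quad_weights(fit$grid)
  integral <- vapply(1:fit$K, function(k)
    sum(w * rowSums(L * fit$phi[, , k])), numeric(1))
  expect_lt(max(abs(sc - integral)), 1e-3)
  expect_equal(integral[1:2], xi_true, tolerance = 1e-6)

  # shrinkage: growing noise variance shrinks scores monotonically to zero
  tt2 <- c(3, 5); Y2 <- Y[c(11, 27), ]
  norms <- vapply(c(fit$sigma2, 0.01, 0.1, 1, 10), function(s2) {
    f2 <- fit; f2$sigma2 <- s2
    sqrt(sum(conditional_scores(f2, tt2, Y2)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("reconstruction and prediction mechanics", {
  params <- default_scenario(); params$n_subjects <- c(120, 0); params$seed <- 41L
  gen <- generate_sample(params, groups = 1)
  fit <- fit_rfpca(gen$sample)

  rec0 <- reconstruct_trajectory(fit, rep(0, fit$K))
  expect_equal(rec0$sphere, fit$mu, tolerance = 1e-12)
  expect_equal(rowSums(rec0$composition), rep(1, length(fit$grid)))

  rec <- reconstruct_trajectory(fit, c(0.2, -0.1)[1:fit$K])
  expect_equal(sqrt(rowSums(rec$sphere^2)), rep(1, length(fit$grid)),
               tolerance = 1e-12)
  expect_equal(rowSums(rec$composition), rep(1, length(fit$grid)))

  # on-mean history predicts the mean composition
  tt <- c(2, 3.5, 5)
  mu_t <- comptraj:::.mean_at_times(fit$pool, fit$grid, fit$mu, tt, fit$bandwidths["mean"])
  pred <- predict_at_age(fit, tt, mu_t, 6.5)
  mu_65 <- comptraj:::.mean_at_times(fit$pool, fit$grid, fit$mu, 6.5, fit$bandwidths["mean"])
  expect_equal(pred, sphere_to_comp(mu_65[1, ]), tolerance = 1e-6)
  expect_equal(sum(pred), 1)
  expect_error(predict_at_age(fit, tt, mu_t, 99), "outside")

  # dense noiseless 2-component subject reconstructed within 0.02 rad
  xi_true <- c(-0.12, 0.06)
  Y <- t(vapply(seq_along(fit$grid), function(q) {
    v <- xi_true[1] * fit$phi[q, , 1] + xi_true[2] * fit$phi[q, , 2]
    exp_map(fit$mu[q, ], v)
  }, numeric(3)))
  sc <- conditional_scores(fit, fit$grid, Y)
  rec2 <- reconstruct_trajectory(fit, sc[1:2], K = 2)
  errs <- vapply(seq_along(fit$grid), function(q)
    geodesic_distance(rec2$sphere[q, ], Y[q, ]), numeric(1))
  expect_lt(max(errs), 0.02)
})

test_that("tangent-space FPCA matches Euclidean FPCA in the small-curvature limit", {
  params <- default_scenario()
  params$n_subjects <- c(120, 0); params$seed <- 43L
  params$lambda <- c(4e-8, 1e-8); params$sigma <- 5e-5
  params$visit_probs <- c(0, 0, 1, 0, 0, 0)
  cc <- c(0.25, 0.4, 0.35)
  params$mean_anchors <- list(ages = c(1.5, 8), comps = rbind(cc, cc))
  gen <- generate_sample(params, groups = 1)
  # data diameter is tiny: all points within a ball of radius << 0.01 rad
  pool <- comptraj:::.pool_sample(gen$sample)
  ctr <- comp_to_sphere(cc)
  expect_lt(max(acos(pmin(1, pool$obs %*% ctr))), 0.005)

  opts <- rfpca_options(n_grid = 31, bw_mean = 0.9, bw_cov = 1.6)
  fit <- fit_rfpca(gen$sample, opts)
  eu <- euclidean_sparse_fpca(gen$sample, bw_mean = 0.9, bw_cov = 1.6, n_grid = 31)
  for (k in 1:2)
    expect_equal(fit$lambda[k], eu$lambda[k], tolerance = 0.01)
})
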
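# Seeded synthetic-cohort generator with known Karhunen-Loeve ground truth.
# Emulates a sparse longitudinal neuroimaging design: two maternal-education
# groups, 1-6 visits per child with a long-tailed repeat distribution, ages
# 1.5-8 years, and a smooth mean composition with white matter increasing and
# grey matter decreasing over age.

#' Default simulation scenario
#'
#' Two groups of 227 and 116 subjects; visit counts drawn from the pooled
#' repeat frequencies (207, 82, 30, 13, 10, 1 for 1..6 visits, about 1.81
#' visits per child); visit ages i.i.d. uniform on 1.5–8 years; two
#' Karhunen–Loève components with eigenvalues 0.012 and 0.004 (tangent
#' radians squared); intrinsic noise with total variance `sigma^2 = 0.02^2`;
#' and a group-2 mean offset that slows white-matter growth between ages 1.5
#' and 4.5 years.
#'
#' @return A scenario parameter list accepted by [generate_sample()].
#' @export
default_scenario <- function() {
  list(
    n_subjects = c(227, 116),
    visit_probs = c(207, 82, 30, 13, 10, 1) / 343,
    age_range = c(1.5, 8.0),
    mean_anchors = list(
      ages = c(1.5, 3.5, 5.5, 8.0),
      comps = rbind(c(0.100, 0.600, 0.300),
                    c(0.095, 0.565, 0.340),
                    c(0.090, 0.545, 0.365),
                    c(0.085, 0.530, 0.385))),
    group2_anchors = list(
      ages = c(1.5, 3.5, 5.5, 8.0),
      comps = rbind(c(0.100, 0.600, 0.300),
                    c(0.098, 0.600, 0.302),
                    c(0.092, 0.570, 0.338),
                    c(0.087, 0.538, 0.375))),
    lambda = c(0.012, 0.004),
    sigma = 0.02,
    seed = 1L)
}

#' Smooth mean curve on the sphere from compositional anchors
#'
#' Natural cubic spline interpolation of the anchor compositions over age
#' (renormalized to sum to 1), mapped to the sphere by the square-root
#' transform. The curve passes through the mapped anchors at the anchor ages.
#'
#' @param anchors List with `ages` and a matrix `comps` of anchor
#'   compositions (rows summing to 1).
#' @param grid Evaluation ages (within the anchor range).
#' @return Matrix `length(grid) x 3` of unit rows, strictly inside the
#'   positive segment.
#' @export
make_mean_curve <- function(anchors, grid) {
  ages <- anchors$ages
  comps <- as.matrix(anchors$comps)
  stopifnot(nrow(comps) == length(ages))
  for (i in seq_len(nrow(comps))) comps[i, ] <- as_composition(comps[i, ])
  C <- sapply(1:3, function(d)
    stats::spline(ages, comps[, d], xout = grid, method = "natural")$y)
  C <- matrix(C, ncol = 3)
  if (any(C < 0)) stop("interpolated mean composition leaves the simplex")
  C <- C / rowSums(C)
  t(apply(C, 1, comp_to_sphere))
}

#' Construct orthonormal tangent eigenfunctions along a mean curve
#'
#' Builds two smooth tangent fields along `mu` (a slowly varying direction
#' and an oscillating mixture of the two frame directions) and
#' Gram–Schmidt-orthonormalizes them under the grid quadrature. Tangency to
#' `mu(t)` holds at every grid point.
#'
#' @param mu Mean matrix (`ng x 3` unit rows).
#' @param grid Grid ages.
#' @param k Number of eigenfunctions (1 or 2).
#' @return Array `ng x 3 x k`.
#' @export
make_eigenfunctions <- function(mu, grid, k = 2) {
  ng <- length(grid)
  a <- c(0, 0, 1)
  U <- matrix(NA_real_, ng, 3); V <- matrix(NA_real_, ng, 3)
  for (q in 1:ng) {
    u <- a - sum(a * mu[q, ]) * mu[q, ]
    nu <- sqrt(sum(u^2))
    if (nu < 1e-6) stop("degenerate frame: mean curve passes through the frame pole")
    U[q, ] <- u / nu
    V[q, ] <- c(mu[q, 2] * U[q, 3] - mu[q, 3] * U[q, 2],
                mu[q, 3] * U[q, 1] - mu[q, 1] * U[q, 3],
                mu[q, 1] * U[q, 2] - mu[q, 2] * U[q, 1])
  }
  s <- (grid - grid[1]) / (grid[ng] - grid[1])
  raw <- array(NA_real_, c(ng, 3, 2))
  raw[, , 1] <- U
  raw[, , 2] <- sin(2 * pi * s) * U + cos(pi * s) * V
  w <- .quad_weights(grid)
  ip <- function(f, g) sum(w * rowSums(f * g))
  phi <- array(NA_real_, c(ng, 3, k))
  phi[, , 1] <- raw[, , 1] / sqrt(ip(raw[, , 1], raw[, , 1]))
  if (k >= 2) {
    g2 <- raw[, , 2] - ip(raw[, , 2], phi[, , 1]) * phi[, , 1]
    n2 <- sqrt(ip(g2, g2))
    if (n2 < 1e-8) stop("degenerate frame: second field collinear with first")
    phi[, , 2] <- g2 / n2
  }
  phi
}

#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' Per subject: the visit count is drawn from the categorical repeat law,
#' visit ages are i.i.d. uniform and sorted, Karhunen–Loève scores are
#' `N(0, lambda_k)`, the smooth tangent signal is `L_i(t) = sum_k xi_ik
#' phi_k(t)`, measurement noise is isotropic in the tangent plane with total
#' variance `sigma^2`, and observations are `Y_ij =
#' Exp_{mu(T_ij)}(L_i(T_ij) + eps_ij)` (projected back to the positive
#' segment if necessary). Fully reproducible from `params$seed`.
#'
#' @param params Scenario list (see [default_scenario()]).
#' @param groups Which groups to generate (default both).
#' @return List with `sample` (a [longitudinal_sample()]) and `truth`
#'   (dense-grid mean, eigenfunctions, eigenvalues, noise variance, and
#'   per-subject true scores).
#' @export
generate_sample <- function(params = default_scenario(), groups = NULL) {
  stopifnot(params$lambda[1] >= params$lambda[2], all(params$lambda >= 0),
            params$sigma >= 0,
            abs(sum(params$visit_probs) - 1) < 1e-8)
  if (sqrt(sum(params$lambda)) * 4 + 4 * params$sigma > pi / 2)
    stop("wraparound: score/noise scale implies tangent norms near pi")
  n_groups <- length(params$n_subjects)
  if (is.null(groups)) groups <- seq_len(n_groups)
  rng <- .local_rng(params$seed)
  on.exit(.restore_rng(rng))

  dense <- seq(params$age_range[1], params$age_range[2], length.out = 101)
  mu_g <- list(make_mean_curve(params$mean_anchors, dense))
  if (n_groups >= 2)
    mu_g[[2]] <- make_mean_curve(params$group2_anchors, dense)
  phi <- make_eigenfunctions(mu_g[[1]], dense, k = 2)

  ids <- character(0); times <- list(); obs <- list(); grp <- character(0)
  true_scores <- NULL
  sigma2 <- params$sigma^2
  for (g in groups) {
    n_g <- params$n_subjects[g]
    mu <- mu_g[[min(g, length(mu_g))]]
    for (i in seq_len(n_g)) {
      m <- sample.int(length(params$visit_probs), 1, prob = params$visit_probs)
      tt <- sort(stats::runif(m, params$age_range[1], params$age_range[2]))
      xi <- stats::rnorm(2, 0, sqrt(params$lambda))
      Y <- matrix(NA_real_, m, 3)
      for (j in seq_len(m)) {
        muj <- .interp_rows(dense, mu, tt[j])
        muj <- muj / sqrt(sum(muj^2))
        L <- xi[1] * .interp_rows(dense, phi[, , 1], tt[j]) +
             xi[2] * .interp_rows(dense, phi[, , 2], tt[j])
        # noise in an orthonormal tangent basis at muj, sigma^2/2 per direction
        e1 <- .tangent_basis(muj)
        eps <- stats::rnorm(2, 0, params$sigma / sqrt(2))
        L <- L + eps[1] * e1$u + eps[2] * e1$v
        L <- L - sum(L * muj) * muj
        Y[j, ] <- project_to_positive_segment(exp_map(muj, L))
      }
      id <- sprintf("g%d_s%04d", g, i)
      ids <- c(ids, id); times <- c(times, list(tt)); obs <- c(obs, list(Y))
      grp <- c(grp, sprintf("group%d", g))
      true_scores <- rbind(true_scores, xi)
    }
  }
  rownames(true_scores) <- ids
  list(sample = longitudinal_sample(ids, times, obs, group = grp),
       truth = list(grid = dense, mu = mu_g, phi = phi,
                    lambda = params$lambda, sigma2 = sigma2,
                    scores = true_scores))
}

# Orthonormal basis of the tangent plane at unit vector p.
.tangent_basis <- function(p) {
  a <- if (abs(p[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * p) * p
  u <- u / sqrt(sum(u^2))
  v <- c(p[2] * u[3] - p[3] * u[2],
         p[3] * u[1] - p[1] * u[3],
         p[1] * u[2] - p[2] * u[1])
  list(u = u, v = v)
}
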
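# Group inference: energy-distance two-sample permutation test on principal
# component scores, ternary coordinates, and bootstrap confidence regions for
# mean compositions at fixed ages.

#' Energy distance between two multivariate samples
#'
#' V-statistic convention: `2 * mean ||a - b|| - mean ||a - a'|| -
#' mean ||b - b'||`, with within-sample means over all ordered pairs
#' including self-pairs, so the statistic is nonnegative and zero exactly
#' when the two empirical distributions coincide.
#'
#' @param A,B Numeric matrices (rows = observations) or vectors; same number
#'   of columns.
#' @return Nonnegative scalar.
#' @export
energy_distance <- function(A, B) {
  A <- if (is.null(dim(A))) matrix(A, ncol = 1) else as.matrix(A)
  B <- if (is.null(dim(B))) matrix(B, ncol = 1) else as.matrix(B)
  if (ncol(A) != ncol(B)) stop("dimension mismatch between samples")
  if (nrow(A) < 1 || nrow(B) < 1) stop("both samples must be non-empty")
  D <- .pdist(rbind(A, B))
  .energy_from_dist(D, seq_len(nrow(A)), nrow(A) + seq_len(nrow(B)))
}

# Euclidean distance matrix of the rows of X.
.pdist <- function(X) {
  G <- tcrossprod(X)
  n2 <- diag(G)
  D2 <- outer(n2, n2, "+") - 2 * G
  sqrt(pmax(D2, 0))
}

.energy_from_dist <- function(D, ia, ib) {
  2 * mean(D[ia, ib]) - mean(D[ia, ia]) - mean(D[ib, ib])
}

#' Energy-distance two-sample permutation test
#'
#' Tests equality of the two generating distributions by permuting group
#' labels (group sizes preserved). The p-value uses the add-one convention
#' `(1 + #{perm >= obs}) / (1 + B)`, so it never reaches zero. For small
#' samples `exhaustive = TRUE` enumerates all label assignments instead.
#'
#' @param A,B Score matrices (rows = subjects).
#' @param n_perm Number of random permutations (default 9999).
#' @param seed Integer seed; the test is deterministic given the seed.
#' @param exhaustive Enumerate all `choose(nA + nB, nA)` relabelings.
#' @return List of class `energy_test` with `statistic`, `p_value`,
#'   `n_permutations`, `seed`, and group sizes.
#' @export
energy_permutation_test <- function(A, B, n_perm = 9999, seed = 1,
                                    exhaustive = FALSE) {
  A <- if (is.null(dim(A))) matrix(A, ncol = 1) else as.matrix(A)
  B <- if (is.null(dim(B))) matrix(B, ncol = 1) else as.matrix(B)
  if (ncol(A) != ncol(B)) stop("dimension mismatch between samples")
  na <- nrow(A); nb <- nrow(B); N <- na + nb
  if (na < 1 || nb < 1) stop("degenerate group size")
  if (N < 2) stop("pooled sample too small")
  D <- .pdist(rbind(A, B))
  obs <- .energy_from_dist(D, seq_len(na), na + seq_len(nb))

  if (exhaustive) {
    combos <- utils::combn(N, na)
    stats <- apply(combos, 2, function(ia)
      .energy_from_dist(D, ia, setdiff(seq_len(N), ia)))
    p <- mean(stats >= obs - 1e-12)  # includes the identity relabeling
    return(structure(list(statistic = obs, p_value = p,
                          n_permutations = ncol(combos) - 1L, seed = NA_integer_,
                          n_A = na, n_B = nb, exhaustive = TRUE),
                     class = "energy_test"))
  }

  rng <- .local_rng(seed)
  on.exit(.restore_rng(rng))
  # vectorized permutation statistics via indicator algebra:
  # with z the 0/1 group-A indicator, sum_AA = z'Dz etc., all computed for a
  # block of permutations with one matrix product.
  rs <- rowSums(D); S <- sum(D)
  n_ge <- 0L
  done <- 0L
  block <- 250L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    Z <- matrix(0, N, b)
    for (j in seq_len(b)) Z[sample.int(N, na), j] <- 1
    M <- D %*% Z
    saa <- colSums(M * Z)
    sa_tot <- colSums(rs * Z)
    sab <- sa_tot - saa
    sbb <- S - 2 * sa_tot + saa
    stat <- 2 * sab / (na * nb) - saa / na^2 - sbb / nb^2
    n_ge <- n_ge + sum(stat >= obs - 1e-12)
    done <- done + b
  }
  p <- (1 + n_ge) / (1 + n_perm)
  structure(list(statistic = obs, p_value = p, n_permutations = n_perm,
                 seed = seed, n_A = na, n_B = nb, exhaustive = FALSE),
            class = "energy_test")
}

#' @export
print.energy_test <- function(x, ...) {
  cat(sprintf("Energy-distance two-sample permutation test\n"))
  cat(sprintf("  statistic = %.6g, p-value = %.4g (%s permutations)\n",
              x$statistic, x$p_value,
              if (isTRUE(x$exhaustive)) "exhaustive" else format(x$n_permutations)))
  cat(sprintf("  group sizes: %d vs %d\n", x$n_A, x$n_B))
  invisible(x)
}

#' Compare two groups of trajectories by their principal component scores
#'
#' Fits a single pooled RFPCA model (so both groups share a basis), extracts
#' the top `n_scores` BLUP scores, and runs the energy-distance permutation
#' test between the two groups.
#'
#' @param sample A [longitudinal_sample()] with exactly two group labels.
#' @param n_perm,seed Permutation settings.
#' @param n_scores Number of leading scores compared (default 2).
#' @param fit Optional pre-computed pooled [fit_rfpca()] result.
#' @param options Fitting options when `fit` is not supplied.
#' @return An `energy_test` with the pooled fit attached as `fit`.
#' @export
test_group_difference <- function(sample, n_perm = 9999, seed = 1,
                                  n_scores = 2, fit = NULL,
                                  options = rfpca_options()) {
  if (is.null(sample$group)) stop("sample has no group labels")
  gl <- unique(sample$group)
  if (length(gl) != 2) stop("exactly two groups required")
  if (is.null(fit)) fit <- fit_rfpca(sample, options)
  k <- min(n_scores, ncol(fit$scores))
  sc <- fit$scores[, seq_len(k), drop = FALSE]
  res <- energy_permutation_test(sc[sample$group == gl[1], , drop = FALSE],
                                 sc[sample$group == gl[2], , drop = FALSE],
                                 n_perm = n_perm, seed = seed)
  res$groups <- gl
  res$fit <- fit
  res
}

#' Ternary plane coordinates of a composition
#'
#' Maps a composition `(a, b, c)` to the Cartesian coordinates of the
#' ternary diagram: `x = b + c/2`, `y = sqrt(3)/2 * c`, so the three
#' vertices are `(0,0)`, `(1,0)` and `(0.5, sqrt(3)/2)`.
#'
#' @param c Composition (3-vector) or matrix with one composition per row.
#' @return Numeric vector `(x, y)` or a 2-column matrix.
#' @export
ternary_coords <- function(c) {
  if (is.null(dim(c))) {
    c <- as_composition(c)
    return(c(x = c[2] + c[3] / 2, y = sqrt(3) / 2 * c[3]))
  }
  t(apply(c, 1, ternary_coords))
}

# Bivariate Gaussian KDE with Scott's-rule bandwidths, evaluated both on a
# regular grid and at the data points themselves.
.kde2 <- function(pts, n_grid = 200) {
  n <- nrow(pts)
  sds <- pmax(apply(pts, 2, stats::sd), 1e-9)
  h <- sds * n^(-1 / 6)
  lims <- c(range(pts[, 1]) + c(-4, 4) * h[1],
            range(pts[, 2]) + c(-4, 4) * h[2])
  kd <- MASS::kde2d(pts[, 1], pts[, 2], h = 4 * h, n = n_grid, lims = lims)
  # density at the points via the same kernel sum
  f_pts <- vapply(seq_len(n), function(i) {
    mean(stats::dnorm(pts[, 1], pts[i, 1], h[1]) *
         stats::dnorm(pts[, 2], pts[i, 2], h[2]))
  }, numeric(1))
  list(x = kd$x, y = kd$y, z = kd$z, f_pts = f_pts, h = h)
}

#' Bootstrap confidence regions for mean compositions at fixed ages
#'
#' Resamples subjects with replacement, re-estimates the kernel-localized
#' Fréchet mean composition at each requested age per replicate, converts the
#' bootstrap point cloud to ternary coordinates, and anchors the confidence
#' region on a kernel density contour: the smallest-density threshold whose
#' superlevel set contains at least `level` of the bootstrap points.
#'
#' @param sample A [longitudinal_sample()].
#' @param ages Ages at which regions are built (default 2.8, 4.1, 5.4, 6.7).
#' @param n_boot Number of bootstrap replicates (default 400).
#' @param level Coverage level (default 0.95).
#' @param seed Integer seed.
#' @param bandwidth Mean bandwidth (default 0.10 of the observed range).
#' @return Object of class `confidence_regions`: per age, the point estimate,
#'   the bootstrap ternary points, the density threshold, the contour
#'   polylines (each closed), and a membership function is available through
#'   [in_region()].
#' @export
bootstrap_mean_regions <- function(sample, ages = c(2.8, 4.1, 5.4, 6.7),
                                   n_boot = 400, level = 0.95, seed = 1,
                                   bandwidth = NULL) {
  pool <- .pool_sample(sample)
  rng_t <- range(pool$times)
  if (any(ages < rng_t[1]) || any(ages > rng_t[2]))
    stop("requested ages outside the observed range")
  if (is.null(bandwidth)) bandwidth <- 0.10 * diff(rng_t)
  est <- t(vapply(ages, function(a)
    sphere_to_comp(.local_frechet(pool$times, pool$obs, a, bandwidth)),
    numeric(3)))

  n <- n_subjects(sample)
  rng <- .local_rng(seed)
  on.exit(.restore_rng(rng))
  boot_comp <- array(NA_real_, c(n_boot, length(ages), 3))
  failures <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bt <- unlist(sample$times[idx], use.names = FALSE)
    bo <- do.call(rbind, sample$obs[idx])
    ok <- tryCatch({
      for (ai in seq_along(ages))
        boot_comp[b, ai, ] <- sphere_to_comp(
          .local_frechet(bt, bo, ages[ai], bandwidth))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) { failures <- failures + 1L; boot_comp[b, , ] <- NA_real_ }
  }
  if (failures > 0.10 * n_boot)
    stop(sprintf("too many bootstrap failures (%d of %d)", failures, n_boot))
  if (failures > 0)
    warning(sprintf("%d bootstrap replicate(s) failed and were skipped", failures))

  regions <- vector("list", length(ages))
  for (ai in seq_along(ages)) {
    Mb <- boot_comp[, ai, ]
    pts <- ternary_coords(Mb[stats::complete.cases(Mb), , drop = FALSE])
    nb <- nrow(pts)
    if (max(apply(pts, 2, stats::sd)) < 1e-10) {
      # degenerate: all bootstrap points coincide
      ctr <- colMeans(pts)
      eps <- 1e-6
      poly <- cbind(x = ctr[1] + eps * cos(seq(0, 2 * pi, length.out = 33)),
                    y = ctr[2] + eps * sin(seq(0, 2 * pi, length.out = 33)))
      regions[[ai]] <- list(age = ages[ai], level = level, estimate = est[ai, ],
                            points = pts, threshold = 0, degenerate = TRUE,
                            contours = list(poly), kde = NULL)
      next
    }
    kd <- .kde2(pts)
    k_drop <- floor((1 - level) * nb)
    thr <- if (k_drop >= 1) sort(kd$f_pts)[k_drop + 1] else min(kd$f_pts)
    thr <- thr * (1 - 1e-9)
    cl <- grDevices::contourLines(kd$x, kd$y, kd$z, levels = thr)
    contours <- lapply(cl, function(cc) {
      P <- cbind(x = cc$x, y = cc$y)
      if (any(P[1, ] != P[nrow(P), ])) P <- rbind(P, P[1, ])
      P
    })
    regions[[ai]] <- list(age = ages[ai], level = level, estimate = est[ai, ],
                          points = pts, threshold = thr, degenerate = FALSE,
                          contours = contours,
                          kde = kd[c("x", "y", "z", "h")])
  }
  structure(list(ages = ages, level = level, n_boot = n_boot, seed = seed,
                 n_failures = failures, regions = regions),
            class = "confidence_regions")
}

#' Test whether a composition lies inside a bootstrap confidence region
#'
#' Membership is defined by the kernel density superlevel set anchoring the
#' region: a point is inside when the estimated density at its ternary
#' coordinates reaches the region's threshold.
#'
#' @param regions A `confidence_regions` object.
#' @param age One of the ages the regions were built at.
#' @param comp Composition to test.
#' @return Logical.
#' @export
in_region <- function(regions, age, comp) {
  ai <- which(abs(regions$ages - age) < 1e-9)
  if (length(ai) != 1) stop("no region at that age")
  r <- regions$regions[[ai]]
  xy <- ternary_coords(comp)
  if (isTRUE(r$degenerate))
    return(sqrt(sum((xy - colMeans(r$points))^2)) < 1e-4)
  h <- r$kde$h
  f <- mean(stats::dnorm(r$points[, 1], xy[1], h[1]) *
            stats::dnorm(r$points[, 2], xy[2], h[2]))
  f >= r$threshold
}

#' @export
print.confidence_regions <- function(x, ...) {
  cat(sprintf("Bootstrap confidence regions (level %.0f%%, %d replicates)\n",
              100 * x$level, x$n_boot))
  for (r in x$regions)
    cat(sprintf("  age %.2f: estimate (%.3f, %.3f, %.3f)%s\n", r$age,
                r$estimate[1], r$estimate[2], r$estimate[3],
                if (r$degenerate) " [degenerate]" else ""))
  invisible(x)
}
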
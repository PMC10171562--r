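# Local-linear kernel smoothers used by the mean and covariance estimators.
# Sparse longitudinal designs leave near-empty kernel windows close to the
# domain boundary, so both smoothers adaptively widen the local bandwidth
# (doubling, up to 3 times) before failing.

#' Epanechnikov kernel
#'
#' `0.75 * (1 - u^2)` on `[-1, 1]`, zero outside. The default kernel for all
#' mean and covariance smoothing in this package.
#'
#' @param u Numeric vector.
#' @return Kernel weights.
#' @export
epanechnikov <- function(u) {
  w <- 0.75 * (1 - u^2)
  w[abs(u) > 1] <- 0
  w
}

# Local-linear fit at a single point x0. Returns fitted value or NA when the
# (widened) window never gains >= 2 distinct predictor values.
.ll1_at <- function(x, y, w, h, x0, max_widen = 3L) {
  for (k in 0:max_widen) {
    hk <- h * 2^k
    kw <- epanechnikov((x - x0) / hk) * w
    idx <- which(kw > 0)
    if (length(idx) >= 2 && length(unique(x[idx])) >= 2) {
      xs <- x[idx] - x0
      ww <- kw[idx]
      sw <- sum(ww); s1 <- sum(ww * xs); s2 <- sum(ww * xs^2)
      sy <- sum(ww * y[idx]); sxy <- sum(ww * xs * y[idx])
      den <- sw * s2 - s1^2
      if (den > .Machine$double.eps * sw * max(s2, 1)) {
        return((s2 * sy - s1 * sxy) / den)
      }
    }
    if (length(idx) >= 1 && k == max_widen) {
      # degenerate but nonempty window: fall back to the local constant fit
      return(sum(kw[idx] * y[idx]) / sum(kw[idx]))
    }
  }
  NA_real_
}

#' One-dimensional local-linear smoother
#'
#' Weighted local-linear regression with the Epanechnikov kernel, evaluated on
#' a grid. Reproduces affine functions exactly.
#'
#' @param x Predictor values (e.g. age in years).
#' @param y Responses.
#' @param grid Sorted evaluation points.
#' @param bandwidth Kernel half-width, same units as `x`; must be positive.
#' @param weights Optional nonnegative observation weights.
#' @return Numeric vector of fitted values, one per grid point.
#' @export
local_linear_1d <- function(x, y, grid, bandwidth, weights = NULL) {
  stopifnot(length(x) == length(y), bandwidth > 0)
  if (is.unsorted(grid)) stop("grid must be sorted ascending")
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x)) stop("weights length mismatch")
  fit <- vapply(grid, function(g) .ll1_at(x, y, weights, bandwidth, g), numeric(1))
  if (anyNA(fit))
    stop(sprintf("bandwidth too small: empty window at grid point(s) %s even after widening",
                 paste(signif(grid[is.na(fit)], 4), collapse = ", ")))
  fit
}

# Local plane fit at (s0, t0) for a multi-response matrix V (n x q) with
# product Epanechnikov weights. Returns the q fitted values, or NULL when the
# window stays deficient. The projection row of the weighted LS system is
# shared across responses, so all q surfaces cost one solve.
.ll2_at <- function(s, t, V, w, h, s0, t0, max_widen = 3L) {
  for (k in 0:max_widen) {
    hk <- h * 2^k
    kw <- epanechnikov((s - s0) / hk) * epanechnikov((t - t0) / hk) * w
    idx <- which(kw > 0)
    if (length(idx) >= 3) {
      ds <- s[idx] - s0; dt <- t[idx] - t0
      X <- cbind(1, ds, dt)
      ww <- kw[idx]
      XtW <- t(X * ww)
      A <- XtW %*% X
      if (rcond(A) > 1e-12) {
        b <- solve(A, XtW %*% V[idx, , drop = FALSE])
        return(b[1L, ])
      }
    }
    if (length(idx) >= 1 && k == max_widen) {
      kwv <- kw[idx]
      return(colSums(V[idx, , drop = FALSE] * kwv) / sum(kwv))
    }
  }
  NULL
}

#' Two-dimensional local-linear surface smoother
#'
#' Fits a weighted local plane (intercept + two slopes) at every node of
#' `grid x grid` with product Epanechnikov weights, for one or several
#' response surfaces sharing the same design points. Scalar output is
#' symmetrized as `(S + t(S)) / 2`.
#'
#' @param s,t Pair coordinates of the scattered input points.
#' @param values Numeric vector (single surface) or matrix with one column
#'   per surface.
#' @param grid Sorted evaluation grid (the surface is evaluated on
#'   `grid x grid`).
#' @param bandwidth Kernel half-width in each coordinate.
#' @param weights Optional nonnegative weights.
#' @param symmetrize Symmetrize each fitted surface (default `TRUE`).
#' @return For a vector input, a `length(grid) x length(grid)` matrix; for a
#'   matrix input, a 3-d array `length(grid) x length(grid) x ncol(values)`.
#' @export
local_linear_2d <- function(s, t, values, grid, bandwidth, weights = NULL,
                            symmetrize = TRUE) {
  V <- if (is.null(dim(values))) matrix(values, ncol = 1) else as.matrix(values)
  stopifnot(length(s) == length(t), nrow(V) == length(s), bandwidth > 0)
  if (is.null(weights)) weights <- rep(1, length(s))
  ng <- length(grid); q <- ncol(V)
  out <- array(NA_real_, c(ng, ng, q))
  for (a in seq_len(ng)) {
    for (b in seq_len(ng)) {
      v <- .ll2_at(s, t, V, weights, bandwidth, grid[a], grid[b])
      if (is.null(v))
        stop(sprintf("bandwidth too small: deficient window at (%.3g, %.3g) even after widening",
                     grid[a], grid[b]))
      out[a, b, ] <- v
    }
  }
  if (symmetrize) for (j in seq_len(q)) out[, , j] <- (out[, , j] + t(out[, , j])) / 2
  if (q == 1L) out[, , 1L] else out
}

#' Cross-validated bandwidth selection
#'
#' Selects the bandwidth minimizing k-fold cross-validated squared prediction
#' error for the 1-d local-linear smoother. Folds are split by subject so that
#' within-subject correlation does not leak across folds.
#'
#' @param x,y Observations.
#' @param subject_ids Subject identifier per observation (fold unit).
#' @param candidates Candidate bandwidths (at least one).
#' @param k_folds Number of folds.
#' @param seed Integer seed controlling the fold split.
#' @return The selected bandwidth (scalar).
#' @export
select_bandwidth_cv <- function(x, y, subject_ids, candidates, k_folds = 5, seed = 1) {
  stopifnot(length(candidates) >= 1)
  subj <- unique(subject_ids)
  rng <- .local_rng(seed)
  fold_of <- setNames(sample(rep_len(seq_len(k_folds), length(subj))), subj)
  .restore_rng(rng)
  err <- rep(NA_real_, length(candidates))
  for (ci in seq_along(candidates)) {
    h <- candidates[ci]
    sse <- 0; nok <- 0; failed <- FALSE
    for (f in seq_len(k_folds)) {
      hold <- fold_of[as.character(subject_ids)] == f
      if (!any(hold) || !any(!hold)) next
      pred <- tryCatch({
        xs <- sort(unique(x[hold]))
        fit <- local_linear_1d(x[!hold], y[!hold], xs, h)
        fit[match(x[hold], xs)]
      }, error = function(e) NULL)
      if (is.null(pred)) { failed <- TRUE; break }
      sse <- sse + sum((y[hold] - pred)^2); nok <- nok + sum(hold)
    }
    if (!failed && nok > 0) err[ci] <- sse / nok
  }
  if (all(is.na(err)))
    stop("no candidate bandwidth admissible: ",
         paste(signif(candidates, 4), collapse = ", "))
  candidates[which.min(err)]
}

# Run code under a private RNG state so package internals never disturb the
# caller's random stream.
.local_rng <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(has = has, old = old)
}

.restore_rng <- function(state) {
  if (state$has) assign(".Random.seed", state$old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
  invisible(NULL)
}
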
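# Sphere geometry and compositional transforms.
#
# Compositions (nonnegative 3-vectors summing to 1) are mapped to the positive
# segment of the unit sphere S^2 by the elementwise square root; all intrinsic
# statistics are then carried out with the sphere's geodesic geometry.

.COMP_SUM_TOL <- 1e-8
.UNIT_NORM_TOL <- 1e-10
.TANGENT_TOL <- 1e-8

#' Validate a composition
#'
#' A composition is a nonnegative numeric vector (here length 3: e.g. pCSF,
#' pGM, pWM) whose entries sum to 1.
#'
#' @param c Numeric vector of proportions.
#' @param renormalize If `TRUE`, nonnegative input is divided by its sum
#'   (useful when raw volumes are supplied); if `FALSE` the sum must equal 1
#'   within `1e-8`.
#' @return The validated (possibly renormalized) composition.
#' @export
as_composition <- function(c, renormalize = FALSE) {
  c <- as.numeric(c)
  if (any(!is.finite(c))) stop("composition contains non-finite entries")
  if (any(c < -.COMP_SUM_TOL)) stop("composition has negative entries")
  c[c < 0] <- 0
  s <- sum(c)
  if (renormalize) {
    if (s <= 0) stop("composition has zero total; cannot renormalize")
    return(c / s)
  }
  if (abs(s - 1) > .COMP_SUM_TOL)
    stop(sprintf("composition entries sum to %.10f, not 1 (use renormalize = TRUE for raw volumes)", s))
  c / s
}

#' Square-root map from the simplex to the sphere
#'
#' Maps a composition to the positive segment of the unit sphere by taking
#' elementwise square roots.
#'
#' @inheritParams as_composition
#' @return Unit 3-vector with nonnegative coordinates.
#' @export
comp_to_sphere <- function(c, renormalize = FALSE) {
  c <- as_composition(c, renormalize = renormalize)
  p <- sqrt(c)
  p / sqrt(sum(p^2))
}

#' Inverse square-root map
#'
#' Squares the coordinates of a point on the closed positive segment of the
#' sphere, recovering a composition. Exact left inverse of [comp_to_sphere()].
#'
#' @param p Unit 3-vector with coordinates `>= -1e-8`.
#' @return Composition (entries sum to 1).
#' @export
sphere_to_comp <- function(p) {
  p <- .check_unit(p)
  if (any(p < -.TANGENT_TOL))
    stop("point lies outside the positive segment; apply project_to_positive_segment() first")
  p[p < 0] <- 0
  c <- p^2
  c / sum(c)
}

.check_unit <- function(p, tol = 1e-6) {
  p <- as.numeric(p)
  n <- sqrt(sum(p^2))
  if (abs(n - 1) > tol) stop(sprintf("not a unit vector (norm %.8f)", n))
  p / n
}

#' Geodesic (great-circle) distance on the sphere
#'
#' @param p,q Unit vectors.
#' @return Distance in radians, in `[0, pi]`.
#' @export
geodesic_distance <- function(p, q) {
  acos(.clip1(sum(p * q)))
}

.clip1 <- function(x) pmin(1, pmax(-1, x))

#' Riemannian exponential map on the sphere
#'
#' Follows the geodesic from `p` in direction `v` (a tangent vector at `p`)
#' for arc length `||v||`.
#'
#' @param p Base point (unit vector).
#' @param v Tangent vector at `p` (orthogonal to `p`).
#' @return Unit vector.
#' @export
exp_map <- function(p, v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-14) return(p)
  out <- cos(nv) * p + sin(nv) * (v / nv)
  out / sqrt(sum(out^2))
}

#' Riemannian logarithm map on the sphere
#'
#' Inverse of [exp_map()]: the tangent vector at `p` pointing toward `q` with
#' length equal to the geodesic distance. Undefined for antipodal pairs.
#'
#' @param p Base point (unit vector).
#' @param q Target point (unit vector), not antipodal to `p`.
#' @param antipodal_tol Distance to `pi` below which the pair is treated as
#'   antipodal.
#' @return Tangent 3-vector at `p`.
#' @export
log_map <- function(p, q, antipodal_tol = 1e-9) {
  ip <- .clip1(sum(p * q))
  d <- acos(ip)
  if (pi - d < antipodal_tol)
    stop("logarithm map undefined: points are (numerically) antipodal")
  w <- q - ip * p
  nw <- sqrt(sum(w^2))
  if (nw < 1e-14) return(numeric(length(p)))
  d * w / nw
}

# Log maps of the rows of Y (n x 3) at common base p; returns n x 3.
.log_map_rows <- function(p, Y) {
  ip <- .clip1(drop(Y %*% p))
  d <- acos(ip)
  W <- Y - outer(ip, p)
  nw <- sqrt(rowSums(W^2))
  scl <- ifelse(nw < 1e-14, 0, d / nw)
  W * scl
}

#' Weighted Fréchet mean on the sphere
#'
#' Intrinsic mean: the minimizer of the weighted sum of squared geodesic
#' distances. Solved by fixed-point iteration: from the current estimate,
#' average the log-mapped points and step along the exponential map.
#' Initialized at the normalized extrinsic weighted average, which is
#' well-defined when the points lie within an open hemisphere.
#'
#' @param points Matrix with one unit row vector per point (n x 3), or a list
#'   of unit vectors.
#' @param weights Nonnegative weights, at least one strictly positive.
#'   Defaults to equal weights.
#' @param tol Convergence tolerance on the tangent-step norm.
#' @param max_iter Maximum number of iterations.
#' @return Unit 3-vector.
#' @export
frechet_mean <- function(points, weights = NULL, tol = 1e-10, max_iter = 100) {
  Y <- if (is.list(points)) do.call(rbind, points) else
    if (is.null(dim(points))) matrix(points, nrow = 1) else as.matrix(points)
  n <- nrow(Y)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length does not match number of points")
  if (any(weights < 0)) stop("weights must be nonnegative")
  sw <- sum(weights)
  if (sw <= 0) stop("at least one weight must be strictly positive")
  w <- weights / sw
  p0 <- drop(w %*% Y)
  n0 <- sqrt(sum(p0^2))
  if (n0 < 1e-8)
    stop("extrinsic average is (near) zero: points do not lie within an open hemisphere")
  p <- p0 / n0
  for (it in seq_len(max_iter)) {
    step <- drop(w %*% .log_map_rows(p, Y))
    # project out any numerical normal component
    step <- step - sum(step * p) * p
    ns <- sqrt(sum(step^2))
    p <- exp_map(p, step)
    if (ns < tol) return(p)
  }
  if (ns < 1e-6) return(p)  # accept near-converged solutions
  stop(sprintf("Frechet mean did not converge (last step %.3e after %d iterations)", ns, max_iter))
}

#' Project a sphere point onto the closed positive segment
#'
#' Returns the geodesically nearest point of the sphere with all coordinates
#' nonnegative: negative coordinates are set to zero and the remainder is
#' renormalized. Identity on the closed positive segment; idempotent.
#'
#' @param p Unit 3-vector, possibly with negative coordinates.
#' @return Unit 3-vector with nonnegative coordinates.
#' @export
project_to_positive_segment <- function(p) {
  p <- as.numeric(p)
  if (all(p <= 0)) stop("degenerate input: no positive coordinate")
  q <- pmax(p, 0)
  q / sqrt(sum(q^2))
}

#' Fisher–Rao distance between two compositions
#'
#' Geodesic distance between the square-root images on the sphere, i.e.
#' `acos` of the Bhattacharyya coefficient `sum(sqrt(c1 * c2))`. This package
#' uses the factor-1 convention throughout, so the Fisher–Rao distance equals
#' the sphere geodesic distance after the square-root map and takes values in
#' `[0, pi/2]` for compositions; some references scale this by 2. All scaled
#' quantities reported by the package (e.g. holdout benchmark errors, which
#' are ratios of Fisher–Rao distances) are invariant to that convention.
#'
#' @param c1,c2 Compositions.
#' @return Nonnegative distance in radians; zero iff `c1 == c2`.
#' @export
fisher_rao_distance <- function(c1, c2) {
  c1 <- as_composition(c1)
  c2 <- as_composition(c2)
  acos(.clip1(sum(sqrt(c1 * c2))))
}
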
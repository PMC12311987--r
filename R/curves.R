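#' Planar landmark contour for one subject
#'
#' Light container for the raw landmark trace of a planar contour:
#' an `m x 2` matrix of ordered coordinates (arbitrary image units) plus a
#' subject identifier. Landmarks are assumed ordered along the contour with a
#' consistent seed point; the contour is treated as an open curve on `[0, 1]`.
#'
#' @param points numeric `m x 2` matrix, `m >= 3`, finite, with nonzero total
#'   arc length.
#' @param subject_id identifier attached to the curve (used in error messages
#'   and writers).
#' @return An object of class `landmark_curve`.
#' @export
landmark_curve <- function(points, subject_id = NA_character_) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("points must be a numeric m x 2 matrix")
  if (nrow(points) < 3L)
    stop("a landmark curve needs at least 3 points")
  if (any(!is.finite(points)))
    stop("non-finite landmark coordinates for subject ", subject_id)
  seg <- sqrt(rowSums(diff(points)^2))
  if (sum(seg) <= 0)
    stop("degenerate landmark curve (zero arc length) for subject ", subject_id)
  structure(list(points = unname(points), subject_id = subject_id),
            class = "landmark_curve")
}

#' @export
print.landmark_curve <- function(x, ...) {
  cat("<landmark_curve>", nrow(x$points), "landmarks, subject:",
      as.character(x$subject_id), "\n")
  invisible(x)
}

new_coord_curve <- function(grid, values) {
  structure(list(grid = grid, values = values), class = "coord_curve")
}

#' SRVF curve on a shared grid
#'
#' Two-component square-root velocity function \eqn{q(s) = \dot f(s) /
#' \sqrt{|\dot f(s)|}} evaluated on a grid over `[0, 1]`. When derived from a
#' unit-arc-length curve, \eqn{\int_0^1 |q(s)|^2 ds = 1}.
#'
#' @param grid numeric vector in `[0, 1]`, strictly increasing, spanning 0 to 1.
#' @param values numeric `T x 2` matrix of SRVF coordinates.
#' @return An object of class `srvf_curve`.
#' @export
srvf_curve <- function(grid, values) {
  values <- as.matrix(values)
  if (length(grid) != nrow(values) || ncol(values) != 2L)
    stop("values must be a length(grid) x 2 matrix")
  if (any(!is.finite(grid)) || any(!is.finite(values)))
    stop("non-finite entries in SRVF curve")
  if (any(diff(grid) <= 0) || abs(grid[1]) > 1e-12 || abs(grid[length(grid)] - 1) > 1e-12)
    stop("grid must be strictly increasing from 0 to 1")
  structure(list(grid = grid, values = unname(values)), class = "srvf_curve")
}

#' @export
print.srvf_curve <- function(x, ...) {
  cat("<srvf_curve> T =", length(x$grid),
      " L2 norm =", format(sqrt(srvf_norm2(x)), digits = 4), "\n")
  invisible(x)
}

# Squared L2 norm of an SRVF by trapezoid quadrature.
srvf_norm2 <- function(q) trapz(q$grid, rowSums(q$values^2))

#' Remove translation and scale from a landmark contour
#'
#' Resamples the contour to `n_grid` points uniformly by arc length over
#' `[0, 1]`, centers it at its centroid, and scales it to unit total arc
#' length, removing the two shape-preserving transformations that carry no
#' shape information (translation and scale). Rotation and reparameterization
#' are handled later through alignment.
#'
#' @param curve a [landmark_curve()].
#' @param n_grid number of output grid points (`>= 3`).
#' @return A `coord_curve`: list with `grid` (uniform on `[0, 1]`) and
#'   `values` (`n_grid x 2`, centroid zero, unit arc length).
#' @export
normalize_landmarks <- function(curve, n_grid = 100L) {
  if (!inherits(curve, "landmark_curve")) curve <- landmark_curve(curve)
  if (n_grid < 3L) stop("n_grid must be at least 3")
  P <- curve$points
  seg <- sqrt(rowSums(diff(P)^2))
  len <- sum(seg)
  if (len <= 0) stop("degenerate curve for subject ", curve$subject_id)
  # arc-length parameter of the input polyline, rescaled to [0, 1]
  s_in <- c(0, cumsum(seg)) / len
  # drop duplicated points (zero-length segments) so approx() is well defined
  keep <- c(TRUE, seg > 0)
  s_in <- s_in[keep]
  P <- P[keep, , drop = FALSE]
  grid <- seq(0, 1, length.out = n_grid)
  vals <- cbind(approx(s_in, P[, 1], xout = grid)$y,
                approx(s_in, P[, 2], xout = grid)$y)
  # re-measure the resampled polyline so centroid/arclength hold exactly on it
  seg2 <- sqrt(rowSums(diff(vals)^2))
  vals <- vals / sum(seg2)
  w <- trapz_weights(grid)
  centroid <- colSums(vals * w) / sum(w)
  vals <- sweep(vals, 2L, centroid)
  new_coord_curve(grid, vals)
}

#' Square-root velocity transform
#'
#' Maps normalized coordinate functions \eqn{f} to the SRVF \eqn{q(s) =
#' \dot f(s)/\sqrt{|\dot f(s)|}}, under which the elastic metric on curves
#' becomes the flat L2 metric and rotation/reparameterization act by
#' isometries. Derivatives use central finite differences (one-sided at the
#' endpoints); where the speed \eqn{|\dot f|} falls below `1e-12` of the mean
#' speed, `q` is set to zero.
#'
#' @param f a `coord_curve` on a uniform grid.
#' @return An [srvf_curve()].
#' @export
srvf_transform <- function(f) {
  grid <- f$grid
  df <- fd_gradient(f$values, grid)
  speed <- sqrt(rowSums(df^2))
  eps <- 1e-12 * mean(speed)
  q <- df / sqrt(pmax(speed, eps))
  q[speed < eps, ] <- 0
  srvf_curve(grid, q)
}

#' Reconstruct coordinate functions from an SRVF
#'
#' Inverse of [srvf_transform()] up to translation:
#' \eqn{f(s) = f(0) + \int_0^s q(t)\,|q(t)|\,dt}, evaluated by cumulative
#' trapezoid integration.
#'
#' @param q an [srvf_curve()].
#' @param start length-2 numeric, the value of `f(0)`.
#' @return A `coord_curve` on the same grid.
#' @export
srvf_inverse <- function(q, start = c(0, 0)) {
  grid <- q$grid
  spd <- sqrt(rowSums(q$values^2))
  integrand <- q$values * spd
  d <- diff(grid)
  vals <- matrix(0, length(grid), 2L)
  for (j in 1:2) {
    incr <- d * (integrand[-length(grid), j] + integrand[-1L, j]) / 2
    vals[, j] <- start[j] + c(0, cumsum(incr))
  }
  new_coord_curve(grid, vals)
}

#' Trapezoid inner product of two functions on a shared grid
#'
#' Computes \eqn{\int_0^1 f(s) g(s) ds} by the trapezoid rule. For
#' matrix-valued inputs (multiple components as columns) the component-wise
#' inner products are summed, matching the L2 inner product of vector-valued
#' functions.
#'
#' @param f,g numeric vectors or `T x d` matrices on `grid`.
#' @param grid the common evaluation grid.
#' @return A scalar.
#' @export
functional_inner_product <- function(f, g, grid) {
  f <- as.matrix(f); g <- as.matrix(g)
  if (nrow(f) != length(grid) || nrow(g) != length(grid) || !all(dim(f) == dim(g)))
    stop("f and g must share the evaluation grid")
  sum(trapz_weights(grid) * rowSums(f * g))
}
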
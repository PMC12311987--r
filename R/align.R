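#' Optimal rotation between two SRVF curves
#'
#' Procrustes solution of \eqn{\mathrm{argmin}_{O \in SO(2)} \|q_{ref} - O q\|_{L^2}}
#' via the SVD of the 2x2 cross-covariance \eqn{A = \int q_{ref}(s) q(s)^\top ds},
#' with the determinant-sign correction enforcing a proper rotation
#' (`det = +1`, no reflection).
#'
#' @param q_ref,q [srvf_curve()] objects on a common grid.
#' @return A 2x2 rotation matrix. If the cross-covariance is numerically zero
#'   the identity is returned with attribute `degenerate = TRUE` and a warning.
#' @export
optimal_rotation <- function(q_ref, q) {
  if (length(q_ref$grid) != length(q$grid))
    stop("curves must share a grid")
  w <- trapz_weights(q_ref$grid)
  A <- crossprod(q_ref$values * w, q$values)  # \int q_ref q^T ds
  if (sqrt(sum(A^2)) < 1e-14) {
    warning("cross-covariance numerically zero; returning identity rotation")
    return(structure(diag(2), degenerate = TRUE))
  }
  sv <- svd(A)
  d <- sign(det(sv$u %*% t(sv$v)))
  O <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  O
}

#' Optimal reparameterization by dynamic programming
#'
#' Finds the boundary-preserving, monotone piecewise-linear warping
#' \eqn{\tau} minimizing \eqn{\|q_{ref} - (q \circ \tau)\sqrt{\dot\tau}\|^2}
#' over a lattice of local slopes \eqn{\{l/k : 1 \le k, l \le 3\}} (the
#' standard grid dynamic program for elastic registration). The identity warp
#' lies on the lattice, so the optimal objective never exceeds the unwarped
#' objective.
#'
#' @param q_ref,q [srvf_curve()] objects on a common uniform grid of size
#'   `T >= 5`.
#' @return A list of class `warp_fn` with fields `grid`, `values` (the warp
#'   evaluated on `grid`: `values[1] = 0`, `values[T] = 1`, non-decreasing)
#'   and `value` (the attained objective).
#' @export
optimal_warping <- function(q_ref, q) {
  if (length(q_ref$grid) != length(q$grid))
    stop("curves must share a grid")
  res <- .dp_warp_cpp(q_ref$values, q$values)
  structure(list(grid = q_ref$grid, values = as.numeric(res$tau),
                 value = res$value),
            class = "warp_fn")
}

#' Apply a warping function to an SRVF (the reparameterization group action)
#'
#' Computes \eqn{(q, \tau) \mapsto (q \circ \tau)\sqrt{\dot\tau}}, the action
#' of the reparameterization group on SRVFs. The action is an isometry: the
#' L2 norm is preserved up to grid error.
#'
#' @param q an [srvf_curve()].
#' @param tau a `warp_fn` (or list with `grid`, `values`) on the same grid.
#' @return The warped [srvf_curve()].
#' @export
warp_apply <- function(q, tau) {
  grid <- q$grid
  tv <- tau$values
  if (length(tv) != length(grid)) stop("warp and curve must share a grid")
  if (any(diff(tv) < -1e-12) || abs(tv[1]) > 1e-8 || abs(tv[length(tv)] - 1) > 1e-8)
    stop("invalid warping function: must be non-decreasing from 0 to 1")
  qv <- cbind(approx(grid, q$values[, 1], xout = pmin(pmax(tv, 0), 1))$y,
              approx(grid, q$values[, 2], xout = pmin(pmax(tv, 0), 1))$y)
  dtau <- pmax(fd_gradient(tv, grid), 0)
  srvf_curve(grid, qv * sqrt(dtau))
}

# Invert a warping function numerically (monotone interpolation of the
# reflected graph).
warp_inverse <- function(tau) {
  grid <- tau$grid
  v <- tau$values
  # enforce strict monotonicity for interpolation
  v <- cummax(v + seq_along(v) * 1e-12)
  v <- (v - v[1]) / (v[length(v)] - v[1])
  structure(list(grid = grid, values = approx(v, grid, xout = grid)$y),
            class = "warp_fn")
}

# One alignment pass of q onto q_ref: alternate Procrustes rotation and
# dynamic-programming warping for `sweeps` rounds.
align_pair <- function(q_ref, q, sweeps = 2L) {
  O_tot <- diag(2)
  q_cur <- q
  tau <- NULL
  for (k in seq_len(sweeps)) {
    O <- optimal_rotation(q_ref, q_cur)
    q_cur <- srvf_curve(q_cur$grid, q_cur$values %*% t(O))
    O_tot <- O %*% O_tot
    tau_k <- optimal_warping(q_ref, q_cur)
    q_cur <- warp_apply(q_cur, tau_k)
    tau <- if (is.null(tau)) tau_k else
      structure(list(grid = tau$grid,
                     values = approx(tau$grid, tau$values, xout = tau_k$values)$y,
                     value = tau_k$value),
                class = "warp_fn")
  }
  list(q = q_cur, rotation = O_tot, warp = tau)
}

#' Elastic distance between two SRVF curves
#'
#' L2 distance after optimizing the second curve over rotation and
#' reparameterization (the elastic shape metric restricted to the
#' rotation/warping lattice search).
#'
#' @param q1,q2 [srvf_curve()] objects on a common grid.
#' @return Non-negative scalar distance.
#' @export
elastic_distance <- function(q1, q2) {
  al <- align_pair(q1, q2)
  sqrt(max(0, trapz(q1$grid, rowSums((q1$values - al$q$values)^2))))
}

#' Karcher mean of a sample of SRVF curves
#'
#' Iterative template estimation: initialize at the medoid (the curve with the
#' smallest total elastic distance to the others), then repeat
#' align-all / average / renormalize until the mean changes by less than `tol`
#' or `max_iter` is reached. The total aligned squared distance is
#' non-increasing across iterations.
#'
#' @param curves list of [srvf_curve()] on a shared grid.
#' @param max_iter maximum outer iterations.
#' @param tol L2 change in the mean below which iteration stops.
#' @return A list of class `atlas_shape`: `srvf` (the mean), `n_iterations`,
#'   `converged`, and `objective` (total aligned squared distance per
#'   iteration).
#' @export
karcher_mean <- function(curves, max_iter = 20L, tol = 1e-5) {
  n <- length(curves)
  if (n == 0L) stop("empty list of curves")
  grid <- curves[[1]]$grid
  if (n == 1L) {
    return(structure(list(srvf = curves[[1]], n_iterations = 1L,
                          converged = TRUE, objective = 0),
                     class = "atlas_shape"))
  }
  # medoid initialization: deterministic, avoids seed dependence
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- elastic_distance(curves[[i]], curves[[j]])
  }
  mu <- curves[[which.min(rowSums(D^2))]]
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    aligned <- lapply(curves, function(q) align_pair(mu, q)$q)
    obj_i <- sum(vapply(aligned, function(a)
      trapz(grid, rowSums((mu$values - a$values)^2)), numeric(1)))
    obj <- c(obj, obj_i)
    avg <- Reduce(`+`, lapply(aligned, `[[`, "values")) / n
    nrm <- sqrt(trapz(grid, rowSums(avg^2)))
    if (nrm < 1e-12) stop("degenerate Karcher mean (zero average SRVF)")
    mu_new <- srvf_curve(grid, avg / nrm)
    delta <- sqrt(trapz(grid, rowSums((mu_new$values - mu$values)^2)))
    mu <- mu_new
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(srvf = mu, n_iterations = iter, converged = converged,
                 objective = obj),
            class = "atlas_shape")
}

#' @export
print.atlas_shape <- function(x, ...) {
  cat("<atlas_shape> T =", length(x$srvf$grid),
      " iterations:", x$n_iterations,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

#' Align a cohort of landmark contours to a common atlas
#'
#' Full elastic-shape pipeline: normalize each contour (translation/scale),
#' transform to SRVF, estimate the Karcher-mean atlas, and align every subject
#' to the atlas over rotation and reparameterization. The aligned SRVFs
#' \eqn{m_i(s) = O_i^* (q_i \circ \tau_i^*) \sqrt{\dot\tau_i^*}} are the
#' functional shape mediators used downstream.
#'
#' @param curves list of [landmark_curve()] (length `>= 2`).
#' @param n_grid size of the shared evaluation grid.
#' @param max_iter,tol Karcher-mean iteration controls.
#' @return A list with `atlas` (an `atlas_shape`), `srvfs` (list of aligned
#'   [srvf_curve()]), `M` (the aligned SRVFs as an `n x n_grid x 2` array),
#'   `grid`, and `subject_ids`.
#' @export
align_cohort <- function(curves, n_grid = 100L, max_iter = 20L, tol = 1e-5) {
  if (length(curves) < 2L) stop("need at least 2 curves to build an atlas")
  ids <- vapply(seq_along(curves), function(i) {
    id <- curves[[i]]$subject_id
    if (is.null(id) || is.na(id)) as.character(i) else as.character(id)
  }, character(1))
  qs <- vector("list", length(curves))
  for (i in seq_along(curves)) {
    qs[[i]] <- tryCatch({
      q <- srvf_transform(normalize_landmarks(curves[[i]], n_grid))
      # project onto the unit sphere: unit arc length corresponds to unit
      # SRVF norm only up to discretization, and the atlas is unit-norm
      srvf_curve(q$grid, q$values / sqrt(srvf_norm2(q)))
    }, error = function(e) stop("subject ", ids[i], ": ", conditionMessage(e)))
  }
  atlas <- karcher_mean(qs, max_iter = max_iter, tol = tol)
  aligned <- lapply(qs, function(q) align_pair(atlas$srvf, q)$q)
  M <- array(NA_real_, c(length(curves), n_grid, 2L),
             dimnames = list(ids, NULL, c("q1", "q2")))
  for (i in seq_along(aligned)) M[i, , ] <- aligned[[i]]$values
  list(atlas = atlas, srvfs = aligned, M = M,
       grid = qs[[1]]$grid, subject_ids = ids)
}
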
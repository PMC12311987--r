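#' Basis configuration for the scalar-on-shape model
#'
#' Controls how the functional mediator is reduced to finitely many scores
#' before the outcome regression. The default is functional principal
#' component analysis (FPCA) of the pooled two-dimensional mediator functions
#' (the two SRVF components stacked so cross-component covariance is
#' respected), truncated at a proportion-of-variance-explained threshold.
#'
#' @param method `"fpca"` (data-driven eigenbasis; default).
#' @param pve proportion of variance explained defining the largest
#'   truncation considered (in `(0, 1]`); ignored when `K` is given.
#' @param K fixed number of basis functions, overriding `pve` and `select`.
#' @param select how the truncation dimension is chosen within the `pve`
#'   envelope: `"floor"` (default) additionally drops components whose
#'   eigenvalues are inside the white-noise bulk of the spectrum — the bulk
#'   level is estimated iteratively from the excluded tail and the cut is
#'   the random-matrix bulk edge \eqn{(1+\sqrt{p/n})^2\hat\nu} — guarding
#'   the reconstructed coefficient function against near-noise components
#'   whose tiny eigenvalues inflate its pointwise variance; `"pve"` keeps
#'   every component up to the envelope.
#' @return An object of class `basis_config`.
#' @export
basis_config <- function(method = "fpca", pve = 0.95, K = NULL,
                         select = c("floor", "pve")) {
  method <- match.arg(method)
  select <- match.arg(select)
  if (!is.null(K)) {
    if (K < 1) stop("K must be at least 1")
    pve <- NULL
  } else if (pve <= 0 || pve > 1) stop("pve must lie in (0, 1]")
  structure(list(method = method, pve = pve, K = K, select = select),
            class = "basis_config")
}

# Validate/coerce the mediator array: n x T x 2.
as_mediator_array <- function(M) {
  if (is.list(M) && !is.null(M$M)) M <- M$M  # accept align_cohort() output
  if (length(dim(M)) != 3L || dim(M)[3] != 2L)
    stop("M must be an n x T x 2 array of aligned SRVFs")
  M
}

# Flatten n x T x 2 -> n x 2T (components stacked: q1 block then q2 block).
flatten_M <- function(M) cbind(M[, , 1], M[, , 2])

#' Shape-on-scalar regression (functional-response model)
#'
#' Fits, independently at every grid point \eqn{s_t} and component
#' \eqn{j = 1, 2}, the pointwise OLS regression
#' \eqn{m_{i,j}(s) = x_i \alpha_j(s) + c_i^\top \xi_j(s) + \eta_{i,j}(s) +
#' \epsilon_{i,j}(s)}, giving the exposure coefficient functions
#' \eqn{\alpha_j(s)}, confounder coefficient functions \eqn{\xi_j(s)}, and
#' per-subject residual functions (the sum of the smooth subject effect and
#' measurement error). Fitted plus residual reproduces the observed mediator
#' exactly.
#'
#' @param M aligned SRVF mediators, an `n x T x 2` array (or the result of
#'   [align_cohort()]).
#' @param x exposure vector (dosage of one SNP).
#' @param C covariate matrix including an intercept column.
#' @param grid evaluation grid (defaults to uniform on `[0, 1]`).
#' @return An object of class `shape_on_scalar_fit` with fields `alpha`
#'   (`T x 2`), `xi` (`p x T x 2`), `fitted` and `residuals` (`n x T x 2`),
#'   `grid`, `x`, `C`.
#' @export
fit_shape_on_scalar <- function(M, x, C, grid = NULL) {
  M <- as_mediator_array(M)
  n <- dim(M)[1]; T <- dim(M)[2]
  if (is.null(grid)) grid <- seq(0, 1, length.out = T)
  C <- as.matrix(C)
  if (length(x) != n || nrow(C) != n) stop("subject-count mismatch")
  X <- cbind(x = x, C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("collinear design; offending columns: ", paste(bad, collapse = ", "))
  }
  if (n <= ncol(X)) stop("need n > p + 1 subjects")
  Y <- flatten_M(M)                       # n x 2T
  B <- qr.coef(qrX, Y)                    # (1+p) x 2T
  fitted_flat <- X %*% B
  resid_flat <- Y - fitted_flat
  alpha <- cbind(B[1, 1:T], B[1, (T + 1):(2 * T)])
  p <- ncol(C)
  xi <- array(NA_real_, c(p, T, 2L))
  for (k in seq_len(p)) {
    xi[k, , 1] <- B[k + 1L, 1:T]
    xi[k, , 2] <- B[k + 1L, (T + 1):(2 * T)]
  }
  unflatten <- function(A) {
    out <- array(NA_real_, c(n, T, 2L))
    out[, , 1] <- A[, 1:T]; out[, , 2] <- A[, (T + 1):(2 * T)]
    out
  }
  structure(list(alpha = alpha, xi = xi,
                 fitted = unflatten(fitted_flat),
                 residuals = unflatten(resid_flat),
                 grid = grid, x = x, C = C),
            class = "shape_on_scalar_fit")
}

# FPCA of the pooled mediator functions. Mc: n x 2T column-centered flattened
# mediators; w2: stacked quadrature weights (length 2T). Returns eigenbasis
# phi (2T x K, orthonormal under w2), eigenvalues, and scores (n x K).
fpca_pooled <- function(Mc, w2, pve = 0.95, K = NULL) {
  n <- nrow(Mc)
  sw <- sqrt(w2)
  G <- crossprod(Mc) / n                    # 2T x 2T covariance (biased)
  Gs <- t(G * sw) * sw                      # W^{1/2} G W^{1/2}
  eg <- eigen((Gs + t(Gs)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  tot <- sum(lam)
  if (tot <= .Machine$double.eps)
    return(list(phi = matrix(0, length(w2), 0L), values = numeric(0),
                scores = matrix(0, n, 0L), pve = numeric(0)))
  rank_num <- sum(lam > 1e-10 * tot)   # numerically nonzero components only
  cumpve <- cumsum(lam) / tot
  Ksel <- if (!is.null(K)) min(K, rank_num) else
    min(which(cumpve >= pve * (1 - 1e-12))[1], rank_num)
  phi <- eg$vectors[, seq_len(Ksel), drop = FALSE] / sw
  scores <- Mc %*% (phi * w2)               # z_ik = sum_j \int m_ij phi_kj ds
  list(phi = phi, values = lam[seq_len(Ksel)], scores = scores,
       pve = cumpve[seq_len(Ksel)], all_values = lam)
}

# Number of eigenvalues clearly above the white-noise bulk of a sample
# spectrum: the bulk level nu is estimated iteratively as the mean of the
# excluded eigenvalues and the retention cut is the random-matrix bulk edge
# (1 + sqrt(p/n))^2 * nu. Spectra without a noise bulk keep everything.
noise_floor_rank <- function(lam, n) {
  lam <- lam[lam > 0]
  p <- length(lam)
  if (p < 3L) return(p)
  edge <- (1 + sqrt(p / n))^2
  nu <- mean(lam)
  for (it in 1:100) {
    keep <- lam > edge * nu
    nu_new <- if (all(keep)) 0 else mean(lam[!keep])
    if (abs(nu_new - nu) <= 1e-12 * max(nu, 1)) { nu <- nu_new; break }
    nu <- nu_new
  }
  max(sum(lam > edge * nu), 1L)
}

#' Scalar-on-shape regression (functional-predictor model)
#'
#' Fits \eqn{y_i = x_i\gamma + \sum_{j=1}^{2}\int_0^1 m_{i,j}(s)\beta_j(s)ds
#' + c_i^\top\kappa + \delta_i} by expanding the centered mediator functions
#' in a truncated FPCA basis, computing subject scores by trapezoid
#' quadrature, regressing the outcome on exposure, scores, and covariates by
#' OLS, and reconstructing the coefficient functions \eqn{\beta_j(s)} from the
#' basis. Centering the mediators re-routes their mean into the intercept and
#' leaves \eqn{\gamma} and \eqn{\beta_j} unchanged.
#'
#' @param y outcome vector.
#' @param M aligned SRVF mediators (`n x T x 2` array).
#' @param x exposure vector.
#' @param C covariate matrix including an intercept column.
#' @param basis a [basis_config()].
#' @param grid evaluation grid (defaults to uniform on `[0, 1]`).
#' @return An object of class `scalar_on_shape_fit` with fields `gamma`,
#'   `beta` (`T x 2`), `kappa`, `residuals`, `fitted`, `basis_scores`,
#'   `basis` (eigenfunctions and PVE), `K`, `grid`.
#' @export
fit_scalar_on_shape <- function(y, M, x, C, basis = basis_config(),
                                grid = NULL) {
  M <- as_mediator_array(M)
  n <- dim(M)[1]; T <- dim(M)[2]
  if (is.null(grid)) grid <- seq(0, 1, length.out = T)
  C <- as.matrix(C)
  if (length(y) != n || length(x) != n || nrow(C) != n)
    stop("subject-count mismatch")
  w <- trapz_weights(grid)
  w2 <- c(w, w)
  Mf <- flatten_M(M)
  mbar <- colMeans(Mf)
  Mc <- sweep(Mf, 2L, mbar)
  fp <- fpca_pooled(Mc, w2, pve = basis$pve, K = basis$K)
  K <- ncol(fp$phi)
  if (K >= n - ncol(C) - 1L)
    stop("saturated design: K = ", K, " basis functions with n = ", n,
         " subjects; reduce pve or fix a smaller K")
  if (K > 1L && is.null(basis$K) && identical(basis$select, "floor")) {
    Ksel <- min(K, noise_floor_rank(fp$all_values, n))
    fp$phi <- fp$phi[, seq_len(Ksel), drop = FALSE]
    fp$values <- fp$values[seq_len(Ksel)]
    fp$scores <- fp$scores[, seq_len(Ksel), drop = FALSE]
    fp$pve <- fp$pve[seq_len(Ksel)]
    K <- Ksel
  }
  Z <- fp$scores
  X <- if (K > 0) cbind(x = x, Z, C) else cbind(x = x, C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("collinear design in scalar-on-shape model")
  cf <- qr.coef(qrX, y)
  fitted_y <- as.numeric(X %*% cf)
  resid_y <- y - fitted_y
  gamma <- cf[[1]]
  b <- if (K > 0) cf[2:(K + 1L)] else numeric(0)
  kappa <- cf[(K + 2L):length(cf)]
  beta_flat <- if (K > 0) as.numeric(fp$phi %*% b) else numeric(2 * T)
  beta <- cbind(beta_flat[1:T], beta_flat[(T + 1):(2 * T)])
  structure(list(gamma = gamma, beta = beta, kappa = kappa,
                 residuals = resid_y, fitted = fitted_y,
                 basis_scores = Z, score_coef = b,
                 basis = list(phi = fp$phi, values = fp$values, pve = fp$pve,
                              center = mbar),
                 K = K, grid = grid, y = y, x = x, C = C),
            class = "scalar_on_shape_fit")
}
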
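#' Wild-bootstrap configuration
#'
#' @param n_boot number of bootstrap replicates (default 1000; at least 100
#'   is recommended for interval construction).
#' @param multiplier multiplier distribution: `"rademacher"` (default;
#'   symmetric signs, mean 0 and variance 1), `"mammen"` (two-point
#'   distribution matching the third moment), or `"gaussian"`.
#' @param level miscoverage level \eqn{\vartheta} (default 0.05).
#' @param seed integer seed making the replicate sequence reproducible.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 1000L, multiplier = "rademacher",
                             level = 0.05, seed = NULL) {
  multiplier <- match.arg(multiplier, c("rademacher", "mammen", "gaussian"))
  if (n_boot < 1L) stop("n_boot must be positive")
  if (n_boot < 100L)
    warning("n_boot < 100: intervals built from this run will be unreliable")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  structure(list(n_boot = as.integer(n_boot), multiplier = multiplier,
                 level = level, seed = seed),
            class = "bootstrap_config")
}

# Draw n multipliers with mean 0 and variance 1.
draw_multipliers <- function(n, type) {
  switch(type,
    rademacher = sample(c(-1, 1), n, replace = TRUE),
    mammen = {
      # two-point distribution of Mammen: mean 0, variance 1, E v^3 = 1
      p <- (sqrt(5) + 1) / (2 * sqrt(5))
      a <- -(sqrt(5) - 1) / 2
      b <- (sqrt(5) + 1) / 2
      ifelse(runif(n) < p, a, b)
    },
    gaussian = rnorm(n))
}

#' Wild bootstrap for the functional mediation estimands
#'
#' Residual-multiplier bootstrap preserving heteroscedasticity and the
#' within-curve correlation of the mediator residuals. For each replicate,
#' independent per-subject multipliers \eqn{v_i} and \eqn{w_i} are drawn and
#' starred data are rebuilt from the fitted structural system:
#' \eqn{m_i^*(s) = \hat m_i(s) + v_i\,\tilde r_i(s)} (one multiplier scaling
#' the subject's whole residual function, preserving its within-curve
#' correlation) and
#' \eqn{y_i^* = \hat\gamma x_i + \sum_j \int m_{i,j}^*(s)\hat\beta_j(s)\,ds
#' + \hat\kappa^\top c_i + w_i\,\tilde\delta_i}, so the starred outcome is
#' generated from the starred mediators through the fitted outcome model.
#' Both mediation models are then refitted on the starred data — with the
#' FPCA basis functions held fixed at the original fit's basis, the standard
#' choice: re-estimating the eigenbasis per replicate lets near-degenerate
#' noise-floor eigenvalues swap in and out of the truncation, which makes
#' the reconstructed coefficient function jump discretely between
#' replicates and artificially inflates the simultaneous band — and the
#' replicate estimands ADE*, AIE*, SAIE*(s) are recorded.
#' Residuals are leverage-adjusted before
#' multiplication (\eqn{\tilde r_i = \hat r_i / \sqrt{1 - h_{ii}}}, the HC2
#' form), which restores the residual scale that least squares shrinks —
#' important for the outcome model, whose design can carry many FPCA score
#' columns. The replicate sequence is deterministic given `config$seed`.
#'
#' @param y,M,x,C the data used for the original fits.
#' @param fit4,fit5 the point-estimate fits ([fit_shape_on_scalar()] /
#'   [fit_scalar_on_shape()]).
#' @param config a [bootstrap_config()].
#' @return List of class `wild_bootstrap` with `ade`, `aie`, `ate` (vectors
#'   of length `n_boot`), `saie` (`n_boot x T` matrix), and `config`.
#' @export
wild_bootstrap <- function(y, M, x, C, fit4, fit5, config = bootstrap_config()) {
  M <- as_mediator_array(M)
  n <- dim(M)[1]; T <- dim(M)[2]
  C <- as.matrix(C)
  grid <- fit4$grid
  if (!is.null(config$seed)) set.seed(config$seed)
  nb <- config$n_boot
  K <- fit5$K
  phi <- fit5$basis$phi                           # 2T x K, held fixed
  w2 <- rep(trapz_weights(grid), 2L)
  wphi <- if (K > 0) phi * w2 else matrix(0, 2 * T, 0L)

  # mediator model: refitting on starred data is a single projection
  X4 <- cbind(x = x, C)
  XtXinv4 <- chol2inv(chol(crossprod(X4)))
  h4 <- rowSums((X4 %*% XtXinv4) * X4)
  p4x <- (XtXinv4 %*% t(X4))[1, ]                 # row extracting alpha
  fitted4 <- flatten_M(fit4$fitted)               # n x 2T
  resid4 <- flatten_M(fit4$residuals) / sqrt(pmax(1 - h4, 1e-8))
  X5 <- if (K > 0) cbind(x, fit5$basis_scores, C) else cbind(x, C)
  h5 <- rowSums((X5 %*% chol2inv(chol(crossprod(X5)))) * X5)
  fitted5 <- fit5$fitted
  resid5 <- fit5$residuals / sqrt(pmax(1 - h5, 1e-8))

  # starred outcome tracks the starred mediators through the fitted
  # coefficient functions; everything linear in the multipliers is
  # precomputed: ystar = fitted5 + u0 + v*u1 + w*resid5
  Mf <- flatten_M(M)
  beta_w <- if (K > 0) as.numeric(wphi %*% fit5$score_coef)
            else numeric(2 * T)
  u0 <- as.numeric((fitted4 - Mf) %*% beta_w)
  u1 <- as.numeric(resid4 %*% beta_w)
  # scores of the starred mediators in the fixed basis: Zstar = Z0 + v*Z1
  ctr <- fit5$basis$center
  Z0 <- sweep(fitted4, 2L, ctr) %*% wphi          # n x K
  Z1 <- resid4 %*% wphi
  a0 <- as.numeric(p4x %*% fitted4)               # alpha of the fitted part

  ade <- aie <- numeric(nb)
  saie <- matrix(NA_real_, nb, T)
  for (b in seq_len(nb)) {
    v <- draw_multipliers(n, config$multiplier)
    w <- draw_multipliers(n, config$multiplier)
    ystar <- fitted5 + u0 + v * u1 + w * resid5
    alpha_flat <- a0 + as.numeric((p4x * v) %*% resid4)
    X <- if (K > 0) cbind(x, Z0 + Z1 * v, C) else X4
    cf <- qr.coef(qr(X), ystar)
    beta_flat <- if (K > 0) as.numeric(phi %*% cf[2:(K + 1L)])
                 else numeric(2 * T)
    saie[b, ] <- alpha_flat[1:T] * beta_flat[1:T] +
      alpha_flat[(T + 1):(2 * T)] * beta_flat[(T + 1):(2 * T)]
    ade[b] <- cf[[1]]
    aie[b] <- trapz(grid, saie[b, ])
  }
  structure(list(ade = ade, aie = aie, ate = ade + aie, saie = saie,
                 config = config, grid = grid),
            class = "wild_bootstrap")
}
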
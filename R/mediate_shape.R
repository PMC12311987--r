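#' Causal mediation analysis with an elastic shape mediator
#'
#' Main model-fitting entry point. For one genetic exposure (a single SNP's
#' dosage, contrasting levels 0 vs 1), fits the two structural models —
#' the shape-on-scalar regression of the aligned SRVF mediator on exposure
#' and confounders, and the scalar-on-shape regression of the outcome on
#' exposure, mediator functions, and confounders — and derives the plug-in
#' causal estimands ADE, AIE, SAIE(s), ATE and the mediation proportion.
#' When `boot` is supplied, a wild bootstrap provides symmetric confidence
#' intervals for ADE/AIE/ATE, a simultaneous confidence band for SAIE(s),
#' significance calls, and significant-subregion detection.
#'
#' Identification of the estimands as causal effects rests on the usual
#' sequential-ignorability conditions: no interference between subjects, no
#' unmeasured exposure-outcome, mediator-outcome, or exposure-mediator
#' confounding given the supplied covariates, and no mediator-outcome
#' confounder affected by the exposure. None of these are testable from the
#' data; [simulate_hidden_confounder()] supports sensitivity analysis against
#' violations of the mediator-outcome condition.
#'
#' @param y numeric outcome vector.
#' @param M aligned SRVF mediators: an `n x T x 2` array or the result of
#'   [align_cohort()].
#' @param x exposure vector (single-SNP dosage).
#' @param C covariate matrix including an intercept column (default:
#'   intercept only).
#' @param basis a [basis_config()] for the scalar-on-shape model.
#' @param boot a [bootstrap_config()], or `NULL` to skip inference.
#' @param grid evaluation grid (defaults to uniform on `[0, 1]`).
#' @param snp_id,outcome_name optional labels carried into reports.
#' @return An object of class `shape_mediation`: fields `effects`
#'   (a `causal_effects`), `fit_mediator`, `fit_outcome`, `intervals`,
#'   `band`, `subregions`, `significant`, `boot`, `call`.
#' @examples
#' sc <- simulation_scenario(n = 80, T = 30, seed = 7)
#' dat <- simulate_cohort(sc)
#' fit <- mediate_shape(dat$y, dat$M, dat$x, dat$C,
#'                      boot = bootstrap_config(n_boot = 199, seed = 1))
#' summary(fit)
#' @export
mediate_shape <- function(y, M, x, C = NULL, basis = basis_config(),
                          boot = NULL, grid = NULL,
                          snp_id = NA_character_, outcome_name = NA_character_) {
  M <- as_mediator_array(M)
  n <- dim(M)[1]
  if (is.null(C)) C <- matrix(1, n, 1L, dimnames = list(NULL, "intercept"))
  C <- as.matrix(C)
  if (is.null(grid)) grid <- seq(0, 1, length.out = dim(M)[2])
  fit4 <- fit_shape_on_scalar(M, x, C, grid = grid)
  fit5 <- fit_scalar_on_shape(y, M, x, C, basis = basis, grid = grid)
  eff <- compute_effects(fit4, fit5, snp_id = snp_id,
                         outcome_name = outcome_name)
  out <- structure(list(effects = eff, fit_mediator = fit4,
                        fit_outcome = fit5, intervals = NULL, band = NULL,
                        subregions = NULL, significant = NULL, boot = NULL,
                        level = if (is.null(boot)) NA_real_ else boot$level,
                        call = match.call()),
                   class = "shape_mediation")
  if (!is.null(boot)) {
    bt <- wild_bootstrap(y, M, x, C, fit4, fit5, config = boot)
    ints <- list(
      ade = interval_from_bootstrap(eff$ade, bt$ade, boot$level),
      aie = interval_from_bootstrap(eff$aie, bt$aie, boot$level),
      ate = interval_from_bootstrap(eff$ate, bt$ate, boot$level))
    band <- band_from_bootstrap(eff$saie, bt$saie, boot$level)
    out$intervals <- ints
    out$band <- band
    out$subregions <- detect_subregions(band, grid)
    out$significant <- call_significance(ints[c("ade", "aie")])
    out$boot <- bt
  }
  out
}

#' @export
print.shape_mediation <- function(x, digits = 4, ...) {
  e <- x$effects
  cat("Shape-mediated causal effect decomposition")
  if (!is.na(e$snp_id)) cat(" - SNP", e$snp_id)
  cat("\n")
  cat(sprintf("  ATE = %.*f   ADE = %.*f   AIE = %.*f\n",
              digits, e$ate, digits, e$ade, digits, e$aie))
  cat("  MP  =", if (is.na(e$mp)) "undefined (ATE = 0)"
      else paste0(formatC(e$mp, digits = 2, format = "f"), "%"), "\n")
  if (!is.null(x$intervals)) {
    ci <- x$intervals$aie
    cat(sprintf("  %g%% AIE CI: [%.*f, %.*f]%s\n", 100 * (1 - x$level),
                digits, ci[1], digits, ci[2],
                if (x$significant[["aie"]]) "  *" else ""))
  }
  invisible(x)
}

#' @export
summary.shape_mediation <- function(object, ...) {
  e <- object$effects
  est <- data.frame(estimate = c(ATE = e$ate, ADE = e$ade, AIE = e$aie))
  if (!is.null(object$intervals)) {
    ord <- c("ate", "ade", "aie")
    est$lower <- vapply(object$intervals[ord], `[`, numeric(1), 1L)
    est$upper <- vapply(object$intervals[ord], `[`, numeric(1), 2L)
    est$significant <- est$lower > 0 | est$upper < 0
  }
  structure(list(estimates = est, mp = e$mp, K = object$fit_outcome$K,
                 level = object$level,
                 subregions = object$subregions$subregions,
                 snp_id = e$snp_id, outcome_name = e$outcome_name),
            class = "summary.shape_mediation")
}

#' @export
print.summary.shape_mediation <- function(x, digits = 4, ...) {
  cat("Causal mediation through an elastic shape mediator\n")
  if (!is.na(x$snp_id)) cat("SNP:", x$snp_id, "")
  if (!is.na(x$outcome_name)) cat("outcome:", x$outcome_name)
  cat("\n\n")
  print(round(x$estimates[vapply(x$estimates, is.numeric, logical(1))],
              digits))
  if (!is.null(x$estimates$significant))
    cat("significant:",
        paste(rownames(x$estimates)[x$estimates$significant], collapse = ", "),
        "\n")
  cat("\nMediation proportion:",
      if (is.na(x$mp)) "undefined" else paste0(formatC(x$mp, digits = 2,
                                                       format = "f"), "%"),
      "  (FPCA dimension K =", x$K, ")\n")
  if (!is.null(x$subregions) && nrow(x$subregions) > 0) {
    cat("Significant SAIE subregions (s):\n")
    print(round(x$subregions, 3))
  } else if (!is.null(x$subregions)) {
    cat("No significant SAIE subregions.\n")
  }
  invisible(x)
}

#' @export
coef.shape_mediation <- function(object, ...) {
  list(gamma = object$fit_outcome$gamma,
       alpha = object$fit_mediator$alpha,
       beta = object$fit_outcome$beta,
       kappa = object$fit_outcome$kappa,
       xi = object$fit_mediator$xi)
}

#' @export
confint.shape_mediation <- function(object, parm = c("ate", "ade", "aie"),
                                    level = NULL, ...) {
  if (is.null(object$intervals))
    stop("no bootstrap was run; refit with a bootstrap_config()")
  if (!is.null(level) && abs((1 - level) - object$level) > 1e-12)
    stop("intervals were built at level ", 1 - object$level,
         "; refit to change it")
  parm <- match.arg(parm, several.ok = TRUE)
  t(vapply(object$intervals[parm], identity, numeric(2)))
}

#' @export
residuals.shape_mediation <- function(object, model = c("outcome", "mediator"),
                                      ...) {
  model <- match.arg(model)
  if (model == "outcome") object$fit_outcome$residuals
  else object$fit_mediator$residuals
}

#' @export
fitted.shape_mediation <- function(object, ...) object$fit_outcome$fitted

#' Plot the spatial indirect-effect curve
#'
#' Draws \eqn{\widehat{SAIE}(s)} along the contour parameter with the
#' simultaneous confidence band (when a bootstrap was run) and shades the
#' detected significant subregions.
#'
#' @param x a `shape_mediation` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.shape_mediation <- function(x, ...) {
  e <- x$effects
  has_band <- !is.null(x$band)
  ylim <- if (has_band) range(x$band$lower, x$band$upper, 0)
          else range(e$saie, 0)
  graphics::plot(e$grid, e$saie, type = "n", xlab = "s (arc length)",
                 ylab = "SAIE(s)", ylim = ylim, ...)
  if (has_band) {
    graphics::polygon(c(e$grid, rev(e$grid)),
                      c(x$band$lower, rev(x$band$upper)),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
    if (nrow(x$subregions$subregions) > 0)
      for (r in seq_len(nrow(x$subregions$subregions)))
        graphics::rect(x$subregions$subregions$start[r], ylim[1],
                       x$subregions$subregions$end[r], ylim[2],
                       col = grDevices::adjustcolor("firebrick", 0.10),
                       border = NA)
  }
  graphics::abline(h = 0, lty = 3)
  graphics::lines(e$grid, e$saie, lwd = 2, col = "steelblue4")
  invisible(x)
}
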
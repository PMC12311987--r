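#' Causal effect estimands from the two fitted mediation models
#'
#' Plug-in estimators for a binary exposure contrast (0 vs 1):
#' the average direct effect \eqn{ADE = \gamma}; the spatial average indirect
#' effect \eqn{SAIE(s) = \sum_j \alpha_j(s)\beta_j(s)} localizing mediation
#' along the contour; the average indirect effect
#' \eqn{AIE = \int_0^1 SAIE(s) ds} (trapezoid quadrature); the average total
#' effect \eqn{ATE = ADE + AIE}; and the mediation proportion
#' \eqn{MP = |AIE/ATE| \times 100} percent.
#'
#' @param fit4 a `shape_on_scalar_fit` (mediator model).
#' @param fit5 a `scalar_on_shape_fit` (outcome model).
#' @param snp_id,outcome_name optional labels carried into reports.
#' @return An object of class `causal_effects` with fields `ade`, `aie`,
#'   `ate`, `mp` (`NA` with `mp_defined = FALSE` when `ATE = 0`), `saie`
#'   (vector on `grid`), `grid`, labels.
#' @export
compute_effects <- function(fit4, fit5, snp_id = NA_character_,
                            outcome_name = NA_character_) {
  if (length(fit4$grid) != length(fit5$grid))
    stop("mediator and outcome fits must share a grid")
  grid <- fit4$grid
  saie <- rowSums(fit4$alpha * fit5$beta)
  aie <- trapz(grid, saie)
  ade <- fit5$gamma
  ate <- ade + aie
  structure(list(ade = ade, aie = aie, ate = ate,
                 mp = compute_mp(aie, ate), mp_defined = ate != 0,
                 saie = saie, grid = grid,
                 snp_id = snp_id, outcome_name = outcome_name),
            class = "causal_effects")
}

#' Mediation proportion
#'
#' Share of the total effect routed through the shape mediator, reported as
#' \eqn{|AIE / ATE| \times 100} percent. The absolute value keeps the
#' proportion interpretable when the direct and indirect effects have
#' opposite signs.
#'
#' @param aie,ate average indirect and total effects.
#' @return Percentage (`NA` when `ATE = 0`).
#' @export
compute_mp <- function(aie, ate) {
  ifelse(ate == 0, NA_real_, abs(aie / ate) * 100)
}

#' @export
print.causal_effects <- function(x, digits = 4, ...) {
  cat("<causal_effects>",
      if (!is.na(x$snp_id)) paste0("SNP ", x$snp_id) else "", "\n")
  cat(sprintf("  ATE = %.*f  ADE = %.*f  AIE = %.*f  MP = %s%%\n",
              digits, x$ate, digits, x$ade, digits, x$aie,
              if (is.na(x$mp)) "NA" else formatC(x$mp, digits = 2, format = "f")))
  invisible(x)
}

#' Symmetric bootstrap confidence interval
#'
#' Builds the interval \eqn{\hat\theta \pm C(\vartheta)} where
#' \eqn{C(\vartheta)} is the empirical \eqn{1 - \vartheta} quantile of the
#' absolute bootstrap deviations \eqn{|\theta_b^* - \hat\theta|}.
#'
#' @param point point estimate.
#' @param replicates vector of bootstrap replicate estimates.
#' @param level \eqn{\vartheta}, the miscoverage level (default 0.05 for a
#'   a 95 percent interval).
#' @return Numeric `c(lower, upper)`; always contains the point estimate.
#' @export
interval_from_bootstrap <- function(point, replicates, level = 0.05) {
  replicates <- replicates[is.finite(replicates)]
  if (length(replicates) < 100L)
    warning("fewer than 100 bootstrap replicates; interval is unreliable")
  C <- unname(quantile(abs(replicates - point), 1 - level, type = 7))
  c(lower = point - C, upper = point + C)
}

#' Simultaneous confidence band for the spatial indirect effect
#'
#' Constant-width band \eqn{\widehat{SAIE}(s) \pm C_{SAIE}(\vartheta)} where
#' \eqn{C_{SAIE}(\vartheta)} is the empirical \eqn{1-\vartheta} quantile over
#' bootstrap replicates of the sup-norm deviation
#' \eqn{\sup_s |SAIE_b^*(s) - \widehat{SAIE}(s)|}. By construction the band
#' half-width is at least every pointwise interval half-width computed from
#' the same replicates.
#'
#' @param saie_hat estimated SAIE curve (vector on the grid).
#' @param saie_replicates `n_boot x T` matrix of replicate curves.
#' @param level miscoverage level \eqn{\vartheta}.
#' @return List with `lower`, `upper` (vectors), and `half_width`.
#' @export
band_from_bootstrap <- function(saie_hat, saie_replicates, level = 0.05) {
  saie_replicates <- as.matrix(saie_replicates)
  if (ncol(saie_replicates) != length(saie_hat))
    stop("replicate curves must share the grid of the point estimate")
  sup_dev <- apply(abs(sweep(saie_replicates, 2L, saie_hat)), 1L, max)
  C <- unname(quantile(sup_dev, 1 - level, type = 7))
  list(lower = saie_hat - C, upper = saie_hat + C, half_width = C)
}

#' Detect contiguous subregions of significant spatial mediation
#'
#' Flags grid points where the simultaneous band excludes zero and groups
#' them into contiguous runs, reported as intervals in the arc-length
#' parameter `s`.
#'
#' @param band list with `lower`/`upper` (from [band_from_bootstrap()]).
#' @param grid evaluation grid.
#' @return List with `mask` (logical per grid point) and `subregions`
#'   (data.frame with `start`, `end` in `s`).
#' @export
detect_subregions <- function(band, grid) {
  mask <- band$lower > 0 | band$upper < 0
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sig <- which(runs$values)
  subregions <- data.frame(start = grid[starts[sig]], end = grid[ends[sig]])
  list(mask = mask, subregions = subregions)
}

#' Significance calls from bootstrap intervals
#'
#' An estimand is called significant when its confidence interval strictly
#' excludes zero (boundary values do not count as exclusion).
#'
#' @param intervals named list of `c(lower, upper)` intervals (e.g. for
#'   `ade`, `aie`).
#' @return Named logical vector.
#' @export
call_significance <- function(intervals) {
  vapply(intervals, function(ci) ci[1] > 0 || ci[2] < 0, logical(1))
}
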
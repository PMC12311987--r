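#' Simulation scenario for the genotype-shape-outcome generative model
#'
#' Bundles every quantity needed to forward-simulate a cohort with the exact
#' generative structure assumed by the mediation framework: a biallelic
#' exposure, clinical confounders, functional shape mediators built from
#' exposure/confounder coefficient functions plus a Gaussian-process subject
#' effect and white measurement noise, and a scalar outcome built from the
#' direct effect, the integrated mediator effect, confounder effects, and
#' Gaussian noise. The implied true estimands (ADE, AIE, SAIE, ATE, MP) are
#' available in closed form by quadrature.
#'
#' Defaults give a moderate signal-to-noise regime: unit-magnitude smooth
#' coefficient functions, a squared-exponential subject-effect kernel with
#' length scale 0.2 and variance 0.5, and noise standard deviations 0.5.
#'
#' @param n subjects.
#' @param T grid size over `[0, 1]`.
#' @param maf minor-allele frequency in `(0, 0.5]`.
#' @param coding `"binary"` (carrier, Bernoulli(maf)) or `"additive"`
#'   (Binomial(2, maf)).
#' @param true_alpha,true_beta lists of two functions of `s`, the exposure
#'   and outcome coefficient functions per SRVF component.
#' @param true_gamma scalar direct effect.
#' @param true_xi list of two functions of `s` per covariate column (a list
#'   of such pairs, one per confounder column including the intercept).
#' @param true_kappa numeric confounder effects on the outcome (one per
#'   covariate column including the intercept).
#' @param gp_length_scale,gp_variance squared-exponential kernel parameters
#'   of the subject-effect process.
#' @param sigma_eps,sigma_delta noise standard deviations for the mediator
#'   measurement error and the outcome error.
#' @param hidden_confounder_strength length-2 numeric: the hidden
#'   confounder's strength on the mediator and on the outcome (used only by
#'   [simulate_hidden_confounder()]).
#' @param hidden_confounder_loading list of two functions of `s`: the shape
#'   along which the hidden confounder shifts each mediator component. The
#'   default, a half-period sine in both components, is a smooth
#'   low-frequency mode that overlaps the default exposure effect — the
#'   regime in which mediator-outcome confounding genuinely distorts the
#'   indirect pathway.
#' @param seed integer seed.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n = 200L, T = 50L, maf = 0.3,
                                coding = c("binary", "additive"),
                                true_alpha = list(function(s) sin(2 * pi * s),
                                                  function(s) cos(2 * pi * s)),
                                true_beta = list(function(s) sin(2 * pi * s),
                                                 function(s) cos(2 * pi * s)),
                                true_gamma = 0.5,
                                true_xi = NULL,
                                true_kappa = c(1, 0.3, -0.3),
                                gp_length_scale = 0.2, gp_variance = 0.5,
                                sigma_eps = 0.5, sigma_delta = 0.5,
                                hidden_confounder_strength = c(0, 0),
                                hidden_confounder_loading =
                                  list(function(s) sin(pi * s),
                                       function(s) sin(pi * s)),
                                seed = NULL) {
  coding <- match.arg(coding)
  if (n < 2) stop("invalid scenario field n: need at least 2 subjects")
  if (T < 3) stop("invalid scenario field T: need at least 3 grid points")
  if (maf <= 0 || maf > 0.5) stop("invalid scenario field maf: need (0, 0.5]")
  if (sigma_eps < 0) stop("invalid scenario field sigma_eps: must be >= 0")
  if (sigma_delta < 0) stop("invalid scenario field sigma_delta: must be >= 0")
  if (gp_variance < 0) stop("invalid scenario field gp_variance: must be >= 0")
  if (gp_length_scale <= 0) stop("invalid scenario field gp_length_scale: must be > 0")
  if (length(hidden_confounder_strength) != 2)
    stop("invalid scenario field hidden_confounder_strength: need length 2")
  if (is.null(true_xi)) {
    # default confounder effects on the mediator: smooth, modest amplitude;
    # first entry is the intercept (mean) function
    true_xi <- list(
      list(function(s) 0.5 * cos(pi * s), function(s) 0.5 * sin(pi * s)),
      list(function(s) 0.3 * s, function(s) -0.3 * s),
      list(function(s) rep(0.2, length(s)), function(s) rep(-0.2, length(s))))
  }
  if (length(true_xi) != length(true_kappa))
    stop("invalid scenario fields true_xi/true_kappa: lengths must match")
  structure(list(n = as.integer(n), T = as.integer(T), maf = maf,
                 coding = coding, true_alpha = true_alpha,
                 true_beta = true_beta, true_gamma = true_gamma,
                 true_xi = true_xi, true_kappa = true_kappa,
                 gp_length_scale = gp_length_scale, gp_variance = gp_variance,
                 sigma_eps = sigma_eps, sigma_delta = sigma_delta,
                 hidden_confounder_strength = hidden_confounder_strength,
                 hidden_confounder_loading = hidden_confounder_loading,
                 seed = seed),
            class = "simulation_scenario")
}

# Squared-exponential kernel matrix on a grid, with a small jitter so the
# Cholesky factor exists even at tiny length scales.
se_kernel <- function(grid, length_scale, variance) {
  D <- outer(grid, grid, `-`)
  variance * exp(-D^2 / (2 * length_scale^2)) + diag(1e-10, length(grid))
}

#' True causal estimands implied by a scenario
#'
#' Evaluates ADE, SAIE(s), AIE (trapezoid quadrature of SAIE), ATE, and MP in
#' closed form from the scenario's coefficient functions.
#'
#' @param scenario a [simulation_scenario()].
#' @return A `causal_effects` object.
#' @export
scenario_truth <- function(scenario) {
  grid <- seq(0, 1, length.out = scenario$T)
  a1 <- scenario$true_alpha[[1]](grid); a2 <- scenario$true_alpha[[2]](grid)
  b1 <- scenario$true_beta[[1]](grid); b2 <- scenario$true_beta[[2]](grid)
  saie <- a1 * b1 + a2 * b2
  aie <- trapz(grid, saie)
  ade <- scenario$true_gamma
  ate <- ade + aie
  structure(list(ade = ade, aie = aie, ate = ate,
                 mp = compute_mp(aie, ate), mp_defined = ate != 0,
                 saie = saie, grid = grid,
                 snp_id = NA_character_, outcome_name = NA_character_),
            class = "causal_effects")
}

# Shared generator: draws everything except the hidden confounder, in a fixed
# RNG order so simulate_cohort and simulate_hidden_confounder produce
# identical base draws from the same seed.
simulate_base <- function(scenario) {
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n <- scenario$n; T <- scenario$T
  grid <- seq(0, 1, length.out = T)
  x <- if (scenario$coding == "binary") rbinom(n, 1L, scenario$maf)
       else rbinom(n, 2L, scenario$maf)
  C <- cbind(intercept = 1, z = rnorm(n), w = rbinom(n, 1L, 0.5))
  # subject effects: independent GPs per component with the shared kernel
  Kc <- if (scenario$gp_variance > 0)
    chol(se_kernel(grid, scenario$gp_length_scale, scenario$gp_variance))
  else matrix(0, T, T)
  eta1 <- matrix(rnorm(n * T), n, T) %*% Kc
  eta2 <- matrix(rnorm(n * T), n, T) %*% Kc
  eps1 <- matrix(rnorm(n * T, sd = scenario$sigma_eps), n, T)
  eps2 <- matrix(rnorm(n * T, sd = scenario$sigma_eps), n, T)
  delta <- rnorm(n, sd = scenario$sigma_delta)
  U <- rnorm(n)   # hidden confounder draw, used only when requested
  a1 <- scenario$true_alpha[[1]](grid); a2 <- scenario$true_alpha[[2]](grid)
  xi1 <- vapply(scenario$true_xi, function(f) f[[1]](grid), numeric(T))
  xi2 <- vapply(scenario$true_xi, function(f) f[[2]](grid), numeric(T))
  m1 <- outer(x, a1) + C %*% t(xi1) + eta1 + eps1
  m2 <- outer(x, a2) + C %*% t(xi2) + eta2 + eps2
  list(x = x, C = C, m1 = m1, m2 = m2, delta = delta, U = U, grid = grid)
}

assemble_outcome <- function(scenario, base) {
  grid <- base$grid
  b1 <- scenario$true_beta[[1]](grid); b2 <- scenario$true_beta[[2]](grid)
  w <- trapz_weights(grid)
  med <- as.numeric(base$m1 %*% (w * b1) + base$m2 %*% (w * b2))
  as.numeric(scenario$true_gamma * base$x + med +
               base$C %*% scenario$true_kappa + base$delta)
}

#' Simulate a cohort from the generative mediation model
#'
#' Forward-simulates genotype exposure, confounders (intercept, one standard
#' normal, one Bernoulli(0.5)), functional mediators, and outcome exactly
#' under the structural models the package fits, and returns the closed-form
#' true estimands alongside. Fully reproducible from `scenario$seed`.
#'
#' @param scenario a [simulation_scenario()].
#' @return List with `x`, `C`, `M` (`n x T x 2` array), `y`, `grid`, and
#'   `truth` (a `causal_effects`).
#' @export
simulate_cohort <- function(scenario) {
  base <- simulate_base(scenario)
  y <- assemble_outcome(scenario, base)
  M <- array(c(base$m1, base$m2), c(scenario$n, scenario$T, 2L))
  list(x = base$x, C = base$C, M = M, y = y, grid = base$grid,
       truth = scenario_truth(scenario))
}

#' Simulate a cohort with an unmeasured mediator-outcome confounder
#'
#' Identical to [simulate_cohort()] (same draws under the same seed) except
#' that a standard-normal hidden confounder \eqn{U_i} is added to both
#' structural equations — to every mediator component with loading
#' `hidden_confounder_strength[1]` and to the outcome with loading
#' `hidden_confounder_strength[2]` — and withheld from the returned
#' covariates. This violates the mediator-outcome no-unmeasured-confounding
#' condition and biases the naive AIE estimator, increasingly so with the
#' loadings; with strengths `c(0, 0)` the output is identical to
#' [simulate_cohort()].
#'
#' @param scenario a [simulation_scenario()] with
#'   `hidden_confounder_strength` set.
#' @return Same structure as [simulate_cohort()]; the returned `C` excludes
#'   `U` (returned separately as `U_hidden` for diagnostics only).
#' @export
simulate_hidden_confounder <- function(scenario) {
  s_m <- scenario$hidden_confounder_strength[1]
  s_y <- scenario$hidden_confounder_strength[2]
  base <- simulate_base(scenario)
  w1 <- scenario$hidden_confounder_loading[[1]](base$grid)
  w2 <- scenario$hidden_confounder_loading[[2]](base$grid)
  base$m1 <- base$m1 + s_m * outer(base$U, w1)
  base$m2 <- base$m2 + s_m * outer(base$U, w2)
  y <- assemble_outcome(scenario, base) + s_y * base$U
  M <- array(c(base$m1, base$m2), c(scenario$n, scenario$T, 2L))
  list(x = base$x, C = base$C, M = M, y = y, grid = base$grid,
       truth = scenario_truth(scenario), U_hidden = base$U)
}

#' Read a simulation scenario from a YAML or JSON config file
#'
#' Scalar scenario fields (`n`, `T`, `maf`, `coding`, `true_gamma`,
#' `true_kappa`, `gp_length_scale`, `gp_variance`, `sigma_eps`,
#' `sigma_delta`, `hidden_confounder_strength`, `seed`) are read from the
#' file; coefficient *functions* cannot be serialized and keep their
#' defaults unless overridden programmatically on the returned object's
#' arguments. Unknown fields raise an error.
#'
#' @param path `.yaml`/`.yml` (requires the yaml package) or `.json` file.
#' @return A [simulation_scenario()].
#' @export
scenario_from_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML scenario configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- c("n", "T", "maf", "coding", "true_gamma", "true_kappa",
               "gp_length_scale", "gp_variance", "sigma_eps", "sigma_delta",
               "hidden_confounder_strength", "seed")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown scenario field(s) in config: ", paste(bad, collapse = ", "))
  do.call(simulation_scenario, cfg)
}

#' Synthetic corpus-callosum-like template contour
#'
#' A smooth closed planar outline built from a low-order Fourier contour,
#' elongated and arched to resemble a midsagittal corpus callosum trace.
#' Entirely synthetic: a stand-in shape for exercising the elastic-shape
#' pipeline, not derived from any imaging data.
#'
#' @param m number of landmarks.
#' @return A [landmark_curve()] with `m` ordered landmarks.
#' @export
cc_template <- function(m = 100L) {
  t <- seq(0, 2 * pi, length.out = m)
  x <- cos(t) * (1 + 0.15 * cos(2 * t))
  y <- 0.35 * sin(t) + 0.18 * sin(2 * t) + 0.12 * cos(t)^2
  landmark_curve(cbind(x, y), subject_id = "template")
}

# Smooth random boundary-preserving warp: identity plus a few sine modes with
# an envelope vanishing at the endpoints; amplitude kept below the monotone
# limit.
random_warp <- function(grid, warp_sd) {
  if (warp_sd <= 0) return(grid)
  K <- 3L
  a <- rnorm(K, sd = warp_sd / (1:K))
  pert <- sapply(1:K, function(k) sin(k * pi * grid))
  g <- grid + as.numeric(pert %*% a) * grid * (1 - grid) * 4
  # enforce monotone boundary-preserving output
  g <- cummax(pmin(pmax(g, 0), 1))
  (g - g[1]) / (g[length(g)] - g[1])
}

#' Simulate a cohort of landmark contours from a template
#'
#' Applies random similarity transforms (rotation, translation, scaling),
#' smooth random reparameterizations, and small landmark jitter to a template
#' contour, producing a cohort whose only shape signal is the template —
#' everything else is nuisance variation that [align_cohort()] should remove.
#'
#' @param template a [landmark_curve()].
#' @param n cohort size.
#' @param rotation_sd SD (radians) of the random rotation angles.
#' @param warp_sd amplitude of the random smooth warps.
#' @param jitter_sd SD of i.i.d. landmark jitter (in template units).
#' @param scale_sd SD of the log random scale factors.
#' @param translate_sd SD of the random translations.
#' @param seed integer seed.
#' @return List of `n` [landmark_curve()] objects; the applied rotation
#'   angles are attached as attribute `"angles"`. With all nuisance
#'   magnitudes zero the output is `n` identical copies of the template.
#' @export
simulate_shape_cohort_from_template <- function(template, n = 30L,
                                                rotation_sd = 0.3,
                                                warp_sd = 0.1,
                                                jitter_sd = 0,
                                                scale_sd = 0.2,
                                                translate_sd = 2,
                                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- template$points
  m <- nrow(P)
  s0 <- seq(0, 1, length.out = m)
  angles <- rnorm(n, sd = rotation_sd)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    gam <- random_warp(s0, warp_sd)
    Pi <- cbind(approx(s0, P[, 1], xout = gam)$y,
                approx(s0, P[, 2], xout = gam)$y)
    th <- angles[i]
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    sc <- exp(rnorm(1, sd = scale_sd))
    shift <- rnorm(2, sd = translate_sd)
    Pi <- sc * Pi %*% t(R)
    Pi <- sweep(Pi, 2L, -shift)
    if (jitter_sd > 0) Pi <- Pi + matrix(rnorm(2 * m, sd = jitter_sd), m, 2L)
    out[[i]] <- landmark_curve(Pi, subject_id = paste0("sim", i))
  }
  attr(out, "angles") <- angles
  out
}
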
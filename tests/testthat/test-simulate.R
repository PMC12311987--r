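test_that("scenario validation names the offending field", {
  expect_error(simulation_scenario(maf = 0.7), "maf")
  expect_error(simulation_scenario(sigma_eps = -1), "sigma_eps")
  expect_error(simulation_scenario(gp_length_scale = 0), "gp_length_scale")
  expect_error(simulation_scenario(hidden_confounder_strength = 1),
               "hidden_confounder_strength")
})

test_that("the generator is reproducible and its truth is self-consistent", {
  sc <- simulation_scenario(n = 40, T = 20, seed = 71)
  d1 <- simulate_cohort(sc)
  d2 <- simulate_cohort(sc)
  expect_identical(d1, d2)

  tr <- d1$truth
  expect_identical(tr$ate - tr$ade - tr$aie, 0)
  w <- shapemed:::trapz_weights(tr$grid)
  expect_equal(sum(w * tr$saie), tr$aie, tolerance = 1e-12)
  # defaults: sin^2 + cos^2 integrates to one, gamma 0.5
  expect_equal(tr$aie, 1, tolerance = 1e-12)
  expect_equal(tr$ate, 1.5, tolerance = 1e-12)
})

test_that("all-zero effects and noise give an all-zero cohort", {
  zero <- function(s) 0 * s
  sc <- simulation_scenario(
    n = 30, T = 15, seed = 72,
    true_alpha = list(zero, zero), true_beta = list(zero, zero),
    true_gamma = 0,
    true_xi = list(list(zero, zero), list(zero, zero), list(zero, zero)),
    true_kappa = c(0, 0, 0),
    gp_variance = 0, sigma_eps = 0, sigma_delta = 0)
  dat <- simulate_cohort(sc)
  expect_true(all(dat$M == 0))
  expect_true(all(dat$y == 0))
  expect_identical(dat$truth$ate, 0)
})

test_that("genotype frequency and subject-effect covariance match the model", {
  zero <- function(s) 0 * s
  sc <- simulation_scenario(
    n = 5000, T = 25, maf = 0.3, seed = 73,
    true_alpha = list(zero, zero), true_beta = list(zero, zero),
    true_xi = list(list(zero, zero), list(zero, zero), list(zero, zero)),
    true_kappa = c(0, 0, 0), sigma_eps = 0)
  dat <- simulate_cohort(sc)
  # binomial sampling bound on the realized allele frequency
  expect_lt(abs(mean(dat$x) - 0.3), 3 * sqrt(0.3 * 0.7 / 5000))
  # with all fixed effects and measurement noise off, M is the pure GP
  emp <- crossprod(dat$M[, , 1]) / 5000
  theo <- shapemed:::se_kernel(dat$grid, 0.2, 0.5)
  rel <- norm(emp - theo, "F") / norm(theo, "F")
  expect_lt(rel, 0.05)
})

test_that("hidden-confounder generator nests the clean generator", {
  sc <- simulation_scenario(n = 50, T = 20, seed = 74,
                            hidden_confounder_strength = c(0, 0))
  clean <- simulate_cohort(sc)
  hidden0 <- simulate_hidden_confounder(sc)
  expect_identical(clean$M, hidden0$M)
  expect_identical(clean$y, hidden0$y)
  expect_identical(clean$x, hidden0$x)

  sc2 <- sc; sc2$hidden_confounder_strength <- c(1, 1)
  hidden1 <- simulate_hidden_confounder(sc2)
  expect_identical(hidden1$x, clean$x)      # same base draws
  expect_false(identical(hidden1$M, clean$M))
  expect_identical(ncol(hidden1$C), 3L)     # U withheld from covariates
})

test_that("scenario configs round-trip through JSON and YAML", {
  tmp <- withr::local_tempdir()
  cfg <- list(n = 35, T = 18, maf = 0.25, sigma_eps = 0.4, seed = 99)
  jp <- file.path(tmp, "scenario.json")
  jsonlite::write_json(cfg, jp, auto_unbox = TRUE)
  sc <- scenario_from_config(jp)
  expect_identical(sc$n, 35L)
  expect_equal(sc$maf, 0.25)
  expect_identical(simulate_cohort(sc)$y,
                   simulate_cohort(simulation_scenario(
                     n = 35, T = 18, maf = 0.25, sigma_eps = 0.4,
                     seed = 99))$y)
  yp <- file.path(tmp, "scenario.yaml")
  writeLines(yaml::as.yaml(cfg), yp)
  expect_identical(simulate_cohort(scenario_from_config(yp))$y,
                   simulate_cohort(sc)$y)
  bad <- file.path(tmp, "bad.json")
  jsonlite::write_json(list(n = 10, bogus = 1), bad, auto_unbox = TRUE)
  expect_error(scenario_from_config(bad), "bogus")
})

test_that("template cohorts degenerate to copies without nuisance", {
  tpl <- cc_template(60)
  same <- simulate_shape_cohort_from_template(tpl, n = 4, rotation_sd = 0,
                                              warp_sd = 0, jitter_sd = 0,
                                              scale_sd = 0, translate_sd = 0,
                                              seed = 75)
  for (i in 2:4)
    expect_equal(same[[i]]$points, same[[1]]$points, tolerance = 1e-12)
  expect_equal(same[[1]]$points, tpl$points, tolerance = 1e-12)
})

test_that("planted rotations are recovered through alignment", {
  tpl <- cc_template(80)
  crv <- simulate_shape_cohort_from_template(tpl, n = 8, rotation_sd = 0.5,
                                             warp_sd = 0, jitter_sd = 0,
                                             seed = 76)
  angles <- attr(crv, "angles")
  q_tpl <- srvf_transform(normalize_landmarks(tpl, 100))
  for (i in c(1L, 4L, 8L)) {
    qi <- srvf_transform(normalize_landmarks(crv[[i]], 100))
    O <- optimal_rotation(q_tpl, qi)
    # the aligning rotation undoes the planted one: O = R(-angle)
    th_hat <- atan2(O[2, 1], O[1, 1])
    d <- (th_hat + angles[i]) %% (2 * pi)
    if (d > pi) d <- d - 2 * pi
    expect_lt(abs(d), 1e-3)
  }
})
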
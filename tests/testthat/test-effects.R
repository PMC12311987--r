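test_that("estimand arithmetic matches closed forms", {
  # orthogonal coefficient functions: indirect effect integrates to zero
  mf <- mock_fits(function(s) sin(2 * pi * s), function(s) 0 * s,
                  function(s) cos(2 * pi * s), function(s) 0 * s,
                  gamma = 1.0)
  eff <- compute_effects(mf$fit4, mf$fit5)
  expect_lt(abs(eff$aie), 1e-6)
  expect_equal(eff$saie,
               sin(2 * pi * eff$grid) * cos(2 * pi * eff$grid),
               tolerance = 1e-12)
  expect_equal(eff$ate, eff$ade + eff$aie, tolerance = 1e-15)

  # constant functions: AIE = 2, ATE = 2.5
  mc <- mock_fits(function(s) rep(1, length(s)), function(s) rep(1, length(s)),
                  function(s) rep(1, length(s)), function(s) rep(1, length(s)),
                  gamma = 0.5)
  eff2 <- compute_effects(mc$fit4, mc$fit5)
  expect_equal(eff2$aie, 2, tolerance = 1e-12)
  expect_equal(eff2$ate, 2.5, tolerance = 1e-12)
  expect_equal(eff2$mp, 80, tolerance = 1e-10)
})

test_that("mediation proportion reproduces printed decompositions", {
  tab <- printed_causal_table()
  # the printed total effect equals direct + indirect up to print rounding
  expect_lt(max(abs(tab$ate - tab$ade - tab$aie)), 1.5e-4)
  # |AIE/ATE| x 100 reproduces the printed MP column; tolerance covers the
  # 4-decimal rounding of the inputs plus the 2-decimal rounding of MP
  mp <- compute_mp(tab$aie, tab$ate)
  expect_lt(max(abs(mp - tab$mp)), 0.06)
  # the largest printed proportion belongs to the row computed here too
  expect_equal(which.max(mp), which.max(tab$mp))
  expect_equal(mp[tab$snp == "rs659554" & tab$outcome == "ADAS-11"],
               36.67, tolerance = 0.06)
  expect_true(is.na(compute_mp(0.3, 0)))
})

test_that("interval construction is symmetric and calibrated", {
  expect_equal(interval_from_bootstrap(1.3, rep(1.3, 200)),
               c(lower = 1.3, upper = 1.3))
  set.seed(51)
  reps <- 2 + rnorm(1e5)
  ci <- interval_from_bootstrap(2, reps, level = 0.05)
  expect_equal(unname(ci[2] - 2), qnorm(0.975), tolerance = 0.03)
  expect_equal(unname(2 - ci[1]), qnorm(0.975), tolerance = 0.03)
  # always contains the point estimate
  for (r in 1:10) {
    reps2 <- rnorm(200, mean = runif(1, -2, 2))
    ci2 <- interval_from_bootstrap(0.7, reps2)
    expect_true(ci2[1] <= 0.7 && 0.7 <= ci2[2])
  }
  expect_warning(interval_from_bootstrap(0, rnorm(50)), "100")
})

test_that("simultaneous band dominates pointwise intervals", {
  set.seed(52)
  T <- 40
  saie_hat <- sin(2 * pi * seq(0, 1, length.out = T))
  reps <- matrix(rnorm(500 * T, sd = 0.3), 500, T) +
    matrix(saie_hat, 500, T, byrow = TRUE)
  band <- band_from_bootstrap(saie_hat, reps, level = 0.05)
  ptw <- apply(reps, 2, function(col)
    unname(quantile(abs(col - mean(col)), 0.95)))
  expect_true(all(band$half_width >= ptw - 1e-12))
  expect_equal(band$upper - saie_hat, rep(band$half_width, T))

  degen <- band_from_bootstrap(saie_hat,
                               matrix(saie_hat, 10, T, byrow = TRUE))
  expect_equal(degen$half_width, 0)
})

test_that("subregion detection reports contiguous runs", {
  g <- seq(0, 1, length.out = 101)
  above <- list(lower = rep(0.2, 101), upper = rep(0.5, 101))
  det <- detect_subregions(above, g)
  expect_true(all(det$mask))
  expect_equal(det$subregions, data.frame(start = 0, end = 1))

  straddle <- list(lower = rep(-0.1, 101), upper = rep(0.1, 101))
  det0 <- detect_subregions(straddle, g)
  expect_false(any(det0$mask))
  expect_identical(nrow(det0$subregions), 0L)

  # one planted window
  lo <- rep(-0.1, 101); lo[31:50] <- 0.05
  det1 <- detect_subregions(list(lower = lo, upper = lo + 0.2), g)
  expect_equal(det1$subregions$start, g[31])
  expect_equal(det1$subregions$end, g[50])
})

test_that("significance calls use strict zero exclusion", {
  calls <- call_significance(list(
    aie = c(-0.3512, -0.0577),    # excludes zero
    ade = c(-0.1284, 0.5571),     # straddles zero
    edge = c(0, 0)))              # boundary: not significant
  expect_true(calls[["aie"]])
  expect_false(calls[["ade"]])
  expect_false(calls[["edge"]])
})
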
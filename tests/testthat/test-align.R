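test_that("Procrustes rotation recovers a planted rotation", {
  set.seed(3)
  q <- random_smooth_srvf(150L)
  expect_equal(optimal_rotation(q, q), diag(2), tolerance = 1e-10)

  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  q_rot <- srvf_curve(q$grid, q$values %*% R)   # values %*% R = t(R) applied
  O <- optimal_rotation(q, q_rot)
  expect_equal(O, R, tolerance = 1e-8)
  # agrees with a brute-force scan over angles
  th_hat <- atan2(O[2, 1], O[1, 1])
  th_oracle <- rotation_angle_oracle(q, q_rot)
  expect_equal(th_hat %% (2 * pi), th_oracle %% (2 * pi), tolerance = 1e-3)
})

test_that("rotation against a reflection still returns a proper rotation", {
  set.seed(4)
  q <- random_smooth_srvf(100L)
  q_ref <- srvf_curve(q$grid, q$values %*% diag(c(1, -1)))
  O <- optimal_rotation(q, q_ref)
  expect_equal(det(O), 1, tolerance = 1e-10)
  expect_equal(O %*% t(O), diag(2), tolerance = 1e-10)
})

test_that("zero cross-covariance yields identity with a warning", {
  g <- seq(0, 1, length.out = 50)
  q0 <- srvf_curve(g, matrix(0, 50, 2))
  q <- srvf_curve(g, cbind(rep(1, 50), 0))
  expect_warning(O <- optimal_rotation(q0, q), "identity")
  expect_equal(unclass(O)[1:2, 1:2], diag(2))
})

test_that("warping a curve onto itself returns the identity warp", {
  set.seed(5)
  q <- random_smooth_srvf(80L)
  tau <- optimal_warping(q, q)
  expect_equal(tau$values, q$grid, tolerance = 1e-12)
  expect_equal(tau$value, 0, tolerance = 1e-12)
  expect_error(optimal_warping(srvf_curve(seq(0, 1, length.out = 4),
                                          matrix(1, 4, 2)),
                               srvf_curve(seq(0, 1, length.out = 4),
                                          matrix(1, 4, 2))), "T >= 5")
})

test_that("dynamic-programming warp matches the independent oracle exactly", {
  set.seed(6)
  for (T in c(10L, 15L, 20L)) {
    for (rep in 1:3) {
      q1 <- random_smooth_srvf(T)
      q2 <- random_smooth_srvf(T)
      tau <- optimal_warping(q1, q2)
      expect_equal(tau$value, dp_warp_oracle(q1, q2), tolerance = 1e-10)
    }
  }
})

test_that("warping recovers a planted smooth reparameterization", {
  set.seed(7)
  T <- 200L
  g <- seq(0, 1, length.out = T)
  q <- random_smooth_srvf(T)
  gam <- g + 0.1 * sin(2 * pi * g) * g * (1 - g) * 4
  gam <- (gam - gam[1]) / (gam[T] - gam[1])
  q_w <- warp_apply(q, list(grid = g, values = gam))
  tau <- optimal_warping(q, q_w)
  # tau should invert gamma: tau(gamma(s)) ~ s within 2 grid steps
  comp <- approx(g, tau$values, xout = gam)$y
  expect_lt(max(abs(comp - g)), 2 / (T - 1))
})

test_that("optimal warp never increases the objective", {
  set.seed(8)
  g <- seq(0, 1, length.out = 60)
  w <- shapemed:::trapz_weights(g)
  for (rep in 1:25) {
    q1 <- random_smooth_srvf(60L)
    q2 <- random_smooth_srvf(60L)
    before <- sum(w * rowSums((q1$values - q2$values)^2))
    tau <- optimal_warping(q1, q2)
    expect_lte(tau$value, before + 1e-10)
  }
})

test_that("the warping group action preserves the L2 norm", {
  set.seed(9)
  T <- 200L
  g <- seq(0, 1, length.out = T)
  q <- random_smooth_srvf(T)
  gam <- g + 0.08 * sin(pi * g) * g * (1 - g) * 4
  gam <- (gam - gam[1]) / (gam[T] - gam[1])
  qw <- warp_apply(q, list(grid = g, values = gam))
  n1 <- sqrt(shapemed:::srvf_norm2(q))
  n2 <- sqrt(shapemed:::srvf_norm2(qw))
  expect_equal(n1, n2, tolerance = 1e-3)
  # identity warp leaves the curve unchanged
  qi <- warp_apply(q, list(grid = g, values = g))
  expect_equal(qi$values, q$values, tolerance = 1e-10)
})

test_that("warp followed by its inverse restores the curve", {
  set.seed(10)
  T <- 200L
  g <- seq(0, 1, length.out = T)
  q <- random_smooth_srvf(T)
  gam <- g + 0.06 * sin(2 * pi * g) * g * (1 - g) * 4
  gam <- (gam - gam[1]) / (gam[T] - gam[1])
  tau <- structure(list(grid = g, values = gam), class = "warp_fn")
  back <- warp_apply(warp_apply(q, tau), shapemed:::warp_inverse(tau))
  # interior comparison; endpoint derivative estimates are one-sided
  interior <- 5:(T - 4L)
  expect_lt(max(abs(back$values[interior, ] - q$values[interior, ])), 0.05)
})

test_that("elastic distance is zero on identical curves and invariant", {
  set.seed(12)
  q <- random_smooth_srvf(100L)
  expect_lt(elastic_distance(q, q), 1e-10)

  # invariance under rotation + reparameterization of the second argument
  g <- q$grid
  q2 <- random_smooth_srvf(100L)
  d0 <- elastic_distance(q, q2)
  for (rep in 1:5) {
    th <- runif(1, -pi, pi)
    gam <- g + runif(1, -0.08, 0.08) * sin(2 * pi * g) * g * (1 - g) * 4
    gam <- (gam - gam[1]) / (gam[length(g)] - gam[1])
    q2t <- rotate_srvf(warp_apply(q2, list(grid = g, values = gam)), th)
    expect_equal(elastic_distance(q, q2t), d0, tolerance = 0.05)
  }
})

test_that("Karcher mean of trivial samples is exact", {
  set.seed(13)
  q <- random_smooth_srvf(80L)
  nrm <- sqrt(shapemed:::srvf_norm2(q))
  qu <- srvf_curve(q$grid, q$values / nrm)   # unit norm, as normalized shapes
  one <- karcher_mean(list(qu))
  expect_true(one$converged)
  expect_identical(one$n_iterations, 1L)
  expect_equal(one$srvf$values, qu$values)

  same <- karcher_mean(list(qu, qu, qu))
  expect_true(same$converged)
  expect_equal(same$srvf$values, qu$values, tolerance = 1e-8)
  expect_error(karcher_mean(list()), "empty")
})

test_that("Karcher objective is non-increasing and beats the inputs", {
  set.seed(14)
  q <- random_smooth_srvf(80L)
  qu <- srvf_curve(q$grid, q$values / sqrt(shapemed:::srvf_norm2(q)))
  qr1 <- rotate_srvf(qu, 0.5)
  qr2 <- rotate_srvf(qu, -0.4)
  km <- karcher_mean(list(qr1, qr2))
  expect_true(all(diff(km$objective) < 1e-8))
  total_to <- function(mu) {
    sum(vapply(list(qr1, qr2), function(qi) elastic_distance(mu, qi)^2,
               numeric(1)))
  }
  expect_lte(total_to(km$srvf), total_to(qr1) + 1e-8)
  expect_lte(total_to(km$srvf), total_to(qr2) + 1e-8)
})

test_that("cohort alignment removes nuisance variation from a template", {
  tpl <- cc_template(90)
  crv <- simulate_shape_cohort_from_template(tpl, n = 20, rotation_sd = 0.4,
                                             warp_sd = 0.1, seed = 21)
  al <- align_cohort(crv, n_grid = 80)
  expect_equal(dim(al$M), c(20L, 80L, 2L))
  pre <- vapply(crv, function(cu)
    srvf_transform(normalize_landmarks(cu, 80))$values, matrix(0, 80, 2))
  v_pre <- sum(apply(pre, c(1, 2), var))
  v_post <- sum(apply(al$M, c(2, 3), var))
  expect_lt(v_post / v_pre, 0.1)

  # identical inputs collapse onto the atlas
  same <- align_cohort(list(tpl, tpl, tpl), n_grid = 60)
  for (i in 1:3)
    expect_equal(unname(same$M[i, , ]), same$atlas$srvf$values,
                 tolerance = 1e-6)

  # minimal cohort runs
  two <- align_cohort(crv[1:2], n_grid = 40)
  expect_length(two$srvfs, 2L)
  expect_error(align_cohort(crv[1]), "at least 2")
})
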
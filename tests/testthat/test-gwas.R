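test_that("per-SNP model matches hand linear algebra and lm()", {
  # tiny dataset solved by the closed-form normal equations written out here
  y <- c(1.2, 0.4, 2.5, 1.9)
  x <- c(0, 1, 1, 0)
  C <- cbind(intercept = rep(1, 4), age = c(0.1, -0.2, 0.3, 0))
  X <- cbind(x, C)
  beta_hand <- solve(t(X) %*% X) %*% t(X) %*% y
  r <- fit_snp_model(y, x, C)
  expect_equal(unname(r$effect), unname(beta_hand[1, 1]), tolerance = 1e-12)

  set.seed(31)
  n <- 80
  x2 <- rbinom(n, 1, 0.4)
  C2 <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  y2 <- 0.7 * x2 + C2 %*% c(1, 0.5, -0.2) + rnorm(n)
  r2 <- fit_snp_model(as.numeric(y2), x2, C2)
  lmfit <- summary(lm(y2 ~ x2 + C2[, 2] + C2[, 3]))
  expect_equal(r2$effect, lmfit$coefficients["x2", "Estimate"], tolerance = 1e-10)
  expect_equal(r2$se, lmfit$coefficients["x2", "Std. Error"], tolerance = 1e-10)
  expect_equal(r2$p, lmfit$coefficients["x2", "Pr(>|t|)"], tolerance = 1e-10)
})

test_that("noiseless and degenerate SNP fits behave as specified", {
  n <- 20
  x <- rep(c(0, 1), 10)
  y <- 2 * x
  r <- fit_snp_model(y, x, matrix(1, n, 1))
  expect_equal(r$effect, 2, tolerance = 1e-12)
  expect_equal(r$p, 0)

  mono <- fit_snp_model(rnorm(n), rep(1, n), matrix(1, n, 1))
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$effect))
  expect_error(fit_snp_model(y, x, cbind(1, rep(2, n))), "rank-deficient")
})

test_that("estimated effect is calibrated in simulation", {
  set.seed(32)
  n <- 500
  hits <- replicate(200, {
    x <- rbinom(n, 1, 0.3)
    y <- 0.5 * x + rnorm(n)
    r <- fit_snp_model(y, x, matrix(1, n, 1))
    abs(r$effect - 0.5) < 3 * r$se
  })
  expect_gt(mean(hits), 0.95)   # 3 se ~ 99.7% nominal
})

test_that("BH adjustment matches worked examples and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # order invariance with ties
  p <- c(0.02, 0.01, 0.02, 0.9)
  expect_equal(sort(bh_adjust(p)), sort(bh_adjust(rev(p))))
})

test_that("genome screen equals per-SNP OLS and respects ordering", {
  set.seed(33)
  n <- 120; m <- 25
  G <- matrix(rbinom(n * m, 1, 0.3), n, m,
              dimnames = list(NULL, paste0("rs", 1:m)))
  C <- cbind(intercept = 1, age = rnorm(n))
  y <- 1.0 * G[, 7] + C %*% c(0.5, 0.2) + rnorm(n)
  gt <- genotype_table(G, coding = "binary")
  scr <- genome_screen(as.numeric(y), gt, C, q_threshold = 0.05)

  for (g in c(1L, 7L, 25L)) {
    ref <- fit_snp_model(as.numeric(y), G[, g], C)
    expect_equal(scr$effect[g], ref$effect, tolerance = 1e-10)
    expect_equal(scr$se[g], ref$se, tolerance = 1e-10)
    expect_equal(scr$p[g], ref$p, tolerance = 1e-10)
  }
  expect_true(all(scr$p_adj >= scr$p - 1e-15))
  expect_true(all(scr$p_adj[scr$selected] <= 0.05))

  # permuting SNP order permutes results identically
  perm <- sample(m)
  gt_p <- genotype_table(G[, perm], coding = "binary")
  scr_p <- genome_screen(as.numeric(y), gt_p, C, q_threshold = 0.05)
  expect_equal(scr_p$effect, scr$effect[perm], tolerance = 1e-12)
  expect_equal(scr_p$p_adj, scr$p_adj[perm], tolerance = 1e-12)

  # single-SNP screen reduces to the raw test
  scr1 <- genome_screen(as.numeric(y), genotype_table(G[, 7, drop = FALSE],
                                                      coding = "binary"), C)
  expect_equal(scr1$p_adj, scr1$p)
  expect_error(genome_screen(as.numeric(y)[-1], gt, C), "mismatch")
})

test_that("a planted strong SNP is selected and nulls mostly are not", {
  set.seed(34)
  n <- 500; m <- 101
  G <- matrix(rbinom(n * m, 1, 0.3), n, m,
              dimnames = list(NULL, paste0("rs", 1:m)))
  C <- matrix(1, n, 1)
  y <- 1.0 * G[, 1] + rnorm(n)
  scr <- genome_screen(as.numeric(y), genotype_table(G, coding = "binary"), C)
  expect_true(scr$selected[1])
  expect_lt(sum(scr$selected[-1]), 5)
})

test_that("missing dosages are imputed to the SNP mode", {
  G <- cbind(a = c(0, 1, NA, 1, 1), b = c(NA, 0, 0, 1, 0))
  gt <- genotype_table(G, coding = "binary")
  expect_equal(unname(gt$dosages[3, "a"]), 1)
  expect_equal(unname(gt$dosages[1, "b"]), 0)
  expect_false(anyNA(gt$dosages))
  expect_equal(gt$allele_frequencies[["a"]], 0.8)
})
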
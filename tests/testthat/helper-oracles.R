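# Independent oracles and small constructors used across the test files.

# Build an SRVF curve by evaluating two coordinate functions of s on a grid.
srvf_from_funs <- function(f1, f2, T = 100L) {
  g <- seq(0, 1, length.out = T)
  shapemed::srvf_curve(g, cbind(f1(g), f2(g)))
}

# Smooth random SRVF from a few Fourier modes (seeded by the caller).
random_smooth_srvf <- function(T = 100L, modes = 3L) {
  g <- seq(0, 1, length.out = T)
  mk <- function() {
    a <- rnorm(modes, sd = 1 / seq_len(modes))
    as.numeric(cbind(1, sapply(seq_len(modes), function(k)
      cos(k * pi * g))) %*% c(rnorm(1), a))
  }
  shapemed::srvf_curve(g, cbind(mk(), mk()))
}

# Rotate the values of an SRVF by angle theta (group action on the left).
rotate_srvf <- function(q, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  shapemed::srvf_curve(q$grid, q$values %*% t(R))
}

# Independent dynamic-programming oracle for the optimal lattice warping:
# plain forward recursion over the same slope set, written separately from
# the package's compiled implementation (own interpolation and quadrature).
dp_warp_oracle <- function(q1, q2) {
  v1 <- q1$values; v2 <- q2$values
  T <- nrow(v1)
  ds <- 1 / (T - 1)
  steps <- list(c(1, 1), c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  interp2 <- function(u) {
    if (u <= 0) return(v2[1, ])
    if (u >= T - 1) return(v2[T, ])
    lo <- floor(u); wgt <- u - lo
    (1 - wgt) * v2[lo + 1, ] + wgt * v2[lo + 2, ]
  }
  ecost <- function(a, b, k, l) {
    m <- l / k
    tot <- 0
    for (t in 0:k) {
      d <- v1[a + t + 1, ] - sqrt(m) * interp2(b + m * t)
      w <- if (t == 0 || t == k) 0.5 else 1
      tot <- tot + w * sum(d^2)
    }
    tot * ds
  }
  E <- matrix(Inf, T, T)
  E[1, 1] <- 0
  for (i in 2:T) for (j in 2:T) {
    for (st in steps) {
      a <- i - st[1]; b <- j - st[2]
      if (a >= 1 && b >= 1 && is.finite(E[a, b])) {
        cand <- E[a, b] + ecost(a - 1, b - 1, st[1], st[2])
        if (cand < E[i, j]) E[i, j] <- cand
      }
    }
  }
  E[T, T]
}

# Brute-force rotation oracle: scan angles on a fine grid.
rotation_angle_oracle <- function(q_ref, q, n_angles = 20000L) {
  w <- diff(q_ref$grid)
  tw <- c(w[1] / 2, (w[-length(w)] + w[-1]) / 2, w[length(w)] / 2)
  angles <- seq(0, 2 * pi, length.out = n_angles)
  obj <- vapply(angles, function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    sum(tw * rowSums((q_ref$values - q$values %*% t(R))^2))
  }, numeric(1))
  angles[which.min(obj)]
}

# Printed causal-estimand table used for internal-consistency arithmetic
# (inputs to the package's estimand identities, stored to 4 decimals as
# printed; MP to 2 decimals).
printed_causal_table <- function() {
  data.frame(
    outcome = c("ADAS-11", "ADAS-11", "ADAS-11", "ADAS-11", "ADAS-13",
                "FAQ", "FAQ", "FAQ", "FAQ", "RAVLT.learning"),
    snp = c("rs1556188", "rs659561", "rs648958", "rs659554", "rs1556188",
            "rs1948397", "rs4646797", "rs11657205", "rs1989379", "rs2343121"),
    ate = c(-1.1703, 1.8604, -1.9579, -1.4770, -1.7257,
            -0.6248, 0.5318, 0.4423, 0.3202, 0.1108),
    ade = c(-0.9753, 1.4085, -1.5509, -0.9354, -1.3998,
            -0.5014, 0.4261, 0.3725, 0.2367, 0.1251),
    aie = c(-0.1950, 0.4519, -0.4070, -0.5416, -0.3259,
            -0.1234, 0.1057, 0.0698, 0.0835, -0.0143),
    aie_lower = c(-0.3512, 0.1854, -0.7349, -0.9676, -0.5863,
                  -0.2274, 0.0307, 0.0024, 0.0186, -0.0274),
    aie_upper = c(-0.0577, 0.7807, -0.1383, -0.1801, -0.1128,
                  -0.0312, 0.1900, 0.1389, 0.1547, -0.0032),
    mp = c(16.66, 24.29, 20.79, 36.67, 18.89,
           19.75, 19.88, 15.78, 26.08, 12.91),
    stringsAsFactors = FALSE)
}

# Mock fitted-model pair with prescribed coefficient functions, for testing
# the estimand arithmetic in isolation.
mock_fits <- function(alpha1, alpha2, beta1, beta2, gamma, T = 201L) {
  g <- seq(0, 1, length.out = T)
  fit4 <- structure(list(alpha = cbind(alpha1(g), alpha2(g)), grid = g),
                    class = "shape_on_scalar_fit")
  fit5 <- structure(list(gamma = gamma, beta = cbind(beta1(g), beta2(g)),
                         grid = g),
                    class = "scalar_on_shape_fit")
  list(fit4 = fit4, fit5 = fit5)
}
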
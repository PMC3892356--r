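test_that("knots sit at the empirical terciles", {
  x <- c(0, 0.25, 0.5, 0.75, 1)
  expected <- unname(quantile(x, c(1 / 3, 2 / 3), type = 7))
  k <- place_knots(x)
  expect_equal(k, expected)
  expect_lt(k[1], k[2])

  xg <- seq(0, 1, length.out = 301)
  kg <- place_knots(xg)
  expect_equal(kg, c(1 / 3, 2 / 3), tolerance = 1e-6)
})

test_that("degenerate covariates are rejected and ties are broken", {
  expect_error(place_knots(rep(0.4, 10)), "distinct")
  expect_error(place_knots(c(0.1, 0.9)), "distinct")
  # heavy ties: both terciles land on the same value; upper knot is nudged
  k <- place_knots(c(rep(0.5, 50), 0.1, 0.9))
  expect_lt(k[1], k[2])
})

test_that("the smooth evaluates as a centered broken-stick spline", {
  hab <- matrix(runif(60), 20, 3)
  sp <- spline_spec(hab)
  sp$beta <- c(1, 0, 0)
  sp$u <- matrix(0, 3, 2)
  sp$u[1, ] <- c(2, -3)
  sp$knots[1, ] <- c(0.3, 0.6)
  sp$center[1] <- 0.5

  # below both knots with beta = 0 the smooth vanishes
  sp0 <- sp
  sp0$beta[1] <- 0
  expect_equal(smooth_value(0.1, sp0, 1), 0)
  # at the first knot the first truncated term contributes exactly 0
  expect_equal(smooth_value(0.3, sp, 1), 1 * (0.3 - 0.5))
  # hand-evaluated value at x = 0.8
  expect_equal(smooth_value(0.8, sp, 1), 0.3 + 2 * 0.5 - 3 * 0.2)

  # independent piecewise-linear evaluator: integrate the slopes segment by
  # segment from x = 0
  piecewise <- function(x) {
    brk <- c(0, 0.3, 0.6, 1)
    slope <- c(1, 1 + 2, 1 + 2 - 3)
    val <- 1 * (0 - 0.5)  # value at x = 0
    for (s in seq_len(3)) {
      hi <- min(x, brk[s + 1])
      if (hi > brk[s]) val <- val + slope[s] * (hi - brk[s])
      if (x <= brk[s + 1]) break
    }
    val
  }
  for (x in c(0.05, 0.3, 0.45, 0.6, 0.8, 1))
    expect_equal(smooth_value(x, sp, 1), piecewise(x), tolerance = 1e-12)
})

test_that("the smooth is continuous, and identically zero with zero coefficients", {
  hab <- matrix(runif(90), 30, 3)
  sp <- spline_spec(hab, beta = c(0.7, -1, 2),
                    u = matrix(rnorm(6), 3, 2))
  for (h in 1:3) for (k in sp$knots[h, ]) {
    eps <- 1e-9
    expect_lt(abs(smooth_value(k + eps, sp, h) - smooth_value(k, sp, h)),
              1e-7)
    expect_lt(abs(smooth_value(k - eps, sp, h) - smooth_value(k, sp, h)),
              1e-7)
  }
  sp0 <- spline_spec(hab)  # zero coefficients
  xs <- seq(0, 1, 0.1)
  expect_equal(smooth_value(xs, sp0, 2), rep(0, length(xs)))
})

test_that("shrinking the penalty collapses the smooth to the linear term", {
  hab <- matrix(runif(40), 20, 2)
  sp <- spline_spec(hab, beta = c(1.5, 0))
  set.seed(3)
  for (sigma_u in c(1e-3, 1e-6)) {
    sps <- sp
    sps$u <- matrix(rnorm(4, 0, sigma_u), 2, 2)
    xs <- seq(0, 1, 0.05)
    lin <- 1.5 * (xs - sp$center[1])
    expect_lt(max(abs(smooth_value(xs, sps, 1) - lin)), 10 * sigma_u)
  }
})

test_that("the design matrix reproduces the sum of smooths", {
  set.seed(9)
  hab <- matrix(runif(50 * 8), 50, 8)
  hab <- hab / rowSums(hab)
  sp <- spline_spec(hab, beta = rnorm(8), u = matrix(rnorm(16), 8, 2),
                    sigma_u = runif(8, 0.5, 2))
  design <- atlasdyn:::spline_design(hab, sp)
  coefs <- atlasdyn:::spline_coef(sp)
  direct <- rowSums(sapply(1:8, function(h) smooth_value(hab[, h], sp, h)))
  expect_equal(drop(design %*% coefs), direct, tolerance = 1e-12)
})
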
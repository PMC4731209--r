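test_that("crossings solve the polynomial exactly in closed form", {
  # linear: alpha + beta1 x* = 0 at x* = 1
  res <- crossing_points(alpha = -1, beta1 = 1)
  expect_equal(res$crossings$crossing_std, 1)
  expect_equal(res$crossings$direction, "rising")

  # the linear crossing is -alpha / beta1 exactly
  expect_identical(crossing_points(-1.3, 0.4)$crossings$crossing_std,
                   -(-1.3) / 0.4)

  # quadratic: roots at +/- 1, one falling, one rising
  res <- crossing_points(alpha = -1, beta1 = 0, beta2 = 1)
  expect_equal(res$crossings$crossing_std, c(-1, 1))
  expect_equal(res$crossings$direction, c("falling", "rising"))

  # no real roots when the parabola never reaches the target
  res <- crossing_points(alpha = 1, beta1 = 0, beta2 = 1)
  expect_equal(nrow(res$crossings), 0)

  # constant curve: degenerate, warned, no crossings
  expect_warning(res <- crossing_points(alpha = 0, beta1 = 0), "degenerate")
  expect_equal(nrow(res$crossings), 0)
  expect_true(res$degenerate)

  expect_error(crossing_points(0, 1, target = 1), "\\(0, 1\\)")
  expect_error(crossing_points(Inf, 1), "finite")
})

test_that("crossings back-transform consistently and equivary under affine maps", {
  set.seed(19)
  for (i in 1:20) {
    alpha <- runif(1, -2, 2); b1 <- runif(1, -2, 2); b2 <- runif(1, -1, 1)
    target <- runif(1, 0.15, 0.85)
    center <- runif(1, -50, 50); scale <- runif(1, 0.1, 20)
    res <- crossing_points(alpha, b1, b2, target = target,
                           center = center, scale = scale)
    for (j in seq_len(nrow(res$crossings))) {
      xs <- (res$crossings$crossing[j] - center) / scale  # re-standardize
      expect_equal(alpha + b1 * xs + b2 * xs^2, qlogis(target),
                   tolerance = 1e-8)
      expect_equal(xs, res$crossings$crossing_std[j], tolerance = 1e-10)
    }
  }
  # linear case: original-unit crossing is center + scale * (-alpha/beta1)
  res <- crossing_points(-0.5, 0.25, center = 100, scale = 4)
  expect_equal(res$crossings$crossing, 100 + 4 * 2)
})

test_that("analytic roots agree with a brute-force scan of the curve", {
  set.seed(23)
  for (i in 1:20) {
    alpha <- runif(1, -2, 2); b1 <- runif(1, -2, 2); b2 <- runif(1, -1, 1)
    eta <- function(x) alpha + b1 * x + b2 * x^2
    # oracle: dense scan + uniroot refinement over the standardized range
    xs <- seq(-3, 3, length.out = 100001)
    s <- sign(eta(xs))
    flips <- which(s[-1] * s[-length(s)] < 0)
    oracle_roots <- sort(vapply(flips, function(f) {
      uniroot(eta, c(xs[f], xs[f + 1]), tol = 1e-12)$root
    }, 0))

    res <- crossing_points(alpha, b1, b2, target = 0.5)
    found <- sort(res$crossings$crossing_std)
    found <- found[found >= -3 & found <= 3]
    expect_equal(length(found), length(oracle_roots))
    if (length(found) > 0) {
      expect_equal(found, oracle_roots, tolerance = 1e-6)
      expect_equal(plogis(eta(found)), rep(0.5, length(found)),
                   tolerance = 1e-6)
    }
  }
})

test_that("threshold reports tabulate fits with posterior intervals", {
  # strong falling linear effect: exactly one crossing, tight interval
  dat <- make_beta_data(600, alpha = 0.2, beta = -1.2, phi = 30, seed = 55)
  fit <- sample_posterior(dat$y, dat$design, iterations = 1500,
                          burn_in = 700, chains = 2, seed = 14)
  rep1 <- threshold_report(list(fit), target = 0.5, taxa = "simtax",
                           o_half = 1)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$direction, "falling")
  expect_equal(rep1$taxon, "simtax")
  expect_true(rep1$in_range)
  expect_true(rep1$lo95 < rep1$crossing && rep1$crossing < rep1$hi95)
  # the reported crossing reproduces the target on the fitted curve
  expect_equal(fitted_curve(fit, rep1$crossing)$mu, 0.5, tolerance = 1e-8)

  # a curve that never spans the target within the data: empty crossing row
  dat2 <- make_beta_data(400, alpha = 2.5, beta = 0.15, phi = 30, seed = 56)
  fit2 <- sample_posterior(dat2$y, dat2$design, iterations = 1200,
                           burn_in = 600, chains = 1, seed = 15)
  rep2 <- threshold_report(list(fit2), target = 0.5)
  expect_equal(nrow(rep2), 1)
  expect_true(is.na(rep2$crossing) || !rep2$in_range)

  # several fits stack into one table with labels recycled
  rep3 <- threshold_report(list(fit, fit), taxa = c("a", "b"),
                           o_half = c(1, 2))
  expect_equal(rep3$taxon, c("a", "b"))
  expect_equal(rep3$o_half, c(1, 2))
})
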
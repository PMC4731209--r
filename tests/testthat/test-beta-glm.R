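test_that("design matrices carry the polynomial and the back-transform", {
  d0 <- build_design(c(1, 2, 3), 0)
  expect_equal(ncol(d0$X), 0)
  expect_equal(nrow(d0$X), 3)

  d1 <- build_design(c(1, 2, 3), 1, standardize = FALSE)
  expect_equal(unname(d1$X[, 1]), c(1, 2, 3))
  expect_equal(d1$center, 0)
  expect_equal(d1$scale, 1)

  d2 <- build_design(c(1, 2, 3), 2, standardize = TRUE)
  expect_equal(unname(d2$X[, 2]), unname(d2$X[, 1]^2))
  expect_equal(unname(d2$X[, 1]), (c(1, 2, 3) - 2) / 1)
  expect_equal(d2$x_range, c(1, 3))

  expect_error(build_design(rep(4, 10), 1, standardize = TRUE),
               "zero-variance")
  expect_error(build_design(c(1, NA), 1), "finite")
  expect_error(build_design(1:3, 3), "0, 1 or 2")
})

test_that("Beta log-likelihood matches closed forms and is symmetric", {
  set.seed(1)
  y <- runif(20, 0.05, 0.95)
  # mu = 0.5, phi = 2 is Beta(1, 1): density 1 everywhere
  expect_equal(beta_loglik(y, 0.5, 2), 0, tolerance = 1e-12)
  # Beta(2, 2) at 0.5 has density 1.5
  expect_equal(beta_loglik(rep(0.5, 7), 0.5, 4), 7 * log(1.5),
               tolerance = 1e-12)
  # symmetry of the Beta family
  mu <- runif(20, 0.1, 0.9)
  expect_equal(beta_loglik(y, mu, 13.7), beta_loglik(1 - y, 1 - mu, 13.7),
               tolerance = 1e-10)
  expect_error(beta_loglik(c(0.5, 1), 0.5, 2), "boundary_adjust")
  expect_error(beta_loglik(0.5, 1, 2), "mu")
  expect_error(beta_loglik(0.5, 0.5, -2), "positive")
})

test_that("the boundary squeeze maps [0,1] into the open interval", {
  expect_equal(boundary_adjust(0.5, 100), 0.5)
  expect_equal(boundary_adjust(1, 100), 0.995)
  expect_equal(boundary_adjust(0, 10), 0.05)
  y <- c(0, 0.2, 0.7, 1)
  ya <- boundary_adjust(y)
  expect_true(all(ya > 0 & ya < 1))
  expect_equal(order(ya), order(y))
  expect_error(boundary_adjust(0.5, 1), "at least 2")
  expect_error(boundary_adjust(c(-0.1, 0.5)), "0, 1")
})

test_that("the sampler is deterministic and recovers the intercept mean", {
  dat <- make_beta_data(250, alpha = -0.7, beta = 0.8, phi = 15, seed = 31)
  f1 <- sample_posterior(dat$y, dat$design, iterations = 800, burn_in = 400,
                         chains = 2, seed = 5)
  f2 <- sample_posterior(dat$y, dat$design, iterations = 800, burn_in = 400,
                         chains = 2, seed = 5)
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$samples, f2$samples)
  f3 <- sample_posterior(dat$y, dat$design, iterations = 800, burn_in = 400,
                         chains = 2, seed = 6)
  expect_false(identical(f3$samples, f1$samples))
  expect_equal(nrow(f1$samples), 2 * 800)
  expect_true(all(f1$samples[, "phi"] > 0))
  expect_true(all(c("alpha", "beta1", "phi") %in% f1$summary$parameter))

  # intercept-only fit: posterior mean of inv-logit(alpha) ~ sample mean
  d0 <- build_design(numeric(400), 0, standardize = FALSE)
  y0 <- simulate_beta_response(d0, alpha = 0.3, beta = numeric(0), phi = 8,
                               seed = 9)
  f0 <- sample_posterior(y0, d0, iterations = 1500, burn_in = 600,
                         chains = 1, seed = 2)
  expect_equal(plogis(f0$posterior_mean[["alpha"]]), mean(y0),
               tolerance = 0.01)

  expect_error(sample_posterior(c(0.5, 1), build_design(c(1, 2), 1)),
               "boundary_adjust")
})

test_that("posterior matches an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  dat <- make_beta_data(500, alpha = -1, beta = 0.6, phi = 20, seed = 77)
  fit <- sample_posterior(dat$y, dat$design, iterations = 4000,
                          burn_in = 1500, chains = 2, seed = 12)

  model_string <- "
  model {
    for (i in 1:n) {
      y[i] ~ dbeta(mu[i] * phi, (1 - mu[i]) * phi)
      logit(mu[i]) <- alpha + beta * x[i]
    }
    alpha ~ dnorm(0, 0.001)
    beta ~ dnorm(0, 0.001)
    phi ~ dgamma(0.1, 0.1)
  }"
  jm <- rjags::jags.model(
    textConnection(model_string),
    data = list(y = dat$y, x = unname(dat$design$X[, 1]),
                n = length(dat$y)),
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1),
    n.chains = 1, quiet = TRUE)
  update(jm, 1500, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("alpha", "beta", "phi"), 4000,
                            progress.bar = "none")[[1]]
  jm_mean <- colMeans(js)
  expect_equal(fit$posterior_mean[["alpha"]], jm_mean[["alpha"]],
               tolerance = 0.02)
  expect_equal(fit$posterior_mean[["beta1"]], jm_mean[["beta"]],
               tolerance = 0.02)
  expect_equal(fit$posterior_mean[["phi"]], jm_mean[["phi"]],
               tolerance = 0.05)
})

test_that("plug-in deviance matches the oracle and improves under signal", {
  dat <- make_beta_data(300, alpha = -0.5, beta = 0.9, phi = 25, seed = 17)
  d0 <- build_design(numeric(300), 0, standardize = FALSE)
  f0 <- sample_posterior(dat$y, d0, iterations = 1200, burn_in = 600,
                         chains = 1, seed = 41)
  f1 <- sample_posterior(dat$y, dat$design, iterations = 1200, burn_in = 600,
                         chains = 1, seed = 42)

  # oracle recomputation at the posterior means
  mu_hat <- plogis(f1$posterior_mean[["alpha"]] +
                     dat$design$X[, 1] * f1$posterior_mean[["beta1"]])
  dev_oracle <- -2 * oracle_beta_loglik(dat$y, mu_hat,
                                        f1$posterior_mean[["phi"]])
  expect_equal(f1$deviance, dev_oracle, tolerance = 1e-8)
  expect_equal(deviance(f1), f1$deviance)

  # a true slope must reduce the deviance
  expect_lt(f1$deviance, f0$deviance)
  # posterior-mean deviance is larger than the plug-in at the means
  expect_gt(deviance(f1, type = "mean"), f1$deviance)
})

test_that("nested comparison applies the 3.84-per-parameter rule exactly", {
  y <- runif(50, 0.2, 0.8)
  null <- make_fake_fit(0, 103.84, y)
  lin_hit <- make_fake_fit(1, 100.00, y)
  expect_true(compare_nested(null, lin_hit)$improves)   # delta exactly 3.84
  lin_miss <- make_fake_fit(1, 100.01, y)
  expect_false(compare_nested(null, lin_miss)$improves) # delta 3.83

  cmp <- compare_nested(null, lin_hit)
  expect_equal(cmp$delta_deviance, 3.84)
  expect_equal(cmp$params_added, 1L)

  # two parameters added need 2 x 3.84
  quad <- make_fake_fit(2, 103.84 - 7.67, y)
  expect_false(compare_nested(null, quad)$improves)
  quad2 <- make_fake_fit(2, 103.84 - 7.68, y)
  expect_true(compare_nested(null, quad2)$improves)

  # antisymmetry in the deviances
  expect_equal(compare_nested(null, quad)$delta_deviance,
               -(quad$deviance - null$deviance))

  expect_error(compare_nested(lin_hit, null), "higher polynomial degree")
  expect_error(compare_nested(make_fake_fit(1, 10, y, "a"),
                              make_fake_fit(2, 5, y, "b")), "share")
  expect_error(compare_nested(null, make_fake_fit(1, 5, runif(50, 0.2, 0.8))),
               "identical responses")
})

test_that("deviance R-squared is 0 at the null and clamped below it", {
  y <- runif(40, 0.2, 0.8)
  null <- make_fake_fit(0, 80, y)
  expect_equal(r_squared(null, null), 0)
  expect_equal(r_squared(make_fake_fit(1, 60, y), null), 25)
  expect_warning(r2 <- r_squared(make_fake_fit(1, 90, y), null), "clamped")
  expect_equal(r2, 0)
  expect_error(r_squared(make_fake_fit(1, 0, y), make_fake_fit(0, 0, y)),
               "undefined")
  expect_error(r_squared(null, make_fake_fit(1, 60, y)), "intercept-only")
})

test_that("stepwise selection follows the nested testing order", {
  y <- runif(30, 0.2, 0.8)
  null <- make_fake_fit(0, 100, y)

  # linear rejected: null retained even if quadratic would beat the null
  lin_bad <- make_fake_fit(1, 98, y)
  quad_good <- make_fake_fit(2, 80, y)
  sel <- select_model(null, lin_bad, quad_good)
  expect_equal(sel$degree, 0)
  expect_equal(sel$r_squared, 0)

  # linear accepted, quadratic rejected
  lin_good <- make_fake_fit(1, 90, y)
  quad_meh <- make_fake_fit(2, 88, y)
  sel <- select_model(null, lin_good, quad_meh)
  expect_equal(sel$degree, 1)
  expect_equal(sel$r_squared, 10)

  # both accepted
  quad_better <- make_fake_fit(2, 84, y)
  sel <- select_model(null, lin_good, quad_better)
  expect_equal(sel$degree, 2)
  expect_true(sel$comparisons$quadratic_vs_linear$improves)
})

test_that("fitted curves honour the link and the standardization record", {
  y <- runif(30, 0.2, 0.8)
  f <- make_fake_fit(1, 50, y)
  f$posterior_mean <- c(alpha = 0, beta1 = 0, phi = 10)
  expect_equal(fitted_curve(f, c(-5, 0, 7))$mu, rep(0.5, 3))

  f$posterior_mean <- c(alpha = -20, beta1 = 0, phi = 10)
  expect_true(all(fitted_curve(f, 0)$mu < 1e-8))

  # at the covariate mean (x* = 0) the curve equals inv-logit(alpha)
  dat <- make_beta_data(300, alpha = -0.8, beta = 0.5, phi = 20, seed = 3)
  fit <- sample_posterior(dat$y, dat$design, iterations = 800, burn_in = 400,
                          chains = 1, seed = 8)
  expect_equal(fitted_curve(fit, mean(dat$x))$mu,
               plogis(fit$posterior_mean[["alpha"]]), tolerance = 1e-12)
  expect_false(fitted_curve(fit, max(dat$x) + 1)$in_range)
})
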
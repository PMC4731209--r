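# Independent oracles and small fixture builders shared across tests.

# brute-force Beta log-likelihood via log-Gamma functions, one term at a time
# (kept deliberately naive and independent of the package implementation)
oracle_beta_loglik <- function(y, mu, phi) {
  if (length(mu) == 1) mu <- rep(mu, length(y))
  total <- 0
  for (i in seq_along(y)) {
    a <- mu[i] * phi
    b <- (1 - mu[i]) * phi
    total <- total + lgamma(a + b) - lgamma(a) - lgamma(b) +
      (a - 1) * log(y[i]) + (b - 1) * log(1 - y[i])
  }
  total
}

# independent maximum-likelihood fit by numerical optimization of the naive
# log-likelihood; theta = (alpha, beta..., log phi)
oracle_beta_mle <- function(y, X) {
  X <- as.matrix(X)
  k <- ncol(X)
  nll <- function(theta) {
    mu <- plogis(theta[1] + if (k > 0) drop(X %*% theta[2:(k + 1)]) else 0)
    if (any(mu <= 0 | mu >= 1)) return(1e10)
    a <- mu * exp(theta[k + 2])
    b <- (1 - mu) * exp(theta[k + 2])
    -sum(lgamma(a + b) - lgamma(a) - lgamma(b) +
           (a - 1) * log(y) + (b - 1) * log(1 - y))
  }
  mu0 <- mean(y)
  start <- c(qlogis(mu0), rep(0, k),
             log(max(mu0 * (1 - mu0) / var(y) - 1, 0.5)))
  opt <- optim(start, nll, method = "BFGS", control = list(maxit = 500))
  est <- opt$par
  c(alpha = est[1],
    if (k > 0) setNames(est[2:(k + 1)], paste0("beta", seq_len(k))),
    phi = exp(est[k + 2]))
}

# minimal stand-in posterior_fit carrying just what deviance-based
# comparisons read; used to pin decision boundaries without MCMC noise
make_fake_fit <- function(degree, deviance, y, covariate = "x") {
  structure(
    list(spec = model_spec(covariate_name = covariate, degree = degree),
         design = list(degree = degree, center = 0, scale = 1,
                       x_range = if (degree > 0) c(-3, 3)),
         y = y, deviance = deviance,
         posterior_mean = c(alpha = 0,
                            if (degree >= 1) c(beta1 = 0),
                            if (degree >= 2) c(beta2 = 0),
                            phi = 10)),
    class = "posterior_fit")
}

# quick Beta-regression dataset on a standard-normal covariate
make_beta_data <- function(n, alpha, beta, phi, seed) {
  set.seed(seed)
  x <- rnorm(n)
  design <- build_design(x, length(beta), covariate_name = "cov")
  y <- simulate_beta_response(design, alpha, beta, phi, seed = seed + 1)
  list(x = x, design = design, y = y)
}
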
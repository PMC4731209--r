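#' Model specification for a single-covariate Beta regression
#'
#' Describes one candidate model for the ignorance scores of a taxon: an
#' intercept-only null (`degree = 0`), a linear (`degree = 1`) or a quadratic
#' (`degree = 2`) effect of one geographic covariate on the logit of the mean
#' ignorance. Priors follow the vague choices used for this analysis:
#' precision `phi ~ Gamma(0.1, 0.1)` and coefficients `~ Normal(0, 1000)`
#' (variance parameterization, so SD = sqrt(1000)).
#'
#' @param covariate_name Name of the covariate (ignored for `degree = 0`).
#' @param degree Polynomial degree, 0, 1 or 2.
#' @param standardize Whether the covariate is centred and scaled before
#'   fitting (curves and thresholds are always reported back on the original
#'   scale).
#' @param prior_phi_shape,prior_phi_rate Gamma prior on the precision `phi`.
#' @param prior_coef_sd Normal prior SD on intercept and coefficients.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(covariate_name = "x", degree = 1, standardize = TRUE,
                       prior_phi_shape = 0.1, prior_phi_rate = 0.1,
                       prior_coef_sd = sqrt(1000)) {
  degree <- as.integer(degree)
  if (is.na(degree) || !degree %in% 0:2) {
    stop("`degree` must be 0, 1 or 2", call. = FALSE)
  }
  if (prior_phi_shape <= 0 || prior_phi_rate <= 0 || prior_coef_sd <= 0) {
    stop("prior parameters must be positive", call. = FALSE)
  }
  structure(list(covariate_name = as.character(covariate_name),
                 degree = degree, standardize = isTRUE(standardize),
                 prior_phi_shape = prior_phi_shape,
                 prior_phi_rate = prior_phi_rate,
                 prior_coef_sd = prior_coef_sd),
            class = "model_spec")
}

#' Build the design matrix for a polynomial covariate effect
#'
#' Returns the covariate columns entering `logit(mu) = alpha + X beta`:
#' nothing for the null model, `x` for a linear effect, `(x, x^2)` for a
#' quadratic effect, where `x` is optionally centred and scaled. The
#' standardization record (centre, scale, observed range) is kept so fitted
#' curves and threshold crossings can be reported in original units.
#'
#' @param values Numeric vector of covariate values (one per grid cell), all
#'   finite.
#' @param degree Polynomial degree, 0, 1 or 2.
#' @param standardize Centre/scale the covariate first (default `TRUE`).
#'   Standardizing a zero-variance covariate is an error.
#' @param covariate_name Name carried through to fits and reports.
#' @return An object of class `design_matrix`: list with the matrix `X`
#'   (`n x degree`), `degree`, `standardize`, `center`, `scale`,
#'   `covariate_name` and `x_range` (original units).
#' @export
build_design <- function(values, degree, standardize = TRUE,
                         covariate_name = "x") {
  values <- as.numeric(values)
  if (any(!is.finite(values))) {
    stop("covariate `values` must all be finite", call. = FALSE)
  }
  degree <- as.integer(degree)
  if (is.na(degree) || !degree %in% 0:2) {
    stop("`degree` must be 0, 1 or 2", call. = FALSE)
  }
  center <- 0; scale <- 1
  x <- values
  if (degree > 0 && standardize) {
    center <- mean(values)
    scale <- stats::sd(values)
    if (!is.finite(scale) || scale == 0) {
      stop("zero-variance covariate cannot be standardized", call. = FALSE)
    }
    x <- (values - center) / scale
  }
  X <- switch(degree + 1L,
              matrix(numeric(0), nrow = length(values), ncol = 0),
              cbind(x = x),
              cbind(x = x, x2 = x^2))
  structure(list(X = X, degree = degree, standardize = isTRUE(standardize),
                 center = center, scale = scale,
                 covariate_name = as.character(covariate_name),
                 x_range = if (degree > 0) range(values) else NULL),
            class = "design_matrix")
}

#' Beta log-likelihood in the mean/precision parameterization
#'
#' Total log-likelihood of responses `y ~ Beta(a_i, b_i)` with
#' `a_i = mu_i * phi` and `b_i = (1 - mu_i) * phi`, the parameterization in
#' which `mu` is the mean and `phi` the precision of the Beta distribution.
#'
#' @param y Responses strictly inside (0, 1). Boundary values must be squeezed
#'   first with [boundary_adjust()].
#' @param mu Means strictly inside (0, 1); scalar or vector of `length(y)`.
#' @param phi Positive precision scalar.
#' @return The scalar sum of log Beta densities.
#' @export
beta_loglik <- function(y, mu, phi) {
  if (any(y <= 0 | y >= 1)) {
    stop("`y` must lie strictly inside (0, 1); apply boundary_adjust() to ",
         "responses on the boundary first", call. = FALSE)
  }
  if (any(mu <= 0 | mu >= 1)) {
    stop("`mu` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi <= 0) {
    stop("`phi` must be a single positive number", call. = FALSE)
  }
  if (length(mu) == 1L) mu <- rep(mu, length(y))
  if (length(mu) != length(y)) {
    stop("`mu` must be scalar or the length of `y`", call. = FALSE)
  }
  sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

#' Squeeze boundary responses into the open unit interval
#'
#' The Beta likelihood excludes 0 and 1, but unsampled grid cells have
#' ignorance exactly 1. The standard squeeze
#' `y' = (y (n - 1) + 0.5) / n` maps `[0, 1]` into the open interval while
#' preserving order, shrinking less as the number of cells `n` grows; 0.5 is
#' its fixed point.
#'
#' @param y Numeric responses in `[0, 1]`.
#' @param n Number of cells behind the scores (default `length(y)`); must be
#'   at least 2.
#' @return Responses strictly inside (0, 1).
#' @export
boundary_adjust <- function(y, n = length(y)) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("`n` must be at least 2", call. = FALSE)
  }
  if (any(y < 0 | y > 1, na.rm = TRUE)) {
    stop("`y` must lie in [0, 1]", call. = FALSE)
  }
  (y * (n - 1) + 0.5) / n
}

# log-posterior closure over theta = (alpha, beta..., log phi);
# includes the Jacobian of the log-phi transform. The Beta log-density is
# expanded through lgamma with log(y) terms precomputed once per fit, which
# matters because the sampler evaluates this thousands of times.
make_log_post <- function(X, y, spec) {
  k <- ncol(X)
  sd_coef <- spec$prior_coef_sd
  a0 <- spec$prior_phi_shape
  r0 <- spec$prior_phi_rate
  n <- length(y)
  ly <- log(y)
  l1y <- log1p(-y)
  function(theta) {
    lphi <- theta[k + 2L]
    # keep phi inside a numerically safe window; far outside it the
    # lgamma differences below lose all precision
    if (!is.finite(lphi) || lphi > 27 || lphi < -18) return(-Inf)
    phi <- exp(lphi)
    eta <- if (k > 0) {
      theta[1L] + drop(X %*% theta[2:(k + 1L)])
    } else {
      rep(theta[1L], n)
    }
    mu <- stats::plogis(eta)
    a <- mu * phi
    b <- (1 - mu) * phi
    ll <- n * lgamma(phi) - sum(lgamma(a)) - sum(lgamma(b)) +
      sum((a - 1) * ly) + sum((b - 1) * l1y)
    if (!is.finite(ll)) return(-Inf)
    ll +
      sum(stats::dnorm(theta[1:(k + 1L)], 0, sd_coef, log = TRUE)) +
      stats::dgamma(phi, shape = a0, rate = r0, log = TRUE) +
      theta[k + 2L]
  }
}

# one adaptive random-walk Metropolis chain; returns post-burn-in draws.
# Adaptation (Robbins-Monro step scale towards 30% acceptance; proposal
# covariance re-estimated midway through burn-in) stops at the end of burn-in.
run_chain <- function(log_post, theta0, iterations, burn_in) {
  p <- length(theta0)
  s <- 2.38 / sqrt(p)
  R <- diag(0.1, p)  # Cholesky factor of the proposal covariance
  theta <- theta0
  lp <- log_post(theta)
  total <- iterations + burn_in
  draws <- matrix(NA_real_, total, p)
  lps <- numeric(total)
  n_acc <- 0L
  half <- floor(burn_in / 2)
  for (i in seq_len(total)) {
    prop <- theta + s * drop(stats::rnorm(p) %*% R)
    lpp <- log_post(prop)
    acc <- is.finite(lpp) && log(stats::runif(1)) < lpp - lp
    if (acc) {
      theta <- prop
      lp <- lpp
      n_acc <- n_acc + 1L
    }
    draws[i, ] <- theta
    lps[i] <- lp
    if (i <= burn_in) {
      s <- s * exp((as.numeric(acc) - 0.3) / sqrt(max(i, 20)))
      if (i == half && half >= 100) {
        C <- stats::cov(draws[max(1L, half %/% 2):half, , drop = FALSE])
        C <- C + diag(pmax(1e-8, 1e-6 * diag(C)), p)
        Rtry <- try(chol(C), silent = TRUE)
        if (!inherits(Rtry, "try-error")) {
          R <- Rtry
          s <- 2.38 / sqrt(p)
        }
      }
    }
  }
  keep <- (burn_in + 1L):total
  list(draws = draws[keep, , drop = FALSE], lps = lps[keep],
       accept = n_acc / total)
}

# split-chain potential scale reduction factor
split_rhat <- function(x, chain) {
  groups <- split(x, chain)
  subs <- list()
  for (g in groups) {
    h <- length(g) %/% 2
    if (h < 2) return(NA_real_)
    subs <- c(subs, list(g[1:h]), list(g[(h + 1):(2 * h)]))
  }
  L <- min(lengths(subs))
  subs <- lapply(subs, function(v) v[1:L])
  means <- vapply(subs, mean, 0)
  vars <- vapply(subs, stats::var, 0)
  W <- mean(vars)
  B <- L * stats::var(means)
  if (!is.finite(W) || W <= 0) return(1)
  sqrt(((L - 1) / L * W + B / L) / W)
}

#' Sample the posterior of a Beta regression by adaptive Metropolis
#'
#' Fits `I_i ~ Beta(mu_i phi, (1 - mu_i) phi)` with
#' `logit(mu_i) = alpha + X_i beta` by a joint random-walk Metropolis sampler
#' on `(alpha, beta, log phi)`. The proposal is adapted (step size and
#' covariance) during burn-in only, so the retained draws come from a fixed
#' kernel. Multiple chains start from jittered initial values; convergence is
#' monitored with the split-chain potential scale reduction factor (`Rhat`),
#' flagged when any exceeds 1.1. Runs are fully reproducible from `seed`.
#'
#' @param y Responses strictly inside (0, 1) (see [boundary_adjust()]).
#' @param design A [build_design()] object.
#' @param spec A [model_spec()]; defaults to vague priors matching the design.
#' @param iterations Retained iterations per chain after burn-in (default
#'   5000).
#' @param burn_in Burn-in iterations per chain (default 2000).
#' @param chains Number of chains (default 2).
#' @param seed Integer seed.
#' @return An object of class `posterior_fit`: posterior `samples` (with
#'   `chain` ids and per-draw log posterior), a `summary` table (mean, sd,
#'   2.5/97.5 percentiles, Rhat per parameter, `phi` on its natural scale),
#'   the plug-in `deviance` at posterior means, the maximum-posterior draw
#'   `map`, acceptance rates and the inputs needed to evaluate curves.
#' @export
sample_posterior <- function(y, design, spec = NULL,
                             iterations = 5000, burn_in = 2000, chains = 2,
                             seed = 1L) {
  if (!inherits(design, "design_matrix")) {
    stop("`design` must come from build_design()", call. = FALSE)
  }
  y <- as.numeric(y)
  if (any(!is.finite(y)) || any(y <= 0 | y >= 1)) {
    stop("`y` must lie strictly inside (0, 1); apply boundary_adjust() ",
         "first", call. = FALSE)
  }
  X <- design$X
  if (nrow(X) != length(y)) {
    stop("design matrix rows must match length(y)", call. = FALSE)
  }
  if (is.null(spec)) {
    spec <- model_spec(covariate_name = design$covariate_name,
                       degree = design$degree,
                       standardize = design$standardize)
  }
  if (spec$degree != design$degree) {
    stop("`spec$degree` does not match the design matrix", call. = FALSE)
  }
  if (iterations < 1 || burn_in < 0 || chains < 1) {
    stop("invalid MCMC settings", call. = FALSE)
  }
  k <- ncol(X)
  p <- k + 2L
  log_post <- make_log_post(X, y, spec)

  set.seed(as.integer(seed))
  # moment-based start: intercept at the logit mean, precision from the
  # Beta variance identity var = mu (1 - mu) / (1 + phi)
  mu0 <- min(max(mean(y), 1e-3), 1 - 1e-3)
  phi0 <- max(mu0 * (1 - mu0) / max(stats::var(y), 1e-8) - 1, 0.5)
  theta0 <- c(stats::qlogis(mu0), rep(0, k), log(phi0))

  draws <- vector("list", chains)
  lps <- vector("list", chains)
  accepts <- numeric(chains)
  for (ch in seq_len(chains)) {
    start <- theta0
    if (ch > 1) start <- start + stats::rnorm(p, 0, 0.2)
    tries <- 0L
    while (!is.finite(log_post(start))) {
      tries <- tries + 1L
      if (tries > 50L) {
        stop("could not find a finite starting point for the sampler",
             call. = FALSE)
      }
      start <- c(stats::rnorm(k + 1L, 0, 1), log(stats::rgamma(
        1, shape = spec$prior_phi_shape, rate = spec$prior_phi_rate) + 0.1))
    }
    res <- run_chain(log_post, start, iterations, burn_in)
    draws[[ch]] <- res$draws
    lps[[ch]] <- res$lps
    accepts[ch] <- res$accept
  }
  samples <- do.call(rbind, draws)
  chain_id <- rep(seq_len(chains), each = iterations)
  lp_all <- unlist(lps)

  par_names <- c("alpha", if (k >= 1) paste0("beta", seq_len(k)), "phi")
  nat <- samples
  nat[, p] <- exp(nat[, p])  # phi on natural scale
  colnames(nat) <- par_names

  summ <- data.frame(
    parameter = par_names,
    mean = colMeans(nat),
    sd = apply(nat, 2, stats::sd),
    q2.5 = apply(nat, 2, stats::quantile, probs = 0.025, names = FALSE),
    q97.5 = apply(nat, 2, stats::quantile, probs = 0.975, names = FALSE),
    rhat = vapply(seq_len(p), function(j) split_rhat(nat[, j], chain_id), 0),
    row.names = NULL
  )
  post_mean <- summ$mean
  names(post_mean) <- par_names
  map <- nat[which.max(lp_all), ]
  names(map) <- par_names

  fit <- structure(
    list(spec = spec, design = design, y = y,
         samples = nat, chain = chain_id, lp = lp_all,
         summary = summ, posterior_mean = post_mean, map = map,
         n_iterations = iterations, burn_in = burn_in, chains = chains,
         seed = as.integer(seed), accept_rate = accepts,
         converged = all(summ$rhat <= 1.1, na.rm = TRUE)),
    class = "posterior_fit"
  )
  fit$deviance <- plugin_deviance(fit)
  fit
}

# linear predictor -> mu at given coefficients, on the standardized scale
fit_mu <- function(fit, coefs = fit$posterior_mean) {
  k <- fit$design$degree
  eta <- coefs[["alpha"]]
  if (k > 0) {
    eta <- eta + drop(fit$design$X %*% coefs[paste0("beta", seq_len(k))])
  }
  stats::plogis(eta)
}

plugin_deviance <- function(fit) {
  mu <- fit_mu(fit)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -2 * beta_loglik(fit$y, mu, fit$posterior_mean[["phi"]])
}

#' Deviance of a fitted Beta regression
#'
#' By default the plug-in deviance `-2 log L` evaluated at the posterior means
#' of `(alpha, beta, phi)`, the quantity differenced in nested model
#' comparison against chi-squared quantiles. `type = "mean"` instead returns
#' the posterior mean of the per-draw deviance.
#'
#' @param object A `posterior_fit`.
#' @param type `"plugin"` (default) or `"mean"`.
#' @param ... Unused.
#' @return A single deviance value.
#' @export
deviance.posterior_fit <- function(object, type = c("plugin", "mean"), ...) {
  type <- match.arg(type)
  if (type == "plugin") return(object$deviance)
  k <- object$design$degree
  n_draws <- nrow(object$samples)
  dev <- numeric(n_draws)
  idx <- split(seq_len(n_draws), ceiling(seq_len(n_draws) / 500))
  for (ii in idx) {
    eta <- matrix(object$samples[ii, "alpha"],
                  nrow = length(object$y), ncol = length(ii), byrow = TRUE)
    if (k > 0) {
      eta <- eta + object$design$X %*%
        t(object$samples[ii, paste0("beta", seq_len(k)), drop = FALSE])
    }
    mu <- stats::plogis(eta)
    phi <- object$samples[ii, "phi"]
    a <- sweep(mu, 2, phi, `*`)
    b <- sweep(1 - mu, 2, phi, `*`)
    dev[ii] <- -2 * colSums(stats::dbeta(object$y, a, b, log = TRUE))
  }
  mean(dev)
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf(
    "Beta regression fit: %s, degree %d, %d cells\n",
    if (x$spec$degree > 0) x$spec$covariate_name else "(null model)",
    x$spec$degree, length(x$y)))
  cat(sprintf("  %d chains x %d iterations (burn-in %d), accept %.2f%s\n",
              x$chains, x$n_iterations, x$burn_in, mean(x$accept_rate),
              if (x$converged) "" else "  [NOT CONVERGED: Rhat > 1.1]"))
  cat(sprintf("  plug-in deviance: %.3f\n", x$deviance))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Compare nested Beta regression fits by deviance difference
#'
#' The difference in (plug-in) deviance between a reduced and a full model is
#' referred to the chi-squared scale: with `threshold = 3.84` (the 95th
#' percentile of chi-squared with 1 df) per added parameter, the full model is
#' declared an improvement when
#' `delta_deviance >= threshold * params_added`.
#'
#' @param reduced,full `posterior_fit` objects on identical responses, same
#'   covariate, with `full` of strictly higher polynomial degree.
#' @param threshold Deviance improvement required per added parameter
#'   (default 3.84).
#' @return An object of class `model_comparison` with `delta_deviance`,
#'   `params_added`, `improves`, and the two deviances.
#' @export
compare_nested <- function(reduced, full, threshold = 3.84) {
  if (!inherits(reduced, "posterior_fit") || !inherits(full, "posterior_fit")) {
    stop("`reduced` and `full` must be posterior_fit objects", call. = FALSE)
  }
  if (full$spec$degree <= reduced$spec$degree) {
    stop("`full` must have higher polynomial degree than `reduced`",
         call. = FALSE)
  }
  if (reduced$spec$degree > 0 && full$spec$degree > 0 &&
      reduced$spec$covariate_name != full$spec$covariate_name) {
    stop("nested models must share the covariate", call. = FALSE)
  }
  if (length(reduced$y) != length(full$y) ||
      !isTRUE(all.equal(reduced$y, full$y))) {
    stop("nested models must be fitted to identical responses", call. = FALSE)
  }
  params_added <- full$spec$degree - reduced$spec$degree
  delta <- reduced$deviance - full$deviance
  structure(
    list(reduced = reduced$spec, full = full$spec,
         deviance_reduced = reduced$deviance, deviance_full = full$deviance,
         delta_deviance = delta, params_added = params_added,
         threshold = threshold,
         improves = delta >= threshold * params_added),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "delta deviance %.3f (%d parameter%s added, needs >= %.2f): %s\n",
    x$delta_deviance, x$params_added, if (x$params_added > 1) "s" else "",
    x$threshold * x$params_added,
    if (x$improves) "improves" else "does not improve"))
  invisible(x)
}

#' Percentage of deviance explained relative to the null model
#'
#' `R^2 = 100 (D_null - D_model) / D_null`, the percent reduction in deviance
#' achieved by the covariate model over the intercept-only fit on the same
#' responses. Negative raw values are clamped to 0 with a warning. Because the
#' Beta likelihood is a continuous density, deviances can be negative for
#' sharply concentrated responses, in which case this statistic is not a
#' proportion; it is most interpretable when `D_null > 0`.
#'
#' @param fit A `posterior_fit` for the covariate model.
#' @param null_fit The intercept-only `posterior_fit` on identical responses.
#' @return R-squared in percent.
#' @export
r_squared <- function(fit, null_fit) {
  if (null_fit$spec$degree != 0) {
    stop("`null_fit` must be the intercept-only model (degree 0)",
         call. = FALSE)
  }
  if (length(fit$y) != length(null_fit$y) ||
      !isTRUE(all.equal(fit$y, null_fit$y))) {
    stop("`fit` and `null_fit` must share the responses", call. = FALSE)
  }
  d_null <- null_fit$deviance
  if (d_null == 0) {
    stop("null deviance is exactly 0; deviance R^2 undefined", call. = FALSE)
  }
  raw <- 100 * (d_null - fit$deviance) / d_null
  if (raw < 0) {
    warning("negative deviance R^2 clamped to 0", call. = FALSE)
    raw <- 0
  }
  raw
}

#' Stepwise-forward selection among null, linear and quadratic fits
#'
#' Follows the nested testing order used for each geographic variable: the
#' linear model is accepted only if it improves on the null by at least the
#' chi-squared criterion; the quadratic is then accepted only if it improves
#' on the linear. A quadratic model is never selected when the linear term was
#' rejected.
#'
#' @param null_fit,linear_fit,quadratic_fit `posterior_fit` objects on
#'   identical responses and covariate (degrees 0, 1, 2).
#' @param threshold Deviance improvement required per added parameter.
#' @return An object of class `model_selection`: the `selected` fit, its
#'   `degree`, both `comparisons`, and the deviance `r_squared` (%) of the
#'   selected model versus the null (0 when the null is retained).
#' @export
select_model <- function(null_fit, linear_fit, quadratic_fit,
                         threshold = 3.84) {
  stopifnot(null_fit$spec$degree == 0, linear_fit$spec$degree == 1,
            quadratic_fit$spec$degree == 2)
  lin_vs_null <- compare_nested(null_fit, linear_fit, threshold)
  quad_vs_lin <- compare_nested(linear_fit, quadratic_fit, threshold)
  if (!lin_vs_null$improves) {
    selected <- null_fit
  } else if (quad_vs_lin$improves) {
    selected <- quadratic_fit
  } else {
    selected <- linear_fit
  }
  r2 <- if (selected$spec$degree == 0) 0 else r_squared(selected, null_fit)
  structure(
    list(selected = selected, degree = selected$spec$degree,
         comparisons = list(linear_vs_null = lin_vs_null,
                            quadratic_vs_linear = quad_vs_lin),
         r_squared = r2),
    class = "model_selection"
  )
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("selected degree %d model (deviance R^2 = %.2f%%)\n",
              x$degree, x$r_squared))
  print(x$comparisons$linear_vs_null)
  print(x$comparisons$quadratic_vs_linear)
  invisible(x)
}

#' Fitted ignorance curve over a covariate grid
#'
#' Evaluates the posterior-mean curve
#' `mu(x) = inv_logit(alpha + beta1 x* + beta2 x*^2)` at covariate values `x`
#' given in original units (`x*` is the internally standardized coordinate).
#' Values outside the covariate range observed at fit time are flagged, not
#' refused: the curve extrapolates smoothly but was not constrained there.
#'
#' @param fit A `posterior_fit`.
#' @param x_grid Numeric vector of covariate values (original units).
#' @return A data frame with columns `x`, `mu` and logical `in_range`.
#' @export
fitted_curve <- function(fit, x_grid) {
  x_grid <- as.numeric(x_grid)
  k <- fit$design$degree
  cm <- fit$posterior_mean
  xs <- (x_grid - fit$design$center) / fit$design$scale
  eta <- rep(cm[["alpha"]], length(x_grid))
  if (k >= 1) eta <- eta + cm[["beta1"]] * xs
  if (k >= 2) eta <- eta + cm[["beta2"]] * xs^2
  in_range <- if (is.null(fit$design$x_range)) {
    rep(TRUE, length(x_grid))
  } else {
    x_grid >= fit$design$x_range[1] & x_grid <= fit$design$x_range[2]
  }
  data.frame(x = x_grid, mu = stats::plogis(eta), in_range = in_range)
}
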
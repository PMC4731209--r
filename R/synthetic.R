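# moving-average smoothing used to give synthetic fields spatial structure;
# window [i-k, i+k] clipped at the edges (partial windows renormalized)
running_mean <- function(x, k) {
  n <- length(x)
  S <- c(0, cumsum(x))
  hi <- pmin(seq_len(n) + k, n)
  lo <- pmax(seq_len(n) - k, 1)
  (S[hi + 1] - S[lo]) / (hi - lo + 1)
}

box_smooth <- function(m, k, passes = 2) {
  if (k < 1) return(m)
  for (p in seq_len(passes)) {
    m <- apply(m, 2, running_mean, k = k)
    m <- t(apply(m, 1, running_mean, k = k))
  }
  m
}

# standardize a matrix/vector to mean 0, sd 1
zscale <- function(m) {
  s <- stats::sd(as.vector(m))
  if (!is.finite(s) || s == 0) return(m * 0)
  (m - mean(m)) / s
}

#' Define a synthetic landscape-and-recording scenario
#'
#' Bundles the generative parameters for a synthetic study region: a
#' rectangular analysis grid of 10 km cells, six covariate layers built on a
#' finer subgrid (smoothed random fields for elevation and population,
#' randomly placed road/path segments whose density can track population), and
#' a recording-effort model in which the expected number of observation
#' records per cell increases with accessibility:
#' `log lambda_i = gamma0 + sum_k gamma_k z_k,i` over standardized covariates,
#' with Poisson (or negative-binomial) count noise. Defaults describe a
#' moderately recorded taxon (about 5 records per cell) whose recorders favour
#' road access and populated areas and avoid steep, high ground.
#'
#' @param grid Analysis [grid_spec()] (default 50 x 50 cells of 10 km).
#' @param seed Integer seed; fully determines all generated outputs.
#' @param fine_factor Fine subcells per analysis cell and axis (default 10,
#'   i.e. 1 km subcells).
#' @param smooth_cells Half-width (fine cells) of the moving-average window
#'   that gives fields their spatial range.
#' @param elevation_max Maximum elevation (m) of the rescaled field.
#' @param population_log_mean,population_log_sd Mean and SD of log population
#'   density (people/km2); the default yields a heavily right-skewed layer
#'   spanning well over four orders of magnitude.
#' @param n_roads,n_paths Numbers of random line segments per class.
#' @param segment_length Mean segment length (m, exponential).
#' @param road_pop_weight Exponent `w` tying segment placement intensity to
#'   `population^w` (0 = uniform placement).
#' @param effort List with `gamma0` (intercept of log intensity) and named
#'   vector `gamma` of effort coefficients per covariate layer.
#' @param noise `"poisson"` or `"negbin"` count noise.
#' @param kappa Negative-binomial dispersion (size) when `noise = "negbin"`.
#' @param taxon Label given to the simulated records.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(
    grid = grid_spec(0, 0, 10000, 50, 50, "synthetic metric CRS"),
    seed = 1L,
    fine_factor = 10,
    smooth_cells = 15,
    elevation_max = 1000,
    population_log_mean = 2,
    population_log_sd = 2,
    n_roads = 4000,
    n_paths = 4000,
    segment_length = 20000,
    road_pop_weight = 0.5,
    effort = list(gamma0 = log(5),
                  gamma = c(elevation = -0.5, slope = -0.3,
                            road_density = 1, path_density = 0.3,
                            population_density = 0,
                            log_population_density = 0.8)),
    noise = c("poisson", "negbin"),
    kappa = 5,
    taxon = "synthetic_taxon") {
  assert_grid(grid)
  noise <- match.arg(noise)
  fine_factor <- as.integer(fine_factor)
  if (fine_factor < 1L) stop("`fine_factor` must be >= 1", call. = FALSE)
  if (kappa <= 0) stop("`kappa` must be positive", call. = FALSE)
  structure(
    list(grid = grid, seed = as.integer(seed), fine_factor = fine_factor,
         smooth_cells = smooth_cells, elevation_max = elevation_max,
         population_log_mean = population_log_mean,
         population_log_sd = population_log_sd,
         n_roads = n_roads, n_paths = n_paths,
         segment_length = segment_length,
         road_pop_weight = road_pop_weight,
         effort = effort, noise = noise, kappa = kappa,
         taxon = as.character(taxon)),
    class = "synthetic_scenario"
  )
}

#' Generate the six synthetic covariate layers
#'
#' Builds, on the scenario's fine subgrid and aggregated to the analysis grid:
#' elevation (smoothed nonnegative field with a broad regional trend, m);
#' slope derived from that same elevation via [slope_percent()] so the two are
#' internally consistent (%); population density as an exponentiated smoothed
#' field, heavily right-skewed (people/km2), plus its log via [log_density()];
#' and road/path densities from randomly placed segments (via
#' [line_density()]) whose placement intensity tracks `population^w`.
#'
#' @param scenario A [synthetic_scenario()].
#' @return Named list of six [covariate_layer()] objects (`elevation`,
#'   `slope`, `road_density`, `path_density`, `population_density`,
#'   `log_population_density`), with the generated [line_feature_set()]s and
#'   the fine elevation matrix attached as attributes `lines` and
#'   `fine_elevation`.
#' @export
generate_covariates <- function(scenario) {
  if (!inherits(scenario, "synthetic_scenario")) {
    stop("`scenario` must come from synthetic_scenario()", call. = FALSE)
  }
  g <- scenario$grid
  f <- scenario$fine_factor
  set.seed(scenario$seed)
  nr <- g$n_rows * f
  nc <- g$n_cols * f
  fine_cs <- g$cell_size / f
  fine_grid <- grid_spec(g$x_min, g$y_min, fine_cs, nr, nc, g$crs_label)

  # elevation: smoothed field plus a west-east regional trend, rescaled to
  # [0, elevation_max]
  z1 <- zscale(box_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                          scenario$smooth_cells))
  trend <- matrix(seq(0, 1.5, length.out = nc), nr, nc, byrow = TRUE)
  u <- z1 + trend
  elev_fine <- scenario$elevation_max * (u - min(u)) / max(u - min(u))
  slope_fine <- slope_percent(elev_fine, fine_cs)

  # population: lognormal field spanning several orders of magnitude
  z2 <- zscale(box_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                          scenario$smooth_cells))
  pop_fine <- exp(scenario$population_log_mean +
                    scenario$population_log_sd * z2)

  # roads/paths: segment start cells drawn with lognormal weights tied to
  # log population (mild concentration; w = 0 gives uniform placement)
  w <- scenario$road_pop_weight
  prob <- exp(w * zscale(log(as.vector(pop_fine))))
  prob <- prob / sum(prob)
  make_lines <- function(n_seg, class) {
    cells <- sample.int(nr * nc, n_seg, replace = TRUE, prob = prob)
    row <- (cells - 1) %% nr + 1
    col <- (cells - 1) %/% nr + 1
    x0 <- g$x_min + (col - 1 + stats::runif(n_seg)) * fine_cs
    y0 <- g$y_min + (row - 1 + stats::runif(n_seg)) * fine_cs
    ang <- stats::runif(n_seg, 0, 2 * pi)
    len <- stats::rexp(n_seg, rate = 1 / scenario$segment_length)
    geoms <- lapply(seq_len(n_seg), function(i) {
      cbind(c(x0[i], x0[i] + len[i] * cos(ang[i])),
            c(y0[i], y0[i] + len[i] * sin(ang[i])))
    })
    line_feature_set(geoms, class)
  }
  roads <- make_lines(scenario$n_roads, "road")
  paths <- make_lines(scenario$n_paths, "path")

  elevation <- covariate_layer(g, aggregate_mean(elev_fine, f), "elevation",
                               "m")
  slope <- covariate_layer(g, aggregate_mean(slope_fine, f), "slope", "%")
  population <- covariate_layer(g, aggregate_mean(pop_fine, f),
                                "population_density", "people/km2")
  layers <- list(
    elevation = elevation,
    slope = slope,
    road_density = line_density(roads, g),
    path_density = line_density(paths, g),
    population_density = population,
    log_population_density = log_density(population)
  )
  attr(layers, "lines") <- list(road = roads, path = paths)
  attr(layers, "fine_elevation") <- elev_fine
  attr(layers, "fine_grid") <- fine_grid
  layers
}

#' Simulate per-cell observation counts from an effort model
#'
#' Draws counts `N_i ~ Poisson(lambda_i)` (or negative-binomial with
#' dispersion `kappa`) with
#' `log lambda_i = gamma0 + sum_k gamma_k z_k,i`, where `z_k` are the
#' standardized covariate layers. Positive coefficients on accessibility
#' layers make well-connected cells accumulate records, so their downstream
#' half-ignorance scores fall — the premise the real analysis tests.
#'
#' @param layers Named list of [covariate_layer()]s on one grid.
#' @param effort List with `gamma0` and a named `gamma` vector whose names
#'   must be a subset of `names(layers)`.
#' @param noise `"poisson"` or `"negbin"`.
#' @param kappa Negative-binomial size parameter.
#' @param seed Integer seed.
#' @param taxon Taxon label for the resulting counts.
#' @return A `count_raster`.
#' @export
simulate_counts <- function(layers, effort, noise = c("poisson", "negbin"),
                            kappa = 5, seed = 1L, taxon = "synthetic_taxon") {
  noise <- match.arg(noise)
  grid <- layers[[1]]$grid
  for (l in layers) {
    if (!identical(l$grid[c("n_rows", "n_cols")],
                   grid[c("n_rows", "n_cols")])) {
      stop("all layers must share one grid", call. = FALSE)
    }
  }
  gamma <- effort$gamma
  if (length(gamma) > 0 && is.null(names(gamma))) {
    stop("`effort$gamma` must be named after covariate layers", call. = FALSE)
  }
  missing_layers <- setdiff(names(gamma), names(layers))
  if (length(missing_layers) > 0) {
    stop("effort coefficients reference unknown layers: ",
         paste(missing_layers, collapse = ", "), call. = FALSE)
  }
  log_lambda <- matrix(effort$gamma0, grid$n_rows, grid$n_cols)
  for (nm in names(gamma)) {
    if (gamma[[nm]] != 0) {
      log_lambda <- log_lambda + gamma[[nm]] * zscale(layers[[nm]]$values)
    }
  }
  lambda <- exp(log_lambda)
  if (any(!is.finite(lambda)) || any(lambda > 1e9)) {
    stop("non-finite or overflowing intensity lambda; check effort ",
         "coefficients", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- length(lambda)
  counts <- if (noise == "poisson") {
    stats::rpois(n, as.vector(lambda))
  } else {
    stats::rnbinom(n, size = kappa, mu = as.vector(lambda))
  }
  structure(
    list(grid = grid, counts = matrix(as.integer(counts), grid$n_rows),
         taxon = taxon),
    class = "count_raster", n_out_of_bounds = 0L
  )
}

#' Simulate Beta-distributed responses from the regression model
#'
#' Generative counterpart of the fitted likelihood:
#' `y_i ~ Beta(mu_i phi, (1 - mu_i) phi)` with
#' `logit(mu_i) = alpha + X_i beta`. Used for exact parameter-recovery tests,
#' where the fitted model *is* the true data-generating process (unlike
#' counts pushed through the half-ignorance transform).
#'
#' @param X A [build_design()] object or plain numeric matrix (0-2 columns).
#' @param alpha Intercept.
#' @param beta Coefficient vector, `length(beta) = ncol(X)`.
#' @param phi Positive precision.
#' @param seed Integer seed.
#' @return Numeric responses strictly inside (0, 1) (draws landing on the
#'   boundary by floating-point underflow are nudged to the nearest
#'   representable interior value).
#' @export
simulate_beta_response <- function(X, alpha, beta = numeric(0), phi,
                                   seed = 1L) {
  if (inherits(X, "design_matrix")) X <- X$X
  X <- as.matrix(X)
  if (length(beta) != ncol(X)) {
    stop("`beta` must have one entry per design column", call. = FALSE)
  }
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0) {
    stop("`phi` must be a single positive number", call. = FALSE)
  }
  eta <- rep(alpha, nrow(X))
  if (ncol(X) > 0) eta <- eta + drop(X %*% beta)
  mu <- stats::plogis(eta)
  set.seed(as.integer(seed))
  y <- stats::rbeta(nrow(X), mu * phi, (1 - mu) * phi)
  eps <- .Machine$double.eps
  pmin(pmax(y, eps), 1 - eps)
}

#' Generate a full synthetic dataset (covariates + counts)
#'
#' Convenience wrapper running [generate_covariates()] and
#' [simulate_counts()] for one scenario; the count seed is derived from the
#' scenario seed so the whole dataset is reproducible from one integer.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with `layers` (six covariate layers) and `counts`
#'   (a `count_raster`).
#' @export
simulate_scenario <- function(scenario) {
  layers <- generate_covariates(scenario)
  counts <- simulate_counts(layers, scenario$effort, noise = scenario$noise,
                            kappa = scenario$kappa,
                            seed = (scenario$seed + 1L) %% .Machine$integer.max,
                            taxon = scenario$taxon)
  list(layers = layers, counts = counts)
}
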
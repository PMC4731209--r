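#' Read observation records from a delimited text file
#'
#' Reads presence-only observation records from a CSV with header columns
#' `taxon`, `x`, `y`, `year`. Rows with non-numeric coordinates or year are
#' routed to a rejects table (attribute `rejects`), never fatal; rows outside
#' the year window are excluded and counted. The default window 2000-2014
#' matches a fixed multi-year recording period.
#'
#' @param path Path to the CSV file.
#' @param year_window Inclusive `c(from, to)` year filter; `NULL` disables
#'   filtering.
#' @param quiet Suppress the summary message.
#' @return A data frame of accepted records (`taxon`, `x`, `y`, `year`) with
#'   attributes `rejects` (malformed rows as read), `n_year_filtered` and
#'   `n_total`.
#' @export
read_observations <- function(path, year_window = c(2000, 2014),
                              quiet = FALSE) {
  if (!file.exists(path)) {
    stop("observation file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("taxon", "x", "y", "year")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n_total <- nrow(raw)
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  year <- suppressWarnings(as.integer(raw$year))
  ok <- is.finite(x) & is.finite(y) & !is.na(year)
  rejects <- raw[!ok, , drop = FALSE]
  rec <- data.frame(taxon = raw$taxon[ok], x = x[ok], y = y[ok],
                    year = year[ok], stringsAsFactors = FALSE)
  n_year_filtered <- 0L
  if (!is.null(year_window)) {
    keep <- rec$year >= year_window[1] & rec$year <= year_window[2]
    n_year_filtered <- sum(!keep)
    rec <- rec[keep, , drop = FALSE]
  }
  rownames(rec) <- NULL
  if (!quiet) {
    message(sprintf(
      "read %d rows: %d accepted, %d outside year window, %d malformed",
      n_total, nrow(rec), n_year_filtered, nrow(rejects)))
  }
  attr(rec, "rejects") <- rejects
  attr(rec, "n_year_filtered") <- n_year_filtered
  attr(rec, "n_total") <- n_total
  rec
}

# pull (grid, values matrix) out of any raster-like object
raster_parts <- function(x) {
  if (inherits(x, "count_raster")) {
    list(grid = x$grid, values = x$counts)
  } else if (inherits(x, "ignorance_raster")) {
    list(grid = x$grid, values = x$scores)
  } else if (inherits(x, "covariate_layer")) {
    list(grid = x$grid, values = x$values)
  } else if (is.list(x) && all(c("grid", "values") %in% names(x))) {
    list(grid = x$grid, values = as.matrix(x$values))
  } else {
    stop("cannot interpret object as a raster", call. = FALSE)
  }
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Plain-text raster format: a 6-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of values from
#' north to south. Values are written with 17 significant digits so reals
#' round-trip exactly through [read_esri_ascii()].
#'
#' @param x A `count_raster`, `ignorance_raster`, [covariate_layer()] or a
#'   `list(grid, values)`.
#' @param path Output file path.
#' @param nodata No-data sentinel written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(x, path, nodata = -9999) {
  p <- raster_parts(x)
  g <- p$grid
  v <- p$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", g$n_cols),
    paste("nrows", g$n_rows),
    paste("xllcorner", format(g$x_min, digits = 17)),
    paste("yllcorner", format(g$y_min, digits = 17)),
    paste("cellsize", format(g$cell_size, digits = 17)),
    paste("NODATA_value", format(nodata, digits = 17))
  ), con)
  # internal row 1 is the southern edge; files are written north first
  for (r in rev(seq_len(g$n_rows))) {
    writeLines(paste(formatC(v[r, ], digits = 17, format = "g"),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path File path.
#' @param crs_label Optional CRS label to attach to the grid.
#' @return A list with `grid` (a [grid_spec()]) and `values` (matrix, row 1 =
#'   south, `NA` for no-data cells).
#' @export
read_esri_ascii <- function(path, crs_label = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[key]])) {
      stop("malformed ESRI ASCII header: missing ", key, call. = FALSE)
    }
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    stop("expected ", nr * nc, " values, found ", length(vals), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]  # back to row 1 = south
  if (!is.null(hdr$nodata_value)) {
    m[m == hdr$nodata_value] <- NA
  }
  list(grid = grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                        nr, nc, crs_label),
       values = m)
}

#' Write covariate layers to a tidy CSV
#'
#' Long format with one row per cell and layer: `cell_id` (column-major index,
#' row 1 = south), `row`, `col`, `name`, `value`.
#'
#' @param layers A [covariate_layer()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_layer_csv <- function(layers, path) {
  if (inherits(layers, "covariate_layer")) layers <- list(layers)
  rows <- lapply(layers, function(l) {
    g <- l$grid
    data.frame(cell_id = seq_len(g$n_rows * g$n_cols),
               row = rep(seq_len(g$n_rows), g$n_cols),
               col = rep(seq_len(g$n_cols), each = g$n_rows),
               name = l$name,
               value = as.vector(l$values))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# deterministic sub-seed per fit, independent of which other fits run
fit_seed <- function(seed, o_half, cov_index, degree) {
  (as.integer(seed) %% 100000L) * 10000L +
    (as.integer(round(o_half * 100)) %% 9973L) + 13L * cov_index + degree
}

#' Run the ignorance-score analysis pipeline end to end
#'
#' Orchestrates the full workflow: grid the observation records (or simulate a
#' synthetic scenario), compute half-ignorance rasters over the `O_0.5` sweep,
#' regress each ignorance raster on each covariate layer (null / linear /
#' quadratic Beta regressions), select the model per covariate by the
#' chi-squared deviance criterion, compute deviance R-squared, and extract
#' covariate thresholds where the selected curve crosses `target`. All
#' randomness derives from `seed`; rerunning with the same inputs reproduces
#' every output, and adding an `O_0.5` value leaves existing fits unchanged.
#'
#' @param records Data frame of observation records (or `NULL` when
#'   `scenario` is given); see [count_observations()].
#' @param layers Named list of [covariate_layer()]s (or `NULL` with
#'   `scenario`).
#' @param grid Analysis [grid_spec()]; defaults to the layers' grid.
#' @param scenario Optional [synthetic_scenario()]: generates `layers` and
#'   counts in place of `records` (its seed is replaced by `seed`).
#' @param o_half_values `O_0.5` sweep (default `c(1, 2, 5, 10, 20, 50)`).
#' @param covariates Names of layers to model (default all).
#' @param target Threshold ignorance score for crossing extraction.
#' @param boundary `"squeeze"` (default: [boundary_adjust()] all cells, so
#'   unsampled cells inform the fit) or `"drop"` (exclude cells with
#'   ignorance exactly 1 — this answers a different question).
#' @param mcmc List of sampler settings: `iterations`, `burn_in`, `chains`.
#' @param seed Master integer seed for the run.
#' @param mask Optional logical matrix marking cells to include (e.g. a land
#'   mask); `NULL` includes all cells.
#' @param out_dir If non-`NULL`, write rasters (ESRI ASCII), tidy CSV tables
#'   and a JSON manifest there.
#' @param quiet Suppress progress messages.
#' @return An object of class `ignorance_pipeline`: `counts`, `ignorance`
#'   (list per `O_0.5`), `layers`, `fits` (per `O_0.5` and covariate, each a
#'   `model_selection`), tables `summaries`, `comparisons`, `thresholds`, and
#'   a bookkeeping `log`.
#' @export
run_pipeline <- function(records = NULL, layers = NULL, grid = NULL,
                         scenario = NULL,
                         o_half_values = c(1, 2, 5, 10, 20, 50),
                         covariates = NULL, target = 0.5,
                         boundary = c("squeeze", "drop"),
                         mcmc = list(iterations = 5000, burn_in = 2000,
                                     chains = 2),
                         seed = 1L, mask = NULL, out_dir = NULL,
                         quiet = FALSE) {
  boundary <- match.arg(boundary)
  say <- function(...) if (!quiet) message(...)
  log <- list(seed = as.integer(seed), boundary = boundary, target = target)

  if (!is.null(scenario)) {
    scenario$seed <- as.integer(seed)
    say("generating synthetic scenario (seed ", seed, ")")
    sim <- simulate_scenario(scenario)
    layers <- sim$layers
    counts <- sim$counts
    grid <- counts$grid
    log$source <- "synthetic"
  } else {
    if (is.null(records) || is.null(layers)) {
      stop("provide either `scenario` or both `records` and `layers`",
           call. = FALSE)
    }
    if (is.null(grid)) grid <- layers[[1]]$grid
    counts <- count_observations(records, grid, quiet = quiet)
    log$source <- "records"
    log$n_records <- nrow(records)
    log$n_out_of_bounds <- attr(counts, "n_out_of_bounds")
  }
  if (is.null(covariates)) covariates <- names(layers)
  missing_layers <- setdiff(covariates, names(layers))
  if (length(missing_layers) > 0) {
    stop("unknown covariate layer(s): ",
         paste(missing_layers, collapse = ", "), call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, grid$n_rows, grid$n_cols)
  }
  included <- as.vector(mask)
  log$n_cells <- sum(included)
  taxon <- counts$taxon

  ign <- o_half_sweep(counts, o_half_values)
  it <- mcmc$iterations %||% 5000
  bi <- mcmc$burn_in %||% 2000
  ch <- mcmc$chains %||% 2

  fits <- list()
  summaries <- list()
  comparisons <- list()
  sel_fits <- list()
  sel_taxa <- character(0)
  sel_o <- numeric(0)
  for (oi in seq_along(o_half_values)) {
    o <- o_half_values[oi]
    scores <- as.vector(ign[[oi]]$scores)[included]
    if (boundary == "squeeze") {
      y <- boundary_adjust(scores)
      keep <- rep(TRUE, length(y))
    } else {
      keep <- scores < 1
      y <- scores[keep]
      if (length(y) < 10) {
        stop("too few sampled cells left after dropping boundary scores",
             call. = FALSE)
      }
      y[y == 1] <- NA  # unreachable; defensive
    }
    say(sprintf("O_0.5 = %g: fitting %d covariates on %d cells",
                o, length(covariates), length(y)))
    # the intercept-only fit is shared by every covariate at this O_0.5
    null_design <- build_design(numeric(length(y)) , 0, standardize = FALSE)
    null_fit <- sample_posterior(y, null_design,
                                 iterations = it, burn_in = bi, chains = ch,
                                 seed = fit_seed(seed, o, 0L, 0L))
    fits_o <- list()
    for (ci in seq_along(covariates)) {
      cov_name <- covariates[ci]
      vals <- as.vector(layers[[cov_name]]$values)[included][keep]
      d1 <- build_design(vals, 1, covariate_name = cov_name)
      d2 <- build_design(vals, 2, covariate_name = cov_name)
      f1 <- sample_posterior(y, d1, iterations = it, burn_in = bi,
                             chains = ch,
                             seed = fit_seed(seed, o, ci, 1L))
      f2 <- sample_posterior(y, d2, iterations = it, burn_in = bi,
                             chains = ch,
                             seed = fit_seed(seed, o, ci, 2L))
      sel <- select_model(null_fit, f1, f2)
      fits_o[[cov_name]] <- sel
      for (f in list(null_fit, f1, f2)) {
        s <- f$summary
        s$taxon <- taxon; s$o_half <- o
        s$covariate <- if (f$spec$degree == 0) "(null)" else cov_name
        s$degree <- f$spec$degree
        summaries[[length(summaries) + 1L]] <- s
      }
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        taxon = taxon, o_half = o, covariate = cov_name,
        deviance_null = null_fit$deviance,
        deviance_linear = f1$deviance,
        deviance_quadratic = f2$deviance,
        delta_linear = sel$comparisons$linear_vs_null$delta_deviance,
        delta_quadratic = sel$comparisons$quadratic_vs_linear$delta_deviance,
        improves_linear = sel$comparisons$linear_vs_null$improves,
        improves_quadratic = sel$comparisons$quadratic_vs_linear$improves,
        selected_degree = sel$degree,
        r_squared = sel$r_squared,
        converged = null_fit$converged && f1$converged && f2$converged)
      sel_fits[[length(sel_fits) + 1L]] <- sel$selected
      sel_taxa <- c(sel_taxa, taxon)
      sel_o <- c(sel_o, o)
    }
    fits[[paste0("O", o)]] <- fits_o
  }
  summaries <- do.call(rbind, summaries)
  comparisons <- do.call(rbind, comparisons)
  thresholds <- threshold_report(sel_fits, target = target,
                                 taxa = sel_taxa, o_half = sel_o)

  result <- structure(
    list(counts = counts, ignorance = ign, layers = layers, fits = fits,
         summaries = summaries, comparisons = comparisons,
         thresholds = thresholds, log = log),
    class = "ignorance_pipeline"
  )
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir, o_half_values, covariates, seed)
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_outputs <- function(result, out_dir, o_half_values,
                                   covariates, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  taxon <- result$counts$taxon
  files <- character(0)
  f <- file.path(out_dir, paste0("counts_", taxon, ".asc"))
  write_esri_ascii(result$counts, f)
  files <- c(files, basename(f))
  for (nm in names(result$ignorance)) {
    f <- file.path(out_dir, paste0("ignorance_", taxon, "_", nm, ".asc"))
    write_esri_ascii(result$ignorance[[nm]], f)
    files <- c(files, basename(f))
  }
  for (nm in names(result$layers)) {
    f <- file.path(out_dir, paste0("covariate_", nm, ".asc"))
    write_esri_ascii(result$layers[[nm]], f)
    files <- c(files, basename(f))
  }
  for (tbl in c("summaries", "comparisons", "thresholds")) {
    f <- file.path(out_dir, paste0(tbl, ".csv"))
    utils::write.csv(result[[tbl]], f, row.names = FALSE)
    files <- c(files, basename(f))
  }
  config_string <- paste(deparse(list(o_half = o_half_values,
                                      covariates = covariates,
                                      seed = seed)), collapse = "")
  manifest <- list(
    package = "ignorance",
    version = as.character(utils::packageVersion("ignorance")),
    seed = seed,
    taxon = taxon,
    o_half_values = o_half_values,
    covariates = covariates,
    config_checksum = sprintf("%08x", sum(utf8ToInt(config_string) *
                                            seq_along(utf8ToInt(config_string)))
                              %% 4294967291),
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.ignorance_pipeline <- function(x, ...) {
  cat(sprintf("ignorance pipeline [%s]: %d cells, O_0.5 in {%s}\n",
              x$counts$taxon, x$log$n_cells,
              paste(vapply(x$ignorance, function(i) i$o_half, 0),
                    collapse = ", ")))
  cat("model selection by covariate:\n")
  print(x$comparisons[, c("o_half", "covariate", "selected_degree",
                          "r_squared")], row.names = FALSE, digits = 3)
  invisible(x)
}
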
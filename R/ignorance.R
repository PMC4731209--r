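#' Half-ignorance score of gridded observation counts
#'
#' Transforms per-cell record counts `N_i` of a reference taxonomic group into
#' ignorance scores
#' \deqn{I_i = O_{0.5} / (N_i + O_{0.5}),}
#' where `O_0.5` is the number of observations considered enough to halve the
#' ignorance. Scores lie in `(0, 1]`: 1 means no observations at all (absolute
#' ignorance about whether absence of reports reflects true absence), and the
#' score decays towards 0 as records accumulate. A cell with `N = O_0.5`
#' scores exactly 0.5; with `O_0.5 = 1` a single record already leaves the
#' absence of further reports 50% attributable to true absence.
#'
#' @param counts A `count_raster` from [count_observations()].
#' @param o_half Positive scalar `O_0.5`, the half-ignorance threshold count.
#' @return An `ignorance_raster`: list with `grid`, a `scores` matrix in
#'   `(0, 1]`, `o_half` and `taxon`.
#' @examples
#' g <- grid_spec(0, 0, 10000, 1, 1)
#' cr <- count_observations(data.frame(x = 5000, y = 5000), g, taxon = "t")
#' half_ignorance(cr, o_half = 1)$scores  # 0.5
#' @seealso [o_half_sweep()] for a sweep over several `O_0.5` values.
#' @export
half_ignorance <- function(counts, o_half) {
  if (!inherits(counts, "count_raster")) {
    stop("`counts` must be a count_raster from count_observations()",
         call. = FALSE)
  }
  if (!is.numeric(o_half) || length(o_half) != 1L || !is.finite(o_half) ||
      o_half <= 0) {
    stop("`o_half` must be a single positive number", call. = FALSE)
  }
  scores <- o_half / (counts$counts + o_half)
  structure(
    list(grid = counts$grid, scores = scores, o_half = o_half,
         taxon = counts$taxon),
    class = "ignorance_raster"
  )
}

#' @export
print.ignorance_raster <- function(x, ...) {
  cat(sprintf(
    "ignorance_raster [%s], O_0.5 = %g: %d x %d cells, %.0f%% cells at 1.0\n",
    x$taxon, x$o_half, x$grid$n_rows, x$grid$n_cols,
    100 * mean(x$scores == 1)))
  invisible(x)
}

#' Sweep the half-ignorance threshold over several values
#'
#' Computes one ignorance raster per `O_0.5` value on a shared count raster.
#' The default sweep `{1, 2, 5, 10, 20, 50}` spans from "one record halves the
#' ignorance" to a threshold suited to intensely recorded groups, and is used
#' to test how sensitive downstream conclusions are to the choice.
#'
#' @param counts A `count_raster`.
#' @param o_half_values Vector of positive thresholds.
#' @return A named list of `ignorance_raster` objects (names `"O<value>"`).
#' @export
o_half_sweep <- function(counts, o_half_values = c(1, 2, 5, 10, 20, 50)) {
  if (length(o_half_values) == 0) {
    stop("`o_half_values` must contain at least one value", call. = FALSE)
  }
  if (!is.numeric(o_half_values) || any(!is.finite(o_half_values)) ||
      any(o_half_values <= 0)) {
    stop("all `o_half_values` must be positive numbers", call. = FALSE)
  }
  out <- lapply(o_half_values, function(o) half_ignorance(counts, o))
  names(out) <- paste0("O", o_half_values)
  out
}

#' Invert the half-ignorance score
#'
#' Recovers the observation count from an ignorance score,
#' `N = O_0.5 (1 - I) / I`. Exact (up to floating rounding) for scores
#' produced by [half_ignorance()].
#'
#' @param scores Numeric vector/matrix of scores in `(0, 1]`.
#' @param o_half The threshold the scores were computed with.
#' @return Counts on the same shape as `scores`.
#' @export
ignorance_to_count <- function(scores, o_half) {
  if (any(scores <= 0 | scores > 1, na.rm = TRUE)) {
    stop("scores must lie in (0, 1]", call. = FALSE)
  }
  o_half * (1 - scores) / scores
}
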
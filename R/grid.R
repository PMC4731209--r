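#' Define a regular analysis grid
#'
#' A `grid_spec` describes a rectangular grid of square cells in projected
#' (metric) coordinates. Cells are indexed by `(row, col)` with row 1 at the
#' southern edge and column 1 at the western edge; values on a grid are stored
#' as an `n_rows x n_cols` matrix in that orientation.
#'
#' Cell membership uses half-open intervals `[low, high)` on both axes, so a
#' point on a shared cell edge belongs to exactly one cell. Points lying
#' exactly on the global maximum edge (east or north boundary of the grid) are
#' assigned to the last cell, so the full closed extent is covered.
#'
#' @param x_min,y_min Coordinates of the grid origin (south-west corner), in
#'   metres.
#' @param cell_size Cell edge length in metres; must be positive.
#' @param n_rows,n_cols Number of rows (south to north) and columns (west to
#'   east); positive integers.
#' @param crs_label Free-text label for the coordinate reference system, kept
#'   as metadata only (no reprojection is performed).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(0, 0, cell_size = 10000, n_rows = 10, n_cols = 10)
#' g
#' @export
grid_spec <- function(x_min, y_min, cell_size, n_rows, n_cols,
                      crs_label = "") {
  if (!is.numeric(cell_size) || length(cell_size) != 1L ||
      !is.finite(cell_size) || cell_size <= 0) {
    stop("`cell_size` must be a single positive number (metres)",
         call. = FALSE)
  }
  if (!is.numeric(x_min) || !is.numeric(y_min) ||
      !is.finite(x_min) || !is.finite(y_min)) {
    stop("grid origin `x_min`, `y_min` must be finite numbers", call. = FALSE)
  }
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop("`n_rows` and `n_cols` must be positive integers", call. = FALSE)
  }
  structure(
    list(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         cell_size = as.numeric(cell_size),
         n_rows = n_rows, n_cols = n_cols,
         crs_label = as.character(crs_label)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "grid_spec: %d x %d cells of %g m, origin (%g, %g)%s\n",
    x$n_rows, x$n_cols, x$cell_size, x$x_min, x$y_min,
    if (nzchar(x$crs_label)) paste0(" [", x$crs_label, "]") else ""))
  invisible(x)
}

grid_x_max <- function(grid) grid$x_min + grid$n_cols * grid$cell_size
grid_y_max <- function(grid) grid$y_min + grid$n_rows * grid$cell_size

is_grid_spec <- function(x) inherits(x, "grid_spec")

assert_grid <- function(grid) {
  if (!is_grid_spec(grid)) {
    stop("expected a `grid_spec` object; see ?grid_spec", call. = FALSE)
  }
  invisible(grid)
}

#' Locate points on a grid
#'
#' Maps projected coordinates to `(row, col)` cell indices under the half-open
#' cell convention of [grid_spec()] (points on the global east/north edge fall
#' in the last column/row).
#'
#' @param grid A [grid_spec()].
#' @param x,y Numeric vectors of equal length, projected coordinates (m).
#' @return A data frame with columns `row`, `col` (NA when out of bounds) and
#'   logical `in_bounds`.
#' @export
cell_index <- function(grid, x, y) {
  assert_grid(grid)
  stopifnot(length(x) == length(y))
  col <- floor((x - grid$x_min) / grid$cell_size) + 1
  row <- floor((y - grid$y_min) / grid$cell_size) + 1
  # closed global max edge: snap into the last cell
  col[x == grid_x_max(grid)] <- grid$n_cols
  row[y == grid_y_max(grid)] <- grid$n_rows
  ok <- is.finite(x) & is.finite(y) &
    col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  data.frame(row = ifelse(ok, row, NA_integer_),
             col = ifelse(ok, col, NA_integer_),
             in_bounds = ok)
}

new_grid_matrix <- function(grid, fill = 0) {
  matrix(fill, nrow = grid$n_rows, ncol = grid$n_cols)
}

#' Count observation records per grid cell
#'
#' Bins presence-only observation records onto a regular grid, producing the
#' per-cell record counts `N_i` that feed the half-ignorance score. Records
#' falling outside the grid are dropped (their number is reported as the
#' `n_out_of_bounds` attribute and via a message), never an error.
#'
#' @param records A data frame with numeric columns `x` and `y` (projected
#'   metres) and optionally a `taxon` column. All records must belong to a
#'   single taxon: scores are computed per reference taxonomic group, with no
#'   cross-taxon pooling.
#' @param grid A [grid_spec()].
#' @param taxon Taxon label. If `NULL` and `records$taxon` exists with a
#'   single unique value, that value is used; multiple taxa raise an error
#'   (filter first).
#' @param quiet Suppress the dropped-records message.
#' @return A `count_raster`: list with the `grid`, an integer `counts` matrix
#'   (rows south to north), the `taxon`, and attribute `n_out_of_bounds`.
#' @examples
#' g <- grid_spec(0, 0, 10000, 2, 2)
#' rec <- data.frame(x = c(5000, 15000), y = c(5000, 5000))
#' count_observations(rec, g, taxon = "Odonata")
#' @export
count_observations <- function(records, grid, taxon = NULL, quiet = FALSE) {
  assert_grid(grid)
  if (!is.data.frame(records)) {
    stop("`records` must be a data frame", call. = FALSE)
  }
  if (nrow(records) > 0 && (!all(c("x", "y") %in% names(records)))) {
    stop("`records` must have columns `x` and `y`", call. = FALSE)
  }
  if (is.null(taxon)) {
    if ("taxon" %in% names(records) && nrow(records) > 0) {
      taxa <- unique(records$taxon)
      if (length(taxa) > 1L) {
        stop("`records` contains ", length(taxa),
             " taxa; ignorance is computed per taxon - filter first or pass ",
             "`taxon`", call. = FALSE)
      }
      taxon <- as.character(taxa)
    } else {
      taxon <- "unspecified"
    }
  } else if ("taxon" %in% names(records) && nrow(records) > 0) {
    records <- records[records$taxon == taxon, , drop = FALSE]
  }

  counts <- new_grid_matrix(grid, 0L)
  n_oob <- 0L
  if (nrow(records) > 0) {
    idx <- cell_index(grid, records$x, records$y)
    n_oob <- sum(!idx$in_bounds)
    keep <- idx$in_bounds
    if (any(keep)) {
      lin <- (idx$col[keep] - 1L) * grid$n_rows + idx$row[keep]
      tab <- tabulate(lin, nbins = grid$n_rows * grid$n_cols)
      counts <- matrix(as.integer(tab), nrow = grid$n_rows)
    }
  }
  if (n_oob > 0 && !quiet) {
    message(n_oob, " record(s) outside the grid were dropped")
  }
  structure(
    list(grid = grid, counts = counts, taxon = taxon),
    class = "count_raster", n_out_of_bounds = n_oob
  )
}

#' @export
print.count_raster <- function(x, ...) {
  cat(sprintf("count_raster [%s]: %d x %d cells, %d records, max count %d\n",
              x$taxon, x$grid$n_rows, x$grid$n_cols,
              sum(x$counts), max(x$counts)))
  invisible(x)
}
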
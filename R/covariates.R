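#' Gridded geographic covariate layer
#'
#' Wraps one geographic explanatory variable on the analysis grid. Layers are
#' the columns of the design matrix in the Beta regression of ignorance
#' scores: elevation (m), slope (%), road and path density (km/km2),
#' population density (people/km2) and its log.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix `n_rows x n_cols` (row 1 = south); `NA` marks
#'   no-data cells.
#' @param name Layer name, e.g. `"road_density"`.
#' @param units Unit string, e.g. `"km/km2"`.
#' @return An object of class `covariate_layer`.
#' @export
covariate_layer <- function(grid, values, name, units = "") {
  assert_grid(grid)
  values <- as.matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop("`values` must be a ", grid$n_rows, " x ", grid$n_cols,
         " matrix matching the grid", call. = FALSE)
  }
  if (any(is.infinite(values))) {
    stop("`values` must be finite or NA", call. = FALSE)
  }
  structure(list(grid = grid, values = values, name = as.character(name),
                 units = as.character(units)),
            class = "covariate_layer")
}

#' @export
print.covariate_layer <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("covariate_layer %s [%s]: %d x %d cells, range %.4g..%.4g\n",
              x$name, x$units, x$grid$n_rows, x$grid$n_cols, rng[1], rng[2]))
  invisible(x)
}

layer_values <- function(layer) {
  if (inherits(layer, "covariate_layer")) layer$values else as.matrix(layer)
}

# pad a matrix by replicating its border cells (for edge slope estimates)
pad_replicate <- function(z) {
  z <- rbind(z[1, , drop = FALSE], z, z[nrow(z), , drop = FALSE])
  cbind(z[, 1, drop = FALSE], z, z[, ncol(z), drop = FALSE])
}

#' Slope (percent) from a digital elevation model
#'
#' Computes per-cell slope in percent from a fine-resolution elevation raster
#' using Horn's 3x3 finite-difference kernel (the estimator behind the
#' standard GIS *slope* tool):
#' \deqn{slope = 100 \sqrt{(dz/dx)^2 + (dz/dy)^2}}
#' with the east-west gradient `dz/dx = ((zNE + 2 zE + zSE) - (zNW + 2 zW +
#' zSW)) / (8 d)` and the analogous north-south gradient, `d` the cell size.
#' Edge cells use edge-replicated neighbourhoods; a planar surface yields its
#' exact analytic slope on every interior cell (replication flattens the
#' estimate along the border). `NA` cells propagate to their 3x3
#' neighbourhood.
#'
#' @param dem Elevation matrix in metres (row 1 = south), at least 3x3.
#' @param cell_size DEM cell edge length in metres.
#' @return Matrix of slope values in percent, same shape as `dem`.
#' @examples
#' z <- outer(1:5, 1:5, function(r, c) 0.1 * 50 * c)  # plane, 10% grade
#' slope_percent(z, cell_size = 50)
#' @export
slope_percent <- function(dem, cell_size) {
  dem <- layer_values(dem)
  if (nrow(dem) < 3 || ncol(dem) < 3) {
    stop("DEM must be at least 3 x 3 cells", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  nr <- nrow(dem); nc <- ncol(dem)
  p <- pad_replicate(dem)
  # shifted views of the padded matrix; row+1 = north, col+1 = east
  sh <- function(dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  zN <- sh(1, 0); zS <- sh(-1, 0); zE <- sh(0, 1); zW <- sh(0, -1)
  zNE <- sh(1, 1); zNW <- sh(1, -1); zSE <- sh(-1, 1); zSW <- sh(-1, -1)
  dzdx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * cell_size)
  dzdy <- ((zNE + 2 * zN + zNW) - (zSE + 2 * zS + zSW)) / (8 * cell_size)
  100 * sqrt(dzdx^2 + dzdy^2)
}

#' Aggregate a fine raster to a coarser resolution by block means
#'
#' Each coarse cell is the arithmetic mean of its `factor x factor` block of
#' fine cells, ignoring `NA` (no-data) cells; a block that is entirely no-data
#' stays `NA`. When the fine dimensions are not divisible by `factor`, the
#' trailing partial blocks are averaged over the cells they do contain (a
#' message notes this).
#'
#' @param fine Numeric matrix (or `covariate_layer`) of fine-resolution
#'   values.
#' @param factor Positive integer aggregation factor (e.g. 10 to go from 1 km
#'   to 10 km cells).
#' @param quiet Suppress the partial-block message.
#' @return Matrix with `ceiling(dim(fine) / factor)` rows and columns.
#' @export
aggregate_mean <- function(fine, factor, quiet = FALSE) {
  fine <- layer_values(fine)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) {
    stop("`factor` must be a positive integer", call. = FALSE)
  }
  nr <- nrow(fine); nc <- ncol(fine)
  if ((nr %% factor != 0 || nc %% factor != 0) && !quiet) {
    message("fine raster dimensions not divisible by ", factor,
            "; trailing partial blocks averaged over available cells")
  }
  gr <- ceiling(seq_len(nr) / factor)
  gc <- ceiling(seq_len(nc) / factor)
  ngr <- max(gr); ngc <- max(gc)
  lin <- factor(outer(gr, (gc - 1) * ngr, `+`), levels = seq_len(ngr * ngc))
  v <- as.vector(fine)
  ok <- !is.na(v)
  sums <- tapply(ifelse(ok, v, 0), lin, sum, default = 0)
  ns <- tapply(as.numeric(ok), lin, sum, default = 0)
  out <- ifelse(ns > 0, sums / ns, NA_real_)
  matrix(out, nrow = ngr, ncol = ngc)
}

#' Polyline feature set (roads or paths)
#'
#' A set of polylines in grid (projected, metric) coordinates with a single
#' class label. Class filtering (e.g. excluding forestry access roads, keeping
#' footpaths and hiking trails) is expected to happen when the features are
#' read, before this object is built.
#'
#' @param geometries List of numeric matrices with 2 columns (x, y in metres),
#'   each with at least 2 vertices.
#' @param class Feature class label, e.g. `"road"` or `"path"`.
#' @return An object of class `line_feature_set`.
#' @export
line_feature_set <- function(geometries, class = "road") {
  if (!is.list(geometries)) stop("`geometries` must be a list", call. = FALSE)
  geometries <- lapply(geometries, function(g) {
    g <- as.matrix(g)
    if (ncol(g) != 2 || nrow(g) < 2 || !all(is.finite(g))) {
      stop("each polyline needs >= 2 finite (x, y) vertices", call. = FALSE)
    }
    storage.mode(g) <- "double"
    g
  })
  structure(list(geometries = geometries, class = as.character(class)),
            class = "line_feature_set")
}

# split one segment at every grid line it crosses; returns per-piece
# (row, col, length_m) for the pieces inside the grid
segment_cell_lengths <- function(grid, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) return(NULL)
  ts <- c(0, 1)
  cs <- grid$cell_size
  if (dx != 0) {
    k0 <- ceiling((min(x1, x2) - grid$x_min) / cs)
    k1 <- floor((max(x1, x2) - grid$x_min) / cs)
    if (k0 <= k1) {
      xs <- grid$x_min + (k0:k1) * cs
      ts <- c(ts, (xs - x1) / dx)
    }
  }
  if (dy != 0) {
    k0 <- ceiling((min(y1, y2) - grid$y_min) / cs)
    k1 <- floor((max(y1, y2) - grid$y_min) / cs)
    if (k0 <= k1) {
      ys <- grid$y_min + (k0:k1) * cs
      ts <- c(ts, (ys - y1) / dy)
    }
  }
  ts <- sort(unique(pmin(1, pmax(0, ts))))
  if (length(ts) < 2) return(NULL)
  tm <- (ts[-length(ts)] + ts[-1]) / 2          # piece midpoints
  plen <- (ts[-1] - ts[-length(ts)]) * len      # piece lengths (m)
  idx <- cell_index(grid, x1 + tm * dx, y1 + tm * dy)
  keep <- idx$in_bounds & plen > 0
  if (!any(keep)) return(NULL)
  cbind(row = idx$row[keep], col = idx$col[keep], len = plen[keep])
}

#' Line density of polyline features on a grid
#'
#' Per cell, the total length (km) of all polylines clipped to the cell,
#' divided by the cell area (km2). This is the exact, parameter-free
#' cell-clipped variant of the GIS *line density* operator: it uses no search
#' radius, is additive over feature sets and invariant to subdividing polyline
#' vertices.
#'
#' @param lines A [line_feature_set()].
#' @param grid A [grid_spec()].
#' @return A [covariate_layer()] named `"<class>_density"`, units `km/km2`.
#' @examples
#' g <- grid_spec(0, 0, 10000, 1, 1)
#' road <- line_feature_set(list(cbind(c(0, 10000), c(5000, 5000))), "road")
#' line_density(road, g)$values  # 10 km / 100 km2 = 0.1
#' @export
line_density <- function(lines, grid) {
  assert_grid(grid)
  if (!inherits(lines, "line_feature_set")) {
    stop("`lines` must be a line_feature_set", call. = FALSE)
  }
  km <- new_grid_matrix(grid, 0)
  for (g in lines$geometries) {
    for (i in seq_len(nrow(g) - 1)) {
      pieces <- segment_cell_lengths(grid, g[i, 1], g[i, 2],
                                     g[i + 1, 1], g[i + 1, 2])
      if (!is.null(pieces)) {
        for (j in seq_len(nrow(pieces))) {
          km[pieces[j, 1], pieces[j, 2]] <-
            km[pieces[j, 1], pieces[j, 2]] + pieces[j, 3] / 1000
        }
      }
    }
  }
  area_km2 <- (grid$cell_size / 1000)^2
  covariate_layer(grid, km / area_km2,
                  name = paste0(lines$class, "_density"), units = "km/km2")
}

#' Population polygons
#'
#' Census-style polygons, each carrying a total population count. Used to
#' rasterize population density onto a fine (nominally 1 km) grid.
#'
#' @param geometries List of numeric matrices with 2 columns (x, y in metres),
#'   each a polygon ring with at least 3 vertices (closing vertex optional).
#' @param population Numeric vector of nonnegative counts, one per polygon.
#' @return An object of class `population_polygon_set`.
#' @export
population_polygons <- function(geometries, population) {
  if (!is.list(geometries) || length(geometries) != length(population)) {
    stop("`geometries` and `population` must have equal length",
         call. = FALSE)
  }
  if (any(!is.finite(population)) || any(population < 0)) {
    stop("`population` must be nonnegative and finite", call. = FALSE)
  }
  geometries <- lapply(geometries, function(g) {
    g <- as.matrix(g)
    if (ncol(g) != 2 || nrow(g) < 3 || !all(is.finite(g))) {
      stop("each polygon needs >= 3 finite (x, y) vertices", call. = FALSE)
    }
    # drop an explicit closing vertex
    if (nrow(g) > 3 && all(g[1, ] == g[nrow(g), ])) g <- g[-nrow(g), ]
    storage.mode(g) <- "double"
    g
  })
  structure(list(geometries = geometries, population = as.numeric(population)),
            class = "population_polygon_set")
}

# signed shoelace area (m2); abs() for magnitude
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

# Sutherland-Hodgman clip of a polygon ring to an axis-aligned rectangle
clip_ring_rect <- function(ring, xlo, xhi, ylo, yhi) {
  clip_edge <- function(poly, inside, intersect) {
    if (nrow(poly) == 0) return(poly)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(poly)
    for (i in seq_len(n)) {
      cur <- poly[i, ]; prv <- poly[if (i == 1) n else i - 1, ]
      cin <- inside(cur); pin <- inside(prv)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prv, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prv, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, coord) {
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  ring <- clip_edge(ring, function(p) p[1] >= xlo,
                    function(p, q) ix(p, q, xlo, 1))
  ring <- clip_edge(ring, function(p) p[1] <= xhi,
                    function(p, q) ix(p, q, xhi, 1))
  ring <- clip_edge(ring, function(p) p[2] >= ylo,
                    function(p, q) ix(p, q, ylo, 2))
  ring <- clip_edge(ring, function(p) p[2] <= yhi,
                    function(p, q) ix(p, q, yhi, 2))
  ring
}

#' Population density on a fine grid from census polygons
#'
#' Distributes each polygon's population uniformly over its area and
#' accumulates, per fine grid cell, `sum(polygon density x overlap area) /
#' cell area`, in people/km2. Aggregate the result with [aggregate_mean()]
#' (factor 10 for 1 km to 10 km) to obtain the analysis-scale layer. Total
#' population is conserved when all polygons lie inside the grid.
#'
#' @param polygons A [population_polygons()] set.
#' @param fine_grid A [grid_spec()], nominally with 1 km cells.
#' @return A [covariate_layer()] named `"population_density"`, units
#'   `people/km2`.
#' @export
population_density <- function(polygons, fine_grid) {
  assert_grid(fine_grid)
  if (!inherits(polygons, "population_polygon_set")) {
    stop("`polygons` must be a population_polygon_set", call. = FALSE)
  }
  vals <- new_grid_matrix(fine_grid, 0)
  cs <- fine_grid$cell_size
  cell_km2 <- (cs / 1000)^2
  for (k in seq_along(polygons$geometries)) {
    ring <- polygons$geometries[[k]]
    area_m2 <- abs(polygon_area(ring))
    if (area_m2 <= 0) {
      warning("skipping zero-area polygon ", k, call. = FALSE)
      next
    }
    dens_km2 <- polygons$population[k] / (area_m2 / 1e6)
    # candidate cells from the polygon bounding box
    c0 <- max(1L, floor((min(ring[, 1]) - fine_grid$x_min) / cs) + 1L)
    c1 <- min(fine_grid$n_cols,
              floor((max(ring[, 1]) - fine_grid$x_min) / cs) + 1L)
    r0 <- max(1L, floor((min(ring[, 2]) - fine_grid$y_min) / cs) + 1L)
    r1 <- min(fine_grid$n_rows,
              floor((max(ring[, 2]) - fine_grid$y_min) / cs) + 1L)
    if (c0 > c1 || r0 > r1) next
    for (cc in c0:c1) {
      xlo <- fine_grid$x_min + (cc - 1) * cs
      for (rr in r0:r1) {
        ylo <- fine_grid$y_min + (rr - 1) * cs
        clipped <- clip_ring_rect(ring, xlo, xlo + cs, ylo, ylo + cs)
        if (nrow(clipped) >= 3) {
          ov_m2 <- abs(polygon_area(clipped))
          vals[rr, cc] <- vals[rr, cc] +
            dens_km2 * (ov_m2 / 1e6) / cell_km2
        }
      }
    }
  }
  covariate_layer(fine_grid, vals, "population_density", "people/km2")
}

#' Log-transform a nonnegative density layer
#'
#' Natural log with a positive offset, `ln(value + offset)`, used to examine
#' the effect of changes in population at the lowest densities. The default
#' offset is the smallest positive value in the layer (1 if there is none), so
#' zero cells map to the bottom of the observed range rather than -Inf.
#'
#' @param layer A [covariate_layer()] (or matrix) with values >= 0.
#' @param offset Positive offset; `NULL` for the default rule.
#' @return A layer of the same type, name `"log_<name>"`.
#' @export
log_density <- function(layer, offset = NULL) {
  v <- layer_values(layer)
  if (any(v < 0, na.rm = TRUE)) {
    stop("`layer` must be nonnegative", call. = FALSE)
  }
  if (is.null(offset)) {
    pos <- v[!is.na(v) & v > 0]
    offset <- if (length(pos)) min(pos) else 1
  }
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset) ||
      offset <= 0) {
    stop("`offset` must be a single positive number", call. = FALSE)
  }
  out <- log(v + offset)
  if (inherits(layer, "covariate_layer")) {
    covariate_layer(layer$grid, out, paste0("log_", layer$name),
                    paste0("log(", layer$units, ")"))
  } else {
    out
  }
}
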
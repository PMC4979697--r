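#' Define a geographic grid for survey binning
#'
#' A grid of rectangular cells in decimal degrees (WGS84 assumed, no
#' reprojection), anchored so that cell edges fall on multiples of
#' `cell_size` from the origin. Cells are half-open, closed on their lower
#' (south/west) edge, so every point falls in exactly one cell.
#'
#' @param cell_size Cell edge length in decimal degrees (default 0.1, i.e.
#'   0.1 x 0.1 degree cells of roughly 80-112 km^2 over the mid latitudes).
#' @param origin Length-2 numeric `(lon0, lat0)` anchoring cell edges.
#'   The default `c(-180, -90)` puts edges on multiples of 0.1 degree.
#' @param extent Length-4 numeric bounding box
#'   `(lon_min, lon_max, lat_min, lat_max)`; records outside it are dropped
#'   by [assign_cells()]. `NULL` means unbounded.
#' @param mask Optional character vector of cell ids constituting the study
#'   region (the "background" cells). When given, records falling outside
#'   the mask are dropped and counted, and background-cell counts used by
#'   the coverage stage are `length(mask)`.
#' @return An object of class `grid_spec`.
#' @seealso [assign_cells()], [cell_geometry()]
#' @export
grid_spec <- function(cell_size = 0.1, origin = c(-180, -90),
                      extent = NULL, mask = NULL) {
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("'cell_size' must be a single positive number", call. = FALSE)
  if (length(origin) != 2L || !is.numeric(origin))
    stop("'origin' must be numeric (lon0, lat0)", call. = FALSE)
  if (!is.null(extent)) {
    if (length(extent) != 4L || extent[1] >= extent[2] || extent[3] >= extent[4])
      stop("'extent' must be (lon_min, lon_max, lat_min, lat_max)", call. = FALSE)
  }
  if (!is.null(mask)) mask <- as.character(mask)
  structure(list(cell_size = cell_size, origin = as.numeric(origin),
                 extent = if (is.null(extent)) NULL else as.numeric(extent),
                 mask = mask),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("Grid: ", x$cell_size, " deg cells, origin (",
      x$origin[1], ", ", x$origin[2], ")\n", sep = "")
  if (!is.null(x$extent))
    cat("  extent: lon [", x$extent[1], ", ", x$extent[2], "], lat [",
        x$extent[3], ", ", x$extent[4], "]\n", sep = "")
  if (!is.null(x$mask))
    cat("  mask: ", length(x$mask), " background cells\n", sep = "")
  invisible(x)
}

# Snap-tolerant floor for cell indexing: points within ~1e-7 cells of an
# edge are treated as lying on it, and an edge point belongs to the cell on
# its greater side (half-open convention).
.cell_index <- function(coord, origin, cell_size) {
  as.integer(floor((coord - origin) / cell_size + 1e-7))
}

.cell_id <- function(ix, iy) paste0(ix, "_", iy)

# Inverse of .cell_id: integer matrix with columns ix, iy.
.cell_ij <- function(cell_id) {
  parts <- strsplit(as.character(cell_id), "_", fixed = TRUE)
  ix <- suppressWarnings(vapply(parts, function(p) as.integer(p[1]), integer(1)))
  iy <- suppressWarnings(vapply(parts, function(p) as.integer(p[2]), integer(1)))
  cbind(ix = ix, iy = iy)
}

#' Cell ids and centers for every cell of a bounded grid
#'
#' Enumerates the background cells of a grid: the mask when one is set,
#' otherwise all cells tiling the extent.
#'
#' @param grid A [grid_spec()] with a mask or a finite extent.
#' @return Data frame with `cell_id`, `ix`, `iy`, `lon` and `lat`
#'   (cell-center coordinates, decimal degrees).
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  cs <- grid$cell_size
  if (!is.null(grid$mask)) {
    ij <- .cell_ij(grid$mask)
    out <- data.frame(cell_id = grid$mask, ix = ij[, "ix"], iy = ij[, "iy"],
                      stringsAsFactors = FALSE)
  } else if (!is.null(grid$extent)) {
    ix0 <- .cell_index(grid$extent[1], grid$origin[1], cs)
    ix1 <- .cell_index(grid$extent[2] - cs / 2, grid$origin[1], cs)
    iy0 <- .cell_index(grid$extent[3], grid$origin[2], cs)
    iy1 <- .cell_index(grid$extent[4] - cs / 2, grid$origin[2], cs)
    g <- expand.grid(ix = ix0:ix1, iy = iy0:iy1, KEEP.OUT.ATTRS = FALSE)
    out <- data.frame(cell_id = .cell_id(g$ix, g$iy), ix = g$ix, iy = g$iy,
                      stringsAsFactors = FALSE)
  } else {
    stop("grid has neither a mask nor a finite extent", call. = FALSE)
  }
  out$lon <- grid$origin[1] + (out$ix + 0.5) * cs
  out$lat <- grid$origin[2] + (out$iy + 0.5) * cs
  out
}

#' Number of background cells of a grid
#' @param grid A [grid_spec()].
#' @return Integer count of background (study-region) cells.
#' @export
n_background_cells <- function(grid) nrow(grid_cells(grid))

#' Assign occurrence records to grid cells
#'
#' Point-in-cell assignment with half-open cells `[edge, edge + size)` on
#' both axes: a record exactly on a shared edge lands in the cell on the
#' greater side, never in two cells. Records outside the grid extent or
#' mask are dropped; their count is attached as attribute `"dropped"`.
#'
#' @param records An occurrence table (see [read_occurrences()]), already
#'   filtered.
#' @param grid A [grid_spec()].
#' @return The records with `cell_id` (and integer `ix`, `iy`) columns;
#'   attribute `dropped` holds the number of out-of-region records.
#' @export
assign_cells <- function(records, grid) {
  stopifnot(inherits(grid, "grid_spec"), is.data.frame(records))
  n0 <- nrow(records)
  ix <- .cell_index(records$decimal_longitude, grid$origin[1], grid$cell_size)
  iy <- .cell_index(records$decimal_latitude, grid$origin[2], grid$cell_size)
  records$ix <- ix
  records$iy <- iy
  records$cell_id <- .cell_id(ix, iy)
  keep <- rep(TRUE, n0)
  if (!is.null(grid$mask)) {
    keep <- records$cell_id %in% grid$mask
  } else if (!is.null(grid$extent)) {
    # keep records whose cell is one of the background cells tiling the extent
    e <- grid$extent
    cs <- grid$cell_size
    ix0 <- .cell_index(e[1], grid$origin[1], cs)
    ix1 <- .cell_index(e[2] - cs / 2, grid$origin[1], cs)
    iy0 <- .cell_index(e[3], grid$origin[2], cs)
    iy1 <- .cell_index(e[4] - cs / 2, grid$origin[2], cs)
    keep <- ix >= ix0 & ix <= ix1 & iy >= iy0 & iy <= iy1
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- n0 - nrow(out)
  out
}

#' Geographic geometry of a grid cell
#'
#' Widths from the spherical model: east-west width
#' `dlon * (pi/180) * R * cos(center latitude)`, north-south height
#' `dlat * (pi/180) * R`, with mean Earth radius R = 6371.0088 km. On a
#' 0.1 degree grid this gives ~112 km^2 cells at 25 N shrinking to
#' ~80 km^2 at 49.4 N.
#'
#' @param cell_id Character vector of cell ids.
#' @param grid A [grid_spec()].
#' @return Data frame with the degree bounds (`lon_min`, `lon_max`,
#'   `lat_min`, `lat_max`), `width_km`, `height_km` and `area_km2`.
#' @export
cell_geometry <- function(cell_id, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.null(grid$mask) && !all(cell_id %in% grid$mask))
    stop("cell id outside the grid mask", call. = FALSE)
  R <- 6371.0088
  cs <- grid$cell_size
  ij <- .cell_ij(cell_id)
  if (anyNA(ij)) stop("malformed cell id", call. = FALSE)
  lon_min <- grid$origin[1] + ij[, "ix"] * cs
  lat_min <- grid$origin[2] + ij[, "iy"] * cs
  lat_mid <- lat_min + cs / 2
  width <- cs * (pi / 180) * R * cos(lat_mid * pi / 180)
  height <- cs * (pi / 180) * R
  data.frame(cell_id = as.character(cell_id),
             lon_min = lon_min, lon_max = lon_min + cs,
             lat_min = lat_min, lat_max = lat_min + cs,
             width_km = width, height_km = height,
             area_km2 = width * height,
             stringsAsFactors = FALSE)
}

#' Named time-period schemes for survey definition
#'
#' Three built-in schemes: `"complete"` (one period, 1800-2013),
#' `"contemporary"` (one period, 1990-2013) and `"intervals"` (ten 20-year
#' intervals 1800-1819 ... 1980-1999 plus a final 14-year interval
#' 2000-2013; eleven periods that tile 1800-2013 exactly).
#'
#' @param scheme One of `"complete"`, `"contemporary"`, `"intervals"`, or a
#'   named list of inclusive `c(start, end)` year pairs for a custom scheme.
#' @return Named list of inclusive year intervals (integer length-2
#'   vectors), of class `time_period_scheme`.
#' @export
time_periods <- function(scheme = c("complete", "contemporary", "intervals")) {
  if (is.list(scheme)) {
    per <- lapply(scheme, function(p) as.integer(p[1:2]))
    if (is.null(names(per)) || any(!nzchar(names(per))))
      stop("custom period schemes must be fully named", call. = FALSE)
    bad <- vapply(per, function(p) anyNA(p) || p[1] > p[2], logical(1))
    if (any(bad)) stop("invalid period interval(s): ",
                       paste(names(per)[bad], collapse = ", "), call. = FALSE)
    return(structure(per, class = "time_period_scheme"))
  }
  scheme <- match.arg(scheme)
  per <- switch(scheme,
    complete = list(complete = c(1800L, 2013L)),
    contemporary = list(contemporary = c(1990L, 2013L)),
    intervals = {
      starts <- seq(1800L, 2000L, by = 20L)
      ends <- c(starts[-1] - 1L, 2013L)
      p <- Map(c, starts, ends)
      names(p) <- paste0(starts, "-", ends)
      p
    })
  structure(per, class = "time_period_scheme")
}
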
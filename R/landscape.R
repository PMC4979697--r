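#' Parameters for the synthetic landscape generator
#'
#' Controls the gridded environment that [make_landscape()] builds. The
#' defaults sketch a temperate mid-latitude window: elevation rising
#' westward from ~200 m to ~1700 m, MAT falling with latitude (-0.05 degC
#' per 0.1 degree, i.e. -0.5 degC per degree) and with elevation
#' (-6.5 degC/km), MAP rising eastward from ~400 to ~1300 mm/yr, modest
#' recent warming (+1.5 degC) and drying (-20 mm/yr), and land cover
#' dominated by natural classes with sparse urban and moderate
#' agricultural cover (NLCD-style codes: 21-24 urban, 41/52/90 natural,
#' 81/82 agriculture).
#'
#' @param lon0,lat0 South-west corner of the landscape (degrees).
#' @param cell_size Cell edge in degrees (default 0.1).
#' @param elevation `list(base, ew_range, noise_sd)`: west-east linear
#'   ramp (high in the west) plus Gaussian noise, floored at 0 m.
#' @param mat `list(base, lat_lapse, elevation_lapse, noise_sd)`:
#'   `lat_lapse` is degC per 0.1 degree of latitude northward;
#'   `elevation_lapse` is degC per km of elevation.
#' @param map `list(base, ew_range, noise_sd)`: east-west ramp (wet in
#'   the east), floored at 10 mm/yr.
#' @param dmat,dmap `list(mean, sd)` for the climate-change deltas.
#' @param landcover `list(classes, alpha)`: Dirichlet concentration per
#'   class for the per-cell cover fractions.
#' @return List of class `landscape_params`.
#' @export
landscape_params <- function(lon0 = -100, lat0 = 35, cell_size = 0.1,
                             elevation = list(base = 200, ew_range = 1500,
                                              noise_sd = 100),
                             mat = list(base = 18, lat_lapse = -0.05,
                                        elevation_lapse = -6.5, noise_sd = 0.5),
                             map = list(base = 400, ew_range = 900,
                                        noise_sd = 50),
                             dmat = list(mean = 1.5, sd = 0.3),
                             dmap = list(mean = -20, sd = 30),
                             landcover = list(
                               classes = c(21L, 22L, 23L, 24L, 41L, 52L, 81L,
                                           82L, 90L),
                               alpha = c(0.1, 0.1, 0.1, 0.1, 3, 2, 1, 1, 0.5))) {
  stopifnot(length(landcover$classes) == length(landcover$alpha),
            all(landcover$alpha > 0), cell_size > 0)
  structure(list(lon0 = lon0, lat0 = lat0, cell_size = cell_size,
                 elevation = elevation, mat = mat, map = map,
                 dmat = dmat, dmap = dmap, landcover = landcover),
            class = "landscape_params")
}

#' Generate a synthetic gridded landscape
#'
#' Builds an `n_lon` x `n_lat` cell landscape with one value per cell for
#' each audited environmental gradient (elevation, MAT, MAP, delta MAT,
#' delta MAP) plus per-cell land-cover class fractions that are
#' non-negative and sum to one. Deterministic given `seed`.
#'
#' @param n_lon,n_lat Number of cells west-east and south-north (>= 1).
#' @param params A [landscape_params()] configuration.
#' @param seed Integer seed (mandatory; the generator is a simulation).
#' @return Object of class `landscape`: list with `grid` (a
#'   [grid_spec()] whose mask is all landscape cells) and `cells`, a data
#'   frame with `cell_id`, cell-center `lon`/`lat`, `elevation`, `mat`,
#'   `map`, `dmat`, `dmap` and one `lc_<code>` fraction column per
#'   land-cover class.
#' @export
make_landscape <- function(n_lon, n_lat, params = landscape_params(), seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (n_lon < 1 || n_lat < 1)
    stop("'n_lon' and 'n_lat' must be >= 1", call. = FALSE)
  stopifnot(inherits(params, "landscape_params"))
  n_lon <- as.integer(n_lon); n_lat <- as.integer(n_lat)
  set.seed(seed)
  cs <- params$cell_size
  grid <- grid_spec(cell_size = cs, origin = c(params$lon0, params$lat0),
                    extent = c(params$lon0, params$lon0 + n_lon * cs,
                               params$lat0, params$lat0 + n_lat * cs))
  cells <- grid_cells(grid)
  grid$mask <- cells$cell_id
  n <- nrow(cells)
  # unit positions across the window ([0, 1] west->east, south->north)
  u_ew <- if (n_lon > 1) (cells$ix + 0.5) / n_lon else rep(0.5, n)
  elev <- params$elevation$base +
    params$elevation$ew_range * (1 - u_ew) +
    stats::rnorm(n, 0, params$elevation$noise_sd)
  elev <- pmax(elev, 0)
  mat <- params$mat$base +
    params$mat$lat_lapse * (cells$lat - params$lat0) / cs +
    params$mat$elevation_lapse * elev / 1000 +
    stats::rnorm(n, 0, params$mat$noise_sd)
  map <- params$map$base + params$map$ew_range * u_ew +
    stats::rnorm(n, 0, params$map$noise_sd)
  map <- pmax(map, 10)
  dmat <- stats::rnorm(n, params$dmat$mean, params$dmat$sd)
  dmap <- stats::rnorm(n, params$dmap$mean, params$dmap$sd)
  alpha <- params$landcover$alpha
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  lc <- g / rowSums(g)
  colnames(lc) <- paste0("lc_", params$landcover$classes)
  out <- list(grid = grid,
              cells = data.frame(cells, elevation = elev, mat = mat, map = map,
                                 dmat = dmat, dmap = dmap, lc,
                                 stringsAsFactors = FALSE),
              params = params)
  class(out) <- "landscape"
  out
}

#' @export
print.landscape <- function(x, ...) {
  cat("Synthetic landscape: ", nrow(x$cells), " cells of ",
      x$grid$cell_size, " deg\n", sep = "")
  cat("  MAT ", round(min(x$cells$mat), 1), "..", round(max(x$cells$mat), 1),
      " degC; MAP ", round(min(x$cells$map)), "..", round(max(x$cells$map)),
      " mm/yr; elevation ", round(min(x$cells$elevation)), "..",
      round(max(x$cells$elevation)), " m\n", sep = "")
  invisible(x)
}

#' Per-cell gradient table of a synthetic landscape
#'
#' Converts a [make_landscape()] object to the [join_gradients()] table
#' the coverage stage consumes: land-cover fractions become percent urban
#' (classes 21-24), percent agriculture (81, 82) and their sum (total
#' disturbance).
#'
#' @param landscape A `landscape` object.
#' @param urban_classes,agriculture_classes Integer land-cover codes
#'   summed into the two anthropogenic gradients.
#' @return A `cell_gradients` data frame (see [join_gradients()]).
#' @export
landscape_gradients <- function(landscape,
                                urban_classes = c(21L, 22L, 23L, 24L),
                                agriculture_classes = c(81L, 82L)) {
  stopifnot(inherits(landscape, "landscape"))
  cells <- landscape$cells
  pct <- function(classes) {
    cols <- paste0("lc_", classes)
    cols <- cols[cols %in% names(cells)]
    if (!length(cols)) return(rep(0, nrow(cells)))
    100 * rowSums(as.matrix(cells[cols]))
  }
  urban <- pct(urban_classes)
  agriculture <- pct(agriculture_classes)
  out <- data.frame(cell_id = cells$cell_id, latitude = cells$lat,
                    longitude = cells$lon, elevation = cells$elevation,
                    mat = cells$mat, map = cells$map,
                    urban = urban, agriculture = agriculture,
                    disturbed = urban + agriculture,
                    dmap = cells$dmap, dmat = cells$dmat,
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_gradients", "data.frame")
  out
}

#' Write a landscape as delimited text (and optional ASCII grids)
#'
#' One table keyed by cell id with every gradient and land-cover
#' fraction; optionally one single-band ESRI ASCII grid per continuous
#' gradient.
#'
#' @param landscape A `landscape` object.
#' @param path Output CSV path.
#' @param grids_dir Optional directory for per-gradient ASCII grids.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path, grids_dir = NULL) {
  stopifnot(inherits(landscape, "landscape"))
  utils::write.csv(landscape$cells, path, row.names = FALSE, quote = FALSE)
  if (!is.null(grids_dir)) {
    dir.create(grids_dir, showWarnings = FALSE, recursive = TRUE)
    cs <- landscape$grid$cell_size
    cells <- landscape$cells
    nx <- max(cells$ix) - min(cells$ix) + 1L
    ny <- max(cells$iy) - min(cells$iy) + 1L
    for (g in c("elevation", "mat", "map", "dmat", "dmap")) {
      v <- matrix(NA_real_, nrow = ny, ncol = nx)
      v[cbind(cells$iy - min(cells$iy) + 1L, cells$ix - min(cells$ix) + 1L)] <-
        cells[[g]]
      r <- simple_raster(v,
                         xmin = landscape$grid$origin[1] + min(cells$ix) * cs,
                         ymin = landscape$grid$origin[2] + min(cells$iy) * cs,
                         res = cs)
      write_ascii_grid(r, file.path(grids_dir, paste0(g, ".asc")))
    }
  }
  invisible(path)
}

#' Generate a synthetic species pool
#'
#' Species with relative abundances drawn from a configurable
#' species-abundance distribution (SAD) and Gaussian niches on one
#' environmental axis. Abundances are sorted decreasing (ties broken by
#' species id), strictly positive and sum to one. The log-series default
#' produces the long rare tail that makes completeness estimation hard;
#' `"uniform"` is the easy regime; `"lognormal"` sits between.
#'
#' @param n_species Number of species (>= 1).
#' @param sad `"logseries"` (default), `"lognormal"` or `"uniform"`.
#' @param sad_params SAD parameters: `theta` in (0,1) for the log-series
#'   (abundance_k proportional to theta^k / k), `meanlog`/`sdlog` for the
#'   lognormal.
#' @param niche `list(axis, optimum_range, breadth_range)`: the gradient
#'   the niches live on (default `"mat"`, degC), uniform niche optima over
#'   `optimum_range` and uniform breadths (Gaussian sd) over
#'   `breadth_range`.
#' @param taxon_group Label carried into simulated records.
#' @param seed Integer seed (mandatory).
#' @return Data frame of class `species_pool`: `species_id`, `abundance`,
#'   `niche_axis`, `niche_optimum`, `niche_breadth`, `taxon_group`.
#' @export
make_species_pool <- function(n_species,
                              sad = c("logseries", "lognormal", "uniform"),
                              sad_params = list(theta = 0.95, meanlog = 0,
                                                sdlog = 1),
                              niche = list(axis = "mat",
                                           optimum_range = c(8, 20),
                                           breadth_range = c(2, 6)),
                              taxon_group = "synthetic",
                              seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (n_species < 1) stop("'n_species' must be >= 1", call. = FALSE)
  if (is.character(sad)) sad <- match.arg(sad)
  else stop("unknown species-abundance distribution", call. = FALSE)
  n_species <- as.integer(n_species)
  set.seed(seed)
  ab <- switch(sad,
    uniform = rep(1 / n_species, n_species),
    logseries = {
      k <- seq_len(n_species)
      w <- sad_params$theta^k / k
      w / sum(w)
    },
    lognormal = {
      w <- stats::rlnorm(n_species, sad_params$meanlog, sad_params$sdlog)
      w <- sort(w, decreasing = TRUE)
      w / sum(w)
    })
  ab <- sort(ab, decreasing = TRUE)
  opt <- stats::runif(n_species, niche$optimum_range[1], niche$optimum_range[2])
  br <- stats::runif(n_species, niche$breadth_range[1], niche$breadth_range[2])
  if (any(br <= 0)) stop("niche breadths must be positive", call. = FALSE)
  out <- data.frame(
    species_id = sprintf("sp%04d", seq_len(n_species)),
    abundance = ab,
    niche_axis = niche$axis,
    niche_optimum = opt,
    niche_breadth = br,
    taxon_group = taxon_group,
    stringsAsFactors = FALSE)
  class(out) <- c("species_pool", "data.frame")
  out
}
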
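#' Two-sample Kolmogorov-Smirnov D statistic
#'
#' The coverage index: the supremum over x of the absolute difference
#' between the right-continuous empirical CDFs of the surveyed-cell and
#' background-cell gradient values, evaluated at every pooled data point.
#' Used descriptively -- no p-value is computed. D = 0 iff the two
#' multisets induce identical ECDFs; D = 1 for disjoint supports.
#'
#' @param surveyed Numeric gradient values of the surveyed cells.
#' @param background Numeric gradient values of all background cells
#'   (surveyed cells included; the comparison is against the whole
#'   landscape).
#' @param na.rm Drop non-finite values first (default `TRUE`).
#' @return D in `[0, 1]`.
#' @export
ks_d <- function(surveyed, background, na.rm = TRUE) {
  if (na.rm) {
    surveyed <- surveyed[is.finite(surveyed)]
    background <- background[is.finite(background)]
  }
  if (!length(surveyed) || !length(background))
    stop("both samples must be non-empty", call. = FALSE)
  pts <- sort(unique(c(surveyed, background)))
  f1 <- findInterval(pts, sort(surveyed)) / length(surveyed)
  f2 <- findInterval(pts, sort(background)) / length(background)
  max(abs(f1 - f2))
}

#' Temporal coverage D against a uniform interval null
#'
#' One-sample discrete K-S index comparing the distribution of surveys
#' across the eleven 20-year intervals (1800-2013, final interval 14
#' years) to an ideal null of equal sampling in every interval:
#' D = max_k |cumulative observed proportion through interval k - k/11|.
#' A duration-proportional null (weights proportional to interval length,
#' e.g. 14/214 for the final interval) is available via `null`.
#'
#' @param interval_counts Integer vector of surveyed-cell counts per
#'   interval, in chronological order (length 11 for the built-in scheme).
#' @param null `"uniform"` (equal weight per interval, the default) or
#'   `"duration"` (weight proportional to interval length in years; needs
#'   `scheme`).
#' @param scheme The [time_periods()] scheme behind the counts; only used
#'   for the duration-proportional null. Default `time_periods("intervals")`.
#' @return D in `[0, 1]`.
#' @export
temporal_d <- function(interval_counts, null = c("uniform", "duration"),
                       scheme = time_periods("intervals")) {
  null <- match.arg(null)
  counts <- as.numeric(interval_counts)
  if (!length(counts) || anyNA(counts) || any(counts < 0) || sum(counts) == 0)
    stop("'interval_counts' must be non-negative with a positive total",
         call. = FALSE)
  k <- length(counts)
  w <- if (null == "uniform") rep(1 / k, k) else {
    stopifnot(length(scheme) == k)
    len <- vapply(scheme, function(p) p[2] - p[1] + 1, numeric(1))
    len / sum(len)
  }
  max(abs(cumsum(counts) / sum(counts) - cumsum(w)))
}

#' Percent cover of categorical classes per grid cell
#'
#' Zonal summary of an integer-coded categorical grid (e.g. land cover)
#' over the survey cells: for each named class set, the percentage of a
#' cell's valid pixels whose code is in the set. The pixel grid must align
#' with the cell grid (cell size an integer multiple of the pixel size,
#' shared edges).
#'
#' @param class_grid A [simple_raster()] with integer codes (`NA` = no
#'   data).
#' @param grid The survey [grid_spec()].
#' @param class_sets Named list of integer code vectors, e.g.
#'   `list(urban = c(21, 22, 23, 24), agriculture = c(81, 82))`.
#' @return Data frame keyed by `cell_id` with one percent column per
#'   class set; cells with no valid pixels get `NA`.
#' @export
zonal_percent <- function(class_grid, grid,
                          class_sets = list(urban = c(21L, 22L, 23L, 24L),
                                            agriculture = c(81L, 82L))) {
  stopifnot(inherits(class_grid, "simple_raster"), inherits(grid, "grid_spec"))
  ratio <- grid$cell_size / class_grid$res
  if (abs(ratio - round(ratio)) > 1e-6)
    stop("pixel grid does not align with the cell grid (cell size must be ",
         "an integer multiple of the pixel size)", call. = FALSE)
  agg <- .aggregate_raster(class_grid, grid,
                           function(v) vapply(class_sets, function(set) {
                             100 * mean(v %in% set)
                           }, numeric(1)))
  agg
}

#' A minimal in-memory single-band grid
#'
#' Row 1 of `values` is the southernmost row; columns run west to east.
#' This is the plain-text-friendly grid container used for synthetic
#' gradient and land-cover layers (ESRI ASCII grid import/export via
#' [read_ascii_grid()] / [write_ascii_grid()]).
#'
#' @param values Numeric matrix (rows = south-to-north, cols =
#'   west-to-east).
#' @param xmin,ymin Coordinates of the grid's south-west corner (degrees).
#' @param res Pixel size in degrees.
#' @return Object of class `simple_raster`.
#' @export
simple_raster <- function(values, xmin, ymin, res) {
  stopifnot(is.matrix(values), res > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin, res = res),
            class = "simple_raster")
}

# Aggregate raster pixels to survey cells with an arbitrary summary `f`
# returning a fixed-length named numeric vector. NA pixels are dropped
# before summarising; all-NA cells give NA.
.aggregate_raster <- function(r, grid, f) {
  cells <- grid_cells(grid)
  cs <- grid$cell_size
  nr <- nrow(r$values); nc <- ncol(r$values)
  px_x <- r$xmin + (seq_len(nc) - 0.5) * r$res
  px_y <- r$ymin + (seq_len(nr) - 0.5) * r$res
  ix <- .cell_index(px_x, grid$origin[1], cs)
  iy <- .cell_index(px_y, grid$origin[2], cs)
  # column-major flattening: element (row j, col i) sits at (i-1)*nr + j
  cell_of <- .cell_id(rep(ix, each = nr), rep(iy, times = nc))
  vals <- as.vector(r$values)
  ok <- !is.na(vals)
  sp <- split(vals[ok], cell_of[ok])
  want <- intersect(names(sp), cells$cell_id)
  probe <- f(if (any(ok)) vals[ok][1] else 0)
  res <- matrix(NA_real_, nrow = nrow(cells), ncol = length(probe),
                dimnames = list(NULL, names(probe)))
  m <- match(want, cells$cell_id)
  for (k in seq_along(want)) res[m[k], ] <- f(sp[[want[k]]])
  out <- data.frame(cell_id = cells$cell_id, res, stringsAsFactors = FALSE)
  out
}

#' Join gradient layers to the survey grid
#'
#' Builds the per-cell gradient table the coverage stage audits: the two
#' spatial gradients (cell-center latitude and longitude) are appended
#' automatically; continuous layers are taken as given per-cell values or
#' aggregated from finer rasters by the cell mean; categorical land cover
#' is summarised to percent urban / agriculture, with total disturbance
#' defined as their sum.
#'
#' @param grid The survey [grid_spec()].
#' @param continuous Named list of continuous gradient sources; each
#'   element is either a data frame (`cell_id` + value column), a named
#'   numeric vector keyed by cell id, or a [simple_raster()].
#' @param categorical Optional [simple_raster()] of integer land-cover
#'   codes.
#' @param class_sets Class sets for `categorical`; see [zonal_percent()].
#'   A `disturbed` column (sum of all class-set percentages) is appended.
#' @param max_missing Error when a gradient is missing for more than this
#'   fraction of background cells (misconfiguration guard, default 0.5).
#' @return Data frame of class `cell_gradients`: `cell_id`, `latitude`,
#'   `longitude`, then one column per gradient.
#' @export
join_gradients <- function(grid, continuous = list(), categorical = NULL,
                           class_sets = list(urban = c(21L, 22L, 23L, 24L),
                                             agriculture = c(81L, 82L)),
                           max_missing = 0.5) {
  cells <- grid_cells(grid)
  out <- data.frame(cell_id = cells$cell_id,
                    latitude = cells$lat, longitude = cells$lon,
                    stringsAsFactors = FALSE)
  add_col <- function(out, name, vals) {
    miss <- mean(!is.finite(vals))
    if (miss > max_missing)
      stop("gradient '", name, "' missing for ", round(100 * miss),
           "% of background cells", call. = FALSE)
    out[[name]] <- vals
    out
  }
  for (name in names(continuous)) {
    src <- continuous[[name]]
    vals <- if (inherits(src, "simple_raster")) {
      agg <- .aggregate_raster(src, grid, function(v) c(mean = mean(v)))
      agg$mean[match(out$cell_id, agg$cell_id)]
    } else if (is.data.frame(src)) {
      vcol <- setdiff(names(src), "cell_id")[1]
      src[[vcol]][match(out$cell_id, src$cell_id)]
    } else if (is.numeric(src) && !is.null(names(src))) {
      unname(src[out$cell_id])
    } else stop("unsupported gradient source for '", name, "'", call. = FALSE)
    out <- add_col(out, name, vals)
  }
  if (!is.null(categorical)) {
    zp <- zonal_percent(categorical, grid, class_sets)
    m <- match(out$cell_id, zp$cell_id)
    for (name in names(class_sets)) out <- add_col(out, name, zp[[name]][m])
    out$disturbed <- rowSums(as.matrix(out[names(class_sets)]))
  }
  class(out) <- c("cell_gradients", "data.frame")
  out
}

#' Default audit gradients
#'
#' The eleven gradients audited by default: one temporal (record
#' distribution over the 20-year intervals), two spatial (latitude,
#' longitude), three natural environmental (elevation, MAT, MAP), three
#' anthropogenic (percent urban, agriculture, total disturbance) and two
#' climate-change (delta MAP, delta MAT).
#'
#' @return Character vector of gradient names.
#' @export
audit_gradients <- function() {
  c("temporal", "latitude", "longitude", "elevation", "mat", "map",
    "urban", "agriculture", "disturbed", "dmap", "dmat")
}

#' Coverage D indices per dataset, gradient and cell class
#'
#' For every dataset and gradient, computes the K-S D index between the
#' gradient distribution of the surveyed cells and that of all background
#' cells, for two cell classes: all surveyed cells and well-surveyed
#' cells (the chosen tier, moderate by default). Spatial and
#' environmental gradients use the contemporary-period surveys (historic
#' land cover is not comparable); the temporal gradient compares the
#' number of surveyed cells per 20-year interval to a uniform null over
#' the intervals. Classes with no cells yield `NA` ("n/a") indices.
#'
#' @param metrics A [survey_completeness()] table covering the
#'   `contemporary` period and the interval periods (as produced by
#'   [survey_audit()]).
#' @param gradients A [join_gradients()] table for the background cells.
#' @param gradient_names Gradients to audit; default [audit_gradients()].
#' @param tier Well-surveyed tier: `"low"`, `"moderate"` (default) or
#'   `"high"`.
#' @param spatial_period Period whose surveys enter the spatial and
#'   environmental ECDFs (default `"contemporary"`).
#' @param interval_scheme The interval scheme for the temporal gradient.
#' @param temporal_null Null for [temporal_d()].
#' @return Data frame of class `coverage_index`: `dataset`, `gradient`,
#'   `cell_class`, `d`, `n_surveyed`, `n_background`.
#' @export
coverage_matrix <- function(metrics, gradients,
                            gradient_names = audit_gradients(),
                            tier = "moderate",
                            spatial_period = "contemporary",
                            interval_scheme = time_periods("intervals"),
                            temporal_null = c("uniform", "duration")) {
  temporal_null <- match.arg(temporal_null)
  stopifnot(is.data.frame(metrics), inherits(gradients, "cell_gradients"))
  tier_col <- paste0("pass_", match.arg(tier, c("low", "moderate", "high")))
  unknown <- setdiff(gradient_names, c("temporal", names(gradients)))
  unknown <- setdiff(unknown, c("latitude", "longitude"))
  if (length(unknown))
    stop("unknown gradient name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  datasets <- sort(unique(metrics$dataset))
  classes <- c("surveyed", "well_surveyed")
  interval_names <- names(interval_scheme)
  rows <- list()
  for (ds in datasets) {
    mds <- metrics[metrics$dataset == ds, , drop = FALSE]
    contemp <- mds[mds$period == spatial_period, , drop = FALSE]
    cells_by_class <- list(
      surveyed = contemp$cell_id,
      well_surveyed = contemp$cell_id[contemp[[tier_col]]])
    ivs <- mds[mds$period %in% interval_names, , drop = FALSE]
    counts_by_class <- list(
      surveyed = table(factor(ivs$period, levels = interval_names)),
      well_surveyed = table(factor(ivs$period[ivs[[tier_col]]],
                                   levels = interval_names)))
    for (g in gradient_names) {
      for (cl in classes) {
        if (g == "temporal") {
          cnt <- as.numeric(counts_by_class[[cl]])
          d <- if (sum(cnt) == 0) NA_real_ else
            temporal_d(cnt, null = temporal_null, scheme = interval_scheme)
          ns <- sum(cnt)
          nb <- length(interval_scheme)
        } else {
          ids <- cells_by_class[[cl]]
          gv <- gradients[[g]]
          sv <- gv[match(ids, gradients$cell_id)]
          sv <- sv[is.finite(sv)]
          bg <- gv[is.finite(gv)]
          d <- if (!length(ids) || !length(sv)) NA_real_ else ks_d(sv, bg)
          ns <- length(ids)
          nb <- length(bg)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = ds, gradient = g, cell_class = cl, d = d,
          n_surveyed = ns, n_background = nb, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("coverage_index", "data.frame")
  out
}

#' Default gradient groupings for coverage summaries
#'
#' Matches the reporting groups: all eleven gradients; the two spatial
#' gradients; the five contemporary environmental gradients (MAT, MAP,
#' urban, agriculture, total disturbance); the two climate-change
#' gradients. Elevation and the temporal gradient deliberately appear
#' only in the all-gradient group.
#'
#' @return Named list of gradient-name vectors.
#' @export
gradient_groups <- function() {
  list(all = audit_gradients(),
       spatial = c("latitude", "longitude"),
       environmental = c("mat", "map", "urban", "agriculture", "disturbed"),
       climate_change = c("dmap", "dmat"))
}

#' Cumulative and grouped coverage summaries
#'
#' Per dataset and cell class: the cumulative D (sum over all audited
#' gradients) and the mean D per gradient group. Optionally, per gradient:
#' mean D over dataset groups (e.g. GBIF vs standardized, terrestrial vs
#' aquatic). `NA` ("n/a") indices are excluded from sums and means; the
#' exclusions are recorded in the `excluded` attribute. Pooled and
#' per-class grand means are attached as the `grand_means` attribute.
#'
#' @param coverage A [coverage_matrix()] table.
#' @param groups Named list of gradient groups; default
#'   [gradient_groups()].
#' @param dataset_groups Optional named list of dataset-label vectors.
#' @return List with `cumulative` (dataset x class: cumulative D),
#'   `group_means` (dataset x class x group mean D), and, when
#'   `dataset_groups` is given, `gradient_means` (gradient x dataset-group
#'   x class mean D). Attributes `excluded` and `grand_means` carry the
#'   n/a bookkeeping and the overall mean D per class and pooled.
#' @export
summarize_coverage <- function(coverage, groups = gradient_groups(),
                               dataset_groups = NULL) {
  stopifnot(inherits(coverage, "coverage_index"))
  bad_groups <- unlist(lapply(groups, setdiff, y = unique(coverage$gradient)))
  if (length(bad_groups))
    stop("grouping references unaudited gradient(s): ",
         paste(unique(bad_groups), collapse = ", "), call. = FALSE)
  if (any(!vapply(groups, length, integer(1))))
    stop("empty gradient group", call. = FALSE)
  ok <- !is.na(coverage$d)
  excluded <- coverage[!ok, c("dataset", "gradient", "cell_class")]
  cc <- coverage[ok, , drop = FALSE]

  cum <- stats::aggregate(list(cumulative_d = cc$d),
                          by = list(dataset = cc$dataset,
                                    cell_class = cc$cell_class), FUN = sum)
  gm <- do.call(rbind, lapply(names(groups), function(gn) {
    sub <- cc[cc$gradient %in% groups[[gn]], , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    a <- stats::aggregate(list(mean_d = sub$d),
                          by = list(dataset = sub$dataset,
                                    cell_class = sub$cell_class), FUN = mean)
    a$group <- gn
    a
  }))
  gm <- gm[, c("dataset", "cell_class", "group", "mean_d")]
  out <- list(cumulative = cum[order(cum$dataset, cum$cell_class), ],
              group_means = gm[order(gm$dataset, gm$cell_class, gm$group), ])
  if (!is.null(dataset_groups)) {
    dgm <- do.call(rbind, lapply(names(dataset_groups), function(dn) {
      sub <- cc[cc$dataset %in% dataset_groups[[dn]], , drop = FALSE]
      if (!nrow(sub)) stop("empty dataset group '", dn, "'", call. = FALSE)
      a <- stats::aggregate(list(mean_d = sub$d),
                            by = list(gradient = sub$gradient,
                                      cell_class = sub$cell_class), FUN = mean)
      a$dataset_group <- dn
      a
    }))
    out$gradient_means <- dgm[, c("gradient", "dataset_group", "cell_class",
                                  "mean_d")]
  }
  grand <- stats::aggregate(list(mean_d = cc$d),
                            by = list(cell_class = cc$cell_class), FUN = mean)
  grand <- rbind(grand, data.frame(cell_class = "pooled", mean_d = mean(cc$d)))
  rownames(out$cumulative) <- rownames(out$group_means) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "grand_means") <- grand
  out
}

#' Paired surveyed/background histograms along a gradient
#'
#' Relative-frequency histograms of the surveyed cells and the background
#' cells on a shared equal-width binning, the tabular form of the overlap
#' plots used to localise coverage gaps along a gradient. Each frequency
#' column sums to 1.
#'
#' @param surveyed,background Numeric gradient values.
#' @param bins Number of equal-width bins over the pooled range (default
#'   20), or a numeric vector of explicit break points.
#' @return Data frame with `bin_left`, `bin_right`, `freq_surveyed`,
#'   `freq_background`.
#' @export
export_histograms <- function(surveyed, background, bins = 20) {
  surveyed <- surveyed[is.finite(surveyed)]
  background <- background[is.finite(background)]
  if (!length(surveyed) || !length(background))
    stop("both samples must be non-empty", call. = FALSE)
  if (length(bins) == 1L) {
    if (bins < 1) stop("at least one bin required", call. = FALSE)
    rng <- range(c(surveyed, background))
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  } else {
    breaks <- sort(bins)
    if (length(breaks) < 2L) stop("at least one bin required", call. = FALSE)
  }
  cut2 <- function(x) {
    b <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(b, nbins = length(breaks) - 1L)
  }
  fs <- cut2(surveyed); fb <- cut2(background)
  data.frame(bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
             freq_surveyed = fs / sum(fs), freq_background = fb / sum(fb))
}
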
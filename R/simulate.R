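#' Sampling-effort model for the occurrence simulator
#'
#' Encodes how (and how unevenly) the virtual collectors sample the
#' landscape: how many cells are visited, how many records a visited cell
#' yields (negative binomial, overdispersed like per-cell museum-record
#' effort), how strongly effort tracks an environmental gradient
#' (taxonomist/institutional bias), and how records spread over the
#' 1800-2013 calendar (categorical weights over the eleven 20-year
#' intervals).
#'
#' @param mean_effort Mean records per visited cell (> 0) at the gradient
#'   mean.
#' @param dispersion Negative-binomial size parameter; smaller is more
#'   overdispersed. `Inf` gives Poisson counts.
#' @param bias_gradient Gradient name the sampling bias acts on (any
#'   column of [landscape_gradients()], e.g. `"mat"`).
#' @param beta Bias strength: per-cell intensity is
#'   `mean_effort * exp(beta * z)` with `z` the standardized gradient
#'   value. `beta = 0` is unbiased.
#' @param visited_fraction Fraction of landscape cells visited, in (0, 1].
#' @param temporal_weights Probability weights over the intervals of
#'   `scheme` (normalized internally). Default: exponential recency bias,
#'   a long thin tail back to 1800 with most mass in recent decades.
#' @param scheme [time_periods()] scheme the weights refer to.
#' @param mode `"opportunistic"` (records drawn species-proportional to
#'   local suitability x abundance) or `"systematic"` (stratified cells,
#'   near-constant effort, sequential detection until `stop_k` consecutive
#'   draws add no new species -- a near-complete inventory protocol).
#' @param stop_k Stopping rule for systematic mode.
#' @param basis_of_record Record-type label stamped on simulated records.
#' @param coordinate_issue_rate Fraction of records flagged with a
#'   (simulated) coordinate issue.
#' @param seed Integer seed (mandatory); all simulator randomness flows
#'   from it.
#' @return Object of class `effort_model`.
#' @export
effort_model <- function(mean_effort = 50, dispersion = 1,
                         bias_gradient = "mat", beta = 0,
                         visited_fraction = 1,
                         temporal_weights = NULL,
                         scheme = time_periods("intervals"),
                         mode = c("opportunistic", "systematic"),
                         stop_k = 20L,
                         basis_of_record = "specimen",
                         coordinate_issue_rate = 0,
                         seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  mode <- match.arg(mode)
  if (mean_effort <= 0) stop("'mean_effort' must be > 0", call. = FALSE)
  if (visited_fraction <= 0 || visited_fraction > 1)
    stop("'visited_fraction' must be in (0, 1]", call. = FALSE)
  if (is.null(temporal_weights))
    temporal_weights <- exp(0.6 * (seq_along(scheme) - 1))
  if (length(temporal_weights) != length(scheme) || any(temporal_weights < 0) ||
      sum(temporal_weights) == 0)
    stop("'temporal_weights' must be non-negative, one per period",
         call. = FALSE)
  structure(list(mean_effort = mean_effort, dispersion = dispersion,
                 bias_gradient = bias_gradient, beta = beta,
                 visited_fraction = visited_fraction,
                 temporal_weights = temporal_weights / sum(temporal_weights),
                 scheme = scheme, mode = mode, stop_k = as.integer(stop_k),
                 basis_of_record = basis_of_record,
                 coordinate_issue_rate = coordinate_issue_rate,
                 seed = as.integer(seed)),
            class = "effort_model")
}

#' Opportunistic (GBIF-style) effort preset
#'
#' Heavily overdispersed per-cell effort, a configurable environmental
#' sampling bias, and a long temporal tail back to 1800. Qualitative
#' conventions, not fits to real databases.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [effort_model()].
#' @return An `effort_model`.
#' @export
effort_opportunistic <- function(seed, ...) {
  args <- list(mean_effort = 20, dispersion = 0.5, beta = 1,
               visited_fraction = 0.6, mode = "opportunistic",
               basis_of_record = "specimen", seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(effort_model, args)
}

#' Systematic (BBS/FFS-style) survey preset
#'
#' Few, stratified cells; high, near-constant per-cell effort; sequential
#' detection with a stop-after-no-new-species rule, emulating
#' near-complete inventories; all records in the most recent interval.
#'
#' @inheritParams effort_opportunistic
#' @return An `effort_model`.
#' @export
effort_systematic <- function(seed, ...) {
  scheme <- time_periods("intervals")
  w <- c(rep(0, length(scheme) - 1L), 1)
  args <- list(mean_effort = 300, dispersion = Inf, beta = 0,
               visited_fraction = 0.05, temporal_weights = w,
               mode = "systematic", stop_k = 25L,
               basis_of_record = "observation", seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(effort_model, args)
}

#' Simulate biased occurrence records over a synthetic landscape
#'
#' The virtual-ecologist generator: visited cells receive
#' negative-binomial record counts with intensity
#' `mean_effort * exp(beta * z)` (z = standardized bias-gradient value),
#' and records within a cell are drawn species-proportional to local
#' suitability x relative abundance. Suitability is a Gaussian response
#' on the niche axis truncated at 1e-6, which also defines the true
#' occupancy recorded in the truth table. Record coordinates are uniform
#' within the cell; record years follow the effort model's temporal
#' weights (uniform within the drawn interval). Deterministic given the
#' effort model's seed.
#'
#' @param landscape A [make_landscape()] object.
#' @param pool A [make_species_pool()] table; its `niche_axis` must be a
#'   gradient of the landscape.
#' @param effort An [effort_model()].
#' @param dataset Dataset label stamped on the records.
#' @return List with `records` (occurrence table: `species`,
#'   `taxon_group`, `decimal_latitude`, `decimal_longitude`, `year`,
#'   `basis_of_record`, `coordinate_issue`, `dataset`) and `truth`, a
#'   `truth_table`: per-cell true richness, the per-cell occupancy lists,
#'   and the effort model used.
#' @export
simulate_records <- function(landscape, pool, effort, dataset = "synthetic") {
  stopifnot(inherits(landscape, "landscape"), inherits(effort, "effort_model"))
  if (!is.data.frame(pool) || !nrow(pool))
    stop("empty species pool", call. = FALSE)
  grads <- landscape_gradients(landscape)
  axis <- pool$niche_axis[1]
  if (!axis %in% names(grads))
    stop("pool niche axis '", axis, "' is not a landscape gradient",
         call. = FALSE)
  if (!effort$bias_gradient %in% names(grads))
    stop("bias gradient '", effort$bias_gradient,
         "' is not a landscape gradient", call. = FALSE)
  cells <- landscape$cells
  n_cells <- nrow(cells)
  n_visit <- max(0L, round(effort$visited_fraction * n_cells))
  if (n_visit < 1L) stop("zero visited cells", call. = FALSE)

  set.seed(effort$seed)
  # suitability: cells x species Gaussian response, truncated to define
  # true occupancy
  gx <- grads[[axis]]
  suit <- exp(-0.5 * ((outer(gx, pool$niche_optimum, "-") /
                         rep(pool$niche_breadth, each = n_cells)))^2)
  suit[suit < 1e-6] <- 0
  occupancy <- lapply(seq_len(n_cells),
                      function(i) pool$species_id[suit[i, ] > 0])
  truth <- structure(list(
    cells = data.frame(cell_id = cells$cell_id,
                       true_richness = rowSums(suit > 0),
                       stringsAsFactors = FALSE),
    occupancy = stats::setNames(occupancy, cells$cell_id),
    effort = effort), class = "truth_table")

  visited <- if (effort$mode == "systematic") {
    unique(round(seq(1L, n_cells, length.out = n_visit)))
  } else {
    sort(sample.int(n_cells, n_visit))
  }
  gb <- grads[[effort$bias_gradient]]
  z <- if (stats::sd(gb) > 0) (gb - mean(gb)) / stats::sd(gb) else rep(0, n_cells)
  intensity <- effort$mean_effort * exp(effort$beta * z[visited])
  counts <- if (is.finite(effort$dispersion)) {
    stats::rnbinom(length(visited), mu = intensity, size = effort$dispersion)
  } else {
    stats::rpois(length(visited), intensity)
  }

  w_ab <- pool$abundance
  rec_cell <- integer(0)
  rec_sp <- character(0)
  for (j in seq_along(visited)) {
    ci <- visited[j]
    w <- suit[ci, ] * w_ab
    if (!any(w > 0)) next
    if (effort$mode == "systematic") {
      # sequential inventory with stop-after-stop_k-no-new-species rule
      draws <- character(0)
      seen <- character(0)
      no_new <- 0L
      max_draws <- max(10L * effort$stop_k, ceiling(10 * effort$mean_effort))
      while (no_new < effort$stop_k && length(draws) < max_draws) {
        sp <- sample(pool$species_id, 1L, prob = w)
        draws <- c(draws, sp)
        if (sp %in% seen) no_new <- no_new + 1L
        else { seen <- c(seen, sp); no_new <- 0L }
      }
      k <- length(draws)
      if (k) { rec_cell <- c(rec_cell, rep(ci, k)); rec_sp <- c(rec_sp, draws) }
    } else if (counts[j] > 0) {
      sp <- sample(pool$species_id, counts[j], replace = TRUE, prob = w)
      rec_cell <- c(rec_cell, rep(ci, counts[j]))
      rec_sp <- c(rec_sp, sp)
    }
  }
  n_rec <- length(rec_sp)
  cs <- landscape$grid$cell_size
  lon0 <- landscape$grid$origin[1]
  lat0 <- landscape$grid$origin[2]
  iv_idx <- sample.int(length(effort$scheme), n_rec, replace = TRUE,
                       prob = effort$temporal_weights)
  iv <- effort$scheme
  yr <- vapply(iv_idx, function(k) {
    p <- iv[[k]]
    as.integer(stats::runif(1, p[1], p[2] + 1))
  }, integer(1))
  tg <- pool$taxon_group[match(rec_sp, pool$species_id)]
  records <- data.frame(
    species = rec_sp,
    taxon_group = tg,
    decimal_latitude = lat0 + (cells$iy[rec_cell] + stats::runif(n_rec)) * cs,
    decimal_longitude = lon0 + (cells$ix[rec_cell] + stats::runif(n_rec)) * cs,
    year = yr,
    basis_of_record = effort$basis_of_record,
    coordinate_issue = stats::runif(n_rec) < effort$coordinate_issue_rate,
    dataset = dataset,
    stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' @export
print.truth_table <- function(x, ...) {
  cat("Truth table: ", nrow(x$cells), " cells, richness ",
      min(x$cells$true_richness), "..", max(x$cells$true_richness),
      " species\n", sep = "")
  invisible(x)
}

#' Write an occurrence table as delimited text
#'
#' Darwin-Core-like columns: species, taxon_group, decimal_latitude,
#' decimal_longitude, year, basis_of_record, coordinate_issue_flag (plus
#' dataset). The file round-trips through [read_occurrences()] with the
#' default column map.
#'
#' @param records Occurrence table (e.g. from [simulate_records()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path) {
  out <- data.frame(
    species = records$species,
    taxon_group = records$taxon_group,
    decimal_latitude = records$decimal_latitude,
    decimal_longitude = records$decimal_longitude,
    year = records$year,
    basis_of_record = records$basis_of_record,
    coordinate_issue_flag = tolower(as.character(records$coordinate_issue)),
    dataset = if ("dataset" %in% names(records)) records$dataset else "dataset",
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
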
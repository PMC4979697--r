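#' Chao2 estimated richness of a survey inventory
#'
#' Incidence-based Chao2 estimator with each occurrence record treated as
#' one sampling unit, so the incidence frequencies reduce to Q1 (species
#' with exactly one record) and Q2 (exactly two). The default is the
#' bias-corrected form,
#' \deqn{\hat S = S_{obs} + \frac{m-1}{m}\,\frac{Q_1 (Q_1 - 1)}{2 (Q_2 + 1)},}
#' with m = n sampling units; it is finite for every inventory, including
#' Q2 = 0. The classic form \eqn{S_{obs} + \frac{m-1}{m} Q_1^2 / (2 Q_2)}
#' is available for comparison and is infinite when Q2 = 0 and Q1 > 0.
#'
#' @param counts Integer vector of per-species record counts (one entry
#'   per observed species, all >= 1).
#' @param bias_corrected Use the bias-corrected form (default `TRUE`).
#' @return Estimated richness, a single number >= `length(counts)`.
#' @examples
#' chao2_richness(c(A = 1, B = 1, C = 2))  # 3 + (3/4) * 2 / 4 = 3.375
#' @export
chao2_richness <- function(counts, bias_corrected = TRUE) {
  counts <- .check_counts(counts)
  m <- sum(counts)
  s_obs <- length(counts)
  q1 <- sum(counts == 1L)
  q2 <- sum(counts == 2L)
  if (bias_corrected) {
    s_obs + (m - 1) / m * q1 * (q1 - 1) / (2 * (q2 + 1))
  } else {
    if (q2 == 0 && q1 > 0) return(Inf)
    if (q2 == 0) return(s_obs)
    s_obs + (m - 1) / m * q1^2 / (2 * q2)
  }
}

#' Completeness index of a survey inventory
#'
#' Observed richness divided by Chao2 estimated richness, in (0, 1].
#' Values near 1 indicate a near-complete species inventory for the cell.
#'
#' @inheritParams chao2_richness
#' @return `length(counts) / chao2_richness(counts)`.
#' @export
completeness_index <- function(counts, bias_corrected = TRUE) {
  counts <- .check_counts(counts)
  length(counts) / chao2_richness(counts, bias_corrected = bias_corrected)
}

#' Expected species accumulation (exact rarefaction)
#'
#' Expected richness after drawing `m` of the inventory's `n` records
#' uniformly without replacement, averaged over all orderings:
#' \deqn{E[S(m)] = S_{obs} - \sum_i \binom{n - n_i}{m} / \binom{n}{m}.}
#' Binomial coefficients are evaluated in log space so inventories with
#' thousands of records do not overflow. E[S(0)] = 0 and E[S(n)] = S_obs.
#'
#' @param counts Per-species record counts.
#' @param m Vector of subsample sizes, each in `[0, n]`.
#' @return Numeric vector of expected richness values, one per `m`.
#' @export
sac_expected_richness <- function(counts, m) {
  counts <- .check_counts(counts)
  n <- sum(counts)
  if (any(m < 0 | m > n)) stop("'m' must lie in [0, n]", call. = FALSE)
  s_obs <- length(counts)
  vapply(m, function(mm) {
    s_obs - sum(exp(lchoose(n - counts, mm) - lchoose(n, mm)))
  }, numeric(1))
}

#' Final slope of the species accumulation curve
#'
#' The expected gain in species from the last record added,
#' `E[S(n)] - E[S(n-1)]`, which reduces in closed form to `Q1 / n`: the
#' probability that a uniformly chosen last record carries a species seen
#' nowhere else. Slopes near 0 indicate the curve has reached an
#' asymptote; an inventory of all singletons has slope 1 (still rising at
#' unit rate), and a single-record inventory has slope 1.
#'
#' @param counts Per-species record counts.
#' @return The slope, a number in `[0, 1]`.
#' @export
sac_final_slope <- function(counts) {
  counts <- .check_counts(counts)
  sum(counts == 1L) / sum(counts)
}

.check_counts <- function(counts) {
  if (length(counts) == 0)
    stop("empty inventory: at least one species count required", call. = FALSE)
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 1) || any(counts != round(counts)))
    stop("'counts' must be positive integers (records per species)",
         call. = FALSE)
  counts
}

#' Well-surveyed classification thresholds
#'
#' Conjunctive thresholds on the three completeness metrics at three
#' tiers. Defaults: low = at least 10 records, completeness >= 0.6, final
#' slope <= 0.15; moderate = 25 / 0.7 / 0.10; high = 50 / 0.8 / 0.05.
#' Comparisons are inclusive. Thresholds must be monotone across tiers so
#' that passing a stricter tier implies passing every looser one.
#'
#' @param min_records Integer vector (low, moderate, high).
#' @param min_completeness Numeric vector (low, moderate, high).
#' @param max_slope Numeric vector (low, moderate, high).
#' @return Data frame of class `threshold_set` with one row per tier.
#' @export
threshold_set <- function(min_records = c(10L, 25L, 50L),
                          min_completeness = c(0.6, 0.7, 0.8),
                          max_slope = c(0.15, 0.10, 0.05)) {
  stopifnot(length(min_records) == 3L, length(min_completeness) == 3L,
            length(max_slope) == 3L)
  if (is.unsorted(min_records) || is.unsorted(min_completeness) ||
      is.unsorted(rev(max_slope)))
    stop("thresholds must be monotone across tiers (low <= moderate <= high ",
         "stringency)", call. = FALSE)
  out <- data.frame(tier = c("low", "moderate", "high"),
                    min_records = as.numeric(min_records),
                    min_completeness = as.numeric(min_completeness),
                    max_slope = as.numeric(max_slope),
                    stringsAsFactors = FALSE)
  class(out) <- c("threshold_set", "data.frame")
  out
}

#' Completeness metrics for every survey inventory
#'
#' Computes, per (dataset, period, cell): the record count n, observed
#' richness, Chao2 estimated richness, the completeness index C and the
#' final accumulation-curve slope, then classifies each survey at the
#' three threshold tiers (see [classify_cells()]).
#'
#' @param inventories A [build_inventories()] table.
#' @param thresholds A [threshold_set()].
#' @param bias_corrected Passed to [chao2_richness()].
#' @return Data frame of class `completeness_metrics` with columns
#'   `dataset`, `period`, `cell_id`, `n_records`, `s_obs`, `chao2_s_hat`,
#'   `completeness`, `final_slope`, `pass_low`, `pass_moderate`,
#'   `pass_high`.
#' @export
survey_completeness <- function(inventories, thresholds = threshold_set(),
                                bias_corrected = TRUE) {
  st <- inventory_stats(inventories)
  n <- st$n
  q1 <- st$q1
  q2 <- st$q2
  s_hat <- if (bias_corrected) {
    st$s_obs + ifelse(n > 0, (n - 1) / pmax(n, 1), 0) * q1 * (q1 - 1) / (2 * (q2 + 1))
  } else {
    ifelse(q2 == 0 & q1 > 0, Inf,
           st$s_obs + (n - 1) / pmax(n, 1) * q1^2 / (2 * pmax(q2, 1)))
  }
  out <- data.frame(dataset = st$dataset, period = st$period,
                    cell_id = st$cell_id,
                    n_records = st$n, s_obs = st$s_obs,
                    chao2_s_hat = s_hat,
                    completeness = st$s_obs / s_hat,
                    final_slope = q1 / pmax(n, 1),
                    stringsAsFactors = FALSE)
  out <- classify_cells(out, thresholds)
  class(out) <- c("completeness_metrics", "data.frame")
  out
}

#' Classify surveys as well-surveyed at each threshold tier
#'
#' A survey passes a tier iff all three criteria hold: record count at or
#' above the tier minimum, completeness index at or above the tier
#' minimum, and final slope at or below the tier maximum. Monotone
#' thresholds guarantee tier nesting (high implies moderate implies low).
#'
#' @param metrics Data frame with `n_records`, `completeness`,
#'   `final_slope` columns (e.g. from [survey_completeness()]).
#' @param thresholds A [threshold_set()].
#' @return `metrics` with logical `pass_low`, `pass_moderate`, `pass_high`
#'   columns (re)computed.
#' @export
classify_cells <- function(metrics, thresholds = threshold_set()) {
  stopifnot(inherits(thresholds, "threshold_set"),
            all(c("n_records", "completeness", "final_slope") %in% names(metrics)))
  for (i in seq_len(nrow(thresholds))) {
    tier <- thresholds$tier[i]
    metrics[[paste0("pass_", tier)]] <-
      metrics$n_records >= thresholds$min_records[i] &
      metrics$completeness >= thresholds$min_completeness[i] &
      metrics$final_slope <= thresholds$max_slope[i]
  }
  metrics
}

#' Tabulate surveyed and well-surveyed cells per dataset and period
#'
#' Survey-audit summary table: per dataset and period, the number of
#' surveyed cells (and their percentage of all background cells) and the
#' number of well-surveyed cells at each tier (as a percentage of the
#' surveyed cells).
#'
#' @param metrics A [survey_completeness()] table.
#' @param n_background Number of background (study-region) cells; must be
#'   at least the surveyed-cell count.
#' @return Data frame with one row per dataset x period.
#' @export
completeness_summary <- function(metrics, n_background) {
  if (!is.numeric(n_background) || n_background < 1)
    stop("'n_background' must be a positive cell count", call. = FALSE)
  if (!nrow(metrics)) {
    return(data.frame(dataset = character(), period = character(),
                      n_surveyed = integer(), pct_surveyed = numeric(),
                      n_low = integer(), pct_low = numeric(),
                      n_moderate = integer(), pct_moderate = numeric(),
                      n_high = integer(), pct_high = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- list(dataset = metrics$dataset, period = metrics$period)
  agg <- stats::aggregate(list(n_surveyed = rep(1L, nrow(metrics)),
                               n_low = metrics$pass_low,
                               n_moderate = metrics$pass_moderate,
                               n_high = metrics$pass_high),
                          by = key, FUN = sum)
  if (any(agg$n_surveyed > n_background))
    stop("surveyed cells exceed 'n_background'", call. = FALSE)
  pct <- function(x, denom) {
    out <- 100 * x / denom
    out[!is.finite(out)] <- 0
    out
  }
  out <- data.frame(agg[c("dataset", "period", "n_surveyed")],
                    pct_surveyed = pct(agg$n_surveyed, n_background),
                    n_low = as.integer(agg$n_low),
                    pct_low = pct(agg$n_low, agg$n_surveyed),
                    n_moderate = as.integer(agg$n_moderate),
                    pct_moderate = pct(agg$n_moderate, agg$n_surveyed),
                    n_high = as.integer(agg$n_high),
                    pct_high = pct(agg$n_high, agg$n_surveyed),
                    stringsAsFactors = FALSE)
  out[order(out$dataset, out$period), ]
}
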
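#' Audit occurrence records for completeness and coverage
#'
#' The end-to-end audit: screens the records ([filter_records()]), bins
#' them into grid cells ([assign_cells()]), builds survey inventories for
#' the complete (1800-2013), contemporary (1990-2013) and eleven-interval
#' period schemes ([build_inventories()]), scores every inventory with
#' the three completeness metrics and classifies it at the three
#' threshold tiers ([survey_completeness()]), then computes K-S D
#' coverage indices against the background landscape
#' ([coverage_matrix()]) with cumulative and grouped summaries
#' ([summarize_coverage()]) and paired surveyed/background histograms.
#'
#' @param records Occurrence table ([read_occurrences()] or
#'   [simulate_records()]); may hold several datasets via its `dataset`
#'   column.
#' @param grid The survey [grid_spec()]; its mask (or extent) defines the
#'   background cells.
#' @param gradients Per-cell gradient table ([join_gradients()] or
#'   [landscape_gradients()]).
#' @param criteria Record screen, a [filter_criteria()].
#' @param thresholds A [threshold_set()].
#' @param tier Well-surveyed tier used by the coverage stage (default
#'   `"moderate"`).
#' @param gradient_names Gradients to audit (default [audit_gradients()]).
#' @param histogram_bins Bins for the exported histograms (default 20).
#' @return Object of class `survey_audit`: list with `filter_report`,
#'   `n_dropped` (out-of-region records), `inventories`, `metrics`,
#'   `completeness`, `coverage`, `coverage_summary`, `histograms`,
#'   `n_background`, `thresholds`, `tier`, `grid`.
#' @examples
#' land <- make_landscape(12, 8, seed = 1)
#' pool <- make_species_pool(30, seed = 2)
#' sim <- simulate_records(land, pool, effort_opportunistic(seed = 3))
#' aud <- survey_audit(sim$records, land$grid, landscape_gradients(land))
#' aud
#' @export
survey_audit <- function(records, grid, gradients,
                         criteria = filter_criteria(),
                         thresholds = threshold_set(),
                         tier = "moderate",
                         gradient_names = audit_gradients(),
                         histogram_bins = 20) {
  stopifnot(inherits(grid, "grid_spec"), inherits(gradients, "cell_gradients"))
  filt <- filter_records(records, criteria)
  rc <- assign_cells(filt$records, grid)
  scheme <- time_periods(c(time_periods("complete"),
                           time_periods("contemporary"),
                           time_periods("intervals")))
  inventories <- build_inventories(rc, scheme)
  metrics <- survey_completeness(inventories, thresholds)
  n_bg <- n_background_cells(grid)
  completeness <- completeness_summary(metrics, n_bg)
  coverage <- coverage_matrix(metrics, gradients,
                              gradient_names = gradient_names, tier = tier)
  cov_summary <- summarize_coverage(coverage)
  histograms <- .audit_histograms(metrics, gradients, gradient_names, tier,
                                  histogram_bins)
  out <- list(filter_report = filt$report,
              n_dropped = attr(rc, "dropped"),
              inventories = inventories,
              metrics = metrics,
              completeness = completeness,
              coverage = coverage,
              coverage_summary = cov_summary,
              histograms = histograms,
              n_background = n_bg,
              thresholds = thresholds,
              tier = tier,
              grid = grid)
  class(out) <- "survey_audit"
  out
}

.audit_histograms <- function(metrics, gradients, gradient_names, tier,
                              bins) {
  tier_col <- paste0("pass_", tier)
  numeric_grads <- setdiff(gradient_names, "temporal")
  contemp <- metrics[metrics$period == "contemporary", , drop = FALSE]
  rows <- list()
  for (ds in sort(unique(metrics$dataset))) {
    mds <- contemp[contemp$dataset == ds, , drop = FALSE]
    for (cl in c("surveyed", "well_surveyed")) {
      ids <- if (cl == "surveyed") mds$cell_id else mds$cell_id[mds[[tier_col]]]
      if (!length(ids)) next
      for (g in numeric_grads) {
        gv <- gradients[[g]]
        sv <- gv[match(ids, gradients$cell_id)]
        sv <- sv[is.finite(sv)]
        if (!length(sv)) next
        h <- export_histograms(sv, gv, bins = bins)
        h$dataset <- ds; h$gradient <- g; h$cell_class <- cl
        rows[[length(rows) + 1L]] <- h
      }
    }
  }
  if (!length(rows))
    return(data.frame(dataset = character(), gradient = character(),
                      cell_class = character(), bin_left = numeric(),
                      bin_right = numeric(), freq_surveyed = numeric(),
                      freq_background = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[, c("dataset", "gradient", "cell_class", "bin_left", "bin_right",
          "freq_surveyed", "freq_background")]
}

#' @export
print.survey_audit <- function(x, ...) {
  fr <- x$filter_report
  cat("Occurrence survey audit\n")
  cat("  records: ", fr[["input"]], " in, ", fr[["retained"]],
      " retained after screening, ", x$n_dropped,
      " outside the study region\n", sep = "")
  cat("  background cells: ", x$n_background, "\n", sep = "")
  comp <- x$completeness[x$completeness$period == "complete", , drop = FALSE]
  for (i in seq_len(nrow(comp))) {
    cat(sprintf(
      "  %s (complete period): %d cells surveyed (%.1f%%); well-surveyed %.1f%% / %.1f%% / %.1f%% (low/mod/high)\n",
      comp$dataset[i], comp$n_surveyed[i], comp$pct_surveyed[i],
      comp$pct_low[i], comp$pct_moderate[i], comp$pct_high[i]))
  }
  gm <- attr(x$coverage_summary, "grand_means")
  if (!is.null(gm)) {
    pm <- gm$mean_d[gm$cell_class == "pooled"]
    cat(sprintf("  mean coverage D over %d indices: %.2f\n",
                sum(!is.na(x$coverage$d)), pm))
  }
  invisible(x)
}

#' @export
summary.survey_audit <- function(object, ...) {
  out <- list(filter_report = object$filter_report,
              completeness = object$completeness,
              coverage = .coverage_wide(object$coverage),
              cumulative_d = object$coverage_summary$cumulative,
              group_means = object$coverage_summary$group_means,
              grand_means = attr(object$coverage_summary, "grand_means"),
              tier = object$tier)
  class(out) <- "summary.survey_audit"
  out
}

#' @export
print.summary.survey_audit <- function(x, ...) {
  cat("Filter report:\n")
  print(x$filter_report)
  cat("\nSurveyed / well-surveyed cells per dataset and period:\n")
  print(x$completeness, row.names = FALSE, digits = 3)
  cat("\nCoverage D indices (well-surveyed tier: ", x$tier, "):\n", sep = "")
  print(x$coverage, row.names = FALSE)
  cat("\nCumulative D per dataset:\n")
  print(x$cumulative_d, row.names = FALSE, digits = 3)
  cat("\nMean D across all indices:\n")
  print(x$grand_means, row.names = FALSE, digits = 3)
  invisible(x)
}

# wide Table-2-style layout: rows dataset x class, one column per gradient,
# "n/a" for undefined indices
.coverage_wide <- function(coverage) {
  grads <- unique(coverage$gradient)
  keys <- unique(coverage[c("dataset", "cell_class")])
  out <- keys
  for (g in grads) {
    sub <- coverage[coverage$gradient == g, , drop = FALSE]
    m <- match(paste(keys$dataset, keys$cell_class),
               paste(sub$dataset, sub$cell_class))
    v <- sub$d[m]
    out[[g]] <- ifelse(is.na(v), "n/a", formatC(v, digits = 2, format = "f"))
  }
  rownames(out) <- NULL
  out
}

#' Plot paired surveyed/background histograms from an audit
#'
#' Overlapping relative-frequency histograms of one gradient for one
#' dataset: background cells as hollow bars, surveyed (or well-surveyed)
#' cells shaded, with the D index in the title.
#'
#' @param x A [survey_audit()] object.
#' @param gradient Gradient name (default `"mat"`).
#' @param dataset Dataset label; default the first audited.
#' @param cell_class `"surveyed"` (default) or `"well_surveyed"`.
#' @param ... Passed to [graphics::barplot()].
#' @return The histogram table used, invisibly.
#' @export
plot.survey_audit <- function(x, gradient = "mat", dataset = NULL,
                              cell_class = "surveyed", ...) {
  h <- x$histograms
  if (is.null(dataset)) dataset <- h$dataset[1]
  h <- h[h$dataset == dataset & h$gradient == gradient &
           h$cell_class == cell_class, , drop = FALSE]
  if (!nrow(h)) stop("no histogram for that dataset/gradient/class",
                     call. = FALSE)
  d <- x$coverage$d[x$coverage$dataset == dataset &
                      x$coverage$gradient == gradient &
                      x$coverage$cell_class == cell_class]
  mids <- (h$bin_left + h$bin_right) / 2
  hm <- rbind(background = h$freq_background, surveyed = h$freq_surveyed)
  graphics::barplot(hm, beside = TRUE, names.arg = signif(mids, 3),
                    col = c("white", "grey40"),
                    xlab = gradient, ylab = "relative frequency",
                    main = sprintf("%s: %s (D = %.2f)", dataset, gradient, d),
                    ...)
  graphics::legend("topright", fill = c("white", "grey40"),
                   legend = c("background", cell_class), bty = "n")
  invisible(h)
}
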
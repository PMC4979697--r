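test_that("K-S D matches hand cases and the brute-force sup", {
  expect_equal(ks_d(c(1, 2, 2, 3), c(1, 2, 2, 3)), 0)
  expect_equal(ks_d(1:3, 11:14), 1)  # disjoint supports
  expect_equal(ks_d(1:4, 1:8), 0.5)  # sup attained at x = 4
  expect_error(ks_d(numeric(0), 1:3), "non-empty")
  set.seed(5)
  for (i in 1:100) {
    x <- sample(1:20, sample(1:30, 1), replace = TRUE)  # ties guaranteed
    y <- sample(1:20, sample(1:30, 1), replace = TRUE)
    expect_equal(ks_d(x, y), ks_oracle(x, y), tolerance = 1e-12)
  }
  # cross-check against stats::ks.test on tie-free samples
  for (i in 1:20) {
    x <- rnorm(40); y <- rnorm(25, 0.5)
    expect_equal(ks_d(x, y),
                 unname(stats::ks.test(x, y)$statistic), tolerance = 1e-12)
  }
})

test_that("temporal D compares interval counts to the uniform null", {
  expect_equal(temporal_d(rep(7, 11)), 0)
  expect_equal(temporal_d(c(100, rep(0, 10))), 10 / 11)
  expect_equal(temporal_d(c(rep(0, 10), 100)), 10 / 11)
  expect_error(temporal_d(rep(0, 11)), "positive total")
  # duration-proportional null weights the 14-year interval 14/214
  d <- temporal_d(c(rep(20, 10), 14), null = "duration")
  expect_equal(d, 0, tolerance = 1e-12)
})

test_that("zonal percentages count pixels within aligned cells", {
  g <- grid_spec(cell_size = 0.1, origin = c(0, 0), extent = c(0, 0.2, 0, 0.1))
  # 2x2 pixels per cell (res 0.05); cell 1 all urban class 22,
  # cell 2 mixed {21, 81, 41, 41}
  vals <- matrix(c(22, 22, 22, 22, 21, 81, 41, 41), nrow = 2)
  r <- simple_raster(vals, xmin = 0, ymin = 0, res = 0.05)
  zp <- zonal_percent(r, g)
  zp <- zp[order(zp$cell_id), ]
  expect_equal(zp$urban, c(100, 25))
  expect_equal(zp$agriculture, c(0, 25))
  # empty class set -> 0 everywhere
  z0 <- zonal_percent(r, g, class_sets = list(none = integer(0)))
  expect_equal(z0$none, c(0, 0))
  bad <- simple_raster(vals, xmin = 0, ymin = 0, res = 0.03)
  expect_error(zonal_percent(bad, g), "align")
})

test_that("gradient joining aggregates rasters and round-trips landscapes", {
  g <- grid_spec(cell_size = 0.1, origin = c(0, 0), extent = c(0, 1, 0, 0.5))
  const <- simple_raster(matrix(4.2, nrow = 10, ncol = 20),
                         xmin = 0, ymin = 0, res = 0.05)
  out <- join_gradients(g, continuous = list(flat = const))
  expect_equal(out$flat, rep(4.2, 50))
  expect_equal(sort(unique(out$latitude)), seq(0.05, 0.45, by = 0.1))

  # 10x finer linear field: cell mean equals the trend at the cell center
  px <- seq(0.005, 0.995, by = 0.01)
  lin <- simple_raster(matrix(rep(3 * px, each = 50), nrow = 50),
                       xmin = 0, ymin = 0, res = 0.01)
  out2 <- join_gradients(g, continuous = list(trend = lin))
  expect_equal(out2$trend, 3 * out2$longitude, tolerance = 1e-9)

  # identity path from the synthetic landscape
  fx <- fixture_sim()
  grads <- join_gradients(fx$land$grid,
                          continuous = list(mat = data.frame(
                            cell_id = fx$land$cells$cell_id,
                            mat = fx$land$cells$mat)))
  expect_equal(grads$mat, fx$gradients$mat[match(grads$cell_id,
                                                 fx$gradients$cell_id)])

  # a mostly-missing gradient is a misconfiguration
  short <- data.frame(cell_id = fx$land$cells$cell_id[1:3],
                      v = 1:3)
  expect_error(join_gradients(fx$land$grid, continuous = list(v = short)),
               "missing")
})

test_that("landscape gradients satisfy the table invariants", {
  fx <- fixture_sim()
  gr <- fx$gradients
  expect_equal(nrow(gr), nrow(fx$land$cells))
  expect_true(all(gr$urban >= 0 & gr$urban <= 100))
  expect_true(all(gr$agriculture >= 0 & gr$agriculture <= 100))
  expect_equal(gr$disturbed, gr$urban + gr$agriculture, tolerance = 1e-9)
})

test_that("coverage indices are zero when every background cell is surveyed", {
  fx <- fixture_sim()
  cells <- fx$land$cells$cell_id
  metrics <- data.frame(dataset = "d", period = "contemporary",
                        cell_id = cells, n_records = 100,
                        completeness = 1, final_slope = 0,
                        stringsAsFactors = FALSE)
  metrics <- classify_cells(metrics)
  cov <- coverage_matrix(metrics, fx$gradients)
  spatial <- cov[cov$gradient != "temporal", ]
  expect_equal(nrow(cov), 22L)  # 11 gradients x 2 classes
  expect_true(all(spatial$d == 0))
  # temporal is n/a: no interval-period surveys in this constructed table
  expect_true(all(is.na(cov$d[cov$gradient == "temporal"])))
  expect_error(coverage_matrix(metrics, fx$gradients,
                               gradient_names = c("mat", "nope")), "unknown")
})

test_that("an empty well-surveyed class is reported n/a, not zero", {
  fx <- fixture_sim()
  cells <- fx$land$cells$cell_id[1:10]
  metrics <- classify_cells(data.frame(
    dataset = "crayfishlike", period = "contemporary", cell_id = cells,
    n_records = 3, completeness = 1, final_slope = 0.4,
    stringsAsFactors = FALSE))
  cov <- coverage_matrix(metrics, fx$gradients)
  ws <- cov[cov$cell_class == "well_surveyed" & cov$gradient != "temporal", ]
  expect_true(all(is.na(ws$d)))
  expect_true(all(ws$n_surveyed == 0))
  sv <- cov[cov$cell_class == "surveyed" & cov$gradient != "temporal", ]
  expect_true(all(!is.na(sv$d)))
})

test_that("coverage summaries aggregate exactly", {
  # one dataset, D = 0.1 on all 11 gradients -> cumulative 1.1, means 0.1
  cov <- data.frame(dataset = "d1", gradient = audit_gradients(),
                    cell_class = "surveyed", d = 0.1,
                    n_surveyed = 5L, n_background = 10L,
                    stringsAsFactors = FALSE)
  class(cov) <- c("coverage_index", "data.frame")
  s <- summarize_coverage(cov)
  expect_equal(s$cumulative$cumulative_d, 1.1)
  expect_equal(unique(s$group_means$mean_d), 0.1)
  expect_equal(attr(s, "grand_means")$mean_d,
               c(0.1, 0.1))  # surveyed class and pooled

  # two datasets with known D vectors: hand-computed group means
  cov2 <- rbind(cov, within(cov, {dataset <- "d2"; d <- 0.3}))
  class(cov2) <- c("coverage_index", "data.frame")
  s2 <- summarize_coverage(
    cov2, dataset_groups = list(both = c("d1", "d2"), solo = "d2"))
  expect_equal(s2$cumulative$cumulative_d, c(1.1, 3.3))
  gmat <- s2$gradient_means
  expect_equal(unique(gmat$mean_d[gmat$dataset_group == "both"]), 0.2)
  expect_equal(unique(gmat$mean_d[gmat$dataset_group == "solo"]), 0.3)

  # a constant 264-entry table has that constant as its grand mean
  big <- expand.grid(dataset = sprintf("ds%02d", 1:12),
                     gradient = audit_gradients(),
                     cell_class = c("surveyed", "well_surveyed"),
                     stringsAsFactors = FALSE)
  big$d <- 0.26; big$n_surveyed <- 4L; big$n_background <- 9L
  class(big) <- c("coverage_index", "data.frame")
  gm <- attr(summarize_coverage(big), "grand_means")
  expect_equal(gm$mean_d[gm$cell_class == "pooled"], 0.26)

  # n/a rows are excluded from means and logged
  cov3 <- cov
  cov3$d[cov3$gradient == "mat"] <- NA
  class(cov3) <- c("coverage_index", "data.frame")
  s3 <- summarize_coverage(cov3)
  expect_equal(s3$cumulative$cumulative_d, 1.0)
  expect_equal(attr(s3, "excluded")$gradient, "mat")
  expect_error(summarize_coverage(cov, groups = list(bad = "nope")),
               "unaudited")
})

test_that("histogram export is normalized and approximates D at fine bins", {
  x <- rnorm(200)
  h <- export_histograms(x, x, bins = 13)
  expect_equal(h$freq_surveyed, h$freq_background)
  expect_equal(sum(h$freq_surveyed), 1, tolerance = 1e-12)
  expect_equal(sum(h$freq_background), 1, tolerance = 1e-12)
  expect_error(export_histograms(x, x, bins = 0), "bin")

  set.seed(9)
  a <- rnorm(150); b <- rnorm(200, 0.8)
  hf <- export_histograms(a, b, bins = 1500)
  d_binned <- max(abs(cumsum(hf$freq_surveyed) - cumsum(hf$freq_background)))
  expect_lt(abs(d_binned - ks_d(a, b)), 2 / min(length(a), length(b)))
})

test_that("unbiased subsets drift toward the background as they grow", {
  # under unbiased sampling, the expected D of a random surveyed subset
  # shrinks with subset size
  land <- make_landscape(100, 80, seed = 401)   # 8,000 background cells
  mat_bg <- land$cells$mat
  mean_d <- vapply(c(50L, 500L, 5000L), function(k) {
    mean(vapply(1:20, function(r) {
      set.seed(400 + 17 * k + r)
      ks_d(sample(mat_bg, k), mat_bg)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_d) < 0))
})

test_that("ascii grids round-trip through the raster container", {
  r <- simple_raster(matrix(c(1.5, NA, 3, 4, 5, 6), nrow = 2),
                     xmin = -10, ymin = 40, res = 0.5)
  p <- tempfile(fileext = ".asc")
  write_ascii_grid(r, p)
  back <- read_ascii_grid(p)
  expect_equal(back$values, r$values)
  expect_equal(back$xmin, r$xmin, ignore_attr = TRUE)
  expect_equal(back$res, r$res, ignore_attr = TRUE)
})
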
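test_that("landscapes are valid, seeded, and honour the configured MAT lapse", {
  one <- make_landscape(1, 1, seed = 7)
  expect_equal(nrow(one$cells), 1L)
  lc <- as.matrix(one$cells[grep("^lc_", names(one$cells))])
  expect_equal(unname(rowSums(lc)), 1, tolerance = 1e-12)

  a <- make_landscape(20, 10, seed = 7)
  b <- make_landscape(20, 10, seed = 7)
  expect_identical(a, b)
  lcs <- as.matrix(a$cells[grep("^lc_", names(a$cells))])
  expect_true(all(lcs >= 0))
  expect_equal(unname(rowSums(lcs)), rep(1, 200), tolerance = 1e-12)
  expect_true(all(is.finite(as.matrix(
    a$cells[c("elevation", "mat", "map", "dmat", "dmap")]))))

  # with noise (and the elevation coupling) off, MAT is exactly linear in
  # latitude: regression recovers the lapse per 0.1 degree
  p <- landscape_params(mat = list(base = 18, lat_lapse = -0.5,
                                   elevation_lapse = 0, noise_sd = 0))
  land <- make_landscape(20, 10, p, seed = 1)
  fit <- lm(mat ~ lat, data = land$cells)
  expect_equal(unname(coef(fit)[2]) * 0.1, -0.5, tolerance = 1e-9)

  expect_error(make_landscape(0, 5, seed = 1), ">= 1")
  expect_error(make_landscape(5, 5), "seed")
})

test_that("species pools are normalized for every abundance distribution", {
  single <- make_species_pool(1, seed = 0)
  expect_equal(single$abundance, 1.0)

  ls <- make_species_pool(100, sad = "logseries",
                          sad_params = list(theta = 0.9), seed = 3)
  expect_equal(sum(ls$abundance), 1, tolerance = 1e-12)
  expect_equal(nrow(ls), 100L)
  expect_true(all(diff(ls$abundance) <= 0))
  expect_true(all(ls$abundance > 0))
  expect_true(all(ls$niche_breadth > 0))

  un <- make_species_pool(100, sad = "uniform", seed = 3)
  expect_equal(un$abundance, rep(0.01, 100))

  ln <- make_species_pool(40, sad = "lognormal", seed = 3)
  expect_equal(sum(ln$abundance), 1, tolerance = 1e-12)

  expect_error(make_species_pool(10, sad = "zipf", seed = 1))
  expect_error(make_species_pool(0, seed = 1), ">= 1")
})

test_that("unbiased Poisson effort yields the expected record total", {
  land <- make_landscape(20, 10, seed = 5)   # 200 cells
  pool <- make_species_pool(30, seed = 6)
  eff <- effort_model(mean_effort = 50, dispersion = Inf, beta = 0,
                      visited_fraction = 1, seed = 11)
  sim <- simulate_records(land, pool, eff)
  # Poisson-sum oracle: total ~ Poisson(200 * 50), 3 SE band
  expect_lt(abs(nrow(sim$records) - 200 * 50), 3 * sqrt(200 * 50))
})

test_that("temporal weights confine record years to their intervals", {
  land <- make_landscape(6, 6, seed = 1)
  pool <- make_species_pool(10, seed = 2)
  w <- c(rep(0, 10), 1)  # all mass on 2000-2013
  eff <- effort_model(mean_effort = 20, temporal_weights = w, seed = 3)
  sim <- simulate_records(land, pool, eff)
  expect_true(all(sim$records$year >= 2000 & sim$records$year <= 2013))
  w2 <- c(1, rep(0, 10))
  eff2 <- effort_model(mean_effort = 20, temporal_weights = w2, seed = 3)
  sim2 <- simulate_records(land, pool, eff2)
  expect_true(all(sim2$records$year >= 1800 & sim2$records$year <= 1819))
})

test_that("strong effort bias makes record counts track the biased gradient", {
  land <- make_landscape(20, 10, seed = 21)
  pool <- make_species_pool(30, seed = 22)
  eff <- effort_model(mean_effort = 10, beta = 3, bias_gradient = "mat",
                      visited_fraction = 1, seed = 23)
  sim <- simulate_records(land, pool, eff)
  rc <- assign_cells(sim$records, land$grid)
  per_cell <- table(factor(rc$cell_id, levels = land$cells$cell_id))
  rho <- cor(land$cells$mat, as.numeric(per_cell), method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("simulated records are consistent with the truth table", {
  fx <- fixture_sim()
  sim <- fx$sim
  # determinism: identical inputs and seed give identical output
  eff <- effort_opportunistic(seed = 103, mean_effort = 30,
                              visited_fraction = 0.8)
  again <- simulate_records(fx$land, fx$pool, eff, dataset = "fix")
  expect_identical(sim$records, again$records)

  # conservation: every record's species occupies its cell in truth
  rc <- assign_cells(sim$records, fx$land$grid)
  occ <- sim$truth$occupancy
  ok <- mapply(function(sp, cid) sp %in% occ[[cid]], rc$species, rc$cell_id)
  expect_true(all(ok))
  expect_equal(sim$truth$cells$true_richness,
               lengths(occ[sim$truth$cells$cell_id]), ignore_attr = TRUE)

  # records carry cell-interior coordinates and the stamped metadata
  expect_true(all(sim$records$decimal_latitude >=
                    min(fx$land$cells$lat) - 0.05))
  expect_true(all(sim$records$basis_of_record == "specimen"))

  expect_error(simulate_records(fx$land, fx$pool[0, ],
                                effort_model(seed = 1)), "empty")
  expect_error(effort_model(visited_fraction = 0, seed = 1), "\\(0, 1\\]")
  expect_error(effort_model(mean_effort = 0, seed = 1), "> 0")
})

test_that("the systematic preset yields near-complete inventories on few cells", {
  land <- make_landscape(10, 10, seed = 31)
  pool <- make_species_pool(20, seed = 32)
  sim <- simulate_records(land, pool, effort_systematic(seed = 33),
                          dataset = "bbs")
  rc <- assign_cells(sim$records, land$grid)
  cells <- unique(rc$cell_id)
  expect_lte(length(cells), 6L)  # 5% of 100 cells visited
  # inventories are near-complete: observed richness ~ true occupancy
  inv <- build_inventories(rc, "contemporary")
  st <- inventory_stats(inv)
  truth_s <- sim$truth$cells$true_richness[
    match(st$cell_id, sim$truth$cells$cell_id)]
  # abundance-proportional detection leaves only the rare tail undetected
  expect_gt(mean(st$s_obs / truth_s), 0.75)
  expect_true(all(st$s_obs / truth_s > 0.5))
  expect_true(all(sim$records$year >= 2000))

  # at comparable record totals, the systematic protocol yields a far
  # higher well-surveyed percentage than opportunistic collecting
  opp <- simulate_records(land, pool,
                          effort_opportunistic(seed = 34, mean_effort = 15),
                          dataset = "gbifish")
  pct_ws <- function(recs) {
    m <- survey_completeness(build_inventories(
      assign_cells(recs, land$grid), "complete"))
    100 * mean(m$pass_moderate)
  }
  expect_gt(pct_ws(sim$records), pct_ws(opp$records))
})

test_that("occurrence files round-trip through the reader", {
  fx <- fixture_sim()
  p <- tempfile(fileext = ".csv")
  write_occurrences(fx$sim$records, p)
  back <- read_occurrences(p)
  expect_equal(nrow(back), nrow(fx$sim$records))
  expect_equal(back$species, fx$sim$records$species)
  expect_equal(back$year, as.integer(fx$sim$records$year))
  expect_equal(back$decimal_latitude, fx$sim$records$decimal_latitude,
               tolerance = 1e-12)
  expect_false(any(back$invalid_coordinate))
})
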
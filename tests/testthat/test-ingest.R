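test_that("occurrence files are read with invalid rows retained and flagged", {
  p <- write_occ_fixture(c(
    "Aus bus,insects,40.05,-100.05,1991,specimen,false",
    "Aus bus,insects,40.05,-100.04,1992,specimen,false",
    "Cus dus,insects,40.05,-100.03,2001,specimen,true"))
  tab <- read_occurrences(p)
  expect_equal(nrow(tab), 3L)
  expect_equal(sum(tab$coordinate_issue), 1L)

  # header only: empty table, no error
  empty <- read_occurrences(write_occ_fixture(character(0)))
  expect_equal(nrow(empty), 0L)

  # out-of-bounds latitude and unparseable year flagged, not dropped
  p2 <- write_occ_fixture(c(
    "Aus bus,insects,91.0,-100.05,1991,specimen,false",
    "Aus bus,insects,40.0,-100.05,abc,specimen,false"))
  tab2 <- read_occurrences(p2)
  expect_equal(nrow(tab2), 2L)
  expect_true(tab2$invalid_coordinate[1])
  expect_true(tab2$invalid_year[2])

  # missing mandatory column names the column
  p3 <- tempfile(fileext = ".csv")
  writeLines(c("species,decimal_latitude,year", "a,1,2000"), p3)
  expect_error(read_occurrences(p3), "decimal_longitude")
})

test_that("tab-delimited input is sniffed and custom maps apply", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("sp\tdecimalLatitude\tdecimalLongitude\tyr",
               "Aus bus\t40.05\t-100.05\t1991"), p)
  tab <- read_occurrences(p, occ_column_map(species = "sp",
                                            latitude = "decimalLatitude",
                                            longitude = "decimalLongitude",
                                            year = "yr"))
  expect_equal(tab$year, 1991L)
  expect_equal(tab$decimal_longitude, -100.05)
  expect_error(occ_column_map(nope = "x"), "unknown")
})

test_that("record screening applies rules in fixed order and accounts for every row", {
  rec <- data.frame(
    species = letters[1:10],
    decimal_latitude = rep(40, 10),
    decimal_longitude = rep(-100, 10),
    year = c(1799L, 1799L, 1800L, 2013L, 2014L, rep(1991L, 5L)),
    basis_of_record = c(rep("specimen", 8L), "Observation", "SPECIMEN"),
    coordinate_issue = c(TRUE, rep(FALSE, 9L)),
    taxon_rank = c(rep("species", 9L), "genus"),
    stringsAsFactors = FALSE)
  out <- filter_records(rec)
  rep_ <- out$report
  # row 1 violates both issue and year rules; it is charged to the first
  expect_equal(unname(rep_["coordinate_issue"]), 1L)
  expect_equal(unname(rep_["year"]), 2L)     # 1799 and 2014; 1800/2013 kept
  expect_equal(unname(rep_["rank"]), 1L)     # the genus row (row 10)
  expect_equal(unname(rep_["record_type"]), 1L) # Observation; SPECIMEN kept
  expect_equal(unname(rep_["input"]),
               unname(rep_["retained"]) + sum(rep_[2:5]))
  expect_true(all(out$records$year >= 1800 & out$records$year <= 2013))

  # filtering is idempotent
  again <- filter_records(out$records)
  expect_equal(nrow(again$records), nrow(out$records))
  expect_equal(sum(again$report[2:5]), 0L)

  # all records flagged -> empty output is legal
  allbad <- rec
  allbad$coordinate_issue <- TRUE
  out2 <- filter_records(allbad)
  expect_equal(nrow(out2$records), 0L)
  expect_equal(unname(out2$report["coordinate_issue"]), 10L)
})

test_that("systematic-survey criteria disable issue and record-type rules", {
  rec <- data.frame(species = "a", decimal_latitude = 40,
                    decimal_longitude = -100, year = 2001L,
                    basis_of_record = "observation",
                    coordinate_issue = NA, stringsAsFactors = FALSE)
  crit <- filter_criteria(require_no_coordinate_issue = FALSE,
                          allowed_record_types = NULL)
  expect_equal(nrow(filter_records(rec, crit)$records), 1L)
  expect_equal(nrow(filter_records(rec)$records), 0L)
})

test_that("inventories count species per cell and period, overlapping schemes included", {
  rec <- data.frame(
    species = c("spA", "spA", "spB", "spC"),
    decimal_latitude = c(40.05, 40.06, 40.07, 40.05),
    decimal_longitude = rep(-100.05, 4L),
    year = c(1991L, 1991L, 1995L, 1989L),
    dataset = "d1", stringsAsFactors = FALSE)
  rc <- assign_cells(rec, grid_spec())
  scheme <- time_periods(c(time_periods("complete"),
                           time_periods("contemporary"),
                           time_periods("intervals")))
  inv <- build_inventories(rc, scheme)
  st <- inventory_stats(inv)
  contemp <- st[st$period == "contemporary", ]
  expect_equal(contemp$n, 3L)
  expect_equal(contemp$s_obs, 2L)
  expect_equal(contemp$q1, 1L)
  expect_equal(contemp$q2, 1L)
  # the 1989 record is in the complete period and its 20-year interval,
  # but not the contemporary period
  per_of_1989 <- inv$period[inv$species == "spC"]
  expect_setequal(per_of_1989, c("complete", "1980-1999"))
  expect_equal(st$n[st$period == "complete"], 4L)

  # empty record set -> empty inventory list
  expect_equal(nrow(build_inventories(rc[0, ], scheme)), 0L)
})

test_that("per-cell counts partition the filtered records under a tiling scheme", {
  fx <- fixture_sim()
  filt <- filter_records(fx$sim$records)
  rc <- assign_cells(filt$records, fx$land$grid)
  inv <- build_inventories(rc, time_periods("intervals"))
  expect_equal(sum(inv$record_count), nrow(rc))
  st <- inventory_stats(inv)
  expect_true(all(st$n >= st$s_obs))
  expect_true(all(st$q1 + st$q2 <= st$s_obs))
})

test_that("inventory export carries cell corners and round-trips counts", {
  fx <- fixture_sim()
  rc <- assign_cells(fx$sim$records, fx$land$grid)
  inv <- build_inventories(rc, "complete")
  p <- tempfile(fileext = ".csv")
  write_inventories(inv, p, fx$land$grid)
  back <- read.csv(p)
  expect_equal(nrow(back), nrow(inv))
  expect_equal(sum(back$record_count), sum(inv$record_count))
  expect_true(all(back$cell_lon_min <= max(fx$land$cells$lon)))
})
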
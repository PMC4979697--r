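# in-code fixtures for the ingest tests

write_occ_fixture <- function(rows, path = tempfile(fileext = ".csv"),
                              header = c("species", "taxon_group",
                                         "decimal_latitude",
                                         "decimal_longitude", "year",
                                         "basis_of_record",
                                         "coordinate_issue_flag")) {
  writeLines(c(paste(header, collapse = ","), rows), path)
  path
}

# a small landscape + pool + audit-ready simulation shared across tests
fixture_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      land <- make_landscape(10, 8, seed = 101)
      pool <- make_species_pool(25, seed = 102)
      eff <- effort_opportunistic(seed = 103, mean_effort = 30,
                                  visited_fraction = 0.8)
      sim <- simulate_records(land, pool, eff, dataset = "fix")
      cache <<- list(land = land, pool = pool, sim = sim,
                     gradients = landscape_gradients(land))
    }
    cache
  }
})
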
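# occaudit

Completeness and coverage audits of species occurrence databases.

Point occurrence records -- GBIF-style museum vouchers and observations,
or systematic survey schemes like breeding-bird routes and federal fish
surveys -- are the backbone of biodiversity mapping, but they are
neither complete species inventories nor unbiased samples of the
landscape. `occaudit` is for biodiversity informaticians and
macroecologists who need to quantify both defects before the data feed
richness models or SDMs:

* **Inventory completeness, per grid cell.** Records are screened
  (coordinate issues, year 1800--2013, rank, record type), binned into
  0.1° × 0.1° cells, and each cell-by-period *survey* is scored with
  three metrics: the record count *n*; the Chao2 completeness index
  *C = S_obs / Ŝ* with the bias-corrected incidence estimator
  *Ŝ = S_obs + ((m−1)/m) · Q₁(Q₁−1) / (2(Q₂+1))* (each record one
  sampling unit, so Q₁/Q₂ are singleton/doubleton species); and the
  final slope of the species accumulation curve, which reduces exactly
  to *Q₁/n*. Cells are classified *well-surveyed* at low
  (≥10, ≥0.6, ≤0.15), moderate (≥25, ≥0.7, ≤0.10) and high
  (≥50, ≥0.8, ≤0.05) conjunctive threshold tiers.
* **Survey coverage, per gradient.** The distribution of surveyed (and
  well-surveyed) cells is compared to all background cells along eleven
  gradients -- time (20-year intervals vs a uniform null), latitude,
  longitude, elevation, MAT, MAP, percent urban / agriculture / total
  disturbance, and climate-change ΔMAP / ΔMAT -- with the
  Kolmogorov--Smirnov *D* statistic as a descriptive bias index
  (D = 0: surveys mirror the landscape; D = 1: complete separation),
  plus cumulative and grouped summaries and paired histogram exports.
* **A virtual-ecologist generator** (`make_landscape()`,
  `make_species_pool()`, `effort_model()`, `simulate_records()`) that
  produces occurrence tables with known ground truth under configurable
  species-abundance distributions and effort bias, so the whole audit
  is testable without downloading anything.

## Worked example

```r
library(occaudit)

land <- make_landscape(20, 10, seed = 1)            # 200-cell landscape
pool <- make_species_pool(40, seed = 2)             # log-series abundances
eff  <- effort_opportunistic(seed = 3, mean_effort = 25,
                             visited_fraction = 0.7)
sim  <- simulate_records(land, pool, eff, dataset = "synthetic_gbif")
aud  <- survey_audit(sim$records, land$grid, landscape_gradients(land))
aud
#> Occurrence survey audit
#>   records: 5222 in, 5222 retained after screening, 0 outside the study region
#>   background cells: 200
#>   synthetic_gbif (complete period): 118 cells surveyed (59.0%); well-surveyed 28.8% / 16.1% / 7.6% (low/mod/high)
#>   mean coverage D over 22 indices: 0.22
```

Even with ~44 records per surveyed cell on average, only 16% of
surveyed cells pass the moderate completeness tier: the log-series rare
tail keeps Chao2 completeness low, which is exactly the pathology the
audit exists to expose in opportunistic data. The coverage table (wide,
one column per gradient, `n/a` where a class is empty):

```r
summary(aud)$coverage[, c("dataset", "cell_class", "temporal",
                          "latitude", "mat", "urban", "dmat")]
#>          dataset    cell_class temporal latitude  mat urban dmat
#> 1 synthetic_gbif      surveyed     0.31     0.04 0.09  0.06 0.03
#> 2 synthetic_gbif well_surveyed     0.73     0.15 0.51  0.33 0.13
```

Surveyed cells track the landscape closely (D ≤ 0.09 on the
environmental gradients) because 59% of all cells were hit, but the
*well-surveyed* subset is strongly biased toward warm, disturbed cells
(D = 0.51 on MAT) -- the effort model's β = 1 bias on MAT concentrates
deep sampling there -- and toward recent decades (temporal D = 0.73).
Per-cell metrics are in `aud$metrics`:

```r
head(aud$metrics[aud$metrics$period == "complete",
                 c("cell_id", "n_records", "s_obs", "chao2_s_hat",
                   "completeness", "final_slope", "pass_moderate")], 4)
#>     cell_id n_records s_obs chao2_s_hat completeness final_slope pass_moderate
#> 550     0_5         6     2       2.000    1.0000000   0.1666667         FALSE
#> 551     0_8         1     1       1.000    1.0000000   1.0000000         FALSE
#> 552     0_9         1     1       1.000    1.0000000   1.0000000         FALSE
#> 553     1_0         4     3       3.375    0.8888889   0.5000000         FALSE
```

`plot(aud, gradient = "mat", cell_class = "well_surveyed")` draws the
paired surveyed/background histograms behind any D value. Configured
end-to-end runs (`run_simulate()`, `run_audit()`, `run_report()`, or
the `inst/scripts/occaudit` command line) write the same tables as
delimited text with a reproducibility manifest.

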
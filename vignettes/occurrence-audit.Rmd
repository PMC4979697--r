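---
title: "Auditing occurrence databases for completeness and coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing occurrence databases for completeness and coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occaudit)
```

## The problem

Aggregated occurrence databases -- GBIF-style compilations of museum
vouchers and opportunistic observations -- are the raw material of much
macroecology, yet they are neither complete inventories nor unbiased
samples of the landscape. Before such data feed richness models or
species distribution models, two questions need quantitative answers per
location: *how complete is the species inventory here?* (the Wallacean
shortfall at the grain of a grid cell) and *how representative are the
surveyed locations of the region's environments, geography and history?*
(survey coverage). `occaudit` implements both halves of that audit as a
pipeline from raw Darwin-Core-like records to per-cell completeness
classifications and per-gradient coverage indices, together with a
virtual-ecologist generator that produces records with known ground
truth so the whole audit can be validated end to end.

## The audit model

### Surveys

A *survey* is the multiset of occurrence records falling in one grid
cell within one time period. Records are screened (no known coordinate
issues; calendar year 1800--2013, both ends inclusive; taxonomic rank
"species"; record type "specimen" -- all four rules configurable, and
the latter two disabled for systematic-survey datasets that lack those
fields), then assigned to 0.1° × 0.1° cells. Cells are half-open,
closed on the south/west edge, so a record on a shared edge lands in
exactly one cell; edges sit on multiples of the cell size from the
origin `(-180, -90)`, which is a convention, not a fact about the data.
Surveys are built for three period schemes at once: *complete*
(1800--2013), *contemporary* (1990--2013), and eleven intervals (ten
20-year intervals plus the 14-year 2000--2013 tail).

### Completeness metrics

Each survey is scored with three metrics. With $n$ records of
$S_{obs}$ species, and $Q_1, Q_2$ the numbers of species with exactly
one and two records:

1. **Record count** $n$ -- the bluntest but most robust signal.
2. **Chao2 completeness** $C = S_{obs} / \hat S$, where
   $\hat S = S_{obs} + \frac{m-1}{m}\frac{Q_1(Q_1-1)}{2(Q_2+1)}$ is the
   bias-corrected Chao2 estimate with each record treated as one
   incidence sampling unit ($m = n$). The record-as-unit choice is
   forced by the data model: within a cell there is no sub-cell survey
   structure to use as units. The bias-corrected variant is the default
   because it is finite for every inventory (the classic
   $Q_1^2/(2Q_2)$ form, available behind a flag, diverges when
   $Q_2 = 0$).
3. **Final slope of the species accumulation curve.** The exact
   rarefaction curve is
   $E[S(m)] = S_{obs} - \sum_i \binom{n-n_i}{m}/\binom{n}{m}$; its last
   step $E[S(n)] - E[S(n-1)]$ collapses to $Q_1/n$, the probability
   that a uniformly chosen final record carries a species seen nowhere
   else in the cell. We compute the slope analytically rather than by
   fitting the curve's last segment: it is the same quantity in
   expectation, deterministic, and exact. The permutation estimator
   survives only as a test oracle, where it is compared exhaustively
   (all $n!$ orderings for every inventory shape with $n \le 8$).

A cell is *well-surveyed* at a tier when **all three** criteria hold
(the thresholds are conjunctive and inclusive):

| tier     | min records | min completeness | max slope |
|----------|------------:|-----------------:|----------:|
| low      | 10          | 0.6              | 0.15      |
| moderate | 25          | 0.7              | 0.10      |
| high     | 50          | 0.8              | 0.05      |

Monotone thresholds guarantee tier nesting (high ⇒ moderate ⇒ low),
which the classifier re-checks by construction. Reports show all three
tiers; the coverage stage defaults to the moderate tier for its
well-surveyed cell class, with the tier selectable.

### Coverage indices

Coverage along a gradient is the agreement between the gradient
distribution of surveyed cells and that of *all* background cells in
the study region (surveyed cells included -- the comparison is against
the whole landscape, and each surveyed cell enters once, unweighted by
its record count). The index is the two-sample Kolmogorov--Smirnov
statistic $D = \sup_x |F_{surveyed}(x) - F_{background}(x)|$, evaluated
at every pooled data point with right-continuous ECDFs so ties are
exact. $D$ is used descriptively: low values mean the surveyed cells
mirror the landscape, high values mean bias. No p-value is computed or
wanted -- with tens of thousands of cells any D is "significant", and
the index's job is ranking, not testing. (Whether the original usage
was one- or two-sample is not documentable; two-sample is the design
decision here.)

Eleven gradients are audited by default: temporal (surveys per 20-year
interval against a discrete uniform null, $D = \max_k |\hat F_k -
k/11|$; a duration-proportional null weighting the 14-year tail by
14/214 is available behind a flag), two spatial (cell-center latitude
and longitude), three natural (elevation, MAT, MAP), three
anthropogenic (percent urban, agriculture, and their sum, total
disturbance, from categorical land-cover codes 21--24 and 81--82), and
two climate-change deltas (ΔMAP, ΔMAT). Spatial and environmental
indices are restricted to contemporary-period surveys, since a
present-day land-cover layer says nothing about the landscape a
19th-century record sampled. Summaries report cumulative D per dataset
(the sum over the audited gradients), group means (all; spatial;
contemporary environmental MAT/MAP/urban/agriculture/disturbance;
climate change -- elevation and the temporal gradient deliberately
belong only to the "all" group), optional dataset-group means, and both
per-class and pooled grand means; indices for an empty cell class are
`n/a` and are excluded from every mean with the exclusion logged.

## The synthetic generator

The generator exists so the audit can be tested against known truth; it
emulates the *structure* of real occurrence data, not any particular
database.

* **Landscape**: gridded cells with elevation (west-high ramp plus
  noise), MAT (latitudinal lapse, default -0.5 °C per degree, plus
  -6.5 °C/km elevation lapse and noise), MAP (eastward ramp), Gaussian
  climate-change deltas, and per-cell land-cover fractions drawn from a
  Dirichlet favouring natural classes. Every knob sits in
  `landscape_params()`; with noise and the elevation coupling off, MAT
  is exactly linear in latitude, which pins the generator in tests.
* **Species pool**: relative abundances from a selectable SAD --
  log-series (default, $p_k \propto \theta^k/k$, $\theta = 0.95$),
  lognormal, or uniform -- with Gaussian niches on one gradient
  (default MAT, optima uniform on 8--20 °C, breadths 2--6 °C).
  The log-series default is deliberate: completeness estimation is hard
  exactly when a rare tail exists, and an audit validated only on even
  abundances would be validated on the easy case. The uniform option is
  the even-abundance regime used for parameter-recovery tests (below).
* **Effort**: visited cells receive negative-binomial record counts
  (overdispersed, like per-cell museum effort; dispersion
  configurable, `Inf` for Poisson) with intensity
  $\lambda = \text{effort} \times e^{\beta z}$, $z$ the standardized
  value of a chosen bias gradient -- the knob that emulates taxonomist
  and institutional surveying bias. Records within a cell are drawn
  species-proportional to local suitability × abundance; suitability is
  the Gaussian niche response truncated at $10^{-6}$, and that same
  truncation defines the true occupancy recorded in the truth table, so
  ground-truth richness is crisp. Record years follow categorical
  weights over the eleven intervals (default: exponential recency bias
  with a thin tail back to 1800); coordinates are uniform within the
  cell, since cell membership is the only spatial information the audit
  uses. Two presets bracket the design space: `effort_opportunistic()`
  (GBIF-like: overdispersed, biased, 60% of cells, long time tail) and
  `effort_systematic()` (BBS/FFS-like: ~5% of cells on a regular
  stride, all records recent, and per-cell sequential detection that
  stops after 25 consecutive draws add no new species -- a
  near-complete-inventory protocol). Preset constants are qualitative
  conventions; no quantitative description of real effort skew was
  available to fit.

What the generator does *not* emulate: taxonomic name problems,
spatially autocorrelated effort beyond the gradient bias, species
interactions, dispersal, or range dynamics. Passing tests therefore
show that the estimators and indices recover known structure from
structurally realistic data -- not that any particular real database
will behave like the presets.

## Numerical and degenerate-input choices

* Rarefaction binomials are computed in log space
  (`lchoose`), so inventories with thousands of records do not
  overflow; $\binom{a}{b} = 0$ when $a < b$ falls out of `lchoose`
  returning $-\infty$.
* Cell indexing snaps coordinates within $10^{-7}$ cells of an edge
  onto it before flooring, so points written with finite decimal
  precision land deterministically; an edge point belongs to the cell
  on its greater side.
* A single-record inventory has slope $Q_1/n = 1$ and $\hat S = S_{obs}$
  (the $(m-1)/m$ factor vanishes), both by the formulas, no special
  casing.
* Empty inventories, empty samples, all-zero interval counts, zero
  background cells, and unknown gradient or period names are
  invalid-argument errors, not NAs; an empty *well-surveyed class* is
  data, not an error, and propagates as `n/a`.
* Filtering rules apply in a fixed order (coordinate issue → year →
  rank → record type) so removal counts are reproducible when a record
  violates several rules; unparseable coordinates and years are flagged
  at read time but only removed (and accounted) by the filter.

## Validation design

The test suite pins every estimator to an independent oracle: the final
slope to the exhaustive permutation mean over all record orderings
(exact integer comparison for every inventory shape with $n \le 8$) and
to $Q_1/n$ on 1,000 random inventories; rarefaction to the brute-force
mean over all $\binom{n}{m}$ subsets; Chao2 to vegan's published
incidence implementation (which returns the classic form when
$Q_2 > 0$ and the bias-corrected form when $Q_2 = 0$; both branches are
exercised) and to a direct evaluation from the incidence matrix; the
K-S index to a brute-force sup over pooled step points on 1,000 random
tied and untied pairs, and to `stats::ks.test` on tie-free samples.

Two simulation-based recovery properties close the loop at the problem
sizes the package uses for its own validation (a 200-cell landscape
with 50-species pools, and a 2,000-cell landscape with 20 replicates
per bias level):

* **Completeness recovery** is tested in the even-abundance (uniform
  SAD) regime, where 500 records per cell genuinely saturates a
  50-species inventory: nearly every cell must classify well-surveyed
  at the high tier, and at 5 records per cell almost none may reach
  even the low tier. Under the log-series default this saturation
  deliberately fails -- the rare tail keeps $C$ well below 1 at any
  desk-scale effort -- which is the hard regime the audit exists to
  flag, and the suite asserts that failure too.
* **Bias recovery**: mean $D$ on the biased gradient rises strictly
  with $\beta \in \{0, 1, 2, 3\}$, is exactly 0 when every background
  cell is surveyed, and shrinks with subset size under unbiased
  sampling.

## Design decisions at genuinely open points

* The study-region mask is caller-supplied (any cell-id list); no
  regional mask is bundled, and background counts are whatever the mask
  says.
* The audit recomputes all stages on every run instead of caching
  intermediates: every stage is seconds at package scale, and a cache
  would complicate the guarantee that reruns on identical inputs are
  byte-identical (which the data outputs are; only the run log carries
  timings).
* All randomness flows from one run seed through named substreams
  (`substream_seed()`), so the landscape, pool and effort stages can be
  regenerated independently.
* Reports show all three tiers separately rather than collapsing
  "moderate or high" into one class; the coverage stage's well-surveyed
  class defaults to moderate.
* Coverage grand means are reported per cell class *and* pooled, since
  the two bookkeepings answer different questions and are easy to
  conflate.

## Limitations

Completeness metrics treat names as opaque labels: synonymy and
misidentification inflate apparent richness and singletons. Chao2 is a
lower-bound estimator, so $C$ is optimistic for inventories with many
undetected rare species. The temporal index inherits the arbitrariness
of 20-year binning. And the audit's verdicts are relative to the grid
resolution: a cell well-surveyed at 0.1° says nothing about finer
grains.
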
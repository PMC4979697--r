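# Example occaudit scenario: a GBIF-style opportunistic sampler over a
# 20 x 10 cell synthetic landscape, audited at the moderate tier.
seed: 42
simulate:
  n_lon: 20
  n_lat: 10
  n_species: 50
  sad: logseries          # logseries | lognormal | uniform
  dataset: synthetic_gbif
  effort:
    preset: opportunistic # opportunistic | systematic | custom
    mean_effort: 20
    dispersion: 0.5
    bias_gradient: mat
    beta: 1
    visited_fraction: 0.6
audit:
  records: occurrences.csv
  gradients: gradients.csv
  tier: moderate
  filter:
    require_no_coordinate_issue: true
    year_range: [1800, 2013]
    require_species_rank: true
    allowed_record_types: [specimen]
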
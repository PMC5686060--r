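# Default msdss pipeline configuration.
# Constants reproduce the published method settings:
#   - efficacy lines (percent inhibition of progression vs mean epoch age):
#       low:  Eff = 83.71 - 1.50 * mean_age
#       high: Eff = 206.39 - 4.34 * mean_age
#     negative values floored at 0; per-epoch fraction capped at 0.95
#   - severity-reference bins: 1 y of disease duration (MSSS), 5 y of age (ARMSS)
#   - boosted model: interaction depth 2, shrinkage 0.001, bag fraction 0.5,
#     tree count by five-fold cross-validation; reduction threshold 4.0%
out_dir: msdss_run
seed: 1
n_patients: 201
efficacy_low: [83.71, -1.50]
efficacy_high: [206.39, -4.34]
efficacy_cap: 0.95
msss_bin_width: 1
armss_bin_width: 5
train_fraction: 0.6666666666666666
influence_threshold: 4.0
stability_partitions: 100
model_params:
  interaction_depth: 2
  shrinkage: 0.001
  bag_fraction: 0.5
  nrounds_max: 10000
  nrounds_min: 100
  grid_step: 1.5
  cv_folds: 5
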
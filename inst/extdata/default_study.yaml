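# Default study configuration: every tunable of the synthetic 5-FU
# selection study in one place. Values mirror the package defaults.
master_seed: 42
selection:
  f0: 0.05            # fallback initial CSC fraction
  d_r: 0.002          # CSC death rate under 5-FU (per hour)
  d_s: 0.0288         # sensitive-cell death rate; d_s - d_r = 0.0268 gives
                      # 3.5-fold treated/control enrichment at 52 h
  d0: 0.001           # baseline death rate untreated (per hour)
  noise_sd: 1.0       # replicate noise, percentage points
  times: [24, 33, 43, 52]
  n_replicates: 3
study_design:
  MDA-MB-231:
    "CD24-CD44+": 0.10
    "ALDH1+": 0.05
    "CD24-ABCG2+ALDH1+": 0.02
  HCT-116:
    "CD44+": 0.15
    "ALDH1+": 0.06
    "CD44+ABCG2+ALDH1+": 0.05
cytosim:
  n_events: 100000
  live_fraction: 0.85
gp:
  population_size: 1000
  max_generations: 20
  tournament_size: 20
  p_crossover: 0.9
  p_subtree_mutation: 0.03
  p_point_mutation: 0.03
  p_hoist_mutation: 0.02
  init_depth_range: [2, 6]
  max_depth: 8
  const_range: [-1.0, 1.0]
  int_const_max: 100
  parsimony_coefficient: 0.001
  stopping_threshold: 0.001
  scale_time: false
forecast:
  train_times: [24, 33, 43]
  validation_time: 52
  followup_time: 67
stats:
  alpha_normality: 0.05
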
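# Demo pipeline configuration: simulated two-cohort study, 200 samples.
simulation:
  n_per_cohort: [100, 100]
  cohorts: [TCGA_SIM, ICGC_SIM]
  n_background_genes: 200
  cluster_prop: 0.5
  cluster_effect: 2
  batch_shift: [0.0, 1.5]
  batch_scale: [1.0, 1.6]
  baseline_hazard: 0.001
  beta_cluster: 0.6931472
  censor_rate: 0.3
  seed: 42
seed: 42
out_dir: demo_out
k_range: [2, 3, 4]
reps: 100
subsample: 0.8
adj_p_max: 0.05
lfc_min: 0.5
alpha_surv: 0.05
n_trees: 300
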
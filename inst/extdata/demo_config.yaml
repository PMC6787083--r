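# Demo pipeline configuration: synthetic four-condition knockout-vs-wildtype
# study with three planted pathway signals among 100 gene sets.
seed: 20260901
out_dir: cofgsea_demo
combine_mode: union
gsea_method: deseq2
top_k: 10
simulation:
  n_genes: 5000
  n_sets: 100
  set_size_range: [40, 120]
  cofactor_fraction: 0.1
  n_conditions: 4
  condition_labels: [LF_fed, LF_fasted, HF_fed, HF_fasted]
  methods: [deseq2, voom]
  null_sigma_lfc: 0.4
  df: 10
  planted:
    - target_set: SET0001
      direction: up
      responsive_fraction: 0.5
      delta: 3
    - target_set: SET0002
      direction: up
      responsive_fraction: 0.5
      delta: 3
    - target_set: SET0003
      direction: down
      responsive_fraction: 0.5
      delta: 3
gsea:
  weight_exponent: 1
  n_permutations: 500
  min_set_size: 15
  max_set_size: 500
  fdr_explorative: 0.25
  fdr_significant: 0.05
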
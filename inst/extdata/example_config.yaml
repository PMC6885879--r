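# Example end-to-end pipeline configuration.
# cohort entries are passed to sim_config(); analysis entries steer both
# MR arms. A pleiotropy map gives named SNPs a direct per-allele log-OR on
# disease, violating the exclusion restriction for that SNP.
seed: 20260927
cohort:
  n_cases: 3000
  n_controls: 3000
  causal_log_or_per_kb: 0.405   # OR 1.5 per kb of telomere length
  pleiotropy:
    rs2736100: 0.28             # direct TERT-region path to lung cancer
analysis:
  covariates: [age, sex, pack_years, pc1, study]
  n_knots: 4
  missing_policy: drop
  alpha_pleiotropy: 0.05
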
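# Synthetic-generator calibration record (synthetic data only; no external
# material). Measured with generate_cohort() at the shipped defaults
# (slide 4096 px, densities 1500/800/700 per mm^2, density_sigma 0.6,
# baseline hazard 0.25/yr, censoring target 0.3) while fixing the default
# log-hazard coefficients beta = (9, -9, -3); beta_scale multiplies beta.
# The oracle C-index of the true linear predictor must clear 0.7 at
# beta_scale 1 to leave learnability headroom for the model.
beta_scale,n_patients,seed,oracle_cindex,censored_fraction
0.2,120,8,0.59,0.26
1.0,200,11,0.87,0.34
1.0,260,101,0.87,0.29
1.0,260,102,0.86,0.28
1.0,260,103,0.87,0.27
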
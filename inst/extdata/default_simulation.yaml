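# Default trait parameterisation for the synthetic-data generator.
# Variance partitions and phenotypic variances follow the laboratory-trait
# columns of the package's bundled variance-component tables (pH on the
# natural scale, i.e. printed x100 value / 100). Fractions are renormalised
# to sum exactly to 1 when loaded. r_g_latent is the genetic correlation
# between the measured trait and the latent day-1 surface trait the spectra
# can see; spectral_info is the fraction of latent-trait variance recoverable
# from one replicate-averaged spectrum, calibrated so the implied external
# prediction R^2 (spectral_info x squared latent-measured correlation)
# reproduces the Vis-NIRS external-validation ladder.
traits:
- trait: L
  mean: 39.86
  phen_var: 11.64
  f_additive: 0.23
  f_batch: 0.18
  f_herd: 0.06
  f_residual: 0.54
  r_g_latent: 1.0
  spectral_info: 0.9132
  shared_resid_frac: 0.85
  scale100: false
- trait: a
  mean: 28.59
  phen_var: 3.12
  f_additive: 0.09
  f_batch: 0.25
  f_herd: 0.11
  f_residual: 0.55
  r_g_latent: 0.958
  spectral_info: 0.6044
  shared_resid_frac: 0.85
  scale100: false
- trait: b
  mean: 9.65
  phen_var: 2.79
  f_additive: 0.10
  f_batch: 0.23
  f_herd: 0.08
  f_residual: 0.59
  r_g_latent: 1.0
  spectral_info: 0.6912
  shared_resid_frac: 0.85
  scale100: false
- trait: C
  mean: 30.19
  phen_var: 4.71
  f_additive: 0.09
  f_batch: 0.25
  f_herd: 0.10
  f_residual: 0.56
  r_g_latent: 1.0
  spectral_info: 0.6332
  shared_resid_frac: 0.85
  scale100: false
- trait: h
  mean: 18.53
  phen_var: 4.17
  f_additive: 0.10
  f_batch: 0.21
  f_herd: 0.06
  f_residual: 0.62
  r_g_latent: 1.0
  spectral_info: 0.7064
  shared_resid_frac: 0.85
  scale100: false
- trait: pH
  mean: 5.55
  phen_var: 0.0030
  f_additive: 0.08
  f_batch: 0.61
  f_herd: 0.06
  f_residual: 0.25
  r_g_latent: 0.701
  spectral_info: 0.3278
  shared_resid_frac: 0.85
  scale100: true
- trait: PL
  mean: 4.50
  phen_var: 1.39
  f_additive: 0.10
  f_batch: 0.14
  f_herd: 0.05
  f_residual: 0.71
  r_g_latent: 0.979
  spectral_info: 0.3486
  shared_resid_frac: 0.85
  scale100: false
- trait: CL
  mean: 16.76
  phen_var: 11.78
  f_additive: 0.10
  f_batch: 0.42
  f_herd: 0.04
  f_residual: 0.44
  r_g_latent: 0.703
  spectral_info: 0.1827
  shared_resid_frac: 0.85
  scale100: false
- trait: WBSF
  mean: 40.96
  phen_var: 113.14
  f_additive: 0.16
  f_batch: 0.42
  f_herd: 0.06
  f_residual: 0.37
  r_g_latent: 0.805
  spectral_info: 0.1809
  shared_resid_frac: 0.85
  scale100: false
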
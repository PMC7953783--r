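# nirherit

Quantitative-genetic analysis of near-infrared (NIR) spectral predictions
of beef quality traits, for animal breeders and quantitative geneticists
who want to know whether at-line spectral phenotypes can replace laboratory
measurements in a selection programme.

Nine meat quality traits — lightness L\*, redness a\*, yellowness b\*,
chroma C\*, hue h\*, ultimate pH, purge losses (PL, %), cooking losses
(CL, %) and Warner-Bratzler shear force (WBSF, N) — are measured in the
laboratory on aged samples, but can also be *predicted* from spectra
scanned on the intact muscle surface at the abattoir. Whether such
predictions are useful for breeding hinges on three quantities this
package estimates:

* **External prediction accuracy** R²\_EXT: each slaughter batch is
  predicted from a Bayes B calibration (mixture prior: an effect is zero
  with probability π, otherwise scaled-t) fitted on all other batches;
  R²\_EXT is the squared correlation between accumulated held-out
  predictions and measurements.
* **Variance components and heritability** from a bivariate pedigree
  animal model fitted by AI-REML,

  y = Xβ + W₁c + W₂q + Zu + e,

  with random herd c ~ N(0, C⊗I), slaughter batch q ~ N(0, Q⊗I), additive
  genetic u ~ N(0, G⊗A) (A = numerator relationship matrix) and residual
  e ~ N(0, R⊗I); intra-herd heritability h² = σ²ₐ/(σ²ₐ+σ²ₑ).
* **Genetic and residual correlations** r\_a and r\_e between each measured
  trait and its spectral prediction, from the off-diagonals of G and R —
  the quantities that decide indirect-selection efficiency
  CR/R = r\_a·h\_indicator/h\_target.

Because the underlying animal data are not public, the package ships a
synthetic-data generator that emulates the study design (≈200 sires,
≈1,300 progeny, ≈100 herds and ≈100 slaughter batches, replicated spectra
on Vis 350–1830 nm and micro-NIR 905–1649 nm grids, with per-trait
variance partitions and a tunable spectral information content), plus the
published summary tables as fixtures for a verifier that recomputes every
aggregate they imply.

## Worked example

Simulate a lightness-like trait at reduced scale, calibrate, validate and
estimate genetic parameters:

```r
library(nirherit)

tc <- default_trait_catalog()
cfg <- sim_config(n_sires = 60, n_dams = 380, n_progeny = 400,
                  n_herds = 30, n_batches = 32,
                  traits = tc[tc$trait == "L", ],
                  instruments = list(micro = list(start = 905, stop = 1649, step = 6)),
                  seed = 2026)
ds <- simulate_dataset(cfg)

spectra <- flag_outliers_mahalanobis(ds$spectra$micro, threshold = 3)
per_animal <- average_replicates(spectra)
idx <- match(per_animal$meta$animal, ds$phenotypes$animal)
val <- leave_one_batch_out(per_animal, ds$phenotypes$L[idx],
                           ds$phenotypes$batch[idx],
                           bayesb_settings(niter = 2000, burnin = 500,
                                           thin = 1, seed = 1))
val

ph <- ds$phenotypes
ph$L_pred <- val$predictions$predicted[match(ph$animal, val$predictions$animal)]
fit <- reml_animal(build_design(ph, ds$pedigree, c("L", "L_pred")),
                   build_A_inverse(ds$pedigree))
report <- genetic_parameter_report(fit)
report$variance_table
report$correlations
```

which prints

```
<validation_result> 400 animals | 32 batches | R2_ext = 0.623
   trait phen_var f_additive f_batch f_herd f_residual    h2 h2_se scale100
1      L    10.71      0.112   0.149  0.117      0.622 0.153 0.141    FALSE
2 L_pred     7.03      0.126   0.122  0.120      0.632 0.167 0.147    FALSE
  correlation estimate    se clipped
1         r_a    1.000 0.256   FALSE
2         r_e    0.653 0.069   FALSE
```

Reading: the calibration predicts held-out batches with R²\_EXT = 0.62;
the prediction has lost about a third of the phenotypic variance
(10.71 → 7.03) but keeps a comparable heritability, and its additive
genetic correlation with the measured trait is at the boundary (1.0, SE
0.26) — the prediction ranks animals genetically like the measurement
does, which is what indirect selection needs. (At n = 400 the
heritability SEs are wide; the generating h² is 0.30.)

`verify_printed_aggregates()` returns the reference-table ledger — e.g.
the regression of R²\_EXT on the proportional phenotypic-variance decrease
across the nine traits gives R² = 0.960 (Vis) and 0.986 (Micro), and the
mean genetic correlation between measured traits and predictions is
0.8045.

A thin CLI wraps the same functions: `exec/nirherit run --config sim.yaml`
and `exec/nirherit verify-tables`.

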
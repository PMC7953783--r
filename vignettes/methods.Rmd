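---
title: "Models and methods behind nirherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nirherit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Meat quality traits — colour (L\*, a\*, b\*, C\*, h\*), ultimate pH, purge
and cooking losses (PL, CL) and Warner-Bratzler shear force (WBSF) — are
expensive to phenotype: samples must be collected at the abattoir, aged and
analysed in a laboratory. Portable visible/near-infrared spectrometers can
instead scan the intact muscle surface at the abattoir one day after
slaughter. For such spectral predictions to be useful in *selective
breeding*, what matters is not only their phenotypic accuracy but their
genetic properties: how heritable the predictions are, how much additive
genetic variance survives the prediction step, and how strongly the
predictions correlate genetically with the laboratory measurements they
stand in for.

`nirherit` implements the full inference chain needed to answer those
questions, plus a synthetic-data generator that emulates the kind of
field study this design comes from (roughly 1,300 young bulls by ~200 A.I.
sires, fattened in ~100 herds, slaughtered over ~100 batches), so every
stage is testable without access to animal data.

# Stage 1 — chemometric calibration

## Spectral editing

Spectra are edited in a fixed order: **flag → average → standardize**.

1. *Outlier flagging.* The Mahalanobis distance of each spectrum from the
   centroid is computed in a principal-component subspace retaining 99% of
   the variance, capped at 20 components — the covariance of 1,481
   wavelengths is singular at ~1,300 samples, so a subspace is unavoidable.
   The standardized distance GH = D²/k (k = retained components) is
   compared against a cutoff of 3, the conventional chemometric choice;
   the cutoff is configurable because the underlying screening rule, not a
   specific threshold, is the method. For approximately normal spectra GH
   behaves like a χ²ₖ/k variable, which is the property the test suite
   checks.
2. *Replicate averaging.* The five replicate scans per animal are averaged
   over unflagged replicates, giving one spectrum per animal. Averaging the
   spectra (rather than averaging five separate predictions) was chosen
   because the genetic analysis needs exactly one prediction per animal and
   the two options coincide for the linear predictor; the choice is recorded
   here because the alternative is equally defensible.
3. *Standardization.* Per-wavelength centring and scaling parameters are
   learned from the training set only and applied unchanged to held-out
   data; zero-variance wavelengths are dropped and recorded. Refitting the
   standardization inside every validation fold is what makes the external
   validation leak-free.

## Bayes B

Each trait is regressed on the standardized absorbances under the Bayes B
mixture prior: an effect is exactly zero with probability π (default 0.95),
otherwise normal with its own scaled-inverse-χ² variance (marginally a
scaled-t). The Gibbs sampler integrates the effect out of the inclusion
odds given the per-effect variance, then draws the effect for included
wavelengths, per-effect variances, the intercept and the residual variance.
Prior scales follow the usual expected-proportion-of-variance rule with
R² = 0.5: the effect-variance scale is `var(y)·R2·(df+2)/(MSx·(1-π))` with
MSx the summed covariate variances, and the residual scale is
`var(y)·(1-R2)·(df+2)`, both with 5 prior degrees of freedom. Chain
defaults are 12,000 iterations, 2,000 burn-in, thinning 5; the tests run
much shorter chains (600–2,000 iterations) because the quantities they
check — posterior-mean effects on toy problems, external R² — are stable
at that length, as verified against longer reference chains. π, the
degrees of freedom and the chain settings are all surfaced in
`bayesb_settings()` because none of them is forced by the method. The
π → 0 limit is checked against an independently written BayesA sampler.

## Leave-one-batch-out external validation

Because the slaughter batch (day) is the dominant environmental grouping,
random cross-validation would leak batch information and flatter the
calibration. Instead, for each batch the standardization and the Bayes B
model are refitted on all other batches and the held-out batch is
predicted; predictions are accumulated over batches and the external R²
(`r2_ext`) is the squared Pearson correlation between accumulated
predictions and measurements — pooled, not averaged per batch, so every
animal contributes exactly once. The contract that a batch's own responses
can never influence its own predictions is enforced by construction and
tested by perturbation.

# Stage 2 — genetic parameters

## The animal model

For a (measured, predicted) trait pair the model is

y = Xβ + W₁c + W₂q + Zu + e,

with fixed effects β (dam-parity classes for pH, slaughter-age classes for
L\*, an intercept otherwise), random herd effects c ~ N(0, C⊗I), random
slaughter-batch effects q ~ N(0, Q⊗I), additive genetic effects
u ~ N(0, G⊗A) over the full pedigree, and residuals e ~ N(0, R⊗I). Herd
and batch levels with fewer than three records are removed by dropping the
records (the count is always logged); the alternative — merging small
levels — changes the model, so dropping is the conservative reading of a
minimum-cell-size rule. A is the numerator relationship matrix; its sparse
inverse is built by Henderson's rules with inbreeding from the
Meuwissen-Luo recursion, and unknown parents are treated as unrelated,
non-inbred founders because no grouping structure is available.

The fixed-effect pairing (parity → pH, age class → L\*) follows the natural
reading of the design; the inverse pairing is conceivable, so the rule is a
replaceable function argument of `build_design()`.

Intra-herd heritability is h² = σ²ₐ/(σ²ₐ+σ²ₑ), taken literally: herd *and*
batch variance are excluded from the denominator, because that is what the
formula says even though the label only mentions herds. pH variances are
reported ×100 in output tables, mirroring the reporting convention for a
trait whose natural-scale variance is ~0.003.

## AI-REML

Variance components maximise the restricted likelihood, evaluated exactly
through the sparse mixed-model equations (CHOLMOD factorisations via the
Matrix package):

-2 logL = (N−p)·log 2π + log|R̃| + log|G̃| + log|MME| + y'Py,

an identity with the usual dense form log|V| + log|X'V⁻¹X| + y'Py that the
test suite verifies numerically. Updates are average-information
quasi-Newton steps: the AI matrix is computed exactly from working-vector
solves of the same factorisation, while the score is obtained by central
finite differences of the exact likelihood (two extra sparse
factorisations per parameter). This replaces literal EM steps: the fixed
point, and the inverse-AI asymptotic covariance used for all standard
errors, are identical, but monotonicity is guaranteed by step-halving
whenever a step would decrease the likelihood, and no sparse-inverse-subset
traces (which no installed sparse library exposes) are required. Interim
blocks are bent to the nearest positive-definite matrix (eigenvalue floor
1e-8 of the phenotypic scale); variances are floored at 1e-8 of the largest
phenotypic variance; starting values put 20% of the phenotypic variance in
each non-residual block and the remainder in the residual, with zero
covariances — a neutral interior point. Convergence requires
|ΔlogL| < 1e-8 together with a relative parameter change below 1e-6, or a
likelihood stalled below 1e-8 on two successive iterations (the
finite-difference score has ~1e-4 relative noise near the optimum, so
demanding both criteria simultaneously can chatter). Non-convergence is an
error carrying the last iterate and the likelihood trace.

Animals recorded for one trait only are handled by the
missing-at-random REML formulation: their residual block reduces to the
observed trait's variance. Genetic and residual correlations are
cov/√(var·var) on the G and R blocks with first-order delta-method SEs;
estimates on a bent boundary can exceed |1| and are clipped with a flag —
at a true correlation near 1 the estimate frequently converges onto the
boundary, which is expected behaviour, not a defect.

# The synthetic-data generator

The generator's defaults are the study conditions: 204 sires, 1,286 dams,
1,327 progeny, 98 herds, 106 batches, five replicate spectra per animal and
instrument, a Vis grid of 350–1830 nm at 1 nm (1,481 points) and a
micro-NIR grid of 905–1649 nm at 6 nm (125 points). Per-trait means,
phenotypic variances and additive/batch/herd/residual fractions are taken
from the laboratory columns of the bundled reference tables (fractions
renormalised to sum exactly to 1, since the printed, rounded ratios sum to
0.99–1.01) and ship in a single editable YAML file.

**Latent surface trait.** The discrepancy between what the spectrometer
sees (day-1 intact muscle) and what the laboratory measures (day-7 aged
sample) is modelled statistically, not mechanistically: the latent trait
shares the measured trait's herd and batch effects, carries its own
additive component with a configurable genetic correlation to the measured
one (defaults set to the Vis-NIRS genetic correlations of the reference
tables), and shares a configurable fraction of the measured residual
(default 0.85); the rest of the measured residual is measurement-specific.
Measured and latent breeding values are drawn jointly down the pedigree
with exact Mendelian-sampling variances ½(1−(F_s+F_d)/2)·G, with
inbreeding computed from the pedigree so the simulated covariance is
exactly G⊗A. Distinct traits are genetically independent in the generator
— cross-trait genetic covariances are not reported in the reference
tables, and nothing downstream needs them.

**Spectra.** A spectrum is a fixed smooth baseline, plus one orthonormal
Gaussian-bump loading curve per trait scaled by the animal's standardized
latent value, plus a batch-level offset along the flat direction
(orthogonalised away from all loading curves, so batch artefacts cannot
masquerade as trait signal), plus white noise; replicates differ only in
noise. The per-trait signal scale is set in closed form against the
replicate-averaged noise level so that the population R² of the best
linear predictor of the latent trait from one averaged spectrum equals the
configured `spectral_info` — the orthonormalisation is what makes the
closed form exact, and a ridge-regression oracle reproduces the configured
level in the tests. Default `spectral_info` values are back-calculated so
that the implied external R² (`spectral_info` × squared latent–measured
correlation) reproduces the Vis-NIRS external-validation ladder. A
configurable fraction of spectra (default 1%) is corrupted into gross
outliers — a narrow spike or a flat offset — solely to exercise the QC
stage.

**What the generator does not emulate.** Real NIR spectra have correlated,
wavelength-dependent noise, scatter effects, and many overlapping
absorbance features per trait; real herd and batch sizes are far from
uniform; real pedigrees are deeper than two generations; and the true
day-1/day-7 relationship involves aging chemistry. Passing tests therefore
demonstrate that the *machinery* (QC, calibration, validation, REML) is
correct under a faithful statistical abstraction of the design — they do
not certify performance on real spectra.

# Problem sizes and numerical checks

The test suite works at sizes chosen to keep a full run at desk scale on
one CPU: relationship matrices are checked against a 200,000-replicate
gene-dropping simulation on a 50-animal pedigree and dense inversion up to
200 animals; the REML path is checked against a dense-likelihood grid on an
8-record toy, a balanced half-sib ANOVA oracle (50 sires × 20 progeny), and
a 20-seed parameter-recovery study at n = 2,000 under study-proportioned
pedigree and contemporary-group structure (308 sires, 1,940 dams, 98 herds,
106 batches), where every component must cover its generating value within
2 SEs in at least 90% of runs; calibration properties (leakage,
perfect-signal and permutation limits, monotonicity in spectral
information over five levels at n = 800 with 64 batches, shrinkage across
all nine traits) run on the 125-point micro-NIR grid. The
inverse-AI standard errors were additionally validated against a
numerically differentiated observed information matrix.

# Known limitations

* Genetic groups for unknown parents, maternal effects, and models with
  more than two traits are out of scope.
* No scatter-correction pretreatments (SNV, MSC, derivatives) are applied;
  the editing pipeline is deliberately minimal.
* The derivative-free part of the REML score (finite differences) limits
  attainable gradient accuracy to ~1e-4 relative near the optimum; the
  convergence logic accounts for this, but likelihood values should not be
  compared beyond ~1e-6.
* Asymptotic SEs understate finite-sample variability when family numbers
  are small (e.g. 100 sire families); coverage is validated at the
  study-proportioned design, not for arbitrary designs.
* With a true genetic correlation at or near 1, estimates converge onto
  the bent boundary and their SEs are taken from the inverse AI matrix
  there; they should be read as approximate.
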
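# inflaPD

Pharmacodynamic modelling of the LPS-stimulated inflammatory cascade in
RAW264.7 macrophages and its suppression by baicalein.

When macrophages are stimulated with LPS they release TNF-α within the
first hour, followed — with a lag of about 1.4 h — by IL-6 and inducible
NO synthase (iNOS), whose expression drives NO production. Baicalein,
a flavonoid from *Scutellaria baicalensis*, inhibits TNF-α release and
thereby the downstream mediators. `inflaPD` implements the
semi-mechanistic indirect-response (turnover) model of this cascade

```
dTNF/dt  = k_in,TNF · (1 − α·ln C) − k_out,TNF · TNF
dIL6/dt  = k_in,IL6 · TNF(t − τ1) − k_out,IL6 · IL6
diNOS/dt = k_in,iNOS · TNF(t − τ2) − k_out,iNOS · iNOS
dNO/dt   = k_in,NO · iNOS^δ − k_out,NO · NO
```

with baicalein concentration `C` (µM) acting log-linearly on TNF-α
production, and provides, as a tested pipeline:

* exact/numerical solution of the cascade (closed-form TNF-α, compiled
  adaptive RK45 for the full system, `deSolve` as a cross-check route);
* a synthetic-data generator reproducing the four-arm
  (0/10/20/40 µM) × five-time (1–12 h post-LPS) experimental design with
  additive, proportional or power residual error;
* naive-pooled maximum-likelihood estimation with per-analyte residual
  sigmas profiled out, staged + multi-start optimization, AIC/BIC, and
  Hessian or bootstrap CV%;
* goodness-of-fit tables, visual predictive checks, and
  simulation–refit parameter-recovery studies.

The experimental dataset behind the published analysis was never
deposited, so the workflow (`analysis/01_simulate.R` …
`04_recovery.R`) operates on synthetic data generated at the published
parameter estimates (`baicalein_reference_params()`): α = 0.0832,
k_in,TNF = 3.74×10³, k_out,TNF = 0.0463 h⁻¹, k_in,IL6 = 0.353 h⁻¹,
k_out,IL6 = 0.143 h⁻¹, τ₁ = 1.38 h, k_in,iNOS = 0.00169 h⁻¹,
τ₂ = 1.41 h, k_in,NO = 0.0605 h⁻¹, δ = 1.35, with k_out,iNOS and
k_out,NO fixed at 0.

## Worked example

Simulate one dataset at the reference estimates with 10% proportional
error, refit it, and inspect the fit:

```r
library(inflaPD)

truth <- baicalein_reference_params()
design <- default_design()        # 4 arms x {1,2,4,8,12} h, n = 3 (iNOS 6)
em <- error_model("proportional", sigma_prop = 0.10)

dataset <- generate_dataset(truth, design, em, seed = 101)   # 300 records
fit <- fit_cascade(dataset, init = truth, n_starts = 8, seed = 101)
fit$cv_percent <- parameter_cv(fit)
print(fit)
```

```
Pooled-ML cascade fit (proportional error)
Free parameters:
           estimate cv_percent
alpha     8.128e-02       3.94
k_in_tnf  3.659e+03       2.13
k_out_tnf 4.229e-02      14.00
k_in_il6  3.404e-01       5.64
k_out_il6 1.177e-01      19.50
tau1      1.355e+00       1.79
k_in_inos 1.691e-03       1.85
tau2      1.387e+00       1.26
k_in_no   5.610e-02       6.66
delta     1.366e+00       1.17
Residual sigma: TNF=0.093, IL6=0.0932, iNOS=0.0922, NO=0.0894
-2LL 2387.83 | AIC 2415.83 | BIC 2467.68 | n_obs 300 | p 14
```

Every estimate is within its uncertainty of the generating value — e.g.
α is recovered as 0.0813 (CV 3.9%) against a truth of 0.0832, and the
fitted inhibition slope reads as `100 * drug_effect(0.0832, exp(1))` =
8.32% suppression of TNF-α production per e-fold rise in baicalein
concentration. The residual sigmas recover the generating σ = 0.10.
Diagnostics:

```r
attr(gof(fit, dataset), "summary")    # obs-vs-pred slopes ~ 1
v <- vpc(fit$estimates, fit$error_model, design, n_sim = 200,
         dataset = dataset)
mean(v$obs_median >= v$q5 & v$obs_median <= v$q95)   # ~0.9
```

The numbered scripts under `analysis/` run the same steps as a
narrative pipeline and write their tables under `results/`.

## Layout

```
R/, src/        package code: model core, synthetic data, estimation,
                diagnostics, IO (compiled RK45 cascade solver in src/)
analysis/       numbered narrative pipeline over the package
scripts/        acceptance.R (see above)
tests/testthat  unit, property and end-to-end suites
vignettes/      methods vignette: model, assumptions, numerics, limits
```
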
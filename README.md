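# spalos

Spatial regression analysis of healthcare accessibility and hospital length
of stay (LOS) on small-area (areal) data.

## The problem

Health-services researchers studying how *potential* access to care (how
easily residents can reach hospital beds, general practitioners, nurses,
physiotherapists) relates to *realized* access (how long elderly patients
actually stay in hospital) work with small administrative areas: a fine
census-block scale nested inside a coarser postal-code-like scale. Two
spatial complications break ordinary regression there:

* **spatial autocorrelation** — nearby areas have similar LOS, so OLS
  residuals are not independent and standard errors are wrong;
* **spatial non-stationarity** — the strength and even the sign of the
  accessibility–LOS relationship can differ from one part of the region to
  another, which a single global coefficient hides.

`spalos` implements the full analysis workflow for this setting, plus a
synthetic-data generator with known ground truth so every stage can be
validated without access to confidential hospital-discharge data.

## What is implemented

**Indicator construction.** The per-unit LOS indicator sums, over the
elderly age groups g ∈ {75–84, 85–94, ≥95},

    LOS_i = Σ_g avg_stay_gi / P_gi

(group mean stay standardized by group population; an explicit
"total-days" variant is available behind a flag). Accessibility is an
enhanced two-step floating catchment area (E2SFCA) index: step 1 computes
each provider's capacity-to-weighted-demand ratio
R_j = cap_j / Σ_i P_i·w(t_ij) over travel-time zones with step-function
decay w(·); step 2 sums A_i = 10⁴ · Σ_j R_j·w(t_ij), giving capacity per
10,000 inhabitants. Covariates are screened by variance inflation factor
(VIF = 1/(1−R²_k), threshold 10, greedy elimination).

**Three competing models** for y = ln LOS on X = (1, ln ISA, %precarious,
%non-owner, ln APL):

* **OLS** — y = Xβ + ε;
* **SAR (spatial lag)** — y = ρWy + Xβ + ε, fitted by profile maximum
  likelihood with the log-determinant from the eigenvalues of the
  row-standardized contiguity matrix W, ρ searched on (1/λ_min, 1) by
  golden section; asymptotic SEs from the information matrix;
* **GWR** — y_i = Σ_k β_k(u_i, v_i)·x_ik + ε_i, local weighted least
  squares with an adaptive Gaussian kernel (bandwidth = distance to the
  k-th nearest neighbour, k = ⌈fraction·n⌉), bandwidth chosen by AICc
  minimization; effective parameters tr(S) from the hat rows; local
  pseudo-t maps at α = 0.05.

**Diagnostics.** Global Moran's I (analytic randomization moments and
permutation p), LISA cluster maps (HH/LL/LH/HL from conditional
permutation, GeoDa convention), a coordinate-permutation Monte-Carlo test
for spatial variability of each GWR coefficient, model comparison by
adjusted R²/AIC/residual Moran's I, and fine-vs-coarse scale comparison of
coefficients and standard errors (the MAUP/scale effect).

**Synthetic data.** A regular two-level lattice (fine cells nested in
coarse blocks), negative-binomial elderly populations, logistic-bounded
percentage covariates with target correlations, provider sites, and
outcomes generated under i.i.d., spatial-lag, or spatially-varying
coefficient processes with a recorded `truth_record`.

## Worked example

```r
library(spalos)
cfg <- run_config(seed = 42, nx = 12, ny = 12, coarse_block = 3,
                  process = "sar_lag", rho = 0.5, outdir = "spalos_out")
bundle <- run_pipeline(cfg)
print(bundle$fits$sar)
print(bundle$diagnostics$comparison)
```

prints (n = 144 fine units in 16 coarse units; truth ρ = 0.5):

```
Model: SAR_LAG  n = 144
              coef     se
intercept   3.2620 1.5215
ln_isa     -0.4274 0.1748
precarious  0.0157 0.0107
non_owner  -0.0034 0.0053
ln_apl     -0.2210 0.2255
rho = 0.355 ( se 0.0998 )
adj R2 = 0.2055  AIC = 99.361  logLik = -42.68

Model comparison (ranked by AIC):
 model adj_r2    aic aicc resid_moran_i resid_moran_p rank
   sar 0.2055  99.36   NA    -0.0001563         0.880    1
   gwr 0.1099 107.56  114     0.1938178         0.005    2
   ols 0.1113 108.37   NA     0.2000865         0.005    3
```

Reading this: the outcome was simulated with a genuine spatial-lag process,
so the SAR model wins — its ρ̂ = 0.355 (SE 0.10) is within two standard
errors of the generating ρ = 0.5 at this modest n, its residual Moran's I
is indistinguishable from zero (p = 0.88), while OLS and GWR leave
significant residual autocorrelation (I ≈ 0.2, p = 0.005). Negative
`ln_isa`/`ln_apl` coefficients mean better accessibility goes with shorter
stays. Every artifact (GeoJSON region, weights triplets, fit tables, LISA
map, Monte-Carlo report, config, truth sidecar, MD5 manifest) is written to
`outdir`. A thin CLI wrapper lives at `inst/cli/spalos.R`.

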
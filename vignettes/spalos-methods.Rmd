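---
title: "Methods: spatial regression of healthcare accessibility and length of stay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial regression of healthcare accessibility and length of stay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spalos)
```

`spalos` analyses how spatial accessibility to primary and secondary
healthcare relates to hospital length of stay (LOS) across small
administrative areas. This vignette documents the models, the numerical
choices behind them, what the synthetic-data generator does and does not
emulate, and the design decisions that were genuinely open.

## The indicator layer

### LOS

The outcome is an age-standardized utilization indicator over the three
elderly age groups $g \in \{75\text{–}84, 85\text{–}94, \ge 95\}$:
$$\mathrm{LOS}_i = \sum_g \frac{\overline{\mathrm{stay}}_{gi}}{P_{gi}},$$
the group's mean stay among inpatients divided by the group's *total*
population (inpatients or not). This is a population-standardized rate, not
a per-patient mean; the mean (not median) is used so that the very long
stays that matter for resource allocation are not under-weighted. The
numerator convention is ambiguous in parts of the applied literature — an
alternative reading multiplies the group mean by the inpatient count
("total days"). Both are implemented; `compute_los(mode = "eq1")` (the
literal sum of group means over population) is the default and
`mode = "total_days"` must be requested explicitly, never substituted
silently.

Logs of LOS and of the accessibility indices are taken with an explicit
zero policy: `drop` (default — excluded units are masked and logged, and the
spatial weights are re-subset accordingly), `error`, or `offset(c)`. The
offset policy should only be used when the variable's scale is large
relative to `c`; an offset comparable to the data corrupts the regression,
which is why `drop` is the default.

### E2SFCA accessibility

Accessibility to beds (ISA analogue) and to primary-care practitioners (APL
analogues) is an enhanced two-step floating catchment area index. With
travel time $t_{ij}$ between unit $i$ and provider $j$ and a step-function
decay $w(t)$ over zones:

1. $R_j = \mathrm{cap}_j / \sum_{i} P_i\, w(t_{ij})$ — each provider's
   capacity divided by the zone-weighted demand in its catchment;
2. $A_i = 10^4 \sum_j R_j\, w(t_{ij})$ — capacity per 10,000 inhabitants.

Defaults: zones (10, 20, 30) minutes with weights (1.0, 0.6, 0.3). These
are a documented stand-in for the published configurations of the French
ISA/APL indices, whose exact decay schedules live in their source
publications; nothing downstream depends on the specific zone weights, only
on monotone decay. Demand is the total ≥75 population. A provider whose
catchment contains zero weighted demand has an undefined ratio; this errors
unless `drop_empty_providers = TRUE`. On synthetic data, travel time is
centroid-to-provider Euclidean distance divided by a constant speed
(default 0.6 map units/minute, chosen so that a default 12×12 region spans
all three zones).

Two exact properties are useful for validation and are enforced by tests:
homogeneity (scaling all capacities by $c$ scales all indices by $c$) and
conservation (with a single zone of weight 1 covering everything,
$\sum_i A_i P_i / 10^4 = \sum_j \mathrm{cap}_j$).

### Scale moves

Fine→coarse aggregation is the population-weighted mean within each coarse
unit; coarse→fine disaggregation copies the coarse value to each member
unit (so aggregation of a disaggregated vector is the identity). These are
the two conventions used when variables are only available at one scale.

### VIF screening

$\mathrm{VIF}_k = 1/(1 - R^2_k)$ from regressing column $k$ on the others.
Columns are removed greedily — highest VIF first, recomputed after each
removal — until all are below the threshold (default 10). Greedy
highest-first is a choice: the screening literature specifies the threshold
but not the elimination order.

## The model layer

All three models share the design
$X = (1, \ln \mathrm{ISA}, \text{precarious}, \text{non-owner}, \ln \mathrm{APL})$
and outcome $y = \ln \mathrm{LOS}$.

### OLS

QR-based least squares; classical standard errors with
$\hat\sigma^2 = \mathrm{RSS}/(n-p)$; AIC $= 2(p{+}1) - 2\ell$ with the
Gaussian ML log-likelihood (identical to `stats::logLik.lm` conventions, so
AICs are comparable across the package's models).

### SAR (spatial lag), maximum likelihood

$$y = \rho W y + X\beta + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2 I),$$
with $W$ row-standardized first-order contiguity (rook by default — the
standard choice on lattice data, and queen is one argument away). Row
standardization itself is a modelling decision: it makes $\rho W y$ the
*average* neighbour outcome, which is how lag coefficients are customarily
interpreted, and it is the default of the field's estimation software.

Estimation profiles $\beta, \sigma^2$ out of the likelihood: with
$e_0, e_1$ the residuals of $y$ and $Wy$ on $X$,
$\mathrm{RSS}(\rho) = \|e_0 - \rho e_1\|^2$ in closed form, and
$$\ell_c(\rho) = \mathrm{const} - \tfrac{n}{2}\log(\mathrm{RSS}(\rho)/n) + \sum_i \log(1 - \rho\lambda_i),$$
where $\lambda_i$ are the eigenvalues of $W$. For contiguity weights these
are real: row-standardized $W = D^{-1}B$ with symmetric binary $B$ is
similar to the symmetric $D^{-1/2} B D^{-1/2}$, which is also how the
eigenvalues are computed (a dense symmetric eigenproblem, adequate up to a
few thousand units). $\rho$ is searched by golden section to tolerance
$10^{-8}$ on the correct support $(1/\lambda_{\min},\, 1)$ — not $(-1, 1)$
— and a fit whose optimum touches the boundary carries a warning flag.
Standard errors are asymptotic, from the analytic information matrix of
$(\beta, \rho, \sigma^2)$; whether a bootstrap would be preferable at small
$n$ is left to the user (the asymptotic choice is documented, not hidden).
AIC counts $p + 2$ parameters ($\beta$, $\rho$, $\sigma^2$). The reported
$R^2$ is a pseudo-$R^2$ (squared correlation of observed and fitted
$\rho W y + X\hat\beta$), as no exact decomposition exists for SAR.

### GWR

$$y_i = \sum_k \beta_k(u_i, v_i)\, x_{ik} + \varepsilon_i,$$
estimated by local weighted least squares at every unit with an *adaptive
Gaussian* kernel: the bandwidth at unit $i$ is the distance $b_i$ to its
$k$-th nearest neighbour, $k = \lceil \text{fraction} \cdot n \rceil$, and
$w_{ij} = \exp\{-(d_{ij}/b_i)^2/2\}$ for **all** units — the classic
untruncated adaptive-Gaussian definition. A truncated bisquare is available
as an option; a `uniform` kernel gives the exact global-OLS limit and is
used as a degeneracy check. The adaptive (rather than fixed-distance)
window is the right choice when areal units vary greatly in size; the
bandwidth is parameterized as a fraction of $n$ because that is how
adaptive bandwidths are conventionally reported. Distance ties at the
$k$-th neighbour are harmless by construction (the bandwidth is the $k$-th
order statistic, which does not depend on tie order).

Hat rows $s_i = x_i (X'W_iX)^{-1}X'W_i$ give the effective number of
parameters $\nu = \mathrm{tr}(S)$; $\hat\sigma^2 = \mathrm{RSS}/(n - \nu)$;
per-coefficient standard errors come from
$C_iC_i'\hat\sigma^2$, $C_i = (X'W_iX)^{-1}X'W_i$, and local pseudo-$t$
values are flagged at α = 0.05, *unadjusted across units* — that is how
local-coefficient maps are conventionally drawn; a Benjamini–Hochberg
option exists but is off by default. The bandwidth is selected by
minimizing
$$\mathrm{AICc} = 2n\log\hat\sigma + n\log 2\pi + n\,\frac{n + \mathrm{tr}(S)}{n - 2 - \mathrm{tr}(S)},$$
the corrected criterion standard for GWR; an OLS-comparable
$\mathrm{AIC} = 2(\mathrm{tr}(S){+}1) - 2\ell$ is also reported so model
comparison can use either. The selection itself is deterministic: a coarse
log-spaced scan over the integer neighbour count brackets the minimum,
golden section refines it, and if the scan finds its minimum at an edge the
search falls back to a dense 40-point log-spaced grid (recorded in the
returned `method` field). On stationary data the criterion is nearly flat
over wide fractions — the untruncated Gaussian kernel at fraction ≈ 0.4 is
already effectively global — so "selected fraction" should be read jointly
with the flatness of the criterion, not as a sharp optimum. The local-fit
inner loop is implemented in C++ (RcppArmadillo), as is usual for GWR
software, which keeps permutation tests and replicate studies fast.

## The diagnostics layer

**Global Moran's I** $= (n/S_0)\, z'Wz / z'z$ with $z = x - \bar x$.
Inference both ways: the analytic normal approximation under the
randomization assumption (with the standard $S_1, S_2, b_2$ moment
formulas) and random permutation (default 999), with the two-sided
permutation p-value measured around the randomization expectation
$E[I] = -1/(n-1)$. A constant vector is a hard error — autocorrelation of a
constant is undefined, not zero.

**LISA** $I_i = (z_i/m_2) \sum_j w_{ij} z_j$ with conditional permutation:
the focal value stays in place and the remaining $n-1$ values are permuted
among the other units (999 draws per unit), the convention of the standard
LISA software. The p-value is one-sided *in the direction of the observed
local statistic* — upper tail for positive $I_i$, lower for negative. A
pure upper-tail rule would make negative local association (HL/LH units)
undetectable, so the direction-sided rule is the one that supports all four
quadrant labels. Labels HH/LL/HL/LH are assigned from the signs of
$(z_i, \sum_j w_{ij} z_j)$ only where $p_i < \alpha$ (default 0.01). The
identity $\sum_i I_i = n I$ (row-standardized, no isolates) is asserted in
tests on every input, not just documented. One practical caveat found while
validating: with rook weights and conditional permutation, a unit *outside*
a compact high block borders at most one block cell, so its permutation
p-value cannot reach small thresholds — low-high rings around hot spots
are genuinely hard to flag at α = 0.01 and the package does not pretend
otherwise.

**Monte-Carlo non-stationarity test.** The observed statistic per
coefficient is the variance across units of the local estimates
$\beta_k(i)$ — the natural spread measure, as the test's originating
description leaves the statistic implicit. Under the null that coefficients
do not vary over space, coordinates carry no information, so the coordinate
rows are permuted jointly (one permutation per iteration, default 99), the
GWR refit at the same adaptive $k$, and
$p = (1 + \#\{\mathrm{stat}_\mathrm{perm} \ge \mathrm{stat}_\mathrm{obs}\})/(n_\mathrm{perm}+1)$.
The test is exactly exchangeable — and therefore exactly sized — when the
covariate fields themselves carry no spatial structure; with strongly
smooth covariates it was observed to be conservative, never anti-
conservative, in the package's calibration experiments.

**Model and scale comparison.** `compare_models()` tabulates adjusted
R², AIC (AICc alongside for GWR) and residual Moran's I — GWR residuals
taken as $(I - S)y$ from the accumulated hat rows, tested with the *same*
weights as the global models for comparability — ranked by AIC with stable
ties. `scale_comparison()` reports per-coefficient percent changes in
estimates and standard errors between a fine-scale and a coarse-scale fit,
plus significance counts at α = 0.05 and 0.01.

## The synthetic-data generator

The generator emulates the *structure* of the real inputs — a two-level
areal hierarchy, overdispersed census counts, bounded percentage
covariates, provider sites, travel times, and an outcome driven by a known
spatial process — so that every downstream stage has a ground truth to
recover:

* **Lattice**: a regular grid of unit squares, coarse units as
  `coarse_block`² blocks. Regularity is deliberate: contiguity, nesting and
  centroid logic become exactly testable. Irregular tessellations are a
  non-goal.
* **Population**: three age-group counts per unit, each negative binomial
  with mean `mean_pop` (default 60) and dispersion 1.2 — census counts are
  overdispersed, and real fine-unit populations span orders of magnitude.
  `dispersion = Inf` gives the Poisson limit used in tests.
* **Covariates**: latent Gaussian fields (optionally with a smooth spatial
  component built from linear and sinusoidal surfaces, mixed by
  `spatial_share`), cross-correlated by a Cholesky factor, then mapped to
  (0, 100) by `100·plogis(μ + 0.25 z)`. The small latent scale keeps the
  transform near-linear so realized correlations track the target within
  ±0.1 at n ≥ 400. The joint distribution of the real socioeconomic
  covariates is unknown; the correlation target is a free parameter of the
  simulation, not an emulation claim.
* **Outcome**: `iid` ($y = X\beta + \varepsilon$), `sar_lag`
  ($y = (I-\rho W)^{-1}(X\beta + \varepsilon)$), or
  `varying_coefficients` ($y_i = \sum_k \beta_k(u_i,v_i) x_{ik} +
  \varepsilon_i$ with linear gradient surfaces). Noise is Gaussian on the
  log scale, mirroring the ln-LOS modelling; the observed LOS is
  `exp(y)`, decomposed into a stay table that `compute_los()` reconstructs
  exactly — so the indicator layer is exercised, not bypassed.

What passing tests on this generator do **not** show: robustness to
irregular geometry and very unequal unit sizes, to non-Gaussian outcome
noise, to measurement error in travel times, or to real road-network
topology. Those belong to the data, not the methods, and are out of scope.

## Numerical choices and degenerate inputs

* SAR: golden-section tolerance 1e-8 on ρ; boundary optima flagged;
  rank-deficient designs error naming the dependent columns.
* GWR: singular local designs error naming the unit (a ridge fallback
  exists but must be enabled explicitly — silent regularization would
  change the estimand); `fraction·n < p + 2` errors naming the minimum
  feasible fraction; zero adaptive bandwidth (coincident points) is an
  error.
* Permutations: all seeded; p-values respect the $(1+k)/(n_\mathrm{perm}+1)$
  floor; LISA permutation draws are per-unit without replacement.
* Weights: no self-neighbours; contiguity symmetric before
  standardization; standardization idempotent; subsetting re-standardizes
  and may create isolates (SAR then refuses to run rather than silently
  dropping the log-determinant term).

## Validation problem sizes

The package validates itself on deliberately modest problem sizes chosen to
give stable Monte-Carlo answers on a single CPU: 50-replicate parameter
recovery and model-ordering experiments on a 20×20 lattice (n = 400),
100-replicate size/power studies of the non-stationarity test at n = 100
and n = 400 with 99 permutations, and exact-agreement oracles at n = 25.
`scripts/acceptance.R` re-runs all of them from a single seed.

## Known limitations

* No case-mix or severity adjustment of LOS — the indicator is a
  population rate, not a clinical outcome.
* SAR standard errors are asymptotic ML; no bootstrap.
* Spatial error models, Durbin terms, mixed or multiscale GWR are out of
  scope, as are 3SFCA-style accessibility variants and distance-band or
  higher-order weights.
* The E2SFCA zone weights are a stand-in; reproducing published French
  accessibility values would require the original (non-deposited) data and
  decay schedules.
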
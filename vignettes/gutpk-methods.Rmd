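---
title: "Models and methods in gutpk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gutpk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutpk)
```

gutpk implements five linked quantitative models of the physiology of
gut-secreted heat-shock chaperones (HSP70, GRP78) and their metabolic
consequences, together with synthetic-data generators so that every
estimator can be validated by parameter recovery. This vignette explains
each model, its assumptions, the tunable parameters, and the numerical and
design choices made where the procedure was genuinely open.

## Serum chaperone kinetics

The incremental (above-basal) serum concentration $c(t)$ of HSP70 or GRP78
during an infusion or meal response and the subsequent washout follows

$$\frac{dc}{dt} = A\,(1 - e^{-k_1 t}) - \frac{1}{V}\frac{T_m c}{K_m + c},
  \qquad t \le t_{max},$$
$$\frac{dc}{dt} = A\,e^{-k_2 (t - t_{max})} - \frac{1}{V}\frac{T_m c}{K_m + c},
  \qquad t > t_{max},$$

with $c(0) = 0$. The rising term is the inflow into plasma — subcutaneous
absorption of the recombinant protein, or meal-stimulated secretion by the
gut — and the Michaelis–Menten term is receptor-mediated tissue uptake,
the saturable clearance route that produces the concave washout these
proteins show. Parameters and units: $A$ ng/(mL·min) maximal inflow rate,
$k_1, k_2$ 1/min inflow rise and decay rates, $V$ mL distribution volume,
$T_m$ ng/min maximal elimination rate, $K_m$ ng/mL half-saturation
concentration, $c_b$ ng/mL constant basal level. $t_{max}$ is *fixed* at
the time of the maximal measured concentration before any fitting; it is
never a free parameter.

Two consequences of the model structure matter for estimation:

* Concentration data constrain only the ratio $T_m/V$ — the elimination
  term is $(T_m/V)\,c/(K_m+c)$ — so `fit_hsp()` reports the identifiable
  pair $(T_m/V, K_m)$ and converts to $T_m$ only when the user supplies a
  measured $V$.
* `half_life()` is curve-based, exactly as the quantity is defined for
  these data: the interval from the concentration peak to the linearly
  interpolated time at which the incremental concentration first falls to
  half its maximum. In the linear regime $c \ll K_m$ this approaches
  $\ln 2 \cdot V K_m / T_m$, which the test suite verifies within 2%.

`fit_hsp()` minimizes unweighted least squares on total concentration
($c + c_b$, with $c_b$ fixed at the pre-dose sample), matching how such
fits are usually reported; a `weights` argument provides the
variance-matched weighted objective, which is the statistically efficient
choice when the measurement error is proportional (as the synthetic
generator's 5% CV is), and is what the Monte-Carlo robustness study uses.

## Antibody target-mediated disposition (QSS)

Monoclonal antibodies against HSP70/GRP78, injected subcutaneously at dose
$D$ (pmol), bind their circulating target (total concentration $\bar P$,
assumed constant under sustained high-fat feeding). With binding fast
relative to elimination, the quasi-steady-state (QSS) approximation
collapses the binding dynamics to an algebraic partition of total antibody
$A_t$ into free $A$ and complex $B$:

$$B = \frac{\bar P A}{K_{SS} + A}, \qquad
  K_{SS} = \frac{k_{off} + k_{int}}{k_{on}} = K_D + \frac{k_{int}}{k_{on}},$$

$$\frac{dA_t}{dt} = \frac{I(t)}{V} - k_e A -
  \frac{k_{int} \bar P A}{K_{SS} + A}, \qquad A_t(0) = 0,$$

where $A$ solves $(A_t - A)(K_{SS} + A) = \bar P A$, evaluated in a
cancellation-safe form (`free_mab()`). Fluorescence readings are
proportional to $A_t$ with constant $K$ (RFU/pM). Since $K_{SS} = K_D +
k_{int}/k_{on}$, $K_{SS} \ge K_D$ whenever internalization occurs — the
qualitative signature that bound antibody is cleared into tissues at a
rate comparable to free-antibody elimination.

Subcutaneous absorption is represented as biphasic: half of the dose
enters the blood before the concentration peak ($t_{peak}$, default 2 h)
and half after. Within each half, `reconstruct_inflow()` allocates the
dose over the sampling intervals proportionally to the trapezoidal
fluorescence AUC of each interval. This AUC-ratio rule is an
approximation: the concentration AUC necessarily lags the inflow that
produced it, so the reconstructed profile can never reproduce the true
profile exactly (we verified that the fixed point of the reconstruction
map is degenerate, concentrating all mass at the end of each half).
Recovery tests therefore fit with the generator's true inflow profile —
isolating estimator error from the absorption approximation — while
`fit_tmdd()` defaults to the AUC reconstruction, which is what one does
with real fluorescence data. The analysis scripts report both fits side
by side.

Numerical choices:

* The ODE is integrated in free-antibody space,
  $dA/dt = (dA_t/dt)\,/\,(1 + \bar P K_{SS}/(K_{SS}+A)^2)$, because the
  partition inversion makes the $A_t$-space right-hand side nearly kinked
  around $A_t \approx \bar P$ for small $K_{SS}$, which stalls adaptive
  steppers; the $A$-space dynamics are smooth rational functions and the
  trajectory is identical.
* `simulate_mab_full()` integrates the explicit two-state binding model
  ($k_{on}, k_{off}$) and exists to verify that the QSS trajectory is its
  limit as $k_{on}$ grows at fixed $K_{SS}$; the acceptance suite shows
  the gap decreasing monotonically and below 1% at the largest $k_{on}$
  tested.
* `fit_tmdd()` runs a small deterministic multistart (the user's initial
  estimate and two scaled copies) because the $(k_{int}, K_{SS})$
  direction is sloppy and a single Levenberg–Marquardt run can strand in a
  shallow local minimum; $V$, $K_{SS}$ and $K$ are bounded away from zero
  (they degenerate the model). With $\bar P = 0$ the model reduces to
  linear PK, in which only $k_e$ and the ratio $K/V$ reach the
  observable; `fit_tmdd()` then flags $k_{int}$ and $K_{SS}$ as
  unidentifiable and holds them fixed.

`half_life_descending()` reads the terminal half-life as
$\ln 2 / |\text{slope}|$ of a log-linear regression on the post-peak
samples, the standard way a descending-branch half-life is quoted.

## Oral glucose minimal model

Insulin sensitivity $S_I$ and glucose effectiveness $S_G$ are estimated
from OGTT glucose and insulin curves with the Bergman-type oral minimal
model:

$$\frac{dG}{dt} = -(S_G + S_I Z)\,G + S_G G_b + \frac{Ra}{V_G},
  \qquad G(0) = G_b,$$
$$\frac{dZ}{dt} = p\,(-Z + I - I_b), \qquad Z(0) = 0,$$
$$Ra = \frac{a\,\Delta G + d(\Delta G)/dt}{b},$$

with $\Delta G = G - G_b$. Only the composites $\alpha = a/(bV_G)$ (1/min)
and $\beta = 1/(bV_G)$ (dimensionless) are estimable, so the forcing is
$Ra/V_G = \alpha \Delta G + \beta\, d(\Delta G)/dt$. Units: $S_G$ 1/min,
$S_I$ 1/(min·pM), $p$ 1/min, glucose mmol/L, insulin pmol/L.
Measured points are interpolated every 10 min (linear) before fitting, and
the derivative in $Ra$ is taken by central differences on that grid.

The $Ra$ parameterization is self-referential — it is built from the
glucose excursion it helps produce — and this has two consequences the
package is explicit about:

* $S_G$ and $\alpha$ enter the equations only through $\alpha - S_G$
  (because $-S_G G + S_G G_b = -S_G \Delta G$), so they are individually
  unidentifiable; tests and analyses assert $S_I$ (and $p$), which carry
  the insulin signal.
* A record that is *exactly* consistent with the fitted model cannot be
  generated by feeding the model its own output: the self-consistent ODE
  started at $G(0) = G_b$ has no oral input and produces no excursion.
  The generator therefore drives the $Ra$ term from a known reference
  excursion (`glucose_forcing`), and recovery studies pass the same
  forcing to the fitter. On real data the measured glucose plays both
  roles (forcing and fit target), exactly as the procedure is applied in
  practice; `fit_minimal_model()` does this by default.

Validation records are sampled every 10 min so that the mandated
interpolation is exact and recovery isolates the estimator; at the
coarser 8-sample clinical schedule the interpolation itself biases $S_I$
by several percent, which is a property of the procedure, not of the
implementation. Both simulation modes are available: `"data-driven"`
(forcing from a measured/reference curve, the default and the estimation
mode) and `"self-consistent"` (the $d\Delta G/dt$ inside $Ra$ is the
model's own derivative, resolved algebraically with the requirement
$\beta < 1$).

Fitting uses bounded Levenberg–Marquardt on scaled parameters
(all $\ge 0$, $\beta < 0.99$), with a deterministic multistart and a
second pass using a coarser finite-difference step, which rescues basins
where the default-step Jacobian is dominated by integrator noise.

## C-peptide kinetics, secretion, and responsivity

C-peptide is co-secreted equimolarly with insulin but not extracted by the
liver, so the insulin secretion rate (ISR) is reconstructed from plasma
C-peptide by deconvolution through the linear two-compartment model

$$\frac{dCP_1}{dt} = -(k_{01} + k_{21})\,CP_1 + k_{12}\,CP_2 + SR(t),$$
$$\frac{dCP_2}{dt} = k_{21}\,CP_1 - k_{12}\,CP_2,$$

with both compartments starting at zero (concentrations are above basal)
and $SR$ the secretion above basal normalized by the accessible volume
$V_1$. For rodents the kinetic parameters come from allometric rules
(`kinetics_from_body_weight()`): $V_{tot} = 38\%$ of body weight, $V_1 =
42\%$ of $V_{tot}$, $k_{01} = 8.2\%$, $k_{21} = 7.7\%$ of $V_{tot}/V_1$
and $k_{12} = 7.7\%$ of $V_{tot}/V_2$, per minute. Human parameter sets
are deliberately not bundled: the module is aimed at the rodent OGTT.

The deconvolution represents $SR(t)$ as piecewise constant on the
measurement grid, extended by one coarse segment to 360 min where
C-peptide is assumed back at basal (a terminal pseudo-observation pins the
profile). The discretized convolution $CP_1 = F\,SR$ — the columns of $F$
are exact matrix-exponential responses to unit secretion on each segment —
is solved by penalized least squares with a second-difference (Tikhonov)
smoothing term of weight `lambda_reg` (scaled relative to the design), and
optionally a non-negativity constraint (bounded quasi-Newton on the
quadratic objective). The deconvolution method itself is an
implementation choice; regularized least squares with a curvature penalty
is standard practice for this ill-posed input-estimation problem. With
noise-free data and `lambda_reg` near zero the square-pulse round trip in
the test suite recovers the ISR AUC to well under 2%.

Reported quantities: $ISR = SR \times V_1$ (pmol/min; with $CP_1$ in
nmol/L and $V_1$ in mL the product is already pmol/min), its trapezoidal
AUC over the measured window, and the model-independent responsivity

$$\Phi \approx k_{01} \int CP_1\,dt \Big/ \int (G - G_b)\,dt,$$

evaluated with trapezoids on the measurement grid over 0–180 min (the
formula's infinite window is truncated where the data end; the terminal
assumption at 360 min affects the deconvolution, not the $\Phi$
integrals). $\Phi$ is reported as the raw ratio with these units; it is
undefined (error) when the glucose excursion integral is not positive,
which happens when insulin action pushes glucose below basal for most of
the record.

## Disposition index

Across animals of an experiment, responsivity and insulin sensitivity
trade off along the hyperbola

$$y = \frac{DI}{x - x_\infty} + y_\infty,$$

with $x = S_I$ and $y = \Phi$. `fit_di()` fits $(DI, x_\infty, y_\infty)$
by unweighted least squares, with default bounds keeping the branch
physical ($x_\infty < \min S_I$, $y_\infty < \min \Phi$ among the data)
and initialization $x_\infty = y_\infty = 0$, $DI = \text{median}(S_I
\Phi)$. Per-group weighting is not applied (nothing in the procedure as
stated calls for it).

## NAS regression

Fasting serum HSP70 and GRP78 (pg/mL) predict the NAFLD Activity Score
through an affine model; the bundled reference regression is

$$NAS = -0.368 + 0.009\,\cdot HSP70 + 0.002\,\cdot GRP78$$

with reported $R^2 = 0.78$ and standardized coefficients 0.581 (HSP70)
and 0.438 (GRP78). Under it, +100 pg/mL of HSP70 raises predicted NAS by
0.9 points, +100 pg/mL of GRP78 by 0.2, and both together by 1.1.
`fit_nas()` refits the model to a cohort by ordinary least squares with
$R^2 = 1 - SSE/SST$ and standardized coefficients $b_j\,sd(x_j)/sd(y)$
using $n-1$ sample standard deviations (the convention is a choice; the
printed three-decimal coefficients limit exact reproduction of the
standardized values from the equation alone).

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of (parameters, seed); the RNG state of
the caller is never disturbed. Measurement error is combined proportional
+ additive Gaussian truncated at zero, with a default proportional CV of
5% — a typical immunoassay intra-assay precision; no assay CV is stated
for the serum kinetics measurements, so this default is a modelling
choice. Study conditions used by the validation suite (chosen once, for
physiological plausibility and identifiability):

* Chaperone kinetics: 2-h infusion raising serum from a 2 ng/mL basal to
  ~17 ng/mL against $K_m = 8$ ng/mL (so the clearance visibly saturates),
  $T_m/V = 0.5$ ng/(mL·min), fast post-pump inflow decay
  ($k_2 = 0.1$/min), sampling every 10 min to 360 min.
* Antibody: $V = 44$ mL, $k_e = 0.35$/h, $k_{int} = 0.3$/h, $K_{SS} =
  900$ pM (above the measured-affinity scale of several hundred pM),
  $\bar P = 400$ pM, and a dose (200 pmol) high enough that free antibody
  traverses the $K_{SS}$ region — the regime in which all five parameters
  are jointly identifiable. Sampling to 24 h.
* OGTT: basal glucose 5.5 mmol/L, basal insulin 100 pmol/L, a reference
  excursion peaking +5 mmol/L at 30 min, insulin peaking at 45 min,
  records every 10 min to 180 min; $S_G = 0.02$/min, $S_I = 10^{-4}$
  /(min·pM), $p = 0.02$/min. The cohort analysis gives insulin-resistant
  animals compensatory hyperinsulinemia (insulin excursion scaled as
  $1/S_I$), which is what the disposition-index trade-off implies
  physiologically.
* NASH cohort: covariates uniform over 100–600 (HSP70) and 100–2000
  (GRP78) pg/mL; when no noise SD is given it is calibrated by variance
  arithmetic, $\sigma^2 = \text{var(signal)}\,(1-R^2)/R^2$, so the
  population $R^2$ is 0.78.

What passing tests on these data do **not** show about real data: the
generators share the estimators' structural assumptions (constant basal
levels, constant total target, the biphasic half-dose absorption rule, a
known oral-glucose forcing, Gaussian error). Real serum curves violate
all of these to some degree, so recovery here demonstrates correctness of
the estimation machinery, not accuracy of the models for any particular
animal.

## Numerical choices and degenerate inputs

* ODE integration: deSolve `lsoda` at rtol $10^{-10}$, atol $10^{-12}$,
  with the integration split at inflow discontinuities ($t_{max}$,
  absorption breakpoints). These tolerances are deliberately tight: the
  optimizers differentiate the solutions by finite differences, and
  looser tolerances leave integrator noise in the Jacobians. When a
  pathological trial parameter set stalls the adaptive stepper, a
  fixed-step RK4 sweep completes the evaluation so the least-squares
  surface has no cliffs.
* Nonlinear fits: minpack.lm Levenberg–Marquardt on scaled parameters
  with non-negativity bounds; non-convergence is reported through the
  `converged` flag of the `fit_result`, never as an exception, so batch
  studies proceed.
* Half-life readings require an interior maximum and error informatively
  when the curve never falls to half its peak (`half_life()`), when the
  descending branch has fewer than three positive points or a
  non-negative log-slope (`half_life_descending()`).
* A record flat at basal drives the inflow estimate $A$ to its lower
  bound 0 (`fit_hsp()`) or flags $S_I$ unidentifiable
  (`fit_minimal_model()`).
* Problem sizes throughout the validation suite — 20-seed Monte-Carlo
  studies, 12-animal cohorts, $10^4$-state property checks — are the
  sizes at which the reported medians stabilize while the whole suite
  stays comfortably interactive.

## Known limitations

* $V$ and $T_m$ are not separately identifiable from concentration data
  alone; published tables that report both necessarily used outside
  information, which this package makes explicit rather than reproducing.
* The AUC-ratio inflow reconstruction is an approximation with a known
  bias direction (inflow reconstructed later than truth); fits against
  real fluorescence data inherit it.
* The minimal model's $Ra$ parameterization leaves $S_G$ and $\alpha$
  confounded and makes $S_I$ precision degrade quickly with glucose
  noise; medians around 20–30% at 2–3% noise in the Monte-Carlo studies
  are a property of the design, matching the general experience that
  single-subject OGTT $S_I$ has substantial uncertainty.
* Bivalent antibody binding, tissue biodistribution, human C-peptide
  population parameters, and microbiota or proteomics analyses are out of
  scope.
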
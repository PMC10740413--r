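---
title: "Methods: from ink composition to printability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ink composition to printability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inkflow)
```

inkflow models the printability of gelatin--sodium alginate--methylcellulose
(Gel:SA:MC) biomaterial inks for pneumatic extrusion bioprinting as a chain of
four quantitative stages: composition is mapped to shear-thinning rheology by
response-surface models; rheology and driving pressure are mapped to nozzle
flow rate by a laminar power-law flow model; the flow-rate surface is
approximated by a trained surrogate and partitioned into printability
regimes; and the flow rate feeds a toolpath planner whose slow-start and
overlap rules compensate the start-up behavior of pneumatic extrusion. This
vignette explains each model, its assumptions, the tunable parameters, and
the design decisions taken where the problem was genuinely open.

## Shear-thinning rheology

All inks in the family are treated as power-law (Ostwald--de Waele) fluids,

$$\eta(\dot\gamma) = K \dot\gamma^{\,n-1},$$

with $\eta$ the apparent viscosity (Pa·s), $\dot\gamma$ the shear rate
(1/s), $n$ the dimensionless power-law index ($n<1$: shear-thinning) and $K$
the consistency coefficient (Pa·s$^n$), numerically the viscosity at unit
shear rate. `fit_power_law()` estimates $(n, K)$ by ordinary least squares of
$\log\eta$ on $\log\dot\gamma$. Fitting in log--log space is the natural
choice for flow curves spanning two decades of shear rate: it weights each
decade equally, recovers noise-free power-law data exactly, and makes the
estimator linear. The package does not model yield stress, thixotropy,
temperature dependence or oscillatory moduli; the 30 °C measurement
temperature is carried as an annotation only.

Measurement emulation (`synth_rheometry()`) follows the rheometry protocol of
the study system: 21 shear-rate points placed log-uniformly (endpoint
inclusive) on 1--100 1/s, with multiplicative log-normal noise
($\sigma_{\log} = 0.03$ by default) because rotational-rheometer error scales
with the reading. The noise magnitude is a convention -- instrument error for
this setup is not published -- chosen so that downstream prediction
accuracies resemble the validation-table values.

## Composition-to-rheology response surfaces

The composition space is the cube Gel 6--10, SA 3--5, MC 2--4 wt%. A
three-factor Box--Behnken design (`bb_design_ink()`: 12 edge midpoints + 5
center replicates = 17 runs) supports a full second-order polynomial

$$Y = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
      \sum_{i<j} \beta_{ij} x_i x_j + \varepsilon$$

for each response ($Y_1 = n$, $Y_2 = K$). `fit_quadratic()` fits by OLS and
reports the classical response-surface diagnostics: per-term partial F tests,
$R^2$ and adjusted $R^2$, predicted $R^2$ from PRESS (computed by the exact
leave-one-out identity $e_{(i)} = e_i/(1-h_i)$, verified in the tests against
explicit refits), and a lack-of-fit test whose pure-error term comes from the
five center replicates -- the classical partition, since only the center
point is replicated in this design.

Models are fitted and stored in **uncoded** (wt%) units by default, because
the published final models are printed in uncoded units; coded-unit fitting
is available (`units = "coded"`) and is used for standardized-effect (Pareto)
ranking, where coded units are the convention -- in uncoded units the
collinearity between a factor and its square distorts the $t$ statistics.

`backward_eliminate()` removes, iteratively, the highest-p term with
$p > \alpha$ (default $\alpha = 0.05$) *unless* its removal would decrease
the predicted $R^2$, in which case the term is permanently retained; model
hierarchy is respected (a linear term survives while any surviving
higher-order term contains it) and the intercept is never removable. The
retention override reproduces the documented behavior of keeping weakly
significant pure-quadratic terms that help prediction. One caveat we found by
Monte-Carlo on the 17-run design: the override also retains a truly null term
roughly half the time, because removing a null term lowers PRESS-based
predicted $R^2$ about as often as not; consequently exact structure recovery
is not guaranteed, only that genuinely active terms are never lost. The tests
assert exactly that.

The published final models are shipped as evaluable objects
(`ink_n_model()`, `ink_K_model()`, wrapped by `predict_n()`/`predict_K()`).
The $K$ polynomial's raw output is 1000 times the tabulated Pa·s values --
its coefficients were evidently exported in mPa·s -- so the model carries an
explicit output scale factor of $10^{-3}$, confirmed by evaluating the raw
polynomial at all five validation compositions. Prediction accuracy uses
$1 - |\hat y - y|/\hat y$ (predicted-value denominator); both candidate
denominators were checked against the published accuracy cells and only this
one reproduces them.

## Nozzle flow: quasi-1D power-law model

The nozzle is a slender axisymmetric channel (barrel, conical taper, needle
lumen), so steady laminar incompressible no-slip flow is modelled by the
lubrication approximation: each axial station is treated as locally fully
developed power-law pipe flow with the generalized Hagen--Poiseuille
gradient

$$-\frac{dP}{dz} = \frac{2K}{R(z)}
   \left(\frac{3n+1}{n}\,\frac{Q}{\pi R(z)^3}\right)^{n}.$$

`pressure_drop()` integrates this along the axis -- closed form on cylinders,
composite Simpson quadrature with 2048 fixed panels per conical segment --
and `solve_flow_rate()` inverts it for $Q(\Delta P)$ by bracketed root
finding on $\log Q$ (Brent's method, relative tolerance $10^{-10}$, bracket
$[10^{-6}, 10^{3}]$ µL/s with doubling expansion capped at 60 steps). The
exit velocity profile is the fully developed power-law profile
$u(r) = (G/2K)^{1/n}\, \tfrac{n}{n+1} (R^{1+1/n} - r^{1+1/n})$; integrating
it radially (`flow_rate_from_profile()`, Simpson on uniform grids) recovers
the solved $Q$, which the tests check against closed forms and against a
$10^6$-slice brute-force oracle for conical segments. Entrance and exit
losses, inertia, extrudate swell and transient start-up are deliberately not
modelled.

Interfaces use mm, kPa and µL/s; the solver works in SI internally.

**Default geometry.** Measured dimensions of the simulated channel are not
available, so the default (`default_nozzle_geometry()`) is a documented,
calibrated assumption: a 3 mL syringe barrel (R 4.8 mm × 10 mm), a conical
hub taper (4.8 → 0.125 mm over 20 mm) and a cylindrical 25 G needle lumen
(R 0.125 mm × 25 mm, the standard 25 G length). We considered a short conical
tip with a 1 mm exit land instead; under the purely viscous model it passes
up to several mL/s at the thin end of the printable box -- orders of
magnitude above the low single-digit µL/s scale reported for this space and
physically implausible -- whereas the needle-lumen reading of the stated
hardware reproduces that scale. Every function takes an explicit geometry,
so users with measured dimensions should supply them.

**Filament diameter.** Volume conservation of an extruded stream stretched
into a cylinder moving with the print head gives
$d = 2\sqrt{Q/(\pi v)}$ (`filament_diameter()`), with $v$ the print speed.

## Sampling, surrogate and regimes

The printable box is $n \in [0.45, 0.7]$, $K \in [10, 100]$ Pa·s,
$P \in [50, 350]$ kPa. `latin_hypercube()` draws space-filling samples with
exactly one point per axis stratum (seeded, reproducible);
`build_flow_dataset()` evaluates the solver at each point, recording rather
than dropping failures. The default study protocol is 300 training points
(LHS) plus 50 uniform-random test points (`synth_flow_dataset()`).

`train_surrogate()` fits a single-hidden-layer feed-forward network (8
logistic hidden units, linear output) with an L2 (ridge) weight penalty as a
deterministic, desk-scale counterpart of Bayesian-regularized
backpropagation; a Gaussian radial-basis interpolator with ridge
regularization is available under the same interface (`backend = "rbf"`).
Three numerical choices matter:

* **Log response.** $Q$ is positive and spans roughly 3.5 decades over the
  box, so the network models $\log Q$ by default (`log_response = TRUE`);
  the log surface is smooth and nearly linear in $P$, and raw-$Q$ training
  is markedly worse everywhere we measured it.
* **Restarts.** Training restarts 10 times from random weights (all derived
  from the one seed) and keeps the lowest-training-loss fit; single starts
  occasionally land in poor local minima on this surface.
* **Standardization.** Inputs are z-scored on the training set; predictions
  outside the training box are returned but flagged (and warned about),
  since the surrogate is trusted only inside it.

`evaluate_surrogate()` reports MAE and RMSE raw (µL/s) and as a percentage
of the observed flow-rate range of the test set -- the published error
percentages state no basis, so the range of the observed values is our
documented convention, and raw values are always reported alongside. The
acceptance tests require median MAE and RMSE below 1% of range over five
seeds of the full 300/50 protocol.

`classify_regimes()` runs k-means (k = 3, k-means++-style seeding under a
fixed seed) on standardized $(n, K, Q)$ features of the flow surface at fixed
pressure and labels the clusters by mean flow rate: the lowest-$Q$ cluster is
the *high-viscosity* regime (settings transfer well between inks there, as
its within-cluster flow variance is the smallest), the highest-$Q$ cluster
the *low-viscosity* regime. Labels are canonical under cluster-index
permutation. The feature set is a documented choice -- only "the surface" is
stated as the clustering object in the source material.

## Toolpath planning

`path_config()` holds the print parameters: normal speed 12 mm/s, slow-start
speed 1 mm/s for $t_0 = 0.1$ s, 0.2 mm layers, 0.8 mm fill spacing, 0.5 mm
frame-to-fill offset, 0.3 mm short-edge overlap distance $D_2$ (the
recommended window is 0.2--0.3 mm), 0.25 mm nozzle. Because a pneumatic
printer cannot instantly start extrusion, every transition from travel to
printing begins with a slow-start segment of length $v_0 t_0$ (0.1 mm) at
the slow speed; the slow segment counts toward the designed length, which is
what removes the systematic shortfall of unoptimized lines. `plan_line()`
plans single strokes; `plan_grid_prism()` plans rectangular prisms: per
layer, perimeter frame first, then a serpentine fill whose short edges stop
exactly $D_2$ from the frame. The `grid` pattern alternates fill orientation
0°/90° between layers (the standard alternation; the third-layer variant
shown in the source figures is not otherwise specified); `solid` keeps one
orientation. Coordinates are right-handed mm with the part origin at the
lower-left of the first layer and $z = \ell \times$ layer thickness.

`extrusion_bookkeeping()` assigns each printed segment its residence time,
deposited volume $Q \cdot t$ and predicted filament diameter at that
segment's speed; totals are conserved exactly. `export_gcode()` writes a
minimal dialect (G0/G1 with feeds in mm/min, M101/M103 extrusion toggles --
no E axis on pneumatic machines -- and comments marking layers and
slow-start segments) that `import_gcode()` round-trips losslessly; files
contain no timestamps so reruns are byte-identical. Travel speed (30 mm/s)
is a default, not a studied value. The planner's contract is geometric and
volumetric fidelity of the *plan*: measured filament widths and lengths are
experimental outcomes and are not simulated.

## What the synthetic data does and does not show

The generators reproduce the statistical *structure* the analysis assumes --
power-law curves with multiplicative noise on a log-uniform grid, design
responses equal to the published polynomials plus Gaussian noise, solver
flow rates over LHS designs -- with every output deterministic under its
seed. They do not emulate instrument artifacts (inertia, slip, evaporation),
batch-to-batch material variation, or any disagreement between the true
composition-rheology map and the published quadratics. Passing tests
therefore demonstrate that the pipeline recovers what it assumes
(identifiability, calibrated noise robustness) and that the flow and
planning models are internally correct against closed forms and brute-force
oracles -- not that the published models are accurate for new laboratory
measurements. The printed ANOVA statistics of the original 17-run experiment
cannot be reproduced because the measured response table is not available;
the tests substitute exact identifiability, the PRESS identity, solver
monotonicity, LHS stratification and the toolpath invariants.

## Problem sizes and determinism

Default sizes are the study protocol itself: 17 design runs, 21-point
curves, 300 + 50 flow samples, 15×15 regime grids, and a 10 × 10 × 3 mm
demonstration part. `run_pipeline()` derives all stage seeds from one master
seed and writes every artifact with an MD5 manifest; rerunning a
configuration reproduces byte-identical files. On one CPU the full pipeline
takes on the order of ten seconds.

## Known limitations

* The nozzle geometry is an assumption calibrated to the reported flow-rate
  scale; absolute flow rates inherit its uncertainty even though all
  monotone trends and closed-form limits are exact.
* The lubrication model omits entrance effects and die swell, which are
  known to matter at the nozzle exit (the slow-start scheme exists precisely
  because of such start-up physics).
* The response-surface models extrapolate outside the composition cube with
  no warranty; `composition_ratio()` warns there.
* Backward elimination with the predicted-$R^2$ retention rule is
  conservative: it may keep null terms (about half the time in our
  Monte-Carlo on this design), trading parsimony for predictive safety.
* The surrogate is only valid inside its training box; extrapolation is
  flagged, not prevented.
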
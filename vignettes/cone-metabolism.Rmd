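---
title: "Modelling cone photoreceptor metabolism: model, numerics and sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cone photoreceptor metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conemet)
```

## The biological system

Cone photoreceptors are among the most energy-hungry cells in the body.
They receive glucose from the retinal pigment epithelium (RPE) through the
GLUT1 transporter, metabolise most of it by aerobic glycolysis, and divert a
fraction into the Kennedy pathway to make glycerol-3-phosphate (G3P), the
lipid precursor needed to renew their outer segments. Shed outer-segment
tips are phagocytosed by the RPE, whose β-oxidation of the recovered fatty
acids returns ketone bodies (β-hydroxybutyrate) that the cone can burn in
its TCA cycle. Rod photoreceptors assist via rod-derived cone viability
factor (RdCVF), which accelerates cone glucose uptake. The package models
this economy for a single cone with six metabolite pools, all in mM, with
time in minutes: internal glucose [G], glycerol-3-phosphate [G3P], pyruvate
[PYR], lactate [LACT], acetyl-CoA [ACoA] and citrate [CIT].

## Governing equations

Rates follow mass-action and Michaelis–Menten kinetics with two allosteric
elements (a cooperative RdCVF switch on uptake and citrate inhibition of
glycolysis). Writing $R = \delta\,[\mathrm{G3P}]$ for the RdCVF proxy (the
rod population tracks cone G3P through the shared lipid economy; $\delta$
converts pool size to rod-supplied RdCVF), the pathway fluxes are

$$
\begin{aligned}
J_a &= \lambda\, n\,(G_E - [\mathrm{G}]) &&\text{basal uptake}\\
J_b &= \lambda\, V_G \Big(\tfrac{R}{K_G + R}\Big)^{2} (G_E - [\mathrm{G}])
  &&\text{RdCVF-stimulated uptake}\\
J_c &= q\, V_{G3P}\, \tfrac{[\mathrm{G}]}{K_{G3P} + [\mathrm{G}]}
  &&\text{G3P synthesis (Kennedy)}\\
J_d &= (1-q)\, V_{PYR}\, \tfrac{[\mathrm{G}]^2}{K_{PYR}^2 + [\mathrm{G}]^2}
  \cdot \tfrac{1}{1 + \beta\,[\mathrm{CIT}]}
  &&\text{pyruvate synthesis}\\
J_g &= \psi\, V_{LACT}\, \tfrac{[\mathrm{PYR}]}{K_{LACT} + [\mathrm{PYR}]}
  &&\text{lactate synthesis (LDHA)}\\
J_f &= \psi\, ([\mathrm{LACT}] - L_E)_+ &&\text{lactate export (MCT)}\\
J_h &= \tfrac{\gamma}{\kappa}\,(L_E - [\mathrm{LACT}])_+
  &&\text{lactate import} \to \text{pyruvate (LDHB)}\\
J_i &= \rho\, V_{ACoA}\, \tfrac{[\mathrm{PYR}]}{K_{ACoA} + [\mathrm{PYR}]}
  &&\text{mitochondrial pyruvate entry}\\
J_k &= \alpha\, K_U \tfrac{[\mathrm{G3P}]}{K_U + [\mathrm{G3P}]}
  &&\text{β-HB-derived ACoA}\\
J_m &= r_0\, [\mathrm{G3P}] &&\text{non-oxidative G3P turnover}\\
J_j &= V_{CIT}\, \tfrac{[\mathrm{ACoA}]}{K_{CIT} + [\mathrm{ACoA}]}
  &&\text{citrate synthesis}\\
J_l &= \phi\, [\mathrm{CIT}] &&\text{citrate} \to \text{ATP / cytosol}
\end{aligned}
$$

and the state equations are their stoichiometric sums:

$$
\begin{aligned}
\dot{[\mathrm{G}]} &= J_a + J_b - J_c - J_d, &
\dot{[\mathrm{G3P}]} &= J_c - J_k - J_m, \\
\dot{[\mathrm{PYR}]} &= J_d + J_h - J_g - J_i, &
\dot{[\mathrm{LACT}]} &= J_g - J_f, \\
\dot{[\mathrm{ACoA}]} &= J_i + J_k - J_j, &
\dot{[\mathrm{CIT}]} &= J_j - J_l.
\end{aligned}
$$

`pathway_fluxes()` evaluates the individual fluxes and `cone_rhs()` their
recombination; the identity between the two is exact and is enforced by the
test suite.

Model assumptions worth keeping in mind:

* The RPE and rods are not explicit compartments. Their influence enters
  through $G_E$, $L_E$, the proxy $R=\delta\,[\mathrm{G3P}]$ and the lumped
  oxidation parameter $\alpha$ (which stands for the whole chain of lipid
  utilisation, shedding, phagocytosis and β-oxidation).
* Glucose uptake is driven by the external–internal gradient; equating
  $G_E$ to the instantaneous $[\mathrm{G}]$ therefore shuts uptake down
  exactly, which is how glucose-shutdown experiments are encoded.
* The RdCVF switch is cooperative (squared saturation term). A
  first-order saturation cannot produce the coexisting healthy and
  pathological states that the analysis revolves around, because the
  G3P→RdCVF→uptake→G3P feedback loop then has insufficient gain steepness
  at low G3P.
* Lactate transport is piecewise linear in the gradient: export above
  $L_E$, import (with LDHB conversion to pyruvate) below it. The vector
  field is continuous but has a kink at $[\mathrm{LACT}] = L_E$; the
  analytic Jacobian uses the one-sided derivative there.

### Parameters and auxiliary constants

The 25 named parameters, their nominal values and the physiological and
monotonicity-restricted ranges used for sensitivity analysis ship with the
package (`cone_parameters()`, `cone_factors()`). Two constants of the G3P
utilisation split are structural rather than named parameters: the
β-oxidation branch saturates with half-constant $K_U = 0.2$ mM, and a
first-order leak $r_0 = 0.0125$ min⁻¹ removes G3P carbon that is
incorporated into membranes and never returns as ketones. The split is what
lets a single $\alpha$ both deplete G3P essentially linearly when the pool
is small (pathological regime) and saturate when the pool is large, so that
the healthy state carries a G3P reserve; it also makes the β-HB flux
vanish when $\alpha = 0$, as the pathway reading requires. Their values
were fixed once, jointly with the functional forms, so that the model
reproduces the documented two-state structure (bistability at the nominal
point with the separatrix near $[\mathrm{G}](0) = 0.02$ mM, a unique
healthy state at $\lambda = 0.09$, two saddle-nodes per branch, and the
starvation floor concentrations); they are deliberately not exposed as
tuning knobs.

## Dynamic repertoire

At the nominal parameter point the model is bistable:

```{r equilibria}
eqs <- find_equilibria(cone_parameters())
t(vapply(eqs, function(e)
  c(e$state[c("G", "G3P")], stable = e$stable), numeric(3)))
```

The healthy state holds several mM of glucose and a substantial G3P
reserve; the pathological state sits two orders of magnitude lower in both;
an unstable saddle separates their basins, with its glucose component near
0.01–0.03 mM — which is why an initial glucose of 0.02 mM falls into the
pathological basin while 2 mM recovers.

`continue_branch()` follows an equilibrium curve in one parameter by
pseudo-arclength continuation (tangent predictor, Newton corrector on the
arclength-constrained system, steps adapting by factors of two on corrector
performance) and refines each detected saddle-node by solving the augmented
fold system $\{f = 0,\; J v = 0,\; \lVert v\rVert = 1\}$, giving fold
locations with a residual eigenvalue below $10^{-6}$. Fold curves in two
parameters (`trace_fold_curve()`) continue the same augmented system in
both parameters; the two saddle-node curves of the $(\alpha, G_E)$ plane
meet at a cusp close to the origin (`estimate_cusp()`). Regime maps
(`map_regions()`) instead count stable equilibria cell by cell — slower but
immune to continuation stalls near the cusp — and the two views are
cross-checked in the tests.

Equilibrium location itself uses damped Newton iteration from two kinds of
starts: a deterministic set of *chain-consistent* states (for a grid of
glucose values, every downstream pool is set to its conditional
equilibrium; all true equilibria lie on this manifold) plus random
log-uniform multistarts over $[10^{-6}, 30]$ mM, seed 1729 by default.
Roots are de-duplicated at $10^{-6}$ mM (max norm) and classified by the
eigenvalues of the analytic Jacobian (stability margin $10^{-8}$).

## Simulation experiments

`integrate_scenario()` integrates with `deSolve::lsoda` at rtol $10^{-8}$ /
atol $10^{-10}$, restarting the solver at glucose-shutdown window edges so
the switching is sharp; states are reported on a 1-minute grid by default.
Negative excursions beyond solver tolerance raise a warning, and
trajectories are clipped at zero on output.

Two named experiment families are packaged:

* `run_deprivation_experiment()`: starvation with the uptake gradient
  clamped for the whole 0–120 min window, external lactate set to prevent
  lactate import, and optional rescue by an initial G3P bolus (2 mM) or an
  external-lactate boost (9.92 mM). In the starved arm the oxidative pools
  collapse to a floor set by the citrate chain: as the acetyl-CoA feed
  dwindles, $[\mathrm{CIT}] \to J_j/\phi$ and
  $[\mathrm{ACoA}] \to K_{CIT} J / (V_{CIT} - J)$ for the residual input
  flux $J$ — about $10^{-4}$ mM ACoA and $7\times10^{-4}$ mM CIT by 50 min.
  The G3P bolus sustains the pools for roughly an hour longer before the
  same collapse, the package's account of why mitochondrion-only fuelling
  buys time but not survival.
* `run_shutdown_experiment()`: the 90-minute shutdown protocol
  ($G_E = 10$ mM, uptake clamped between minutes 40 and 130), in which
  recovery depends jointly on the shutdown duration, the oxidation level
  $\alpha$ and the GLUT1 efficiency $\lambda$.

`classify_outcome()` labels a trajectory by continuing the integration from
its final state until it comes within $10^{-3}$ mM (max norm) of a stable
equilibrium, with a settling horizon of 2000 min. The long horizon matters:
some rescues crawl back to the healthy state over several hours, so a
240-min window would misclassify them.

## Sampling and sensitivity analysis

The sampling module generates the input ensembles for the two GSA methods
and the analytic benchmarks used to validate the estimators:

* `lhs_sample()` — Latin hypercube over any factor table; marginal
  stratification is exact (one point per equal-probability stratum).
* `efast_sample()` — eFAST sinusoidal search curves. The factor of
  interest runs at the distinguished frequency
  $\omega_i = \lfloor (N_s - 1)/(2M) \rfloor$ and the complementary factors
  at low frequencies no higher than $\max(1, \lfloor \omega_i/(2M)
  \rfloor)$, so no complementary harmonic up to order $M$ collides with the
  distinguished harmonics. Defaults: $M = 4$, one resample curve, and 325
  points per curve — the 325-sample reference budget is read as *per curve*;
  both the budget and $M$ are arguments.
* `benchmark_function()` — the Ishigami function (closed-form Sobol
  indices), an additive linear function (exact indices and partial
  correlation signs) and a constant (zero-variance degenerate case).

`prcc_over_time()` computes, at every time point, partial rank correlation
coefficients through the inverse rank-correlation matrix (algebraically the
residual-correlation definition), with significance from the t
approximation on $N - 2 - (k - 1)$ degrees of freedom. Degenerate time
points (constant output) yield `NA`, not zero. `efast_over_time()`
Fourier-decomposes each search curve per time point: first-order indices
from the distinguished harmonics, total-order from the complement of the
low-frequency band, averaged over resample curves; `integrate_series()`
provides trapezoidal time-integrated summaries, with the per-timepoint
series as the primary view.

Influence calls follow fixed rules (`influential_set()`): for PRCC,
$|\mathrm{PRCC}| > 0.4$ with $p < 0.001$ somewhere in the window; for
eFAST, a total-order index exceeding the cross-factor median by at least
two median absolute deviations somewhere in the window — a quantitative
stand-in for "visibly separates from the clustered bulk". No
multiple-testing correction is applied across factors or time points; the
thresholds are arguments for users who want different conventions.

The two analysis arms start from $[\mathrm{G}](0) = 0.02$ mM (severe
nutrient stress) and 2 mM (sufficient for cone operation), lactate at
9.4 mM, other pools empty, over 0–240 min (`gsa_template()`). PRCC varies
initial conditions as factors; eFAST varies the 25 parameters with initial
conditions held at the arm's values.

What these ensembles do and do not emulate: they probe the model's own
parameter uncertainty under idealised, noise-free dynamics. There is no
measurement error, no cell-to-cell variability, and no model discrepancy
term, so a passing ranking says which *model* mechanisms drive the outputs,
not which biological measurements would be most informative in a real
retina.

## Numerical choices and degenerate cases

* Solver: `lsoda` (stiff-capable). Ensemble sweeps relax to rtol
  $10^{-6}$ / atol $10^{-9}$; the negative-concentration guard scales with
  atol.
* Newton iterations use the analytic Jacobian with backtracking damping
  and projection onto the non-negative orthant; corrector steps that move
  farther than the predictor step are rejected, which prevents jumps
  between nearby branches where the separatrix passes close to the
  pathological state.
* The continuation seeds both directions from every starting equilibrium
  and deduplicates folds at $10^{-6}$ in the parameter.
* Equilibrium counting near fold curves is intrinsically fragile within
  $\sim10^{-3}$ of the fold; the region maps accept a disagreement band of
  one grid cell against the continuation curves.
* Zero states, zero substrate and $\alpha = 0$ are exact fixed points or
  switch-offs and are tested as such; the constant benchmark exercises the
  zero-variance path of both estimators.

## Scale of the shipped analyses

The test suite and the acceptance script run everything at desk scale,
chosen so the full battery completes comfortably on one CPU: 200 LHS
samples for PRCC, 65 points per eFAST curve, 12-point GLUT1 scans with
bisection to 0.01 mM for the regime ceiling, and settling horizons of
2000 min for outcome classification. The estimator-validation tests use
257-point curves where spectral accuracy matters. Larger budgets (the
full 325-point curves, finer maps) are a matter of passing different
arguments.

## Known limitations

* $\alpha$ lumps lipid utilisation, shedding, phagocytosis and
  β-oxidation into one rate; the model cannot separate failures along that
  chain.
* Lactate export is fast, so $[\mathrm{LACT}]$ stays pinned near $L_E$
  and its sensitivity profile is dominated by $L_E$ itself.
* ATP is not tracked; citrate export is a proxy for energy delivery.
* The healthy/pathological labels are model-state labels; no claim about
  cell-death mechanisms is implied.
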
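---
title: "Population-state dynamics: the Demographic-Wealth Model and its bifurcations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-state dynamics: the Demographic-Wealth Model and its bifurcations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliodyn)
```

## The models

Cliodynamics asks whether the recurring rise and fall of states — the
*secular cycles* seen over decades and centuries in historical population
records — can be generated by simple endogenous mechanisms rather than
external shocks. `cliodyn` implements and analyses two minimal planar ODE
models of a population density $N(t)$ interacting with accumulated state
resources $S(t)$, both dimensionless.

**Demographic-Fiscal Model (DFM).** The state taxes the surplus of a
logistically growing population and spends per capita:
$$\dot N = rN\Big(1 - \frac{N}{k(S)}\Big), \qquad
  \dot S = \rho_0 N\Big(1 - \frac{N}{k(S)}\Big) - \beta N,
  \qquad k(S) = k_0 + \frac{cS}{s_0 + S}.$$
State wealth raises the carrying capacity, but with a hard bound
$k_{\max} = k_0 + c$ (land and productivity are finite). Wealth may not go
negative: once $S$ hits zero with negative drift the state has collapsed,
$S$ is held at zero, and the population relaxes logistically to $k_0$. The
DFM therefore produces exactly one rise-and-fall per run — every state with
positive expenditure rate $\beta$ is transient, and only a perturbation
could start another cycle.

**Demographic-Wealth Model (DWM).** The alternative studied in depth here
changes the modelling assumptions about taxation and expenditure:
$$\dot N = rN\Big(1 - \frac{N}{k_0 + cS}\Big) - \frac{\alpha S N}{d + N},
  \qquad \dot S = gSN - \beta S.$$
Capacity still grows with wealth ($k_0 + cS$, linear because $S$ now
measures expandable assets such as land), but the state also *feeds back
negatively* on its population through a Holling type-II extraction term
$\alpha S N/(d+N)$: a wealthier state extracts more (taxation, warfare,
exploitation), saturating in $N$ with half-saturation constant $d$. State
wealth grows through taxation-and-reinvestment $gSN$ (only the product
$g = \tau\rho$ of tax rate and reinvested fraction matters, so only $g$ is
stored) and decays through upkeep $\beta S$ proportional to wealth itself.
Structurally this is a consumer-resource (predator-prey) system with the
state in the consumer role, which is why classical tools — nullcline
analysis, Hopf theory, the paradox of enrichment — apply.

## Equilibria and the stability functional

The DWM always has the origin (a saddle: its Jacobian is
$\mathrm{diag}(r, -\beta)$) and the stateless population $(k_0, 0)$, whose
triangular Jacobian has eigenvalues $-r$ and $gk_0 - \beta$. The stateless
state is a sink iff $\beta/g > k_0$ — a state that spends faster than it can
grow on the available capacity never establishes itself. (We classify
$(k_0,0)$ for $\beta/g < k_0$ as a saddle, which the eigenvalues force; the
point is unstable either way.)

The interior *coexistence point* has $N^* = \beta/g$ from the wealth
nullcline, and $S^*$ solving
$\alpha S/(d+N^*) = r\,(1 - N^*/(k_0 + cS))$. Clearing denominators gives a
quadratic with a unique positive root whenever $N^* < k_0$ (linear closed
form for $c = 0$); `coexistence()` returns `NULL` when no admissible root
exists. Clearing can in principle introduce a spurious root, so if both
roots are positive the one satisfying the original relation is kept (with a
warning); under the model's constraints this does not occur.

Stability of the coexistence point is governed by the functional
$$\mu(N^*, S^*) \;=\; p(N)\,\frac{\partial}{\partial N}
  \Big(\frac{N\,g(N, S^*)}{p(N)}\Big)\Big|_{N = N^*}
  \;=\; \frac{rN^*}{d+N^*}\Big(1 - \frac{2N^* + d}{k_0 + cS^*}\Big),$$
with $g(N,S) = r(1 - N/(k_0+cS))$ and $p(N) = \alpha N/(d+N)$, the partial
taken in $N$ with $S^*$ held fixed as a parameter of the expression. The
reduction uses $N/p(N) = (d+N)/\alpha$, and `mu_value()` is exactly the
Jacobian trace at the coexistence point (the lower-right entry $gN^*-\beta$
vanishes there) — an identity the test suite checks against the independent
`dwm_jacobian()` route on randomized parameter sets. $\mu < 0$ means
stability; $\mu = 0$ with positive determinant is a Hopf bifurcation.

For $c = 0$ (wealth no longer buys capacity — e.g. an island) the Hopf
condition becomes fully explicit, $k_0 = 2\beta/g + d$, with the
rearrangements for $d$, $\beta$ and $g$ returned by `hopf_critical_c0()`.
Existence restrictions follow from positivity: no Hopf in $d$ unless
$k_0 > 2\beta/g$, none in $g$ or $\beta$ unless $d < k_0$; these return an
explicit no-Hopf value (`NA` with a reason) rather than an error.

## Continuation, Hopf detection, and the first Lyapunov coefficient

Because every DWM equilibrium is available in closed form,
`sweep_equilibria()` implements "continuation" as branch evaluation on a
parameter grid (2001 points by default) plus sign-change detection and
bisection to $10^{-12}$ — predictor-corrector machinery would add nothing
here. Two kinds of points are detected and refined:

* **transcritical (branch) points**, where the signed wealth branch $S^*$
  crosses zero, i.e. $\beta/g = k_0$; for $g$, $\beta$, $k_0$ the root is
  returned in closed form ($\beta/k_0$, $g k_0$, $\beta/g$). The stateless
  and coexistence equilibria exchange stability across it.
* **Hopf points**, where the trace crosses zero with positive determinant.
  `find_hopf()` certifies the candidate (purely imaginary eigenvalue pair)
  and attaches the first Lyapunov coefficient.

`first_lyapunov()` shifts the system to the equilibrium, maps it by the
eigenbasis $T = [\mathrm{Re}\,q, -\mathrm{Im}\,q]$ of the eigenvector for
$i\omega$ (bringing the linear part to rotation form), and evaluates the
classical planar normal-form coefficient from *analytic* second- and
third-order partials of the vector field — no finite differencing, so the
tiny coefficients this slow system produces (order $10^{-7}$) are still
sign-reliable. Only the sign is contract-bearing (normalisation conventions
differ between textbooks): $l_1 < 0$ is a supercritical Hopf, and the suite
corroborates it dynamically by checking that the emergent cycle's amplitude
grows like $\sqrt{g - g_{\mathrm{Hopf}}}$ over five offsets.

For the baseline parameter set $r = 0.02$, $\alpha = 0.05$, $g = 0.15$,
$\beta = 0.1$, $c = 0.5$, $k_0 = 1$, $d = 1$ (preset `fig3`):

```{r hopf}
p <- preset("fig3")$params
find_hopf(p, "g", c(0.5, 1.5))
find_transcritical(p, "g")
round(find_hopf(p, "beta", c(0.005, 0.05))$param_value, 3)
round(find_hopf(p, "k0", c(1, 3))$param_value, 3)
```

## Simulation and cycle measurement

`integrate_dwm()` uses adaptive lsoda (deSolve) at tolerances
`rel_tol = 1e-8`, `abs_tol = 1e-10` — far tighter than plotting needs,
because trajectories feed peak detection. The positive quadrant is
invariant (the axes are orbits), so only round-off excursions are clipped.

`integrate_dfm()` honours the collapse rule by exact event handling rather
than a conditional clamp inside the right-hand side (which makes adaptive
solvers chatter at the discontinuity): a free phase integrates the raw
field with a root function on $S$, recording the collapse time $t^*$; a
collapsed phase pins $S = 0$, integrates the logistic population equation,
and watches the raw drift with a second root function so the state would be
released if the drift turned positive. The clamp is drift-conditional
because with the Fig-1-style start $S_0 = 0$ the drift is positive and the
state must be allowed to rise.

```{r dfm}
pf <- preset("fig1")$params     # beta = 0.25
tr <- integrate_dfm(pf, sim_config(c(0.5, 0), 600))
trajectory_events(tr)
```

`cycle_summary()` discards a transient (50% of the horizon by default,
automatically extended to 70%/85% when inconclusive — convergence slows
dramatically near a Hopf point), finds local maxima of $N(t)$ by
three-point comparison refined with quadratic interpolation, and rules:
fixed point if the late amplitude is below $10^{-6}$ of the mean level;
limit cycle if at least 5 peaks exist and the last successive peak heights
agree within 0.5%; undecided otherwise. The period is the mean refined
inter-peak interval.

```{r cycles}
f11 <- preset("fig11")
cycle_summary(integrate_dwm(f11$params, sim_config(f11$initial, f11$t_end)))
```

## The paradox of enrichment

Sweeping the stateless capacity $k_0$ with everything else at the baseline
reproduces, in the state-population setting, Rosenzweig's enrichment
paradox: below $\beta/g = 2/3$ the state cannot survive; between $2/3$ and
$2.095$ coexistence is stable; beyond $2.095$ a supercritical Hopf sheds a
limit cycle whose amplitude grows with $k_0$ while its wealth and
population minima sink toward zero — enriching the capacity pushes the
society into ever-deeper boom-and-bust, and close to the axes a small
perturbation would mean extinction/collapse. `enrichment_scan()` and
`cycle_branch()` quantify this; the simulated branch uses an adaptive
horizon $14/\mu$ (capped at $2\times 10^6$ time units) because the
relaxation rate onto the cycle is proportional to the trace and vanishes at
the Hopf point, and dense output sampling (20000 points per horizon) so
that the narrow peaks of the relaxation-type cycles at large $k_0$ are
resolved by the 0.5% peak-agreement test.

## Numerical choices, defaults, and scale

* Grid default 2001 points per sweep: ample to bracket every bifurcation
  this model produces at the studied scales; bisection then refines to
  $10^{-12}$, so the grid only needs to bracket, not locate.
* Nonhyperbolicity is flagged scale-aware at
  $|\mathrm{tr}| < 10^{-9}\max(1, |\det|)$.
* Hopf certification requires $|\mathrm{tr}| < 10^{-6}$ and $\det > 0$
  before a Lyapunov coefficient is computed.
* Preset horizons (e.g. 8000 for the baseline, 40000 for $k_0 = 2$, 20000
  for the limit-cycle preset) are chosen as several e-folding times of the
  relevant focus — the baseline damping rate is $\mu/2 \approx -0.0042$ —
  or tens of cycle periods ($\approx 220$ time units for the limit-cycle
  preset); these sizes keep every analysis in this package desk-scale
  (seconds to a couple of minutes).
* All quantities are dimensionless, as in the underlying models; no unit
  system is imposed. Parameter validation rejects zero rates except the two
  analysed special cases $c = 0$ (DWM/DFM) and $\beta = 0$ (DFM).

## What the presets do and do not show

The preset registry transcribes parameter combinations studied with these
models (the damped baseline, its $k_0$, $r$, $\alpha$ variants, the
limit-cycle scenario, and the DFM expenditure/taxation variants). They are
mathematical scenarios, not fitted histories: the models are deliberately
macroscopic, with two state variables standing in for demographic,
economic and political structure. Passing tests show that the package
reproduces the dynamical structure of the models — equilibria, stability
exchanges, Hopf points, cycle growth — not that those models match any
particular historical record; fitting to data (and the overfitting issues
that come with many free parameters) is explicitly out of scope.

## Known limitations

* Cycle branches are simulation-based; there is no collocation/shooting
  continuation of periodic orbits with Floquet multipliers, and no
  two-parameter bifurcation surfaces.
* `cycle_summary()` is undecided on horizons that do not contain at least
  five post-transient peaks; very close to a Hopf point the adaptive
  horizon cap can leave a verdict undecided rather than wrong.
* The DFM revival root (drift turning positive while collapsed) is exact,
  but repeated collapse-revival chatter, which the models studied here do
  not produce, would be reported as a long event list rather than
  coalesced.
* Alternative nonlinearities (different powers of $S$, $N$) and
  class-structured extensions are out of scope.
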
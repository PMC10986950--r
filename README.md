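# cliodyn

Simulation and bifurcation analysis of minimal population–state dynamics
models for cliodynamics — the quantitative study of the long-run rise and
fall of states ("secular cycles").

## The science

The package implements two planar ODE models of a population density
`N(t)` interacting with accumulated state resources `S(t)`:

* the classical **Demographic-Fiscal Model (DFM)**

  $$\dot N = rN\left(1 - \tfrac{N}{k(S)}\right),\qquad
    \dot S = \rho_0 N\left(1 - \tfrac{N}{k(S)}\right) - \beta N,\qquad
    k(S) = k_0 + \tfrac{cS}{s_0 + S},$$

  in which state wealth raises the population's carrying capacity until
  expenditures outrun revenue, `S` hits zero, and the state collapses
  (wealth is constrained nonnegative, handled as an integration event); and

* the **Demographic-Wealth Model (DWM)**

  $$\dot N = rN\left(1 - \tfrac{N}{k_0 + cS}\right)
    - \tfrac{\alpha S N}{d + N},\qquad
    \dot S = gSN - \beta S,$$

  a consumer–resource-type system in which the state also feeds back
  negatively on its population through a saturating (Holling type-II)
  extraction term. Unlike the DFM, the DWM can sustain periodicity without
  resets: its interior *coexistence point* `(N*, S*) = (β/g, S*)` loses
  stability through **supercritical Hopf bifurcations**, producing stable
  limit cycles — an endogenous mechanism for secular cycles. Stability is
  governed by the functional `μ(N*,S*)`, equal to the Jacobian trace at the
  coexistence point, with closed-form critical values when `c = 0`
  (`k0 = 2β/g + d` and its rearrangements). Sweeping the stateless capacity
  `k0` reproduces the **paradox of enrichment**: richer capacity first
  fattens the state, then destabilises the whole society into growing
  boom–bust cycles whose minima approach zero.

The toolkit provides exact Jacobians, closed-form equilibria and
classification, `μ` and its closed-form zeros, one-parameter sweeps with
transcritical/Hopf detection and bisection refinement, analytic first
Lyapunov coefficients, event-aware integration (deSolve), limit-cycle
period/amplitude extraction, an enrichment scan, figure presets, CSV/config
I/O, and a small CLI (`inst/cli/cliodyn.R`).

## Worked example

```r
library(cliodyn)

p <- preset("fig3")$params   # r=0.02, g=0.15, alpha=0.05, beta=0.1, c=0.5, k0=1, d=1
coexistence(p)
#> coexistence equilibrium at (N = 0.666667, S = 0.276142): stable-focus
#>   trace = -0.00840202, det = 0.000686292, eigenvalues = -0.004201+0.0258581i, -0.004201-0.0258581i

find_hopf(p, "g", c(0.5, 1.5))
#> hopf point at parameter value 0.9916079783
#>   l1 = -1.43132e-07 (supercritical), omega = 0.0424734

find_transcritical(p, "g")
#> [1] 0.1
```

The baseline coexistence point is a weakly damped stable focus (complex
eigenvalues with small negative real part: slow decaying oscillations of
population and wealth). Raising the state growth coefficient `g` to 0.992
destabilises it through a supercritical Hopf bifurcation (`l1 < 0`): beyond
that value the society settles into a stable cycle of state growth and
decline with angular frequency near `omega`. Below the branch point
`g = 0.1` (= `beta/k0`) the state cannot establish itself at all.

Simulating the limit-cycle preset:

```r
f11 <- preset("fig11")
cycle_summary(integrate_dwm(f11$params, sim_config(f11$initial, f11$t_end)))
#> attractor: limit-cycle (period 220.184, 46 peaks)
#>   N in [0.0779191, 1.40526], S in [0.0637431, 45.0555]
```

— a sustained secular cycle: population peaks followed by deep troughs,
with state wealth swinging over three orders of magnitude, period about
220 time units. The DFM, by contrast, always ends stateless:

```r
pf <- preset("fig1")$params  # beta = 0.25
tr <- integrate_dfm(pf, sim_config(c(0.5, 0), 600))
trajectory_events(tr)
#>     time          label
#> 1 245.64 state_collapse
```

From the shell:

```sh
Rscript inst/cli/cliodyn.R bifurcate --preset fig3 --sweep g --lo 0.01 --hi 2 --out diag.csv
Rscript inst/cli/cliodyn.R simulate --preset fig11 --out traj.csv
```

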
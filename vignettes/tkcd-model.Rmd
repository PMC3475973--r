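---
title: "The toxicokinetics cell demography model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The toxicokinetics cell demography model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkcd)
```

## The model and its assumptions

The organism is reduced to its intestine, a population of epithelial cells
of one type. Cells can do exactly two things: absorb toxic particles and
die. There is no cell repair and no decontamination; a cell that has
absorbed a particle keeps it until it dies, and a dying cell is discharged
into the gut lumen together with its whole load. Dead cells are replaced by
fresh, uncontaminated ones at a constant rate `b` — the organism does not
(in this minimal version) up-regulate cell production in response to
damage.

Cells are grouped into `l` discrete contamination classes; class `i` holds
the cells carrying `i − 1` particles. Each class has a death probability
`d_i` per unit time, strictly increasing in the load, with `d_1 > 0`
(baseline turnover of healthy epithelium) and `d_l = 1` (a cell in the top
class cannot persist — this is what keeps turnover going even when the
epithelium is saturated). During one time unit, `delta_c` particles arrive;
a surviving cell absorbs one with probability `r = delta_c / N`, where `N`
is the current cell count, and moves up one class. Treating these
per-interval probabilities as continuous-time rates (the time-scale
constant is set to 1, so all times are in model time units) gives the ODE
system implemented in `tkcd_derivatives()`:

$$\dot N_1 = b - \bigl(d_1 + (1-d_1)r\bigr)N_1, \qquad
  \dot N_i = (1-d_{i-1})\,r\,N_{i-1} - \bigl(d_i + (1-d_i)r\bigr)N_i,$$

with the top-class outflow reducing to $N_l$ because $d_l = 1$. Two balance
identities pin the structure down and are asserted in the test suite: total
cells change as births minus deaths, $\sum_i \dot N_i = b - \sum_i d_i N_i$,
and the burden changes as absorption minus removal,
$\sum_i (i-1)\dot N_i = \sum_{i<l}(1-d_i) r N_i - \sum_i d_i (i-1) N_i$.

The interesting emergent quantity is the instantaneous elimination rate
$k = \sum_i N_i d_i (i-1) \big/ \sum_i N_i (i-1)$: the fraction of the
burden removed per time unit. It is invariant under rescaling of the
intestine but depends on the class composition, so it is bounded between
`d_2` (all contamination in the lowest contaminated class, the state right
after onset) and 1 (everything in the top class). The classic
one-compartment model corresponds to the degenerate case of a single
contaminated class, where `k` is genuinely constant; `R/classic.R`
implements that model and its phase-switching variants for comparison.

## Admissibility

`r = delta_c/N` is a probability, so only trajectories with
`delta_c ≤ N(t)` throughout are biologically sensible. The solver treats a
violation as a hard error by default; `clamp = TRUE` instead caps `r` at 1,
warns once, and marks the trajectory inadmissible. We chose the hard error
as the default because a clamped run silently changes the model (absorption
saturates instead of outrunning the epithelium), which should never happen
unnoticed. The built-in high-toxicity scenario sits just inside the
boundary: its equilibrated epithelium keeps `delta_c/N ≈ 0.996`, and no
admissible stationary state exists for `delta_c ≳ 34.2` at those
parameters.

## Parameters and defaults

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `b` | cell production | cells / time unit | 10 (reference scenarios) |
| `l` | number of contamination classes | — | 5 |
| `d` | per-class death probabilities | / time unit | `(0.1, 0.11, 0.2, 0.9, 1)` |
| `delta_c` | toxicant influx | particles (toxic units) / time unit | scenario: 1, 9 or 34 |
| `dt` | RK4 step | time units | 0.01 |
| `eps` | equilibrium threshold on max rate | cells / time unit | 1e-9 |
| `t_max` | default horizon | time units | 200 (presets: 250) |

The reference `d` vector is illustrative rather than fitted: mortality is
nearly flat over the first classes and rises steeply near saturation, which
is what produces the characteristic overshoot-then-decline burden
trajectory at high exposure. `l` is the resolution of the model — more
classes discretize the underlying continuous mortality curve more finely.
`discretize_mortality()` builds `d` from such a curve (tabulated,
linear, or saturating-exponential); only monotonicity and the endpoint
conditions are constrained by the theory, the shape in between is
substance-specific. `effective_influx()` rescales a particle influx by a
potency so that substances with additively acting toxicity and a shared
curve shape can reuse one `d` vector (and composing the two handles
substances that differ in both potency and shape).

How `delta_c` relates to a measured food concentration and ingestion rate
is left to the user: the mapping from mg/kg food to particles per time unit
depends on feeding biology that the model does not describe.

## Numerical choices

*Integration.* The system is non-stiff at realistic parameters, so the
default integrator is fixed-step classical Runge–Kutta (deSolve's `rk4`)
with `dt = 0.01`; `lsoda` is available for unusual parameter ranges.
Halving the step moves the endpoint of a moderate-exposure run by less than
1e-6 relative (asserted in the tests), so the default step is far inside
the converged regime. Integration restarts exactly at exposure-schedule
breakpoints, which are half-open — a breakpoint belongs to the segment that
starts there. Observables are computed after integration at stored points;
peak times therefore have a resolution equal to the storage stride
(default: every step, 0.01 time units).

*Equilibrium detection.* A run is flagged equilibrated when
`max |dN_i/dt| < eps` (default 1e-9) in its final exposure segment, checked
in 5-time-unit chunks so the run can stop early. In double precision the
rates at the numerical fixed point bottom out near 1e-13–1e-12 (rounding
noise on terms of magnitude `b`), so thresholds below ~1e-12 are not
reachable and the default keeps a large margin above that floor.

*Stationary solver.* At constant `delta_c` the stationary composition
follows a forward recursion in the class index given the intestine size
`N`; `solve_equilibrium()` closes it by finding the self-consistent size
with damped fixed-point iteration (damping 0.5, start `b/d_1`, relative
tolerance 1e-10, at most 1e5 iterations) and falls back to a bracketing
root search on `g(N) = \sum_i N_i(N) − N` over `(0, b/d_1]`. Uniqueness of
the fixed point is not guaranteed by theory, so a 257-point sign-change
scan of `g` runs first and the solver refuses to choose if several roots
appear (none do at the reference parameters). The solution is accepted only
if the full right-hand side evaluates below 1e-8 and the admissibility
condition holds at it.

*Undefined elimination rate.* While the burden is zero, `k` is undefined —
there is nothing to eliminate — and is represented as `NA`, serialized as
an empty CSV field, never as 0.

## The reference scenarios and what they show

`run_preset()` runs constant exposure at `delta_c` 1, 9 and 34 from the
uncontaminated equilibrium of 100 cells over a 250-time-unit horizon
(equilibration at the default threshold occurs by t ≈ 201, 207 and 128
respectively, so all three flag equilibrated). Low exposure produces minor
cell loss (≈ 1 %) and a burden plateau ≈ 7.6; moderate exposure an
overshoot to ≈ 43.8 at t ≈ 18 followed by a slight decline to ≈ 42.3 with
≈ 16.6 % cell loss; high exposure massive loss (≈ 65.9 %) and a pronounced
burden peak (≈ 85 at t ≈ 6) that then falls back to ≈ 47 — close to the
moderate scenario's level — as the thinning epithelium sheds its load
faster than it absorbs. The elimination-rate series of the high scenario
starts at `d_2 = 0.11` and rises toward ≈ 0.51 at equilibrium, the clearest
demonstration that a constant `k_e` is a structural approximation.

These scenarios are deterministic ODE runs, not data: passing the checks
shows that the implementation reproduces the model's predicted kinetics,
not that the model fits any particular organism. Fitting the mechanistic
parameters (cell mortalities) to whole-body concentration data is
deliberately not offered as an inference tool — the parameters are not
identifiable from such data in a scientifically meaningful way — though
`fit_one_compartment()` provides a clearly labelled least-squares overlay
of the classic model for diagnostics.

## Known limitations

- Constant birth rate: no damage-induced up-regulation of cell production,
  which real organisms likely have in some form.
- No cell repair or decontamination; a single organ only, with no transport
  between tissues (a multi-organ extension would couple several such cell
  populations).
- Whole-organism mortality is out of scope: the model quantifies damage to
  the intestine, not survival.
- The deterministic ODE treats cells as a continuum; no stochastic
  (individual-cell) counterpart is provided.
- Exposure schedules are piecewise constant; smoothly varying influx must
  be approximated by steps.
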
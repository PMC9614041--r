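---
title: "From molecular motors to the Hill force-velocity curve: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From molecular motors to the Hill force-velocity curve: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(pcmhill)
```

## The scientific question

The hyperbolic force-velocity relation of the Hill muscle model,

$$v_{hill}(f) = v_0\,\frac{f_s - f}{f_s + f/\beta},$$

is usually treated as a phenomenological fit: $v_0$ is the unloaded
shortening velocity, $f_s$ the stall force, and $\beta$ a dimensionless
curvature. `pcmhill` asks whether this shape emerges from a mechanistic
model of the molecular machinery — an ensemble of non-processive myosin-II
motors cyclically binding to actin, executing power strokes, and unbinding
with catch-bond kinetics. The package implements the molecular model, solves
its long-time behaviour both deterministically and stochastically, sweeps
the external load, and fits the Hill hyperbola to the resulting
force-velocity curve.

## The parallel cluster model

A cluster of $N$ identical myosin-II motors shares a constant external
force $f$ (pN). Each motor is free (0), bound pre-power-stroke (1) or bound
post-power-stroke (2); the ensemble state is $(i, j)$ with $i$ bound motors
of which $j$ are post-power-stroke. Each bound motor hangs from the backbone
by a linear spring of stiffness $k_m$ (pN/nm), and the power stroke advances
the lever arm by $d$ (nm). Motors in the same state bear the same load
(the mean-field "parallel cluster" assumption), so force balance fixes the
pre-power-stroke strain

$$\varepsilon_{ij} = \frac{f/k_m - j\,d}{i}, \qquad
  f = k_m\,(i\,\varepsilon_{ij} + j\,d),$$

and a post-power-stroke motor carries $f^{pp}_{ij} = k_m(\varepsilon_{ij} + d)$.
`pcm_strain()`, `pcm_force_balance()` and `pcm_post_stroke_force()` implement
these; the reconstruction identity is exercised in the tests over a grid of
states and forces at relative tolerance $10^{-12}$.

**Local thermodynamic equilibrium (LTE).** Power-stroke transitions occur on
nanosecond scales while binding and unbinding occur on millisecond scales,
so $j$ equilibrates between slow events. Given $i$, the occupancy is
Boltzmann,

$$\Pr(j \mid i) = \frac{e^{-e_{ij}/k_BT}}{Q_i}, \qquad
  e_{ij} = j\,e_{pp} + \frac{k_m}{2}\left[(i-j)\,\varepsilon_{ij}^2
  + j\,(\varepsilon_{ij}+d)^2\right],$$

with $e_{pp} < 0$ the phosphate-release bias. Because $e_{ij}/k_BT$ spans
hundreds of units at realistic $e_{pp}$, the weights are computed with a
max-shift (log-sum-exp); `pcm_boltzmann()` also returns $\log Q_i$, which
stays finite when $Q_i$ itself overflows. The explicit stroke rates
$k_{12}, k_{21}$ are stored in `pcm_params()` for completeness but unused;
asking `pcm_simulate()` for non-LTE dynamics raises a not-implemented error
rather than silently approximating.

**Catch-bond unbinding.** Post-power-stroke unbinding follows a
reaction-rate law with inverted force dependence,
$\mathrm{Tr}_{20}(i,j) = k_{20}^0 e^{-f^{pp}_{ij}/f_0}$: tension
*strengthens* the bond. This is the mechanistic origin of the concave
force-velocity curve — under higher load motors stay attached longer, the
duty ratio rises, and sliding slows smoothly toward stall.

**Position bookkeeping.** The ensemble position is the average position of
the bound heads. Power strokes and most unbindings do not move it; two
event types do:

* a new binding (from $i$ bound, $i \ge 1$) shifts it by
  $\Delta Z_{on}(i) = -\tfrac{1}{i+1}\sum_j \varepsilon_{ij}\Pr(j\mid i)$;
  the first binding of an unbound ensemble occurs at zero strain and is
  defined to move nothing, $\Delta Z_{on}(0) = 0$;
* the unbinding of the *last* bound motor shifts it by minus the strain of
  the departing head.

The drift velocity conditional on $i$ combines both at their rates:

$$V_i = (N - i)\,k_{01}\,\Delta Z_{on}(i)
 - \left[k_{10}\,\varepsilon_{10}\Pr(0\mid 1)
 + \mathrm{Tr}_{20}(1,1)\,\varepsilon_{11}\Pr(1\mid 1)\right]\delta_{i1}.$$

The grouping of both last-unbinding contributions under $\delta_{i1}$ is a
documented reading of a typographically ambiguous expression: only when the
single remaining motor lets go — from either bound state — does its strain
relocate the ensemble. Positive values are motion in the contraction
direction (toward the F-actin barbed end); raw signed values are preserved
everywhere.

## Master equation and the mean bound velocity

Under LTE the slow dynamics reduce to a one-step birth-death chain in $i$
with effective rates

$$g(i) = (N - i)\,k_{01}, \qquad
  r(i) = \sum_j \Pr(j \mid i)\left[(i-j)\,k_{10} + j\,\mathrm{Tr}_{20}(i,j)\right].$$

The reverse rate is the one genuine modelling gap here: the state-conditional
velocities specify displacements, not the $i$-process rates, and the
LTE-weighted sum over $j$ is the construction consistent with the
transition-rate symbols of the molecular model. The stationary distribution
follows from detailed balance, $\Pr_{i+1}/\Pr_i = g(i)/r(i+1)$, accumulated
in log space; the tests verify it against an independent null-space solution
of the full $(N{+}1)$-state generator matrix at $10^{-10}$ for all
$N \le 25$. The mean bound-ensemble velocity renormalizes the stationary
distribution over bound states,

$$V_b = \sum_{i \ge 1} V_i\,\widehat{\Pr}_i(\infty),$$

implemented as simple renormalization of the stationary probabilities over
$i \ge 1$ (not conditioning on non-absorption — the chain has no absorbing
state whenever some unbinding rate is positive).

```{r master}
p <- pcm_params(N = 4)
pcm_master(0, p)
```

## Stochastic simulation

`pcm_simulate()` is an exact stochastic simulation of the same one-step
process: exponential waiting times by Monte-Carlo inversion
($\Delta t = -\log u / (g(i)+r(i))$), events by rate ratio, position updated
by the bookkeeping rules above. On a last-motor unbinding the departing
head's stroke state is sampled from the *unbinding channels* — probability
proportional to $\Pr(j\mid 1)$ times that state's unbinding rate — because
that is the exact decomposition of $r(1)$ into elementary events; sampling
$j$ from the bare Boltzmann weights would bias the mean displacement per
event away from the $\delta_{i1}$ term of $V_i$ (at the default parameters
the two schemes are numerically indistinguishable, since
$\Pr(1\mid 1) \approx 1 - 5\times10^{-7}$).

Trajectories start bound ($i_0 = 1$, $Z = 0$); stationary summaries
(`pcm_occupancy()`, `pcm_empirical_velocity()`) discard the first 10% of
events as burn-in. The same seed, parameters and force always reproduce a
bit-identical trajectory. The empirical velocity is net displacement over
time spent bound, with a nonparametric bootstrap standard error over the
(dwell, displacement) pairs.

```{r ssa}
traj <- pcm_simulate(0, p, n_events = 2e4, seed = 1)
pcm_empirical_velocity(traj)$velocity   # compare: V_b = 640 nm/s
```

## Force-velocity sweep and the Hill fit

`pcm_fv_sweep()` evaluates $V_b(f)$ on a force grid by either method;
`fit_hill()` fits the hyperbola by Levenberg-Marquardt nonlinear least
squares (via `minpack.lm`). Numerical choices: points at or beyond stall
($V_b \le 0$) are excluded, since the relation describes shortening;
starting values are $v_0$ at the smallest-force velocity, $f_s$ at the
interpolated zero crossing, $\beta = 1$; $\beta$ is box-constrained to
$(0, 100]$ to keep the optimizer away from the degenerate linear limit.
`hill_fit_r2()` reports $R^2$ on a restricted force range, conventionally
the sub-stall range $[0, 0.95\,\hat f_s]$.

```{r fit}
grid <- seq(0, 1.05 * pcm_stall_force(p), length.out = 30)
curve <- pcm_fv_sweep(p, grid)
fit <- fit_hill(curve)
fit
plot(fit)
```

For the default parameters the fit is excellent ($R^2 > 0.999$ at
$N \in \{4, 9, 15\}$), which is the package's operational form of the claim
that the molecular force-velocity diagram is Hill-like. The empirical stall
force (`pcm_stall_force()`, bisection on $V_b(f)$) is reported separately
from the fitted $\hat f_s$; the two differ by a few percent because the
hyperbola is only an approximation near stall.

## Default parameters and what they mean

The molecular-model defaults are literature values for skeletal-muscle
myosin-II, not quantities estimated by this package:

| parameter | default | unit | meaning |
|---|---|---|---|
| `N` | 4 | – | motors per ensemble (small clusters; also 9, 15 in the studies) |
| `k_m` | 2.5 | pN/nm | neck-linker stiffness |
| `d` | 8 | nm | power-stroke increment |
| `e_pp` | −60 | pN nm | stroke energy bias |
| `kBT` | 4.14 | pN nm | thermal energy at ~300 K |
| `k01` | 40 | 1/s | binding rate |
| `k10` | 2 | 1/s | pre-stroke unbinding rate |
| `k20_0` | 80 | 1/s | zero-force post-stroke unbinding rate |
| `f0_unbind` | 12.6 | pN | catch-bond force scale |

Every value is overridable through `pcm_params()` or a JSON configuration
(`load_config()`); the shipped fixtures `default.json`, `tiny.json`
(`N = 2`, for fast exercises) and `fig5_like.json` (`N_sweep` of 4, 9, 15)
are labelled as such. Negative external forces are permitted mathematically
but flagged with a warning: the model is formulated for tensile loads.

Problem sizes used by the test-suite and the reproduction script — grids of
30 forces, $N \le 25$ for the generator-matrix cross-checks, $2\times10^5$
Gillespie events — are chosen so every deterministic identity is checked
exhaustively while stochastic comparisons have sampling error well inside
their acceptance bands (total-variation distance ~0.003 against a bound of
0.02 at the default ensemble).

## The macroscopic Hill model

The muscle-level force laws are included to close the loop between scales.
The contractile component is multiplicative and separable,
$f_{cc} = f_0^{iso}\, a\, f_{fl}\, f_{fv}$, with activation
$a \in [0,1]$ taken as a direct input (the excitation-to-activation lag has
no stated dynamics and is out of scope). The force-length factor has no
canonical form at this level of description; the implemented default is a
Gaussian bump $f_{fl} = \exp(-((\ell-1)/w)^2)$ with width $w = 0.45$,
configurable. The force-velocity factor is the normalized inverted
hyperbola, $f_{fv}(v) = (v_0 - v)/(v_0 + v/\beta)$ clamped to $[0,1]$ — the
explicit bridge from the molecular fit into the macroscopic model.

The series-elastic component is slack below its unloaded length $\ell_u$
and quadratic above it, $f_{sec} = \gamma(\ell_{sec}-\ell_u)^2$ with
$\gamma = f_0^{iso}/(u_0 \ell_u)^2$, reaching the maximum isometric force at
strain $u_0 = 0.04$. The source expression is garbled in transmission; the
quadratic reading is dimensionally consistent and matches the nonlinear
tendon-model literature, and a linear law with the same calibration is
available via `sec_form = "linear"`.

**Pennation and the tendon equation.** With pennation angle $\alpha$, the
parallel-elastic balance is implemented as printed,
$f_{pec}\cos\alpha = f_{sec} - f_{cc}\cos\alpha$, and the tendon force as
$f_t = f_{pec} + f_{cc}\cos\alpha$. The often-quoted chain
$f_t = f_{pec} + f_{sec}$ is **not** a general identity of these two
equations: substituting one into the other gives
$f_t = f_{sec} + f_{pec}(1 - \cos\alpha)$, and the two forms coincide
exactly on the locus $f_{sec} = f_{cc}\cos\alpha$ (where the balance also
forces $f_{pec} = 0$) — the series-transmission condition of the topology
in which the PEC lies parallel to the whole muscle-tendon unit. The tests
assert the closure in both honest forms; at $\alpha = 0$ the chain reduces
to $f_t = f_{sec}$, the loop-closing case. `l_pec` is carried in
`hill_params()` but enters no force law.

## What the synthetic studies do and do not show

All inputs here are parameters; there are no external datasets. The
generated force-velocity curves emulate an isotonic experiment on one
mean-field ensemble under constant load. Passing tests therefore show
internal consistency (stochastic vs deterministic solutions, algebraic
identities, parameter recovery under 1% multiplicative noise) and that the
molecular mechanism produces a Hill-shaped curve under the stated
assumptions. They do not show that real muscle obeys these parameters: in
vivo the external force fluctuates through sarcoplasmic friction and
titin-like elasticity, ensembles interact through the filament lattice, and
activation is dynamic. The constant-force assumption is the model's own
stated domain of validity, and the force-velocity curve it yields should be
read as a reference relation, not a tissue-level prediction.

## Known limitations

* Bound counts only: no spatially resolved binding sites, no explicit
  $(i,j)$ jump process (LTE throughout), no multiple interacting ensembles.
* Transient (time-dependent) master-equation solutions are not computed;
  the solver targets the stationary regime.
* The Hill fit weights all sub-stall points equally; no heteroscedastic
  weighting by the Gillespie standard errors is attempted.
* The macroscopic model evaluates force balances pointwise; it does not
  integrate muscle-tendon dynamics.
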
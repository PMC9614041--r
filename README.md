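# pcmhill

Molecular validation of the Hill muscle model's force-velocity relation.

## What this package is for

The hyperbolic Hill relation

    v_hill(f) = v0 * (fs - f) / (fs + f / beta)

describes how muscle shortening velocity falls with load: `v0` is the
unloaded shortening velocity, `fs` the stall force, and `beta` a
dimensionless curvature. In musculoskeletal modelling it is usually taken
as phenomenology. `pcmhill` is for researchers who want to see that shape
emerge from the molecular machinery: it implements a mean-field parallel
cluster of `N` myosin-II motors sharing a constant load, with

* per-state mechanics — shared-load strain `eps_ij = (f/k_m - j d)/i`,
  elastic energies, and Boltzmann occupancy of the power-stroke states
  under local thermodynamic equilibrium;
* catch-bond unbinding, `Tr20 = k20_0 * exp(-f_pp/f0)` — tension makes the
  bond stronger, the mechanistic origin of the concave force-velocity
  curve;
* an effective birth-death master equation in the bound count with its
  stationary distribution and mean bound-ensemble velocity
  `V_b = sum_i V_i Pr_i`;
* an exact, seedable Gillespie simulator of the same process with
  ensemble-position bookkeeping;
* Hill-relation fitting of the resulting force-velocity curves by
  nonlinear least squares, and the macroscopic Hill muscle model
  (contractile / series-elastic / parallel-elastic components with
  pennation geometry) to close the loop between scales.

## Worked example

```r
library(pcmhill)

p <- pcm_params(N = 4)        # literature defaults for skeletal myosin-II
pcm_master(0, p)
#> PCM master-equation solution (N = 4, f = 0 pN)
#>   mean bound-ensemble velocity V_b = 640 nm/s
#>   stationary Pr(i), i = 0..N:
#> [1] 0.1975 0.3951 0.2963 0.0988 0.0123
```

Unloaded, the four-motor ensemble slides at 640 nm/s and spends most of its
time with one or two motors bound. Sweeping the load and fitting the Hill
hyperbola:

```r
grid <- seq(0, 1.05 * pcm_stall_force(p), length.out = 30)
fit  <- fit_hill(pcm_fv_sweep(p, grid))
fit
#> Hill force-velocity fit
#>   v0 = 648.4 nm/s, fs = 26.69 pN, beta = 0.4642
#>   R-squared = 0.9995 on 28 points
plot(fit)
```

The molecular curve is Hill-hyperbolic to R² = 0.9995: the fitted unloaded
velocity (648 nm/s) agrees with the master-equation `V_b(0)` to ~1%, and
the fitted stall force (26.7 pN) sits a few percent below the bisected zero
crossing of `V_b` (27.8 pN) because the hyperbola only approximates the
curve near stall. The stochastic engine reproduces the same physics:

```r
traj <- pcm_simulate(0, p, n_events = 2e4, seed = 1)
pcm_empirical_velocity(traj)
#> $velocity: 646.0   $se: 7.2      # nm/s, within 1 SE of V_b = 640
```

A thin command-line interface wraps the same functions
(`inst/cli/pcm.R fv|simulate|fit|hill`, JSON configs in `inst/extdata/`).

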
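# slabrelease

Intermittent diffusive release of chemicals from slab materials: bounds and
summary-only estimates of the released mass when a material is touched
repeatedly.

## The problem

Many exposure scenarios are intermittent: a ring releases nickel while it
is worn, a child mouths a toy from time to time, a plasticized handle
leaches phthalates only while it is gripped. Physically, a chemical
species at uniform initial concentration `c0` diffuses (coefficient `D`)
in a planar slab of thickness `b` and escapes irreversibly through the
contact interface (area `A`), which alternates between an absorbing state
(release phase, during contact) and a reflecting state (pause phase,
during which the internal concentration profile partially relaxes back to
uniformity).

For risk assessment the exact contact schedule is never known. This
package implements, for exactly that situation, estimates of the total
released mass `m_ext` that need only the number of contacts `N`, the mean
contact duration `τ̄`, and the total elapsed time `t_tot`:

- strict bounds `K√(Nτ̄) < m_ext < K Σ√τ_k ≤ K N √τ̄`, with
  `K = 2 A c0 √(D/π)`;
- the empirical estimator
  `m_ext ≈ K N √τ̄ / [1 + (√N − 1) f(z)]`, where
  `z = (t_tot − Nτ̄)/((N−1)τ̄)` is the pause/release duration ratio and
  `f(z) = 0.2 + 0.8/(1 + 0.6 z)` for `z ≤ 10` (0 beyond);
- a finite-thickness correction: for total contact time below
  `t*·γ` (with `t* = π b²/(4D)` and `γ = [1+(√N−1)f(z)]²/N`) the bound
  `m_ext ≤ 2 c0 A √(Dτ̄/π) N / [1+(√N−1)f(z)]` is informative, otherwise
  only `m_ext ≤ c0 A b` holds.

Around these closed forms the package provides the machinery they were
derived and validated with: a spectral finite-difference solver for the
switching-boundary diffusion equation (exact per-phase propagation through
eigendecompositions of symmetric tridiagonal generators, closed-form flux
integrals, mass balance to round-off), random-schedule generators,
Monte-Carlo ensemble statistics, the minimum-envelope calibration of
`f(z)`, and finite-thickness ratio scans.

## Worked example

A 0.1 mm plastic slab (`D = 1e-13 m²/s`) touched `N = 10` times, 5 h of
cumulative contact within 10 h elapsed:

```r
library(slabrelease)
mat <- material(D = 1e-13, b = 1e-4)
assess_scenario(mat, N = 10, tau_bar = 1800, t_tot = 36000)
```

```
Release scenario assessment
  N = 10, tau_bar = 1800 s, t_tot = 36000 s (t_R_tot = 18000 s)
  z = 1.11, f(z) = 0.68, gamma = 0.61
  K = 3.56825e-07; bounds on m_ext: lower 4.78731e-05, a priori upper 0.000151388
  empirical estimate m_approx = 6.1282e-05
  sigma = 1.67, t* = 78539.8 s (21.8 h), t* * gamma = 47929.9 s
  NON-TRIVIAL bound: m_ext <= 0.61 * c0 * A * b
```

Read: the slab's characteristic time `t*` is about 22 h; for this schedule
the pause/release ratio is `z = 1.11`, the envelope value `f(z) = 0.68`,
and the schedule factor `γ = 0.61`, so the contact time (5 h) is below
`t*·γ` (13.3 h) and at most 61% of the chemical initially present under
the contact area can have been released. Masses are normalized by `A·c0`
(hence in metres); multiply by your area and concentration for absolute
amounts.

Solving an explicit schedule exactly:

```r
res <- released_mass(material(D = 1e-10),
                     random_schedule(10, 3 * 3600, seed = 1),
                     solver_settings("ensemble"))
res$m_final_norm   # released mass / (A c0), metres
```

## Command line

```sh
Rscript inst/cli/slabrelease.R estimate --config config.json --out outdir
Rscript inst/cli/slabrelease.R simulate --config config.json --out outdir --seed 7
```

Commands: `simulate`, `estimate`, `calibrate`, `scan-thickness`. Configs
are JSON with explicit units in key names (`D_m2_per_s`, `t_tot_h`, ...);
schedules may be inline, a CSV (`kind,duration_s`), or randomly generated.
Outputs are CSV/JSON with the full config, seed and version echoed for
reproducibility.

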
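---
title: "Intermittent diffusive release from a slab: model, bounds, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intermittent diffusive release from a slab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slabrelease)
```

## The physical problem

A chemical species is uniformly dissolved, at volumetric concentration
$c_0$, in a homogeneous planar slab of thickness $b$ (possibly effectively
infinite) in which it diffuses with a constant coefficient $D$. The species
escapes irreversibly through the interface of contact area $A$, but only
intermittently: during *release* phases the interface is a perfect
absorbing boundary ($c(0,t)=0$, e.g. skin contact with a consumer article
while the external medium is continuously renewed), and during *pause*
phases it is reflecting ($J(0,t)=0$), letting the internal concentration
profile partially relax back towards uniformity. The quantity of interest
is the cumulative released mass $m_{\mathrm{ext}}(t_{\mathrm{tot}})$, which
we usually report normalized by $A c_0$ (units of length).

The central practical question is not the solution of one schedule — that
is routine numerics — but what can be said about $m_{\mathrm{ext}}$ when
only *summaries* of the schedule are known: the number of contacts $N$, the
mean contact duration $\bar\tau$, and the total elapsed time
$t_{\mathrm{tot}}$. This is the situation of exposure assessment, where
nobody records individual contact times.

## Closed forms

For a single release phase in a semi-infinite slab,
$c(x,t) = c_0\,\mathrm{erf}(x/\sqrt{4Dt})$ and
$m_{\mathrm{ext}} = K\sqrt{t}$ with $K = 2 A c_0 \sqrt{D/\pi}$
(`release_prefactor()`). For $N$ contacts the package provides:

* a strict lower bound $K\sqrt{N\bar\tau}$ (`lower_bound_mass()`): pauses
  can only steepen the interfacial gradient relative to one uninterrupted
  contact of the same cumulative duration;
* strict upper bounds $K\sum_k\sqrt{\tau_k} \le K N\sqrt{\bar\tau}$
  (`upper_bound_mass()`): infinitely long pauses fully restore the initial
  profile before each contact; the summary-only form follows from Jensen's
  inequality on the concave square root;
* the empirical estimator (`approx_released_mass()`)
  $$m_{\mathrm{ext}} \simeq \frac{K N \sqrt{\bar\tau}}
    {1 + (\sqrt{N}-1)\,f(z)}, \qquad
    z = \frac{t_{\mathrm{tot}} - N\bar\tau}{(N-1)\bar\tau},$$
  where $f(z) = 0.2 + 0.8/(1+0.6z)$ for $0 \le z \le 10$ and $0$ beyond
  (`f_of_z()`). $z$ is the mean-pause to mean-release duration ratio; $f$
  interpolates the estimator between the lower bound ($z\to 0$) and the
  a priori upper bound ($z \to \infty$).

At $N = 1$ the estimator reduces *exactly* to $K\sqrt{\bar\tau}$ through an
explicit branch, so the ratio $z$ — undefined for a single contact — is
never evaluated. The discontinuity of $f$ at $z = 10$ is kept exactly as
calibrated, with no smoothing: beyond $z=10$ the calibration data do not
support extrapolation and the estimator falls back on the always-valid
a priori bound. A consequence, visible in `assess_scenario()`, is that a
scenario can flip abruptly from an informative bound to the trivial one as
the elapsed time grows.

## Finite thickness

With $t^{\mathrm{R}}_{\mathrm{tot}} = N\bar\tau$ the total contact time,
the dimensionless thickness $\sigma = b/\sqrt{2 D t^{\mathrm{R}}_{\mathrm{tot}}}$
controls how far the slab is from semi-infinite behaviour. The ratio of the
true release to its infinite-thickness counterpart is bounded by
$u(\sigma) = \sigma\sqrt{\pi/2}$ for $\sigma \le 0.8$ and $1$ beyond
(`u_of_sigma()`; the breakpoint $0.8$ approximates $\sqrt{2/\pi}$, so
$u(0.8) = 1.0027$ deliberately overshoots 1 — the reference piecewise form
is kept as is). Combining this with the estimator gives, for
$t^{\mathrm{R}}_{\mathrm{tot}} \le t^* = \pi b^2/(4D)$, the bound
$$m_{\mathrm{ext}} \le \frac{2 c_0 A \sqrt{D\bar\tau/\pi}\, N}
  {1 + (\sqrt{N}-1) f(z)},$$
which `assess_scenario()` reports as a coefficient multiplying $c_0 A b$.
The bound is informative (`NON_TRIVIAL`) precisely when
$t^{\mathrm{R}}_{\mathrm{tot}} \le t^* \gamma$ with
$\gamma = [1+(\sqrt{N}-1)f(z)]^2/N \in [1/N, 1]$ (`gamma_factor()`);
otherwise the raw coefficient exceeds 1 and the only sound statement is
$m_{\mathrm{ext}} \le c_0 A b$, so the reported bound is capped there while
the raw coefficient is still exposed.

## The solver

`released_mass()` integrates the switching-boundary diffusion equation with
the finite-difference scheme the rest of the package is calibrated against:

* **Grid.** The $x$-axis is truncated at depth $L$ and split into a fine
  uniform sector covering $[0, L_{\mathrm{turn}}]$ with
  $L_{\mathrm{turn}} = \sqrt{2 D t_{\mathrm{tot}}}$ (the rms diffusive
  displacement over the run) and a coarse uniform sector beyond. For a
  semi-infinite medium $L = 50\,L_{\mathrm{turn}}$ by default, with a
  reflecting wall at $L$; for a finite slab $L = b$ (single uniform sector
  when $b \le L_{\mathrm{turn}}$).
* **Generators.** Concentrations live at interval centres and are weighted
  by $\sqrt{\Delta_n}$, which makes both phase evolution matrices symmetric
  tridiagonal; release and pause differ only in the $(1,1)$ entry (the
  absorbing interface is imposed through a mirror interval
  $\Delta_0 \equiv \Delta_1$). On any grid the pause matrix annihilates the
  vector $\sqrt{\Delta_n}$ — a flat profile does not evolve — so pauses
  conserve mass exactly, while the release matrix is positive definite.
* **Propagation.** Each phase applies $e^{-\tau M}$ through the cached
  eigendecomposition (`eigen(symmetric = TRUE)`), and during release phases
  the cumulative mass is obtained by integrating the boundary flux
  $\dot m = A D\, c(x_1,t)/\Delta_1$ mode by mode in closed form
  ($\int_0^\tau e^{-\lambda t}dt = (1-e^{-\lambda\tau})/\lambda$, with a
  defensive $\tau$-linear limit for $\lambda < 10^{-300}$, unreachable for
  release matrices). The final mass therefore carries no time-quadrature
  error, and the discrete mass balance
  $A\sum_n \Delta_n c_n(t) + m_{\mathrm{ext}}(t) = c_0 A L$ holds to
  round-off (asserted below $10^{-8}$ relative in the tests).

Intra-phase output samples (default 50/phase) only affect the plotted
curves, never the final mass.

### Grid profiles and convergence

`solver_settings()` exposes the named profiles used throughout:
`reference` (700/300, $\varepsilon_1 = 2\%$, $\varepsilon_2 = 1\%$),
`ensemble` (200/100, 2%/2%, the default), `survey` (100/50, 5%/2%),
and `slab`/`slab_fine` (100/100, 100/200) for finite slabs.
`check_convergence()` verifies, for semi-infinite runs, that (1) the
far-boundary concentration stays within $\varepsilon_1$% of $c_0$ (the
artificial wall is not felt) and (2) a single release of the full duration
on the same grid reproduces $K\sqrt{t}$ within $\varepsilon_2$%. The
deviation in (2) is measured over $t \ge t_{\mathrm{tot}}/20$: the early
transient, whose diffusion length is below the first interval width, is
unresolvable on any fixed grid and its contribution to the final mass is
what criterion (2) actually controls. On finite slabs both criteria are
skipped with a note — the wall at $b$ is physical and the semi-infinite
reference solution does not apply.

The scheme's boundary discretization is first order, so the released mass
carries a small negative bias that shrinks roughly like $1/N_1$: the
single-release deviation is $-1.7\%$ at `survey`, $-0.68\%$ at `ensemble`,
$-0.13\%$ at `reference`. Statistics that live at the sub-percent scale
(the violation fractions below) are therefore computed at `reference`;
bulk calibration sweeps use `survey`, matching the protocol the envelope
parameters were originally derived with.

## Random schedules

"Unbiased" durations with a fixed sum are drawn uniformly on the simplex
(normalized i.i.d. exponentials, i.e. a flat Dirichlet) — the
maximum-ignorance distribution for positive durations with a sum
constraint. Two modes mirror the two study protocols: mode A draws all
$2N-1$ durations jointly at fixed $t_{\mathrm{tot}}$ (violation-statistics
ensembles); mode B draws release and pause durations on separate simplices
at fixed $t^{\mathrm{R}}_{\mathrm{tot}}$ and $t_{\mathrm{tot}}$
(calibration ensembles, where $\bar\tau$ must stay fixed across
instances). Schedules always begin and end with a release phase — exactly
$N-1$ pauses, consistent with the $(N-1)\bar\tau$ denominator of $z$; a
leading or trailing pause would be observationally irrelevant. No minimum
phase duration is imposed; the spectral propagation handles near-zero
durations gracefully. An alternative reading of "unbiased" (i.i.d.
uniforms rescaled to the sum) concentrates durations near equality and
more than doubles the violation fraction of the estimator; the simplex
choice is both the standard one and the one consistent with the reference
statistics, and is recorded in all output metadata.

What the generator deliberately does not emulate: correlated contact
behaviour (e.g. bursts of short touches), minimum humanly-plausible
contact times, or day/night structure. Passing tests therefore certify the
mathematics of the release model under exchangeable random schedules, not
the realism of any particular human-exposure pattern.

## Ensemble calibration

`run_ensemble()` batches all instances of a condition through one shared
grid and one pair of eigendecompositions (instance states as matrix
columns), which keeps thousand-instance ensembles in the seconds range; a
test pins the batched path to the one-schedule solver at $10^{-10}$
relative. `min_envelope()` extracts, per condition, the minimum of the
ratio $K N\sqrt{\bar\tau}/m_{\mathrm{ext}}$ — confined to
$(1, \sqrt{N})$ by the a priori bounds — and rescales it to
$(\min\mathrm{ratio} - 1)/(\sqrt{N}-1) \in (0,1)$. `fit_envelope()` fits
$f(z) = a + (1-a)/(1+c z^b)$ (which enforces $f(0)=1$) by unweighted
Levenberg–Marquardt least squares from the start $(0.2, 1, 0.6)$.

`calibrate_envelope()` assembles the default condition suite
($D \in \{10^{-10}, 10^{-12}\}\,\mathrm{m^2/s}$, $N \in \{5, 10, 20\}$,
$\bar\tau \in \{5, 10\}$ min, eleven log-spaced elapsed times), with 100
instances per condition at desk scale (500 reproduces the original
protocol; the minimum statistic is then slightly more extreme, lowering
the fitted $a$ by about 0.005). Two condition grids are supported: elapsed
times spanning $1.1$–$50\times t^{\mathrm{R}}_{\mathrm{tot}}$, or — via
`z_values` — conditions placed directly on a chosen $z$ grid. For refits
of the reference parameters the $z \in [0.1, 10]$ grid is the appropriate
one: it covers exactly the domain where $f$ is nonzero, while the
$50\times$ grid reaches $z \approx 60$, deep in the region where $f$ is
defined to be zero and where the envelope is both poorly constrained and
most sensitive to solver bias; including it drags all three parameters
systematically low. With the $z$-grid suite the refit lands within a few
percent of $(0.204, 1.011, 0.594)$, with the exponent $b$ essentially
exact; the remaining offset on $a$ ($\approx +0.017$) decomposes into the
100-draw minimum bias and the `survey`-profile solver bias inflating the
ratio statistic, and is documented rather than absorbed into the
parameters.

`violation_stats()` summarizes how often the estimator is exceeded. Under
the reference conditions ($D=10^{-10}$, $N=10$, 3 h; and $D=10^{-12}$,
$N=20$, 2 h; 1000 mode-A instances) the measured fractions are about 19%
and 7%, with positive deviations of at most $\approx 1.2\%$ of
$m_{\mathrm{ext}}$ — the estimator is an excellent, slightly optimistic
summary, and the acceptance suite asserts these numbers (the deviation
distribution is so tightly concentrated near zero that percent-level
solver bias moves the fraction by tens of points; this is why the finest
grid is used there).

`thickness_scan()` pairs finite- and infinite-thickness runs on identical
schedules across a $\sigma$ grid. The ratios respect $u(\sigma)$ to within
discretization noise, saturate at 1 for $\sigma \gtrsim 5$, and the $N=1$
reference curve grows with the predicted initial slope $\sqrt{\pi/2}$. The
sub-percent overshoot of ratios above 1 near saturation is a pure
discretization artifact (the infinite-thickness denominator is biased
slightly low) and disappears at $N_1 = 200/N_2 = 400$, which the
acceptance test uses. The tentative large-$N$ lower-bound line of slope
$1/5$ is *not* asserted anywhere: it remains an unvalidated visual
diagnostic.

## Worked example

```{r example}
mat <- material(D = 1e-13, b = 1e-4)    # 0.1 mm plastic slab
assess_scenario(mat, N = 10, tau_bar = 1800, t_tot = 36000)
```

A 0.1 mm slab with $D = 10^{-13}\,\mathrm{m^2/s}$ has $t^* \approx 22$ h.
Touched 10 times for 5 h of cumulative contact within 10 h, the schedule
gives $z = 1.11$, $f(z) = 0.68$, $\gamma = 0.61$ and
$t^*\gamma = 13.3$ h $> t^{\mathrm{R}}_{\mathrm{tot}} = 5$ h, so the
finite-thickness bound is informative:
$m_{\mathrm{ext}} \le 0.61\, c_0 A b$. Stretching the same contacts over
30 h (or compressing many short contacts) flips the report to `TRIVIAL`,
where only $m_{\mathrm{ext}} \le c_0 A b$ can be asserted.

```{r solver-example}
res <- released_mass(material(D = 1e-10),
                     random_schedule(10, 3 * 3600, seed = 1),
                     solver_settings("ensemble"))
res
```

## Numerical choices and limitations

* Eigendecomposition of the symmetric tridiagonal generators uses base
  `eigen(symmetric = TRUE)`; orthonormality at $\sim 10^{-12}$ is all the
  propagation requires.
* Convergence failures annotate the result rather than abort: tolerances
  are per-use-case (the profiles), and a flagged run is still often
  useful.
* Degenerate inputs: zero-duration phases are rejected at schedule
  construction; $t = 0$ propagation is the identity; `t_R_tot = 0` gives
  $\sigma = \infty$, $u = 1$.
* Problem sizes in the test and acceptance suites are chosen to keep the
  full run in the minutes range: 1000-instance violation ensembles at the
  `reference` profile, 132-condition calibration at `survey` with 100
  instances, a $10\times3\times3$ thickness scan at $N_1/N_2 = 200/400$.
* Out of scope by design: non-planar geometries, two-sided transport with
  a partition constant, matrix swelling/erosion or dissolution-limited
  release, concentration-dependent $D$, and build-up of the species in the
  external medium.
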
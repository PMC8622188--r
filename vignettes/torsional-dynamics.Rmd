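---
title: "Torsional dynamics of double-stranded DNA as a coupled-pendulum chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsional dynamics of double-stranded DNA as a coupled-pendulum chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnatorsion)
```

## The model

Each nitrogenous base of a duplex is treated as a rigid pendulum rotating
about the sugar-phosphate backbone it is attached to. Base $i$ of strand
$j$ has a moment of inertia $I_{ji}$, a lever arm $R_{ji}$ from its centre
of mass to the backbone, and an angular deviation $\varphi_{ji}(t)$ counted
counterclockwise from the closed (equilibrium) orientation. Three torques
act on it:

* **Backbone torsion.** Adjacent bases on the same strand are coupled
  through the torsional stiffness $K_{ji}$ of the backbone segment between
  them: $K_{ji}(\varphi_{j,i-1} - 2\varphi_{ji} + \varphi_{j,i+1})$ at
  interior sites, with the single-neighbour analogue at the two free chain
  ends.
* **Hydrogen bonding.** The Watson–Crick partner resists opening through
  the pair stiffness $k_{12,i}$ (a property of the pair type, identical for
  both members): a single-base restoring term
  $-k_{12,i} R_{ji}(R_{1i}+R_{2i})\sin\varphi_{ji}$ and a cross term
  $-k_{12,i} R_{1i} R_{2i}\sin(\varphi_{ji}-\varphi_{j'i})$ coupling the
  two members of the pair.
* **Environment.** $F_{ji}(t) = -\lambda\,\beta_{ji}\,\dot\varphi_{ji}
  + M(t)$: viscous dissipation into the surrounding liquid plus an external
  driving torque. $\beta_{ji}$ is the per-base dissipation coefficient and
  the dimensionless factor $\lambda$ rescales it uniformly, standing in for
  the viscosity of the medium (nucleoplasm viscosity varies over orders of
  magnitude, hence a wide sweep range).

Newton's second law for all $2n$ pendulums gives a Cauchy problem for $2n$
second-order ODEs; by default the system starts from equilibrium
($\varphi = \dot\varphi = 0$).

The model deliberately contains **no** hydrogen-bond breaking: large
angular deviations are read as precursors of open states and denaturation
bubbles, not as open states themselves. There are no stacking/helicoidal
terms, no bending, no supercoiling, and no thermal (random) forcing — the
dynamics are fully deterministic.

## Parameters

`base_parameter_table()` carries the per-base constants in SI units
(converted once from the customary publication units: $I \times 10^{-44}$
kg m$^2$, $R$ in Å, $K \times 10^{-18}$ J, $k_{12} \times 10^{-2}$ N/m,
$\beta \times 10^{-34}$ J s):

```{r}
base_parameter_table()
```

Only A, C, G, T are parameterized; ambiguity codes are rejected rather than
coerced, since no constants exist for them. The table can be overridden
per-base from a JSON file (`read_parameter_table()`) for sensitivity
studies; the override is validated against the same invariants (positivity,
pair-equal $k_{12}$). The pair stiffness is tabulated for protiated
hydrogen bonds; isotope-substituted variants are not parameterized here.

Tunables that matter, with defaults:

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `lambda` | viscosity scale on $\beta$ | 1 | – |
| `M0` | driving torque amplitude | `1e-22` | N m |
| `omega` | cosine drive frequency | 0 | s$^{-1}$ |
| `t_end` | integration window | run-specific | s |
| `dt` | integrator step | `1e-14` | s |
| `n_out` | stored snapshots | 1000 | – |

A constant torque of $10^{-22}$ N m is the reference drive; at this
magnitude the response is practically indistinguishable from a cosine
drive $10^{-22}\cos(\omega t)$ N m for $\omega \le 10^9$ s$^{-1}$, which is
why the constant mode is the default and the cosine mode is provided as an
option. By default $M(t)$ acts on every pendulum of both strands with the
same sign; since a narrower target set is physically plausible (e.g. a
protein pulling on one strand), `forcing_spec()` accepts strand and site
subsets.

## The strand-2 sign convention

The design question with real consequences is the sign of the strand-2
single-base hydrogen-bond term. Writing it with a positive sign
($+k_{12}R_{2}(R_1+R_2)\sin\varphi_{2i}$) makes that torque push strand-2
bases *away* from the closed state: the small-angle stiffness matrix of a
single A·T pair then has a positive eigenvalue, the equilibrium is a
saddle, and any perturbation grows at $\approx 6\times10^{11}$ s$^{-1}$ —
the chain overflows within picoseconds regardless of damping, and no
viscosity sweep or relaxation experiment is possible. With the restoring
(minus) sign, mirroring strand 1, the stiffness matrix is negative definite
and the damped, stabilizing behaviour the model is built to study follows.
`dnatorsion` therefore defaults to the symmetric restoring convention
(`strand2_sign = "symmetric"`); the anti-restoring variant is kept as the
clearly labelled diagnostic `strand2_sign = "as_printed"`, and a unit test
documents its instability. Both conventions share the cross term
$-k_{12}R_1R_2\sin(\varphi_{2i}-\varphi_{1i})$.

## Numerical scheme

The integrator is a fixed-step classical fourth-order Runge–Kutta method,
implemented in C++ for speed and chosen for transparency and bit-level
determinism (identical inputs give identical trajectories; there is no
adaptive step controller to introduce platform-dependent step sequences).
The fastest linearized mode is the short-wavelength backbone mode with
$\omega^2 \approx 4K/I \approx 1.2\times10^{26}$ s$^{-2}$ for the A row of
the table, i.e. a period of $\approx 5.6\times10^{-13}$ s; the default
`dt = 1e-14` s resolves it about 56-fold. `integrate_chain()` refuses steps
larger than half that period. Self-convergence is verified in the test
suite: halving `dt` moves the final state of a driven 10-bp, $10^{-11}$ s
run by under $10^{-9}$ rad, and the production path agrees with an
independent pure-R RK4 reference run at `dt = 1e-16` s to better than
$10^{-8}$ rad.

Further numerical choices:

* **Angles are unwrapped** (no modulo $2\pi$): angles enter the force only
  through sines, and cumulative deviations are the observable of interest.
* **Site-varying $K$** is applied verbatim as
  $K_{ji}(\varphi_{j,i-1}-2\varphi_{ji}+\varphi_{j,i+1})$ with the site's
  own $K$, not symmetrized into half-site differences; exact elastic-energy
  bookkeeping therefore holds only for homogeneous chains.
* **Decimation**: roughly `n_out` evenly strided snapshots are stored
  (first and last always); `n_out = Inf` keeps every step.
* **Degenerate inputs**: empty sequences, $n = 1$, non-positive `lambda`,
  `t_end` or `dt`, wrong-shape initial states and non-finite states are
  rejected with informative errors; a non-finite state reached *during*
  integration aborts with the failing time.

## Observables

`mean_angular_deviation()` computes the strand-averaged angle
$\bar\varphi(t)= n^{-1}\sum_i \varphi_{1i}(t)$ (either strand; strand 1 is
the default and the conventional choice). Stability is quantified from it:

* `envelope()` first removes a steady offset — the mean over the final
  quarter of the window, since a constant drive relaxes the chain to a
  nonzero deflection — then takes local maxima of the absolute detrended
  signal. Peaks are thinned to a minimum separation of half the dominant
  period, estimated from the signal's zero crossings; plateau ties keep the
  first sample. At least three extrema are required.
* `damping_metrics()` fits a least-squares line to the log of the envelope
  peaks (`decay_rate`, s$^{-1}$, with the fit's $R^2$ as `fit_quality`),
  and reports the maximal deviation from the steady offset in an early and
  a late window (defaults: first and last sixth of the span, the
  proportional analogue of comparing the onset of a 6 ns run with its last
  fraction). The late/early `amplitude_ratio` is flagged undefined when
  the early amplitude is zero. On synthetic damped cosines the fit recovers
  decay rates across $10^7$–$10^{10}$ s$^{-1}$ within 5%.

`viscosity_sweep()` repeats one simulation across a set of $\lambda$ values
and tabulates these metrics; `plot_sweep()` overlays the traces with a
configurable vertical shift (a presentation offset only — the shifts carry
no physical meaning).

## Synthetic sequences

The generator (`random_sequence()`) draws each site independently, G/C with
probability `gc_fraction`, using R's Mersenne–Twister stream under an
explicit seed (recorded, with the algorithm identifier, in the returned
`spec` attribute; the caller's RNG state is untouched). Homopolymer and
alternating kinds cover the analytically convenient special cases. The
paper-scale presets — `"interferon-like"` ($n = 980$) and
`"drosophila-like"` ($n = 5000$) — are *synthetic stand-ins*: random 50% GC
sequences at fixed seeds that reproduce only the lengths of the gene-scale
systems the model is typically applied to, because the real sequences are
not bundled. Consequently, what the generator emulates is length and
base-composition heterogeneity; it does not emulate genic base ordering,
repeats, or codon structure, and passing tests say nothing about any
specific gene's dynamics — only about the model's behaviour on duplexes of
comparable size and composition.

## Problem sizes used in the tests

The suite runs scaled-down conditions chosen to exercise every claim in
minutes: chains of $n = 2$–100 and windows of $10^{-12}$–$5\times10^{-9}$ s,
with the central viscosity sweep at $n = 100$, $\lambda \in \{0.1, 0.5, 1,
2, 4\}$, constant $M = 10^{-22}$ N m over $[0, 2\times10^{-9}]$ s. The
gene-scale presets ($n = 980$ over 2–6 ns, $n = 5000$) run through exactly
the same code path on demand. Two single-configuration reductions are worth
noting:

* the "single A·T pair" eigenfrequency check uses an $n = 2$
  poly(A)·poly(T) chain initialized uniformly along each strand, for which
  the backbone coupling vanishes identically by symmetry — the dynamics are
  exactly the 2×2 single-pair system, while respecting the $n \ge 2$
  contract of `build_system()`;
* "zero damping" is represented by $\lambda = 10^{-9}$ (effective damping
  $\sim 10^{-43}$ J s), since the parameter-table invariant keeps $\beta$
  strictly positive.

## Limitations

* No open states, bond breaking, or denaturation-bubble statistics; the
  observables are precursors only.
* No helicoidal/stacking coupling, bending, or supercoiling; the global
  conformation does not feed back on the torsional dynamics.
* Dissipation is deterministic and memoryless; there is no
  fluctuation–dissipation pairing (no Langevin noise), so thermal
  equilibrium properties are out of reach.
* The per-site backbone stiffness is applied asymmetrically for
  heterogeneous sequences (see above), which is the conventional discrete
  form but not a conservative discretization of a continuum rod.
* Real nucleoplasm is rheologically heterogeneous; a single global
  $\lambda$ compresses that into one dial.

## A worked example

```{r example, eval = FALSE}
seq <- random_sequence(100, gc_fraction = 0.5, seed = 42)
sweep <- viscosity_sweep(seq, lambdas = c(0.1, 0.5, 1, 2, 4),
                         forcing = forcing_spec("constant", M0 = 1e-22),
                         t_end = 2e-9)
summary(sweep)
plot_sweep(sweep)
```

The summary table reports, per $\lambda$, the envelope decay rate and the
late/early amplitude ratio of the strand-1 mean angular deviation; the
decay rate grows essentially linearly with $\lambda$ (the proportional
damping prediction $\gamma \approx \lambda\beta/2I$), and the amplitude
ratio at $\lambda = 0.1$ stays near unity scale while at $\lambda \ge 1$
the oscillation is gone by the late window — the viscosity-stabilization
effect the model exists to demonstrate.
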
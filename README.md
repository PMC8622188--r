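# dnatorsion

Mechanical simulation of the torsional (rotational) dynamics of nitrogenous
bases in double-stranded DNA, for studying how the viscosity of the
surrounding medium stabilizes — or fails to stabilize — the angular
oscillations that precede local strand opening. It is aimed at researchers
in DNA biophysics and structural bioinformatics who want a fast,
deterministic, sequence-aware alternative to all-atom simulation for
questions about torsional stability.

## The model

The duplex is two chains of pendulums: base $i$ of strand $j$ rotates by
$\varphi_{ji}(t)$ about its backbone, with moment of inertia $I_{ji}$,
lever arm $R_{ji}$, backbone torsional stiffness $K_{ji}$, hydrogen-bond
pair stiffness $k_{12,i}$ and dissipation coefficient $\beta_{ji}$ — all
assigned per base type (A, T, G, C) from a built-in constants table.
Newton's law at an interior site of strand 1 reads

$$
I_{1i}\ddot\varphi_{1i}
 = K_{1i}\left(\varphi_{1,i-1}-2\varphi_{1i}+\varphi_{1,i+1}\right)
 - k_{12,i}R_{1i}(R_{1i}+R_{2i})\sin\varphi_{1i}
 - k_{12,i}R_{1i}R_{2i}\sin(\varphi_{1i}-\varphi_{2i})
 + F_{1i}(t),
$$

with single-neighbour coupling at the chain ends, the mirrored equation on
strand 2, and the environment entering through
$F_{ji}(t) = -\lambda\beta_{ji}\dot\varphi_{ji} + M(t)$: viscous damping
scaled by a dimensionless viscosity factor $\lambda$, plus an external
torque $M(t)$ (constant $10^{-22}$ N m by default, or
$M_0\cos\omega t$). The $2n$ equations are integrated from equilibrium by a
fixed-step classical RK4 scheme (`dt = 1e-14` s) implemented in C++. The
stability observable is the strand-averaged angle
$\bar\varphi(t)=n^{-1}\sum_i\varphi_{1i}(t)$, summarized by an
oscillation-envelope decay rate and late/early amplitude ratios.

See the vignette `vignettes/torsional-dynamics.Rmd` for the full account,
including the strand-2 sign convention and the scheme's accuracy checks.

## Worked example

```r
library(dnatorsion)

seq <- random_sequence(100, gc_fraction = 0.5, seed = 42)
sweep <- viscosity_sweep(seq, lambdas = c(0.1, 0.5, 1, 2, 4),
                         forcing = forcing_spec("constant", M0 = 1e-22),
                         t_end = 2e-9)
summary(sweep)
```

```
  lambda  decay_rate early_amplitude late_amplitude amplitude_ratio fit_quality
1    0.1   275307396     0.002391002   1.402344e-03    5.865088e-01   0.3993724
2    0.5  1426887526     0.002391176   2.051384e-04    8.578976e-02   0.9466170
3    1.0  2866319456     0.002391203   1.855857e-05    7.761184e-03   0.9860906
4    2.0  5745143371     0.002391206   1.518534e-07    6.350496e-05   0.9964389
5    4.0 11502942599     0.002391206   1.010817e-11    4.227227e-09   0.9990778
```

Each row is one 2 ns simulation of the same 100-bp duplex at a different
viscosity scale λ. `decay_rate` (s⁻¹) is the exponential decay of the
oscillation envelope of the mean angular deviation: it grows essentially
linearly with λ, the proportional-damping prediction. `amplitude_ratio` is
the late-window/early-window amplitude: at λ = 0.1 the chain still carries
59% of its early oscillation amplitude at the end of the window (low
viscosity: no attenuation, a destabilized molecule), while at λ = 1 only
0.8% remains (rapid stabilization). `plot_sweep(sweep)` overlays the five
traces with a vertical shift.

A thin command-line front end ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dnatorsion", package="dnatorsion"))')" \
  sweep --seq ACGTACGT... --lambdas 0.1,0.5,1,2,4 --t-end 2e-9 --out out/
```

with `simulate` and `make-fixture` (FASTA generator) subcommands.

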
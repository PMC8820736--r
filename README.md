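# ntamp — nonlinear transient amplification in recurrent E/I networks

Cortical circuits amplify relevant stimuli within tens of milliseconds,
yet most evoked responses are transient: a large onset peak followed by
a much lower steady state, with no runaway excitation and no lingering
persistent activity. `ntamp` implements and analyzes a circuit
mechanism that produces exactly this behavior — **nonlinear transient
amplification (NTA)** — in recurrent excitatory/inhibitory networks
with supralinear (rectified power-law) neuronal gain and short-term
synaptic plasticity (STP).

The core rate model for one ensemble of an excitatory and an
inhibitory population is

    tauE * drE/dt = -rE + [ JEE*rE - JEI*rI + gE ]+ ^ alphaE
    tauI * drI/dt = -rI + [ JIE*rE - JII*rI + gI ]+ ^ alphaI

with `[.]+` the rectification and `alpha = 2` by default. When the
weight determinant `det(J) = -JEE*JII + JIE*JEI` is negative, recurrent
excitation can outrun inhibition: above a critical drive `gE` all fixed
points of the system vanish and activity escapes explosively. Slow
negative feedback then decides the fate of the escape:

* **spike-frequency adaptation** (a subtractive current `a`, with
  `tau_a da/dt = -a + b*rE`) cannot restore a stable fixed point — weak
  adaptation leaves runaway, strong adaptation produces a limit cycle
  through a Hopf bifurcation;
* **E-to-E short-term depression** (`x` scaling `JEE`, with
  `dx/dt = (1-x)/tau_x - Ud*x*rE`) and **E-to-I short-term
  facilitation** (`u` scaling `JIE`) quench the escape into a stable,
  inhibition-stabilized steady state — after a large, stimulus-selective
  onset transient. That transient is NTA.

The package covers the full analysis toolchain around this mechanism:

* fixed-step Euler simulation of the rate models with stimulation
  episodes and probes (inhibition inactivation/freezing, current
  injection into the inhibitory population);
* the 1D characteristic function `F(z)` whose zero crossings are the
  system's fixed points, fixed-point location/classification, and the
  critical input at which they vanish;
* Jacobian stability conditions, the ISN index (leading eigenvalue of
  the excitatory subnetwork), and the analytic ISN/paradoxical-effect
  regime map for depressing synapses;
* block-Jacobian eigenvalue theory for N interacting ensembles with
  global vs. co-tuned inhibition and the resulting uni-stability maps;
* two-ensemble simulations for pattern completion, stimulus
  selectivity, and input-morphing experiments, with the Association
  index, decision-boundary distance, separation and amplification
  indices;
* a conductance-based leaky integrate-and-fire network (AMPA/NMDA/GABA
  synapses, per-synapse STP, Poisson external drive) that reproduces
  the same phenomenology with spikes, plus ensemble-activity and PCA
  readouts.

## Worked example

```r
library(ntamp)
ps <- nta_preset("ensemble")   # canonical ensemble, det(J) = -0.08 < 0

find_fixed_points(ps$weights, ps$params, ps$gain, gE = 1.55, gI = 2)
#> Fixed points at gE = 1.55 , gI = 2 :
#>           rE       rI         z stability
#> 1 0.04341664 1.419783 0.2083666    stable
#> 2 1.26399195 2.700912 1.1242740    saddle

critical_input(ps$weights, ps$params, ps$gain, gI = 2,
               bracket = c(1.55, 3))
#> [1] 1.68833
```

At baseline drive the ensemble rests at 0.043 Hz (stable node), next to
a saddle; raising `gE` above 1.688 annihilates both fixed points. With
E-to-E depression the same suprathreshold stimulus produces NTA instead
of runaway:

```r
prot <- stim_protocol(list(list(t_start = 2, t_end = 4, delta_gE = 1.45)))
tr <- simulate_ensemble(ps$weights, ps$params, ps$gain,
                        nta_preset("mechanism")$std, prot, duration = 8)
extract_features(tr, c(2, 4))
#> onset peak 32545.4 Hz at t = 2.011 s; fixed point 2.90285 Hz; baseline 0.043 Hz
```

The onset peak is a brief positive-feedback excursion (the uncapped
power law makes its height parameter-dependent and very large; a
`rate_cap` in `rate_params()` bounds it); the ensemble then settles at
2.90 Hz while the stimulus lasts and returns to the 0.043 Hz baseline
afterwards. Along the way it becomes inhibition stabilized:

```r
ii <- isn_trajectory_index(tr, ps$weights, ps$params, ps$gain,
                           nta_preset("mechanism")$std)
# ISN index: -5.25 (non-ISN) at t = 1.9 s, +140.3 (ISN) at t = 3.5 s
```

so injecting excitatory current into the inhibitory population during
stimulation *lowers* its rate (the paradoxical effect), but raises it
at baseline — see `run_protocol("fig2h")`.

`run_protocol()` packages these and the multi-ensemble and spiking
experiments under one call each (`"fig1c"`, `"fig2g"`, `"fig3c"`,
`"fig6"`, ...), and `exec/nta` exposes them on the shell.

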
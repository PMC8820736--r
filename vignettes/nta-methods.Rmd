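---
title: "Models and methods behind ntamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ntamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ntamp)
```

This vignette is the package's own account of the models it implements,
the choices behind every tunable default, and the limits of what its
simulations can show. All empirical statements below are computed by
the package's test suite or by `scripts/acceptance.R`; none are taken
on faith.

## The supralinear ensemble

One neuronal ensemble is a pair of population rates, excitatory `rE`
and inhibitory `rI` (Hz), driven through a rectified power law:

$$\tau_E \dot r_E = -r_E + [J_{EE} r_E - J_{EI} r_I + g_E]_+^{\alpha_E},
\qquad
\tau_I \dot r_I = -r_I + [J_{IE} r_E - J_{II} r_I + g_I]_+^{\alpha_I}.$$

The exponents default to 2 (a rectified quadratic): supralinear gain is
what makes stability *input-dependent*, unlike linear networks where
the Jacobian — and hence the ISN index and the stability verdict — is
the same at every operating point. All internal units are seconds and
Hz; the canonical time constants are $\tau_E = 20$ ms and
$\tau_I = 10$ ms, and the canonical weights
$(J_{EE}, J_{IE}, J_{EI}, J_{II}) = (1.8, 1.0, 1.0, 0.6)$ give
$\det(J) = -J_{EE}J_{II} + J_{IE}J_{EI} = -0.08 < 0$, the
positive-feedback regime the whole analysis is about.

**Integration contract.** Everything is integrated by fixed-step
explicit Euler with `dt = 1e-4` s (0.1 ms). This is deliberate: the
models contain genuine finite-time blow-up, which adaptive solvers
handle no more gracefully, and a fixed step makes every protocol
bit-reproducible. A consistency test halves `dt` and checks converged
states move by less than one part in $10^3$.

**Divergence handling.** The uncapped quadratic gain really does reach
infinity in finite time above the critical input. Integration stops
cleanly once `rE` exceeds `divergence_bound` (default $10^6$ Hz) or the
state overflows, and the trajectory carries `diverged = TRUE` plus the
divergence time. One subtlety discovered while testing: E-to-E
depression stabilizes the ensemble *even without inhibition*, but the
excursion before the depression variable collapses transiently reaches
$\sim 10^{13}$ Hz — the escape is supralinear while `x` only decays at
rate $U_d x r_E$, so `x` lags by some thirty e-folds. To observe that
re-stabilization the bound must be lifted (the tests use $10^{15}$); at
the default bound the excursion is reported as a divergence, which is
the right default for every other use. With a `rate_cap` (e.g. 300 Hz,
applied as `min(gain, cap)` after the power law) the same protocol
stays at physiological values, at the price of a saturation-induced
high-activity state in the mechanism-free model.

**Initial conditions.** Rates start at `(0, 0)` and mechanism
variables at their rest values (`a = 0`, `x = 1`, `u = 1`); the rest
values are the unique choices that make an unstimulated quiescent
network an exact fixed point. Every canonical protocol runs at least
2 s of baseline before the first episode so that trajectories start
from the relaxed state shown in all figures. Euler overshoot of the
bounded mechanism variables is absorbed by clipping `x` to
$[10^{-12}, 1]$ and `u` to $[1, U_{max}]$.

## Bifurcation structure: the characteristic function

Fixed points are found through the one-dimensional reduction
$F(z)$, where $z$ is the total current into the excitatory population:
zero crossings of $F$ are fixed points, the sign of $F'$ at a crossing
separates saddles from the rest, and raising $g_E$ shifts $F$ upward
pointwise, so for $\det(J) < 0$ there is a unique critical drive at
which all crossings vanish. `find_fixed_points()` scans a 4000-point
grid (adaptively doubling its upper end until $F$ is past its last
crossing), refines each sign change by bisection, maps roots back to
$(r_E, r_I)$ — the reduction makes the inhibitory steady state exact at
a root, which the code verifies to a residual below $10^{-8}$ — and
classifies each point by the 2D Jacobian's eigenvalues.
`critical_input()` bisects the root count to a $10^{-6}$ tolerance on
`gE`. At rectification corners (a rate exactly zero) the gain
derivative is taken one-sided as 0, a convention that makes the silent
state's Jacobian the pure leak matrix.

For the canonical ensemble: a stable node at
$(r_E, r_I) = (0.0434, 1.4198)$ and a saddle at $(1.264, 2.701)$ at
baseline, both annihilated at $g_E \approx 1.688$.

## Why adaptation fails and depression works

With spike-frequency adaptation the 3D characteristic polynomial
$\lambda^3 - \mathrm{tr}\,\lambda^2 + A\lambda - \det = 0$ has
$-\det < 0$ in the large-rate limit whenever the adaptation strength
`b` is below a rate-dependent bound, so a positive eigenvalue always
survives: adaptation cannot terminate the escape at a fixed point.
Large `b` instead destabilizes the stimulated fixed point through a
Hopf bifurcation (crossing where $\mathrm{tr}\cdot A = \det$) and the
stimulated ensemble oscillates. A practical note on evaluating these
formulas: they are written with the slope factor
$\alpha_E r_E^{(\alpha_E-1)/\alpha_E}$, which presumes
$r_E = [z]_+^{\alpha_E}$; at an adaptation fixed point the gain output
is $(1+b)r_E^*$ instead, so the package's `sfa_fixed_point()` reports
that effective rate and the Hopf cross-check is evaluated there. With
the canonical parameters and $\tau_a = 200$ ms, a sweep
(`sfa_classification_sweep()`) shows runaway up to $b \approx 150$ and
a stable limit cycle from $b \approx 200$; the packaged "strong"
example uses $b = 200$ (the published table's $b = 1.0$ is the "weak"
case). The cycle is a relaxation oscillation at low mean rate; its
classification uses peak counting on the last half of the stimulus
window, requiring at least three periods and a peak-to-trough
amplitude above 5% of the mean — robust and independent of the solver.

Depression changes the algebra qualitatively: `x` multiplies $J_{EE}$,
so the *effective* determinant $-xJ_{EE}J_{II} + J_{IE}J_{EI}$ flips
sign as `x` falls (at the canonical weights, already at $x = 0.5$ it is
$+0.46$), the characteristic function bends downward at large $z$, and
a stable stimulated fixed point appears. All three
stability-determining coefficients of the 3D polynomial keep
stabilizing signs in the large-rate limit with $x$ at its steady state
$x^* = 1/(1 + U_d r_E \tau_x)$. Facilitation of E-to-I synapses
achieves the same through the inhibitory pathway — which is why it
needs intact inhibition, while depression survives inhibition
inactivation (see the divergence note above).

## ISN index and the paradoxical effect under depression

The ISN index is the leading eigenvalue of the frozen-inhibition
Jacobian: for the plain ensemble
$\tau_E^{-1}(J_{EE}\alpha_E r_E^{(\alpha_E-1)/\alpha_E} - 1)$, and for
the depressing ensemble the leading eigenvalue of the 2×2
$(r_E, x)$ subsystem, evaluated in closed form and checked against a
numeric eigensolver to $10^{-8}$. Along the canonical stimulation
protocol the index moves from $-5.2\,s^{-1}$ at baseline to
$+140\,s^{-1}$ during stimulation: the stimulus pushes the ensemble
into the inhibition-stabilized regime, and back out afterwards.

The paradoxical effect (inhibitory rate *falling* under excitatory
current injection into the inhibitory population) requires a positive
excitatory-nullcline slope, $x > 1/(J_{EE}\alpha_E
r_E^{(\alpha_E-1)/\alpha_E})$, together with the slope-ordering
condition between the two nullclines. The ordering condition coincides
with a stability condition of the depressed system, so it holds at any
stable fixed point; the package still evaluates it explicitly (it
genuinely fails at large $J_{EE}$ on the regime map, which is what
separates the paradoxical from the merely inhibition-stabilized
region). The printed inhibitory-nullcline slope is implemented as the
derivative of the inhibitory steady-state relation,
$k_I = J_{IE} / (J_{II} + \alpha_I^{-1} r_I^{(1-\alpha_I)/\alpha_I})$,
which is manifestly positive. Regime maps default to the reference
rate $r_E = 1$ Hz and reference $r_I = 1$ Hz for the slope terms, both
configurable. On the $(J_{EE}, x)$ map the paradoxical region is a
strict subset of the ISN region: a paradoxical response implies
inhibition stabilization but not conversely.

## Many ensembles: global vs. co-tuned inhibition

The linearized N-ensemble network is summarized by gain-scaled weights
$a, b, c, d$ at a common operating point, leaks $e = 1/\tau_E$,
$f = 1/\tau_I$, the inter-ensemble excitation factor $k$, and the
co-tuning degree $m \in [0, 1]$ ($m = 1$: one global inhibitory pool;
$m = 0$: each ensemble has its private inhibition). The package
switches between the analytic view (terms supplied directly) and
concrete networks (terms computed from weights and rates) explicitly,
since the two are easy to conflate. The 2N×2N Jacobian has four
distinct eigenvalues in closed form, verified against `eigen()` to
$10^{-10}$ over a thousand random specifications with $N \le 8$ and
the stated multiplicities ($N-1$ for the degenerate pair).

Co-tuning strictly lowers the leading degenerate eigenvalue,
$\mathrm{Re}(\lambda_1') < \lambda_1$, hence enlarges the uni-stable
region — with one caveat found while testing: the printed derivation
bounds a square root by its argument's positive branch, which assumes
$a - e - ka + Nd(1-m) + f > 0$. Outside that regime (strongly leak-
dominated networks) the strict ordering can reverse while both
eigenvalues are deeply negative; the practically relevant implication —
a uni-stable global network stays uni-stable when co-tuned — holds
unconditionally, and the tests check exactly that split. The canonical
uni-stability map uses $k = 0.1$, $m = 0.5$, $bc = 0.9\,ad$, and
$e = 50, f = 100\ s^{-1}$ (the canonical time constants).

For concrete two-ensemble simulations the package resolves
per-connection weights of a homogeneous all-to-all network (100 E + 25
I neurons per ensemble) into effective population weights, excluding
self-connections; splitting ensemble E1 into 75%/25% subsets is exact
under this homogeneity, which a test verifies by comparing the split
and unsplit networks under identical drive. The attractor demo seeds a
uniform initial-rate perturbation of magnitude $10^{-3}$ (the
symmetry-breaking noise); with within-ensemble $J_{EE} = 1.4$ the
symmetric state is unstable and the network settles into a persistent
asymmetric state, with $J_{EE} = 1.3$ it returns to the symmetric
baseline after stimulation. In this implementation the *identity* of
the high-activity ensemble after a stimulation episode is not
guaranteed to follow the stimulus: at stimulus offset the stimulated
ensemble's depression variable is depleted, which can hand the
advantage back to its competitor. The tests therefore assert
persistence of the asymmetric state, not the winner's identity.

## Metrics

The Association index $1 + (r_{E12}-r_{E11})/(r_{E12}+r_{E11})$ lies in
$[0,1]$ when the unstimulated subset is the weaker one; the
decision-boundary distance is implemented in the printed trigonometric
form (arcsine in degrees) and equals $|x-y|/\sqrt 2$ identically, which
doubles as its test oracle. Onset peaks are defined as the maximum over
the stimulation window (earliest tie wins) — the definition is not
operationalized in the published text, and the maximum matches every
figure annotation. Fixed-point activity averages the middle 1 s of the
canonical 2-s window; for nonstandard windows under 1 s the central
50% is used with a warning.

## The spiking network

Leaky integrate-and-fire neurons with conductance-based synapses:
excitatory transmission is a fast AMPA conductance low-passed into a
slow NMDA component ($g_{exc} = \xi g_{ampa} + (1-\xi) g_{nmda}$,
$\xi = 0.5$), inhibition a single GABA conductance. A presynaptic
spike makes the target conductance jump by the synaptic weight (the
standard conductance-jump reading of the delta-driven synapse
equations). Per-synapse depression/facilitation variables depend only
on the presynaptic spike train, so one variable per presynaptic neuron
is exact and the implementation uses that. Membrane potentials are
clipped to the reversal bounds after an Euler step (counted and
reported). Connectivity is drawn once per seed at 20% probability
without self-connections.

Three published ambiguities had to be resolved, and all three are
exposed as configuration rather than buried:

* **Network size.** The sources give both 800 E/200 I and a table
  entry of 400/100 with the same weights and the same five overlapping
  200-neuron ensembles. At 400/100 any two ensembles share ~50% of
  their members, and in simulation a stimulated ensemble's ignition
  recruits the entire network — onset responses lose their selectivity
  entirely. At 800/200 (~25% overlap) onsets are ensemble-selective
  and robust across seeds. The package defaults to 800/200.
* **Spiking threshold.** Not printed; default $-50$ mV, the
  conventional 20 mV above rest.
* **External input weight and inhibitory co-membership.** Each neuron
  receives an aggregate of 300 Poisson sources (0.1 Hz baseline,
  0.5 Hz to stimulated ensemble members) through the AMPA/NMDA
  cascade; the synaptic weight of that drive is not printed and
  defaults to `w_ext = 1.1`, calibrated so baseline activity is sparse
  (~1 Hz) while stimulation evokes a pronounced onset transient that
  settles well below its peak. The published weight table
  distinguishes within- from inter-ensemble weights for inhibitory
  connections, but membership is only defined for excitatory neurons;
  the package assigns each ensemble a random 75% of the inhibitory
  population, making inhibition broadly shared — this is what keeps
  unstimulated ensembles suppressed during another ensemble's onset.

With these defaults the canonical 26-s protocol (ensembles 1–5
stimulated for 2 s each, then 75% of ensemble 5) yields, in every
stimulation period and across seeds, an onset ensemble-activity
difference (~50–70 Hz) well above the fixed-point difference (~22 Hz),
and a clear onset response in the unstimulated 25% of ensemble 5 — the
spiking signatures of NTA and of onset-dominated pattern completion.

**On the variance captured by the first two PCs.** The reference
description reports roughly 40% of total variance in the first two
principal components of binned excitatory spiking over the first 10 s.
The analysis bin width is not stated there; this package uses the same
10 ms bin as the ensemble-activity traces. At a 10-ms bin the total
variance of spike counts is dominated by per-bin Poisson noise (mean
count per neuron per bin is well below 1 at these rates), and the
measured first-two-PC share in the selective regime is ~20%; the ~40%
level is recovered at a 50–100 ms analysis bin, where the
signal-to-noise ratio per bin is an order of magnitude higher. We
report the 10-ms value and note the bin-width sensitivity rather than
tuning the bin to the reference number. (Operating points that do show
~40% at 10 ms exist — lower thresholds with weaker shared inhibition —
but their extra low-dimensional variance comes from stochastic
network-wide ignition events, which destroy the onset selectivity that
is the phenomenon of interest.)

## Problem sizes and runtime

The canonical test and acceptance runs use: 6–9 s rate-model
simulations at 0.1 ms steps; regime maps of a few thousand grid
points; a thousand random block-network specifications for the
eigenvalue checks; five-value drive grids for the two-ensemble
experiments; and 10–26 s spiking simulations of the 1000-neuron
network. These sizes keep the full suite at a few minutes on one core
while exercising every analytic claim end to end.

## Known limitations

* The rate models are deterministic; there is no ongoing noise, so
  trial-to-trial variability and noise-induced switching are out of
  scope. The synthetic protocols emulate the published stimulation
  paradigms, not recorded data: passing tests show internal
  consistency of the mechanism, not biological fit.
* Inhibition is instantaneous-coupling (no synaptic delay); delayed
  inhibition can destabilize even `det(J) > 0` networks and is not
  modeled.
* Basins of attraction are probed only by multi-start simulation;
  there is no continuation-grade bifurcation tracking.
* The E-to-I facilitation regime conditions are assessed numerically
  (probes), not re-derived analytically.
* The spiking network is a single-compartment, current-free
  conductance LIF; refractoriness caps rates near 333 Hz, which
  truncates the tallest onset transients relative to the unbounded
  rate model.
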
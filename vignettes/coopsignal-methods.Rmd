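---
title: "Methods: signalling, scrounging, and the carrying capacity for cooperation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signalling, scrounging, and the carrying capacity for cooperation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopsignal)
```

## The scientific question

Active recruitment of conspecifics to food — food calls, conspicuous feeding
displays — looks altruistic: the caller pays a cost (energy, predation risk,
increased competition for mates and sites) and competitors gain information.
Yet food calling is observed in nature, e.g. in cliff swallows feeding on
wind-blown insect swarms, precisely when the resource is localized, drifting,
and easily lost. `coopsignal` implements a family of models in which a costly
"signal on food" strategy competes against a silent scrounger strategy inside
a dynamic resource landscape, and asks when a stable number of signallers can
be maintained by direct benefit alone — no kin selection, no reciprocity.

The package has three tiers:

1. a **full agent-based model**: self-propelled foragers advected by a
   synthetic turbulent flow, feeding on an advected, decaying scalar plume;
2. a **reduced moving-patch model**: a single circular patch that relocates
   every `T` time units, foraged by constant-speed agents that cannot stop;
3. an **analytic absorbing-Markov-chain approximation** of the reduced model
   that yields closed-form entry probabilities, transient times, occupancies,
   and the relative uptake of signallers over scroungers.

## Tier 1: the turbulent foraging environment

### Carrier flow

The flow is kinematic (synthetic) turbulence: a sum of Fourier modes on the
unit torus, each mode's velocity direction perpendicular to its integer
wavevector, so the field is divergence-free *by construction*. Mode complex
amplitudes follow exact Ornstein–Uhlenbeck updates whose stationary energies
follow a Kármán–Obukhov spectrum

$$E(k) \propto \frac{k^4}{(k^2 + k_0^2)^{17/6}}, \qquad k_0 = 1/L_{max},$$

and whose relaxation rates scale as $\gamma_k \propto k^{2/3}$ (smaller
eddies decorrelate faster). The spectrum peaks near the system scale. The
field realized at initialization is rescaled — jointly with the stationary
targets — so the dense-grid mean speed equals `U_target` exactly; the
Gaussian-field relation $E|u| = \sqrt{\pi \langle |u|^2 \rangle}/2$ keeps the
stationary statistics at the same level under stepping.

Two numerical notes. Velocity grids are synthesized by FFT (identical to the
trigonometric mode sum to round-off). Because the field is band-limited, its
divergence is checked by *spectral* differentiation, which is exact for this
field; second-order central differences carry an $O(h^2)$ truncation error of
order $10^{-2}\,|u|$ for oblique modes at $k \approx 8$ and would mask the
construction-level incompressibility they are meant to confirm.

### Resource field

The nutrient concentration obeys the nondimensionalized balance
$\partial_t \phi + u\!\cdot\!\nabla\phi = s - \phi$ (unit decay rate, unit
torus). The source $s$ is a kernel $\textrm{rate}\cdot e^{-d/\psi}$ around a
centre that is itself advected by the flow; `width` $\psi$ is one of the two
environmental control parameters, the mean flow speed `U` the other. The
input `rate` only rescales concentrations; uptake is always normalized by
the mean concentration and the signalling cost is specified relative to that
mean, so results are `rate`-invariant (default 1).

Advection uses a semi-Lagrangian midpoint backtrace with periodic bilinear
interpolation: unconditionally stable and positivity-preserving, at the cost
of mild numerical diffusion (there is no explicit diffusion term to
represent). Source input and decay are applied with the exact integrating
factor $\phi \leftarrow \phi\,e^{-dt} + s\,(1 - e^{-dt})$, so with zero flow
the steady state is exactly $\phi = s$, and the spatial-mean balance
$d\langle\phi\rangle/dt = \langle s\rangle - \langle\phi\rangle$ holds to
interpolation tolerance under advection. Defaults: grid $256^2$ (tests and
examples use $64^2$), $dt = 0.05$.

### Behavioural rules

Agents move at constant self-propulsion speed $v$ along their heading and are
advected by the flow. A solitary agent performs a correlated random walk
(heading noise with standard deviation `angular_noise`·$\sqrt{dt}$ per step,
default 1 rad/$\sqrt{t}$), has no taxis, and therefore collects on average
exactly the mean concentration — the asocial baseline against which
cooperation is measured.

State is carried by a normalized concentration $C = \phi/(\phi + K)$,
saturating in $[0,1)$. The half-saturation $K$ defaults to the running mean
concentration of the field: "high concentration" is judged relative to what
the environment typically offers. Per time step:

* a **signaller** emits a signal with probability $C$; a non-signaller never
  does;
* every agent is willing to respond with probability $1 - C$ (a sated agent
  ignores signals, a deprived one follows them) — identical across
  phenotypes;
* a willing agent that perceives at least one *other* signalling agent
  within `interaction_range` turns to the minimum-image centroid of those
  signallers (instantaneous turn: the rules define a preferred direction,
  not a turning law); otherwise the correlated random walk continues.

Uptake accrues as raw concentration × $dt$ and is never depleted — agents
are point particles, and in the absence of signals they are mutually
invisible, which also removes crowding and consumption effects. The entire
cost of signalling is a single rate parameter in the fitness function.

The exact saturating forms of the signal, response and normalization maps
are reconstructions: the qualitative contracts (monotone in $C$, signaller
threshold behaviour, response suppressed at high concentration) are the
fixed points of the design; all three maps are replaceable.

An optional asocial search (`search_gain`) modulates turning noise by
$\exp(g\,(C_{prev} - C))$ — klinokinesis on the temporal concentration
derivative: runs lengthen up-gradient. Its default is 0; switching it on
raises lone-agent uptake monotonically in $g$ and rescales, but does not
restructure, the comparison between social strategies.

## Tier 2: the reduced moving-patch model

The reduced model keeps only the two environmental scales: a circular patch
of radius $R$ (uniform concentration 1 inside, 0 outside) that relocates
uniformly at random every `T_persist` time units, foraged by `N_S`
signallers and `N_NS` scroungers moving at constant speed $v$. *Agents
cannot stop*: constant speed is the surrogate for the relative velocity that
advection imposes in the full model, and guarantees a time scale on which an
unassisted individual loses the patch (about the crossing time $2R/v$).

Inside the patch the concentration is saturating, so the stochastic rules
degenerate: signallers inside always signal, agents inside never respond,
agents outside always respond to an available signal and head to the
centroid of the in-patch signallers. The default perception range is global
(the analytic treatment assumes any agent can perceive the signal); a finite
range is available in configuration. The integration step defaults to
$0.1\,(2R/v)$ so a patch crossing is resolved by ten substeps.

Scroungers are dynamically inert — they signal nothing — so adding them
cannot change anyone else's trajectory. The implementation makes this exact:
relocation centres and per-cohort noise streams are pre-drawn so signaller
trajectories are bit-identical across runs differing only in `N_NS`; a test
asserts the identity. Uptake rate per agent is the fraction of time spent
inside the patch, and the headline statistic is the relative uptake
$F_S/F_{NS}$.

## Tier 3: the Markov-chain approximation

Time is discretized into patch-crossing intervals $\tau = 2R/v$ and the
cohort dynamics after a relocation is approximated by a three-state chain:
`U` (no signaller on the patch), `O1` (exactly one, unstable — it will be
swept off unless another signaller arrives within one step), and the
absorbing `A` (two or more signallers hold the patch by mutual recruitment).

Entry probabilities come from the annulus geometry on the unit-area domain:
with a signal, any agent within one step's reach of the boundary enters,
$p_s = \pi((3R)^2 - R^2) = 8\pi R^2$; without, the chance of entry falls
linearly from $1/2$ at the boundary to $0$ at the outer rim, and averaging
over a uniform position in the ring gives $p_{ns} = \tfrac{5}{3}\pi R^2$
(so $p_{ns}/p_s = 5/24$ for every valid $R$; validity requires $3R < 0.5$,
where planar geometry is a good stand-in for the torus).

With $N$ signallers entering independently, `U` transitions by a binomial
composition (exactly one enters: to `O1`; two or more: straight to `A`), and
`O1` escapes to `A` when the lone occupant recruits at least one of the
other $N-1$ (probability $1-(1-p_s)^{N-1}$). The mean first-passage time
$T_1$ to `A` solves the standard linear system $(I-Q)\,t = \mathbf 1$,
averaged over a binomial initial occupancy (uniform agent positions at
relocation). The transient fraction of a persistence interval is
$\alpha = \min(T_1\tau, T)/T$.

During the transient, focal-agent occupancies follow two-state enter/leave
chains: $Q_S = p_{ns}/(p_{ns} + (1-p_s)^{N-1})$ for a signaller (it can be
*held* by those it recruits) and $Q_{NS} = p_{ns}/(p_{ns} + (1-p_{ns})^N)$
for a scrounger (it relies on a signaller entering by chance). In the stable
regime both phenotypes arrive at the same rate and enjoy equal uptake,
modelled by a common occupancy $Q_2$ (default 1 — the signal is continuously
available; configurable). The assembled prediction is

$$\frac{F_S}{F_{NS}} =
  \frac{\alpha\,Q_S + (1-\alpha)\,Q_2}{\alpha\,Q_{NS} + (1-\alpha)\,Q_2},
  \qquad \delta = \alpha\,(Q_S - Q_{NS}),$$

with $\delta/(\pi R^2)$ the uptake differential on the scale on which cost
is specified (the domain-mean concentration is $\pi R^2$). Both the ratio
and the differential are reported, since either reading of the final
assembly is defensible. `equilibrium_points()` sweeps $\delta(N)$ against a
cost: the smallest upcrossing is the invasion threshold (unstable), the
largest the evolutionarily stable signaller number; the differential is
steep around the stable point, which is why moderate cost changes move the
stable density only marginally.

Because the per-arrow probabilities of the source chain are not recoverable
in closed form from the verbal description alone, all binomial compositions
above are reconstructions honouring every stated property, and they are
validated against the reduced-model simulator (chain Monte-Carlo oracles in
the test-suite check the algebra; the simulator checks the science).

### Where the approximation is honest and where it strains

The chain treats agent positions as uniformly re-randomized every step and
restricts signal-aided entry to the 2R-wide ring. The simulator, run under
the same parameters, reproduces the qualitative structure everywhere — a
lone signaller at or below parity, a threshold cohort that outperforms, and
parity restored both for large cohorts (the transient shrinks) and for
long-lived patches ($\alpha \to 0$). Quantitatively, agreement is close in
the long-persistence and small-patch regimes, but the chain *overstates* the
signaller advantage where transients dominate and the patch is easy to find
(large $R$, short $T$): in the continuous dynamics a signal accelerates
entry for both phenotypes alike and recruitment builds local crowds, both of
which dilute the finder's share that the chain attributes exclusively to
signallers. The acceptance suite measures this pointwise and reports the
discrepancy rather than hiding it; see the repository notes on tolerances.

## Evolutionary dynamics

Each generation draws a fresh flow realization, spins the field up to its
statistical steady state, releases the population uniformly (well-mixed
assumption: no spatial lineage structure is modelled), simulates a foraging
season, and computes fitness

$$w_i = \max\left(\frac{u_i}{\bar\phi\,L} - c\,[i \in S],\, 0\right),$$

normalized uptake rate minus a constant-rate cost $c$ for signallers
(cost per unit time as a fraction of the mean concentration — not per
signal; the two are statistically equivalent). Offspring phenotypes are
drawn by roulette wheel over these weights (all-zero weight vectors fall
back to uniform with a warning); mutation defaults to 0 so the dynamics are
pure selection on the seeded variation. The flooring at zero is required by
roulette selection and preserves the extinction of dominated strategies.

Defaults follow the study conditions: population 512 seeded with 8
signallers (a small founder cohort is necessary because the strategy only
pays above a threshold number), season long enough for a solitary agent to
cross the domain about 50 times, per-generation seeds derived
deterministically from the master seed. Scaled-down runs in the tests use
population 128, a $64^2$ grid and 15-time-unit seasons; the vignette-scale
equilibrium claims are therefore about direction and stability of selection,
not about the precise equilibrium counts at paper scale.

A structural property worth stating: scroungers never influence anyone, so
the *absolute number* of signallers — not their frequency — determines the
direction of selection. Doubling the scrounger count changes the speed of
frequency change, not the location of equilibria.

### What the generator emulates, and what it does not

The synthetic environment reproduces the features the models need —
statistically stationary isotropic stirring with a controlled spectrum, a
localized advected source, steep concentration gradients, uptake-relevant
time scales — but it is kinematic: there is no pressure field, no inertia,
no intermittency beyond Gaussian modes, and the scalar has no explicit
diffusivity (the semi-Lagrangian scheme supplies a small numerical one).
Passing tests on this environment demonstrate the mechanisms, not fidelity
to any particular geophysical flow.

In the full model at the scaled-down sizes we run, the *collective* benefit
of signalling is strong and easy to demonstrate (cohorts of signallers
out-collect matched asocial groups by tens of percent), while the
signaller-minus-scrounger differential at low seeding density is small
relative to seed-to-seed variance: with global information flow through
dense scrounger crowds, free-riding is nearly complete. The reduced model —
which is the analysable core and where the threshold/equilibrium structure
lives — shows the differential cleanly. This ordering (weak full-model
differential, clean reduced-model differential) is itself informative about
how much environmental structure the cooperative advantage needs.

## Numerical choices and degenerate inputs

* `U_target = 0` gives an exactly zero flow (frozen modes), used by the
  fixed-point and decay tests.
* All stochastic components take explicit seeds; same seed, same output,
  bit-for-bit. Component seeds derive from a master seed by a polynomial
  hash (`seed_spawn()`), keeping streams well separated.
* Degenerate recruitment geometry (a responder exactly at the signaller
  centroid) keeps the previous heading plus noise.
* An all-`NS` population is an absorbing state and the relative-uptake
  record is flagged `NA`, never fabricated; zero scrounger uptake flags the
  ratio as missing.
* The three-state chain with $N \le 1$ has an unreachable absorbing state;
  the mean first-passage time is reported as `Inf` and the transient
  fraction saturates at 1.
* Geometry guard: the annulus formulas require `3R < 0.5`; violating
  parameters raise errors rather than silently extrapolating.

## Problem sizes used in the checks

Module tests run on $32^2$–$64^2$ grids with seasons of 2–20 time units and
reduced-model runs of duration 1500–3000; the acceptance suite uses $64^2$
grids, reduced-model durations of 2000 with five pooled seeds per grid
point, 20 replicate seeds for the baseline-uptake law, and evolutionary runs
of 30 generations × 10 seeds at population 128. These sizes were chosen so
the full suite exercises every claim at desk scale; the package defaults
(grid $256^2$, population 512, ~100 generations) reproduce the study-scale
setup and are driven by the same code paths.
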
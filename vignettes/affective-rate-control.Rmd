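---
title: "Controlling the firing rate of a spiking network with an affective system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling the firing rate of a spiking network with an affective system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectnet)
```

## The model

`affectnet` simulates a deliberately simple spiking artificial neural
network coupled to an *affective system*: a feedback controller, analogous
to neuromodulation by the limbic system, that steers the network's ensemble
firing rate by broadcasting threshold changes to every neuron.

**Neurons** live at distinct sites of a discrete 3-D grid (coordinates are
integral multiples of the granularity `g`, within `[-M, M)` per axis). Each
neuron carries a charge and a threshold, both bounded to `[-1, 1]`. Charge
arriving over synapses accumulates (clamped at the bounds) until it reaches
the threshold; the neuron then fires, resets its charge to zero, and enters
a refractory period (default 1 time unit) during which it can accumulate
charge but cannot fire. The comparison is `charge >= threshold`, so an
exact tie fires. There is no charge decay: none is part of the model, and
the charge state changes only through arrivals and firings.

**Synapses** are directed and weighted (`[-1, 1]`). A unit of simulation
time is defined as the time charge needs to travel one grid unit, so a
synapse's propagation delay *is* the Euclidean distance between its
endpoints — there is no myelination, and equidistant synapses deliver
simultaneously. Simulation is discrete-event: a priority queue orders
events by time, with ties broken by insertion order so that every run is
exactly reproducible. Measurement/adjustment ticks are ordered after
same-time charge events, which makes a rate window the half-open interval
`(t - w, t]`.

**Plasticity.** If the charge carried by a synapse is what pushes the
postsynaptic neuron over threshold, that synapse is potentiated by a fixed
step (LTP, default 0.001); if its charge arrives while the postsynaptic
neuron is refractory, it is depressed by the same step (LTD). Each synapse
has a single plasticity refractory clock (default 10 time units) shared by
LTP and LTD that limits how often its weight may change. Attribution is
event-local: only the synapse whose arrival crossed the threshold is
potentiated, not earlier contributors — the unambiguous reading of
"causes the neuron to fire" for a discrete-event engine.

**The affective system.** Every `w` time units (default 10) the controller
measures the firing rate `f(t)` — the number of network firings in the
window divided by `w`, hence in firings per unit time — and computes the
error `e(t) = f(t) - d(t)` against the desired rate `d`. The *simple*
system broadcasts the threshold change `delta = alpha * e(t)`; the
*complex* system first smooths the error geometrically,
`ebar(t) = lambda * ebar(t - w) + (1 - lambda) * e(t)`, and broadcasts
`alpha * ebar(t)`. The two coincide at `lambda = 0`. The broadcast is
skipped, per neuron, when it would push that neuron's threshold out of
`[-1, 1]` (the threshold is left unchanged rather than clipped).

Two unit conventions matter here and are worth stating explicitly:

* `f` is a *per-unit-time* rate. With a refractory period of one, each
  neuron fires at most once per time unit, so `f` is bounded by the neuron
  count (1000 for the default realization) and the error by the same
  number. That is precisely why the default gain is `alpha = 0.001`: the
  largest possible single-step threshold change has magnitude one, the full
  width of the threshold range. Treating `f` as a raw per-window count
  would decouple the gain from the threshold scale and, because of the
  bound-violation skip rule, can freeze the controller entirely after a
  transient burst (the broadcast is always "too large" and never applies —
  a form of integrator windup we verified empirically before settling on
  the per-unit-time convention).
* The error sign: firing above desire yields positive error and *raises*
  thresholds. This is the convention under which settled thresholds
  decrease as the desired rate increases, which is the observed behavior of
  the system.

## The synthetic study conditions

`generate_network()` realizes the study conditions: 1000 neurons at
distinct uniformly random sites of a 200×200×200 grid, 10000 distinct
directed synapses with weights i.i.d. uniform on `[-1, 1]`, every threshold
at 0.5, refractory period 1. The environment is a single input neuron
driven by pulses (charge `+1`, clamped) at exponentially distributed
intervals with mean 10 (rate 0.1 per unit time), generated by
`input_pulse_times()`.

The synapse placement kernel is the one genuinely open generator choice:
the model calls only for a "higher likelihood of connectivity between
spatially close neurons". We sample directed pairs without replacement with
probability proportional to `exp(-dist / tau)`, `tau = 20` grid units —
roughly a fifth of the typical inter-neuron distance, so connectivity is
strongly local without being degenerate. The draw uses exponential sorting
keys (`Exp(1) / p`), which realizes weighted sampling without replacement
in one vectorized pass. `tau` is a parameter, and the proximity preference
is verified in the tests by comparing the mean sampled synapse distance
with a Monte-Carlo mean over uniform pairs.

What the generator does *not* emulate: biologically realistic connectomes,
distance-dependent weights, degree constraints, or any spatial structure
beyond the proximity kernel. Passing tests therefore say that the
*mechanisms* (event engine, controller, plasticity) behave as specified on
random recurrent graphs of this family — not that the quantitative results
transfer to real neural tissue, which the model does not attempt to
represent.

## Rate-control experiments

`run_rate_control()` composes generator, engine, controller and plasticity;
`settling_time()` (first window from which the rate stays within 50 units
of `d` to the end of the segment), `percent_overshoot()` (max excess over
`d` as a percent of `d`, floored at zero) and `oscillation_period()` (mean
spacing of upward crossings through `d` before settling) summarize each
segment of a desired-rate schedule. Unsettled segments are reported as
`NA`. `weight_histogram()` bins weights into the 20 intervals
`[x, x + 0.1)` with the last bin closed at 1; bin indices are computed with
a `1e-9` guard so that values sitting exactly on a bin edge land in the bin
they open despite floating-point representation error.

On the default conditions these experiments reproduce the expected
structure of the system (all of this is asserted by the test suite):

* the simple controller (`alpha = 0.001`) settles a 1000-neuron network at
  `d = 300` and holds it within the 50-unit band;
* the settled threshold decreases monotonically as `d` ranges over
  150–900;
* with plasticity on, most weights migrate into the lowest histogram bin
  (the excitatory subnetwork becomes sparse), and both extreme bins grow
  over the run;
* plasticity with refractory 10 — the same time scale as the controller —
  produces sustained oscillation around the setpoint, while refractory 50
  or disabling plasticity settles quickly and tightly: learning should run
  slower than control.

The last point has a visible consequence for steady-state accuracy: with
the default (fast) plasticity clock the post-settling limit cycle has an
amplitude right at the edge of the 50-unit band, and on some network
realizations it exceeds it slightly. That is a property of the configured
system, not a tuning target, so we report it as measured.

## Numerical choices

* Event times are continuous reals (delays are Euclidean distances);
  adjustment ticks occur at exact multiples of `w` computed as `k * w`
  to avoid accumulation drift, with a `1e-9` slack when comparing against
  the end time.
* Simultaneous events process in insertion order; ticks after same-time
  arrivals (so a firing at exactly `t` counts in the window ending `t`).
* The charge delivered by a firing equals the synapse weight *at the
  moment of firing*; a subsequent weight change does not retroactively
  alter in-flight charge.
* A weight change blocked by the plasticity refractory leaves the clock
  untouched; an accepted change sets it even when clamping makes the
  change a no-op at the bounds.
* `ebar` starts at 0 and is updated every tick regardless of controller
  type, which is what makes the `lambda = 0` complex system bit-identical
  to the simple one.

## Evolutionary training and the cart-pole task

The application stack evolves a *genome* — a network plus its desired
firing rate `d`, which is itself an evolved trait — against a fitness
function. Defaults (population 50, tournament 5, crossover 0.9, mutation
0.9, uniform mutation-type weights, elitism 1, 100 epochs) are documented
substitutes chosen in the usual range for small neuroevolution runs; the
reference values for this system are not available, so all of them are
configurable in `ea_config()`.

Crossover splits both parents by a random axis-aligned plane and exchanges
the sides, respecting the 3-D embedding; synapses follow their endpoints,
and a synapse that loses an endpoint is reattached to the nearest child
neuron on the far side of the plane. Children inherit the *average* of the
parents' `d`. The mutation menu adds/deletes neurons and synapses, perturbs
single weights or thresholds, and resamples `d` uniformly on
`[0, n_neurons]`. The 12 input neurons (three ranges for each of the four
cart-pole state variables) and 2 output neurons (−10 N / +10 N) sit at
fixed grid positions shared by every genome, are never deleted, and are
inherited as a block — this keeps every genome's interface well defined
under arbitrary recombination.

The cart-pole environment is the standard bang-bang benchmark: cart 1 kg,
pole 0.1 kg with half-length 0.5 m, gravity 9.8 m/s², forces
{−10, 0, +10} N, explicit Euler at 0.02 s, failure at |x| > 2.4 m or
|θ| > 0.209 rad. Encoding cutpoints (x: ±0.8 m, ẋ: ±0.5 m/s, θ: ±0.05 rad,
θ̇: ±0.2 rad/s, left-closed), the six fitness starting conditions
(`(±1.5, 0)`, `(0, ±0.1)`, `(±1.0, ∓0.05)` in `(x, θ)`, zero velocities)
and the generalization grid's x origin (−2.2) are configurable defaults
standing in for reference values that are not available. Each control
decision pulses the four active inputs, simulates the network for 200 time
units (with the affective system adjusting thresholds every 10 units when
enabled, holding the genome's `d`), takes the majority output neuron as the
action (ties and silence give 0 N), and advances the physics one step.
Network charges, pending events and controller state persist across
decision windows within an episode; everything is reset between episodes,
including between the six fitness trials.

Full training to the 300 s × six-condition criterion is an overnight-scale
computation and is exercised here only through the `evolve()` harness on
toy fitness functions; the desk-scale tests verify the physics, encoding,
decoding and episode loop against closed-form and pure-physics oracles
instead.

## Problem sizes used by the test suite

Unit and property tests run on scaled-down realizations (200 neurons /
2000 synapses on a 50³ grid, runs of 300–3000 time units, with setpoints
at the same ~20 % of the rate ceiling as the full-scale study conditions)
so the suite stays fast while exercising the identical code paths. The
end-to-end checks in `test-acceptance.R` use the full 1000-neuron
conditions: one 10000-unit tracking run at `d = 300`, a six-point sweep of
desired rates for the threshold-monotonicity and weight-histogram trends,
and a three-seed comparison of plasticity refractory periods 10 and 50.
The paper-scale sweep across 100 network structures is available by
looping `run_rate_control()` over seeds, but is not part of the default
suite.

## Known limitations

* The neuron model is intentionally minimal: no conductances, no charge
  decay, no per-neuron heterogeneity in the generated networks.
* The affective broadcast is uniform across the network; regional or
  network-implemented modulation is out of scope.
* The structural crossover and mutation operators are reasonable
  stand-ins; with the reference operators unavailable, only the
  desired-rate gene semantics (averaging under crossover, uniform
  resampling under mutation) are fixed by the model description.
* LTD is triggered only by arrivals during the postsynaptic refractory
  period; an arrival that merely fails to fire a ready neuron leaves the
  weight unchanged.
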
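# affectnet

Discrete-event simulation of simple spiking artificial neural networks
coupled to an **affective system** — a feedback controller, analogous to
neuromodulation by the limbic system, that regulates the ensemble firing
rate of the network by broadcasting threshold changes to every neuron. The
package is for computational-neuroscience experimentation with
homeostatic rate control: it provides the event engine, LTP/LTD synaptic
plasticity, seeded random network generation, the rate-control experiment
harness (settling time, percent overshoot, oscillation period, weight
histograms), an evolutionary training algorithm over network topology and
the desired firing rate, and the bang-bang cart-pole benchmark.

## The model in brief

Neurons sit on a 3-D grid and integrate incoming charge until it reaches
their threshold; they then fire, reset to zero charge and enter a
refractory period (charges and thresholds are bounded to [−1, 1]). Charge
travels along directed synapses at one grid unit per time unit, so the
synaptic delay is the Euclidean distance between the endpoints. Every *w*
time units (default 10) the affective system measures the firing rate
*f(t)* (firings per unit time, at most the neuron count) and broadcasts a
threshold change to all neurons:

* error: *e(t) = f(t) − d(t)*, with *d* the desired rate;
* simple system: *Δθ(t) = α · e(t)*;
* complex system: *ē(t) = λ ē(t−w) + (1−λ) e(t)*, *Δθ(t) = α · ē(t)*;

with *α* = 0.001 by default, so the largest possible correction has
magnitude one. A change that would push a neuron's threshold out of
[−1, 1] leaves that threshold unchanged. LTP increments a synapse weight
by 0.001 when its charge causes the postsynaptic firing; LTD decrements it
by 0.001 when its charge arrives during the postsynaptic refractory
period; each synapse's weight may change at most once per plasticity
refractory period (default 10).

## Worked example

Hold a random 1000-neuron, 10000-synapse network at a desired rate of 300
firings per unit time for 10000 time units, with input pulses arriving at
exponentially distributed intervals (mean 10):

```r
library(affectnet)
res <- run_rate_control(
  gen        = generation_params(),            # 1000 neurons, 10000 synapses
  controller = affective_system(d = 300),      # simple system, alpha = 0.001
  t_end      = 10000, seed = 1)
res
#> <rate_control_result>
#>  start   end   d settling_time percent_overshoot oscillation_period
#>      0 10000 300          8780              80.6           38.52018
#> final mean threshold: 0.0186
tail(res$trace$rates, 3)
#>       time  rate desired threshold
#> 998   9980 339.9     300    0.0218
#> 999   9990 266.7     300   -0.0115
#> 1000 10000 330.1     300    0.0186
```

The controller drives the rate from zero up to the setpoint, overshoots by
80.6 % of *d* during the transient, oscillates with a mean period of about
39 time units, and from *t* = 8780 stays within 50 units of 300. The mean
threshold falls from 0.5 to about 0.02 — the level at which this network
sustains 300 firings per unit time. The long transient is characteristic
of the default plasticity clock (refractory 10, the same time scale as the
controller): disable plasticity (`plasticity = FALSE`) or slow it down
(`plasticity_params(refractory = 50)`) and the same network settles before
*t* = 400 with errors under 15. The final weight histogram
(`res$final_histogram`) shows the signature of LTP/LTD under rate control:
most weights end in the lowest bin [−1, −0.9), i.e. most synapses become
strongly inhibitory while a small excitatory subnetwork carries the
firing.

A genome for the cart-pole task couples a small network (12 input neurons,
2 output neurons) with an evolved desired rate:

```r
g <- cartpole_genome(seed = 1)
fitness_six(g, max_time = 5)   # mean balancing time over six starts, seconds
#> [1] 0.1866667
```

A command-line surface over the same functions is installed at
`inst/cli/affectnet.R` (subcommands `generate`, `simulate`, `rate-control`,
`sweep`, `evolve`, `cartpole-eval`, `generalize`).

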
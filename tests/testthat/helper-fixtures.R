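# Fixtures are built in code: tiny hand-specified networks with known
# dynamics, plus scaled-down random realizations for property tests.

# A -> B chain: unit distance, weight 1, thresholds 0.5.  A pulse to A at t
# fires A at t and B at t + 1.
chain_network <- function(weight = 1, threshold = 0.5, refractory = 1) {
  new_network(
    neurons = data.frame(id = 1:2, x = c(0, 0), y = c(0, 0), z = c(0, 1),
                         threshold = threshold, refractory = refractory,
                         is_input = c(TRUE, FALSE),
                         is_output = c(FALSE, TRUE)),
    synapses = data.frame(pre = 1, post = 2, weight = weight),
    grid = list(M = c(5, 5, 5), g = 1))
}

# Three neurons converging on B: A at distance 1 and C at distance 2, so
# driving A and C together makes B's second arrival land in B's refractory
# period.
convergent_network <- function(w_ab = 1, w_cb = 1, refractory_b = 2) {
  new_network(
    neurons = data.frame(id = 1:3,
                         x = c(0, 0, 0), y = c(0, 0, 0), z = c(0, 1, 3),
                         threshold = 0.5,
                         refractory = c(1, refractory_b, 1),
                         is_input = c(TRUE, FALSE, TRUE),
                         is_output = FALSE),
    synapses = data.frame(pre = c(1, 3), post = c(2, 2),
                          weight = c(w_ab, w_cb)),
    grid = list(M = c(5, 5, 5), g = 1))
}

# Scaled-down random realization for property tests (the full study
# conditions are 1000 neurons / 10000 synapses).
small_gen <- function(...) {
  generation_params(n_neurons = 200, n_synapses = 2000,
                    grid = list(M = c(25, 25, 25), g = 1), tau = 10, ...)
}

# Independent reference simulator used as an oracle for the event engine:
# a plain R loop over an explicit event list, processed by (time, insertion
# order), built only from the documented add_charge/fire_neuron semantics.
# No plasticity, no controller.
ref_simulate <- function(net, pulse_times, t_end) {
  inp <- which(net$neurons$is_input)[1]
  ev <- data.frame(time = pulse_times, neuron = inp, amount = 1.0,
                   seq = seq_along(pulse_times))
  processed <- rep(FALSE, nrow(ev))
  fired_t <- numeric()
  fired_id <- integer()
  repeat {
    idx <- which(!processed & ev$time <= t_end)
    if (length(idx) == 0) break
    nxt <- idx[order(ev$time[idx], ev$seq[idx])][1]
    processed[nxt] <- TRUE
    e <- ev[nxt, ]
    out <- add_charge(net, e$neuron, e$amount, e$time)
    net <- out$network
    if (out$fired) {
      fired_t <- c(fired_t, e$time)
      fired_id <- c(fired_id, e$neuron)
      arr <- fire_neuron(net, e$neuron, e$time)
      if (nrow(arr) > 0) {
        add <- data.frame(time = arr$arrival_time, neuron = arr$post,
                          amount = arr$amount,
                          seq = max(ev$seq) + seq_len(nrow(arr)))
        ev <- rbind(ev, add)
        processed <- c(processed, rep(FALSE, nrow(arr)))
      }
    }
  }
  data.frame(time = fired_t, neuron = fired_id)
}
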
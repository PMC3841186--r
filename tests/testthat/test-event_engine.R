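test_that("event queue orders by time with insertion-order tie-break", {
  q <- event_queue()
  schedule_event(q, 5, "input_pulse", "late")
  schedule_event(q, 3, "input_pulse", "early")
  expect_equal(pop_event(q)$payload, "early")
  expect_equal(pop_event(q)$payload, "late")
  expect_null(pop_event(q))

  # exhaustive small-queue oracle: any insertion sequence pops in
  # (time, insertion order)
  set.seed(7)
  for (rep in 1:20) {
    times <- sample(1:4, 8, replace = TRUE)
    q <- event_queue()
    for (i in seq_along(times))
      schedule_event(q, times[i], "charge_addition", i)
    got <- vapply(seq_along(times), function(i) pop_event(q)$payload,
                  numeric(1))
    expect_equal(got, order(times))   # stable sort oracle
  }
})

test_that("scheduling into the past is rejected", {
  q <- event_queue()
  schedule_event(q, 10, "neuron_fire", NULL)
  pop_event(q)
  expect_error(schedule_event(q, 5, "neuron_fire", NULL), "past")
  expect_error(schedule_event(q, -1, "neuron_fire", NULL), "nonnegative")
  expect_error(schedule_event(q, 1, "bogus_type", NULL), "unknown event type")
})

test_that("a two-neuron chain fires in sequence with unit delay", {
  net <- chain_network()
  tr <- simulate_network(net, t_end = 10, pulses = 0, plasticity = FALSE)
  expect_equal(tr$firings$time, c(0, 1))
  expect_equal(tr$firings$neuron, c(1, 2))
})

test_that("a network with no events produces an empty trace", {
  tr <- simulate_network(chain_network(), t_end = 100)
  expect_equal(nrow(tr$firings), 0)
  expect_equal(tr$rates$rate, rep(0, 10))
})

test_that("engine agrees with the reference R simulator on a small net", {
  gen <- generation_params(n_neurons = 12, n_synapses = 40,
                           grid = list(M = c(4, 4, 4), g = 1), tau = 4)
  for (seed in 1:3) {
    net <- generate_network(gen, seed = seed)
    net$neurons$threshold <- 0.3   # make activity likely
    pulses <- input_pulse_times(0.5, 60, seed = seed + 100)
    tr <- simulate_network(net, t_end = 60, pulses = pulses,
                           plasticity = FALSE)
    ref <- ref_simulate(net, pulses, t_end = 60)
    expect_equal(tr$firings$time, ref$time)
    expect_equal(tr$firings$neuron, ref$neuron)
  }
})

test_that("causality: charge arrivals follow their firing by the distance", {
  net <- generate_network(small_gen(), seed = 3)
  tr <- simulate_network(net, 200, pulses = input_pulse_times(0.2, 200, 5),
                         plasticity = FALSE)
  # every non-input firing is preceded by an in-synapse firing one
  # propagation delay earlier
  syn <- net$synapses
  fir <- tr$firings
  inp <- which(net$neurons$is_input)
  for (k in which(!fir$neuron %in% inp)) {
    pre_syn <- syn[syn$post == fir$neuron[k], ]
    lag <- outer(fir$time[k] - pre_syn$distance, fir$time, "-")
    match_pre <- abs(lag) < 1e-9 &
      outer(pre_syn$pre, fir$neuron, "==")
    expect_true(any(match_pre))
  }
})

test_that("successive firings of one neuron respect the refractory period", {
  net <- generate_network(small_gen(), seed = 11)
  net$neurons$threshold <- 0.1
  tr <- simulate_network(net, 300, pulses = input_pulse_times(0.5, 300, 12))
  sp <- split(tr$firings$time, tr$firings$neuron)
  gaps <- unlist(lapply(sp, function(t) diff(sort(t))))
  if (length(gaps) > 0)
    expect_gte(min(gaps), net$neurons$refractory[1] - 1e-9)
})

test_that("measured_firing_rate counts the half-open window (t-w, t]", {
  tr <- structure(list(firings = data.frame(time = c(1, 2, 3))),
                  class = "affect_trace")
  expect_equal(measured_firing_rate(tr, 10, 10), 3)
  expect_equal(measured_firing_rate(tr, 12, 10), 1)   # (2, 12] holds {3} only
  expect_equal(measured_firing_rate(tr, 3, 1), 1)     # right-closed
  tr0 <- structure(list(firings = data.frame(time = numeric())),
                   class = "affect_trace")
  expect_equal(measured_firing_rate(tr0, 10, 10), 0)
  expect_error(measured_firing_rate(tr, 5, 10), "window")
  # brute-force count oracle on random firing sets
  set.seed(9)
  for (i in 1:20) {
    times <- sort(runif(50, 0, 100))
    trr <- structure(list(firings = data.frame(time = times)),
                     class = "affect_trace")
    t0 <- runif(1, 20, 100); w <- runif(1, 1, 20)
    expect_equal(measured_firing_rate(trr, t0, w),
                 sum(times > t0 - w & times <= t0))
  }
})

test_that("deterministic replay: identical inputs give identical traces", {
  gen <- small_gen()
  one <- function() {
    net <- generate_network(gen, seed = 21)
    simulate_network(net, 500, pulses = input_pulse_times(0.1, 500, 22),
                     controller = affective_system(d = 30))
  }
  a <- one(); b <- one()
  expect_identical(a$firings, b$firings)
  expect_identical(a$rates, b$rates)
})
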
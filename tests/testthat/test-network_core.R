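test_that("neuron_distance is the Euclidean metric with unit-time meaning", {
  expect_equal(neuron_distance(c(0, 0, 0), c(0, 0, 1)), 1)
  expect_equal(neuron_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(neuron_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  # symmetry and triangle inequality on random triples
  set.seed(42)
  for (i in 1:25) {
    p <- matrix(sample(-10:10, 9, replace = TRUE), 3)
    d_ab <- neuron_distance(p[1, ], p[2, ])
    expect_equal(d_ab, neuron_distance(p[2, ], p[1, ]))
    expect_lte(neuron_distance(p[1, ], p[3, ]),
               d_ab + neuron_distance(p[2, ], p[3, ]) + 1e-12)
  }
  grid <- list(M = c(5, 5, 5), g = 1)
  expect_error(neuron_distance(c(0, 0, 0.5), c(0, 0, 1), grid), "off-grid")
  expect_error(neuron_distance(c(0, 0, 0), c(0, 0, 7), grid), "off-grid")
})

test_that("add_charge accumulates, clamps, and fires at threshold", {
  net <- chain_network(threshold = 0.5)
  net$neurons$charge[1] <- 0.3
  out <- add_charge(net, 1, 0.3, time = 5)
  expect_true(out$fired)
  expect_equal(out$new_charge, 0)            # charge resets to neutral
  expect_equal(out$network$neurons$last_fire[1], 5)

  # inside the refractory period the neuron keeps its charge but cannot fire
  net2 <- out$network
  net2$neurons$charge[1] <- 0.3
  out2 <- add_charge(net2, 1, 0.3, time = 5.5)
  expect_false(out2$fired)
  expect_equal(out2$new_charge, 0.6)

  # clamping at the bounds
  net3 <- chain_network(threshold = 0.5)
  net3$neurons$charge[1] <- 0.9
  net3$neurons$last_fire[1] <- 9.5           # refractory at t = 10
  out3 <- add_charge(net3, 1, 0.5, time = 10)
  expect_false(out3$fired)
  expect_equal(out3$new_charge, 1.0)
  net3$neurons$charge[1] <- -0.9
  out4 <- add_charge(net3, 1, -0.5, time = 10)
  expect_equal(out4$new_charge, -1.0)

  expect_error(add_charge(net, 99, 0.1), "unknown neuron")
  expect_error(add_charge(net, 1, NaN), "finite")
})

test_that("a tie at exact threshold equality fires", {
  net <- chain_network(threshold = 0.5)
  out <- add_charge(net, 1, 0.5, time = 0)
  expect_true(out$fired)
})

test_that("fire_neuron schedules one delayed arrival per outgoing synapse", {
  net <- new_network(
    neurons = data.frame(id = 1:3, x = c(0, 0, 0), y = c(0, 0, 0),
                         z = c(0, 1, 3), threshold = 0.5, refractory = 1),
    synapses = data.frame(pre = c(1, 1), post = c(2, 3),
                          weight = c(0.2, -0.4)),
    grid = list(M = c(5, 5, 5), g = 1))
  arr <- fire_neuron(net, 1, time = 10)
  expect_equal(arr$arrival_time, c(11, 13))
  expect_equal(arr$amount, c(0.2, -0.4))

  # no outgoing synapses -> empty schedule
  expect_equal(nrow(fire_neuron(net, 3, time = 0)), 0)

  # equal distances -> equal arrival times (no myelination)
  net2 <- new_network(
    neurons = data.frame(id = 1:3, x = c(0, 1, -1), y = 0, z = 0,
                         threshold = 0.5, refractory = 1),
    synapses = data.frame(pre = c(1, 1), post = c(2, 3), weight = 0.5),
    grid = list(M = c(5, 5, 5), g = 1))
  arr2 <- fire_neuron(net2, 1, time = 2)
  expect_equal(arr2$arrival_time[1], arr2$arrival_time[2])

  # firing inside the refractory period is a contract violation
  net$neurons$last_fire[1] <- 9.5
  expect_error(fire_neuron(net, 1, time = 10), "refractory")
})

test_that("network invariants are enforced", {
  expect_error(new_network(
    data.frame(id = 1:2, x = c(0, 0), y = c(0, 0), z = c(0, 0),
               threshold = 0.5, refractory = 1),
    data.frame(pre = 1, post = 2, weight = 0.1),
    grid = list(M = c(5, 5, 5), g = 1)), "share a position")
  expect_error(new_network(
    data.frame(id = 1, x = 0, y = 0, z = 0, threshold = 1.5,
               refractory = 1),
    data.frame(pre = integer(), post = integer(), weight = numeric()),
    grid = list(M = c(5, 5, 5), g = 1)), "thresholds")
  expect_error(new_network(
    data.frame(id = 1, x = 9, y = 0, z = 0, threshold = 0.5,
               refractory = 1),
    data.frame(pre = integer(), post = integer(), weight = numeric()),
    grid = list(M = c(5, 5, 5), g = 1)), "\\[-M, M\\)")
  expect_error(new_network(
    data.frame(id = 1:2, x = c(0, 1), y = 0, z = 0, threshold = 0.5,
               refractory = 1),
    data.frame(pre = 1, post = 7, weight = 0.1),
    grid = list(M = c(5, 5, 5), g = 1)), "endpoints")
})
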
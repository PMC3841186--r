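test_that("cart-pole dynamics: equilibrium, falling pole, mirror symmetry", {
  ph <- cartpole_physics()
  s0 <- cartpole_state()
  expect_equal(unclass(step_dynamics(s0, 0, ph)), unclass(s0))

  # a tilted pole under no force accelerates away from vertical; sign check
  # against the closed-form angular acceleration at theta = 0.05
  s <- cartpole_state(theta = 0.05)
  s1 <- step_dynamics(s, 0, ph)
  expect_gt(s1[["theta_dot"]], 0)
  m <- ph$m_cart + ph$m_pole
  th_dd <- (ph$gravity * sin(0.05)) /
    (ph$half_length * (4 / 3 - ph$m_pole * cos(0.05)^2 / m))
  expect_equal(s1[["theta_dot"]], ph$dt * th_dd)

  # mirror symmetry: negating (state, force) negates the next state
  set.seed(12)
  for (i in 1:20) {
    s <- cartpole_state(runif(1, -2, 2), runif(1, -1, 1),
                        runif(1, -0.2, 0.2), runif(1, -1, 1))
    f <- sample(c(-10, 0, 10), 1)
    a <- step_dynamics(s, f, ph)
    b <- step_dynamics(cartpole_state(-s[[1]], -s[[2]], -s[[3]], -s[[4]]),
                       -f, ph)
    expect_equal(unclass(b), -unclass(a), ignore_attr = TRUE)
  }
  expect_error(step_dynamics(s0, 5, ph), "force")
})

test_that("state encoding activates one input per variable, left-closed", {
  enc <- default_encoder()
  idx <- encode_state(cartpole_state(), enc)
  expect_equal(idx, c(2, 5, 8, 11))          # all-zero state: middle ranges
  expect_equal(length(unique((idx - 1) %/% 3)), 4)

  # boundary values belong to the interval they open
  expect_equal(encode_state(cartpole_state(x = -0.8), enc)[1], 2)
  expect_equal(encode_state(cartpole_state(x = 0.8), enc)[1], 3)
  expect_equal(encode_state(cartpole_state(x = -0.81), enc)[1], 1)
  expect_equal(encode_state(cartpole_state(theta = 0.05), enc)[3], 9)
  # any state activates exactly 4 of 12
  set.seed(13)
  for (i in 1:20) {
    s <- cartpole_state(runif(1, -3, 3), runif(1, -2, 2),
                        runif(1, -0.3, 0.3), runif(1, -2, 2))
    ii <- encode_state(s, enc)
    expect_equal(length(ii), 4)
    expect_true(all(ii >= 1 & ii <= 12))
  }
})

test_that("action decoding takes the majority output, with 0 N fallback", {
  expect_equal(decode_action(3, 7), 10)
  expect_equal(decode_action(7, 3), -10)
  expect_equal(decode_action(0, 0), 0)
  expect_equal(decode_action(5, 5), 0)
  expect_error(decode_action(-1, 0))
})

test_that("an episode with a silent network matches the pure-physics fall", {
  # genome whose output neurons can never fire: all weights zero
  g <- cartpole_genome(cartpole_gen_params(n_hidden = 6, n_synapses = 60),
                       seed = 14, d = 5)
  g$network$synapses$weight <- 0
  ph <- cartpole_physics()
  dur <- run_episode(g, affective = FALSE,
                     initial = cartpole_state(theta = 0.1),
                     max_time = 20, physics = ph)
  # oracle: integrate the physics alone under zero force until failure
  s <- cartpole_state(theta = 0.1)
  steps <- 0
  repeat {
    s <- step_dynamics(s, 0, ph)
    steps <- steps + 1
    if (abs(s[["x"]]) > ph$x_limit || abs(s[["theta"]]) > ph$theta_limit)
      break
  }
  expect_equal(dur, steps * ph$dt)
  expect_lt(dur, 20)
  expect_equal(run_episode(g, max_time = 0), 0)
})

test_that("episodes are deterministic and fitness averages six conditions", {
  g <- cartpole_genome(cartpole_gen_params(n_hidden = 6, n_synapses = 60),
                       seed = 15, d = 5)
  f1 <- fitness_six(g, max_time = 3)
  f2 <- fitness_six(g, max_time = 3)
  expect_identical(f1, f2)
  expect_true(f1 >= 0 && f1 <= 3)
  expect_equal(nrow(fitness_conditions()), 6)
  # arithmetic of the mean over per-condition caps
  expect_equal(mean(pmin(c(300, 300, 300, 0, 0, 0), 300)), 150)
})

test_that("the generalization grid covers 126 cells deterministically", {
  g <- cartpole_genome(cartpole_gen_params(n_hidden = 4, n_synapses = 30),
                       seed = 16, d = 3)
  g$network$synapses$weight <- 0   # silent network: episodes end quickly
  grid <- generalization_grid(g, seed = 17, n_per_cell = 2, max_time = 0.5)
  expect_equal(nrow(grid), 126)
  expect_equal(length(unique(grid$x_lo)), 21)
  expect_equal(length(unique(grid$theta_lo)), 6)
  expect_equal(max(grid$x_lo), 1.8)   # lower edges run -2.2 .. 1.8
  expect_equal(range(grid$theta_lo), c(-0.15, 0.10))
  grid2 <- generalization_grid(g, seed = 17, n_per_cell = 2, max_time = 0.5)
  expect_identical(grid, grid2)
  expect_true(all(grid$mean_time >= 0 & grid$mean_time <= 0.5))
})

test_that("affective operation during an episode only changes thresholds", {
  g <- cartpole_genome(cartpole_gen_params(n_hidden = 6, n_synapses = 80),
                       seed = 18, d = 10)
  a <- run_episode(g, affective = TRUE, max_time = 2)
  b <- run_episode(g, affective = FALSE, max_time = 2)
  expect_true(is.finite(a) && is.finite(b))  # same genome, both evaluable
})
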
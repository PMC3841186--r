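fake_trace <- function(times, rates) {
  structure(list(rates = data.frame(time = times, rate = rates,
                                    desired = NA, threshold = NA),
                 firings = data.frame(time = numeric())),
            class = "affect_trace")
}

test_that("settling time finds the first window that stays in band", {
  tr <- fake_trace(seq(10, 80, 10),
                   c(400, 340, 310, 300, 305, 295, 300, 300))
  expect_equal(settling_time(tr, 300, tol = 50), 20)  # time of the 340 entry
  # constant series settles at the first window
  expect_equal(settling_time(fake_trace(c(10, 20, 30), c(300, 300, 300)),
                             300), 10)
  # permanent oscillation beyond the band never settles
  osc <- fake_trace(seq(10, 100, 10), 300 + rep(c(100, -100), 5))
  expect_true(is.na(settling_time(osc, 300)))
  # brute-force scan oracle on random series
  set.seed(17)
  for (i in 1:20) {
    r <- 300 + round(runif(30, -120, 120))
    tt <- seq(10, 300, 10)
    got <- settling_time(fake_trace(tt, r), 300, tol = 50)
    ok <- abs(r - 300) <= 50
    exp_t <- NA_real_
    for (k in seq_along(ok)) if (all(ok[k:length(ok)])) { exp_t <- tt[k]; break }
    expect_identical(got, exp_t)
  }
})

test_that("percent overshoot is the max excess as a percent of desired", {
  expect_equal(percent_overshoot(fake_trace(1:3 * 10, c(200, 330, 300)),
                                 300), 10)
  expect_equal(percent_overshoot(fake_trace(1:3 * 10, c(100, 250, 300)),
                                 300), 0)
  expect_equal(percent_overshoot(fake_trace(1:3 * 10, c(100, 900, 600)),
                                 600), 50)
})

test_that("oscillation period averages spacing of upward crossings", {
  tt <- seq(10, 600, 10)
  r <- ifelse(tt %in% c(100, 300, 500), 350, 250)
  expect_equal(oscillation_period(fake_trace(tt, r), 300, tol = 10), 200)
  # monotone approach has no oscillation
  expect_true(is.na(oscillation_period(
    fake_trace(1:10 * 10, seq(100, 300, length.out = 10)), 300)))
  # synthetic sinusoid of period P sampled every w recovers P within one w
  w <- 10; P <- 173
  tt <- seq(w, 3000, w)
  r <- 300 + 100 * sin(2 * pi * tt / P)
  got <- oscillation_period(fake_trace(tt, r), 300, tol = 10)
  expect_lt(abs(got - P), w + 1e-9)
})

test_that("weight histogram uses 20 bins with a closed last bin", {
  h <- weight_histogram(c(-1, -0.95, 0, 0.95, 1))
  expect_equal(length(h), 20)
  expect_equal(sum(h), 5)
  expect_equal(unname(h[1]), 2)    # -1 and -0.95
  expect_equal(unname(h[20]), 2)   # 0.95 and the closed boundary 1.0
  expect_equal(unname(h[11]), 1)   # 0 lands in [0, 0.1)
  expect_error(weight_histogram(1.2), "\\[-1, 1\\]")
  # multinomial oracle at fixed seed: uniform weights spread ~500 per bin
  set.seed(23)
  w10k <- runif(10000, -1, 1)
  h2 <- weight_histogram(w10k)
  oracle <- table(cut(w10k, breaks = seq(-1, 1, 0.1),
                      include.lowest = TRUE, right = FALSE))
  expect_equal(unname(as.integer(oracle)), unname(as.integer(h2)))
  expect_true(all(abs(h2 - 500) < 5 * sqrt(500 * 0.95)))
})

test_that("a controller-free run keeps thresholds constant", {
  res <- run_rate_control(small_gen(), controller = NULL, t_end = 300,
                          seed = 3)
  expect_true(all(res$trace$rates$threshold == 0.5))
  expect_true(all(is.na(res$segments$settling_time)))
})

test_that("rate control settles a scaled-down network at a moderate setpoint", {
  # 200-neuron realization, setpoint 40/unit (20% of the ceiling, like the
  # full-scale d = 300 study condition), tolerance scaled in proportion
  res <- run_rate_control(small_gen(), affective_system(d = 40),
                          t_end = 3000, seed = 7, tol = 10)
  expect_false(is.na(res$segments$settling_time))
  r <- res$trace$rates
  late <- r$rate[r$time > 2500]
  expect_true(all(abs(late - 40) <= 10))
  expect_false(all(res$trace$rates$threshold == 0.5))  # controller acted
})

test_that("a two-segment schedule settles both segments", {
  sched <- data.frame(time = 1500, rate = 60)
  res <- run_rate_control(small_gen(), affective_system(d = 30),
                          d_schedule = sched, t_end = 3000, seed = 13,
                          tol = 10)
  expect_equal(nrow(res$segments), 2)
  expect_false(any(is.na(res$segments$settling_time)))
  expect_equal(res$segments$d, c(30, 60))
})

test_that("histogram snapshots are consistent with the synapse count", {
  res <- run_rate_control(small_gen(), affective_system(d = 40),
                          t_end = 1000, seed = 19, snapshot_every = 250)
  expect_equal(unname(colSums(res$trace$snapshots$hist)),
               rep(2000, length(res$trace$snapshots$time)))
  expect_equal(sum(res$final_histogram), 2000)
})
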
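#' Run a rate-control experiment
#'
#' Composes the generator, event engine, affective controller and plasticity
#' into the standard experiment: generate a seeded random network, drive its
#' input neuron with exponentially distributed pulses, and let the affective
#' system adjust thresholds every window.  A desired-rate schedule splits the
#' run into segments; settling time, percent overshoot and oscillation period
#' are computed per segment.
#'
#' @param gen a [generation_params()] object.
#' @param controller an [affective_system()] (or `NULL` for a control run
#'   with constant thresholds).
#' @param d_schedule optional data frame `(time, rate)` of desired-rate
#'   changes after the start (times must precede `t_end`).
#' @param t_end total simulated time (default 10000).
#' @param seed integer seed fixing the network realization and pulse train.
#' @param plasticity apply LTP/LTD (default TRUE).
#' @param pulse_rate mean input pulses per unit time (default 0.1).
#' @param snapshot_every cadence of weight-histogram snapshots (0 = off).
#' @param tol settling tolerance in firings per unit time (default 50).
#' @return list of class `rate_control_result`: the `trace`, a `segments`
#'   data frame (start, end, d, settling_time, percent_overshoot,
#'   oscillation_period), `final_threshold` and `final_histogram`.
#' @export
run_rate_control <- function(gen = generation_params(),
                             controller = affective_system(d = 300),
                             d_schedule = NULL, t_end = 10000, seed = 1,
                             plasticity = TRUE, pulse_rate = 0.1,
                             snapshot_every = 0, tol = 50) {
  net <- generate_network(gen, seed = seed)
  pulses <- input_pulse_times(pulse_rate, t_end)
  trace <- simulate_network(net, t_end, pulses = pulses,
                            controller = controller,
                            d_schedule = d_schedule,
                            plasticity = plasticity,
                            snapshot_every = snapshot_every)
  starts <- 0
  ds <- if (is.null(controller)) NA_real_ else controller$d
  if (!is.null(d_schedule) && nrow(d_schedule) > 0) {
    starts <- c(0, d_schedule$time)
    ds <- c(ds, d_schedule$rate)
  }
  ends <- c(starts[-1], t_end)
  segs <- data.frame(start = starts, end = ends, d = ds,
                     settling_time = NA_real_,
                     percent_overshoot = NA_real_,
                     oscillation_period = NA_real_)
  if (!is.null(controller)) {
    for (i in seq_len(nrow(segs))) {
      segs$settling_time[i] <- settling_time(trace, segs$d[i], tol = tol,
                                             start = segs$start[i],
                                             end = segs$end[i])
      segs$percent_overshoot[i] <- percent_overshoot(trace, segs$d[i],
                                                     start = segs$start[i],
                                                     end = segs$end[i])
      segs$oscillation_period[i] <- oscillation_period(trace, segs$d[i],
                                                       start = segs$start[i],
                                                       end = segs$end[i])
    }
  }
  structure(list(trace = trace, segments = segs,
                 final_threshold = mean(trace$network$neurons$threshold),
                 final_histogram =
                   weight_histogram(trace$network$synapses$weight)),
            class = "rate_control_result")
}

seg_rates <- function(trace, start, end) {
  r <- trace$rates
  r[r$time > start & r$time <= end, , drop = FALSE]
}

#' Settling time of a rate-control segment
#'
#' The time required to achieve the desired firing rate and remain within
#' `tol` units of it: the earliest window-end time from which every
#' subsequent window measurement in the segment satisfies
#' `|rate - d| <= tol`.  Returns `NA` ("unsettled") if no such time exists.
#'
#' @param trace an `affect_trace` (its `rates` series is used).
#' @param d desired firing rate of the segment.
#' @param tol tolerance in firings per unit time (default 50).
#' @param start,end segment boundaries (defaults: the whole trace).
#' @return settling time, or `NA_real_` if the segment never settles.
#' @export
settling_time <- function(trace, d, tol = 50, start = 0, end = Inf) {
  r <- seg_rates(trace, start, end)
  if (nrow(r) == 0) stop("trace has no rate measurements in the segment")
  ok <- abs(r$rate - d) <= tol
  bad <- which(!ok)
  first <- if (length(bad) == 0) 1L else max(bad) + 1L
  if (first > nrow(r)) return(NA_real_)
  r$time[first]
}

#' Percent overshoot of a rate-control segment
#'
#' How high above the desired firing rate the recorded rate climbs, as a
#' percentage of the desired rate: `100 * (max rate - d) / d`, floored at 0
#' when the rate never exceeds the setpoint.
#'
#' @inheritParams settling_time
#' @return overshoot percentage (>= 0).
#' @export
percent_overshoot <- function(trace, d, start = 0, end = Inf) {
  r <- seg_rates(trace, start, end)
  if (nrow(r) == 0) stop("trace has no rate measurements in the segment")
  max(0, 100 * (max(r$rate) - d) / d)
}

#' Oscillation period before settling
#'
#' Mean spacing between successive upward crossings of the rate series
#' through the setpoint `d`, restricted to measurements before the segment's
#' settling time.  Returns `NA` ("no oscillation") with fewer than two
#' upward crossings.
#'
#' @inheritParams settling_time
#' @return mean period, or `NA_real_`.
#' @export
oscillation_period <- function(trace, d, tol = 50, start = 0, end = Inf) {
  r <- seg_rates(trace, start, end)
  if (nrow(r) < 2) return(NA_real_)
  st <- settling_time(trace, d, tol = tol, start = start, end = end)
  if (!is.na(st)) r <- r[r$time <= st, , drop = FALSE]
  if (nrow(r) < 2) return(NA_real_)
  below <- r$rate < d
  up <- which(below[-nrow(r)] & !below[-1]) + 1L
  if (length(up) < 2) return(NA_real_)
  mean(diff(r$time[up]))
}

#' Histogram of synapse weights over 20 bins
#'
#' Bins `[x, x + 0.1)` for `x = -1.0, -0.9, ..., 0.8`, with the last bin
#' `[0.9, 1.0]` closed so that a weight of exactly 1 is counted.
#'
#' @param weights numeric vector of weights in `[-1, 1]`.
#' @return named integer vector of 20 bin counts.
#' @export
weight_histogram <- function(weights) {
  if (any(!is.finite(weights)) || any(weights < -1 | weights > 1))
    stop("weights must lie in [-1, 1]")
  b <- floor((weights + 1) * 10 + 1e-9)
  b <- pmin(pmax(b, 0), 19) + 1
  counts <- tabulate(b, nbins = 20)
  lo <- seq(-1, 0.9, by = 0.1)
  names(counts) <- sprintf("[%.1f,%.1f%s", lo, lo + 0.1,
                           c(rep(")", 19), "]"))
  counts
}

#' Sweep controller gains over a fixed network and pulse train
#'
#' Re-runs one seeded rate-control experiment for each `(alpha, lambda)`
#' pair and tabulates settling time, percent overshoot and oscillation
#' period — the summaries used to study how the gain and decay rate shape
#' the transient.
#'
#' @param gen a [generation_params()] object.
#' @param d desired firing rate.
#' @param alphas,lambdas numeric vectors of gains and decay rates.
#' @param t_end simulated time per run.
#' @param seed seed shared by every run (same network, same pulses).
#' @param plasticity apply LTP/LTD.
#' @return data frame with one row per parameter pair.
#' @export
sweep_controller <- function(gen = generation_params(), d = 300,
                             alphas = c(0.0005, 0.001, 0.002),
                             lambdas = c(0, 0.9), t_end = 10000, seed = 1,
                             plasticity = TRUE) {
  grid <- expand.grid(alpha = alphas, lambda = lambdas)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    type <- if (grid$lambda[i] > 0) "complex" else "simple"
    ctrl <- affective_system(d = d, alpha = grid$alpha[i],
                             lambda = grid$lambda[i], type = type)
    res <- run_rate_control(gen, ctrl, t_end = t_end, seed = seed,
                            plasticity = plasticity)
    cbind(grid[i, , drop = FALSE], res$segments[1, c("settling_time",
      "percent_overshoot", "oscillation_period")])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.rate_control_result <- function(x, ...) {
  cat("<rate_control_result>\n")
  print(x$segments, row.names = FALSE)
  cat("final mean threshold:", format(x$final_threshold, digits = 4), "\n")
  invisible(x)
}
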
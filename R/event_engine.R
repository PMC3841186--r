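#' Create an empty event queue
#'
#' Events are ordered by time; events scheduled for the same time are
#' processed in insertion order (a monotone sequence number breaks ties).
#' The queue underlies the discrete-event simulation loop and is exposed
#' directly for inspection and testing.
#'
#' @return an object of class `event_queue`.
#' @export
event_queue <- function() {
  q <- new.env(parent = emptyenv())
  q$ptr <- eq_create()
  q$payloads <- list()
  q$n_pushed <- 0L
  q$current_time <- 0
  class(q) <- "event_queue"
  q
}

#' Schedule an event
#'
#' @param queue an [event_queue()].
#' @param time event time; scheduling before the time of the last popped
#'   event is an error (no scheduling into the past).
#' @param type event tag, one of `"charge_addition"`, `"neuron_fire"`,
#'   `"threshold_adjustment"`, `"input_pulse"`, `"desired_rate_change"`,
#'   `"output_observation"`.
#' @param payload arbitrary type-specific record.
#' @return the queue, invisibly.
#' @export
schedule_event <- function(queue, time, type, payload = NULL) {
  stopifnot(inherits(queue, "event_queue"))
  types <- c("charge_addition", "neuron_fire", "threshold_adjustment",
             "input_pulse", "desired_rate_change", "output_observation")
  if (!type %in% types) stop("unknown event type: ", type)
  if (!is.numeric(time) || !is.finite(time) || time < 0)
    stop("event time must be a finite nonnegative number")
  if (time < queue$current_time)
    stop("cannot schedule an event into the past (t = ", time,
         " < current time ", queue$current_time, ")")
  queue$n_pushed <- queue$n_pushed + 1L
  queue$payloads[[queue$n_pushed]] <-
    list(time = time, type = type, payload = payload)
  eq_push(queue$ptr, time, queue$n_pushed)
  invisible(queue)
}

#' Pop the next event
#'
#' @param queue an [event_queue()].
#' @return the earliest scheduled event (a list with `time`, `type`,
#'   `payload`), or `NULL` when the queue is exhausted.
#' @export
pop_event <- function(queue) {
  stopifnot(inherits(queue, "event_queue"))
  res <- eq_pop(queue$ptr)
  if (isTRUE(res$exhausted)) return(NULL)
  queue$current_time <- res$time
  queue$payloads[[res$id]]
}

#' @export
length.event_queue <- function(x) eq_size(x$ptr)

sim_from_network <- function(net, controller = NULL, plasticity = TRUE,
                             rate_window = 10, pulse_amplitude = 1.0) {
  mode <- 0L
  alpha <- 0; lambda <- 0; d0 <- 0
  w <- rate_window
  if (!is.null(controller)) {
    stopifnot(inherits(controller, "affective_system"))
    mode <- if (controller$type == "simple") 1L else 2L
    alpha <- controller$alpha
    lambda <- controller$lambda
    w <- controller$window
    d0 <- controller$d
  }
  sim_create(net$neurons$threshold, net$neurons$refractory,
             as.integer(net$synapses$pre) - 1L,
             as.integer(net$synapses$post) - 1L,
             net$synapses$weight, net$synapses$distance,
             isTRUE(plasticity), net$plasticity$step,
             net$plasticity$refractory,
             mode, alpha, lambda, w, d0, pulse_amplitude)
}

collect_trace <- function(res, net, window, controller) {
  nsnap <- length(res$snapshot_time)
  structure(list(
    firings = data.frame(time = res$firing_time,
                         neuron = res$firing_neuron + 1L),
    rates = data.frame(time = res$tick_time,
                       rate = res$tick_rate,
                       desired = res$tick_desired,
                       threshold = res$tick_threshold),
    snapshots = if (nsnap > 0)
      list(time = res$snapshot_time, hist = res$snapshot_hist) else NULL,
    window = window,
    events_processed = res$events_processed,
    network = net,
    controller = controller
  ), class = "affect_trace")
}

#' Run a discrete-event simulation
#'
#' Processes the event queue in time order up to `t_end`.  Input pulses
#' deliver `+1` of charge (clamped) to their target neuron; each firing
#' schedules a charge arrival on every outgoing synapse after a delay equal
#' to the synapse distance; every `window` time units a measurement tick
#' counts firings in the elapsed window and — when a controller is supplied —
#' broadcasts the proportional threshold change.  Desired-rate change events
#' update the controller setpoint.  Simultaneous events are processed in
#' insertion order, with measurement ticks ordered after same-time charge
#' events so that a window covers the half-open interval `(t - w, t]`.
#'
#' @param net an `affect_network`.
#' @param t_end simulation end time (> 0).
#' @param pulses input pulse times: a numeric vector (delivered to the
#'   network's input neuron) or a data frame with columns `time`, `neuron`.
#' @param controller optional [affective_system()].
#' @param d_schedule optional data frame `(time, rate)` of desired-rate
#'   change events.
#' @param plasticity logical: apply LTP/LTD during the run?
#' @param snapshot_every if positive, record a 20-bin weight histogram every
#'   that many time units.
#' @param rate_window window used for the firing-rate series when no
#'   controller is present (a controller's own window takes precedence).
#' @return an `affect_trace`: `firings` (time, neuron), `rates` (time, rate,
#'   desired, threshold), optional `snapshots`, and the final `network`
#'   (updated thresholds, charges and weights).
#' @export
simulate_network <- function(net, t_end, pulses = numeric(),
                             controller = NULL, d_schedule = NULL,
                             plasticity = TRUE, snapshot_every = 0,
                             rate_window = 10) {
  stopifnot(inherits(net, "affect_network"), t_end > 0)
  if (is.data.frame(pulses)) {
    pt <- pulses$time
    pn <- as.integer(pulses$neuron)
  } else {
    pt <- as.numeric(pulses)
    inp <- which(net$neurons$is_input)
    if (length(pt) > 0 && length(inp) == 0)
      stop("network has no input neuron to receive pulses")
    pn <- rep(inp[1], length(pt))
  }
  if (any(pt < 0)) stop("input pulse times must be nonnegative")
  dt <- numeric(); dv <- numeric()
  if (!is.null(d_schedule)) {
    dt <- d_schedule$time
    dv <- d_schedule$rate
    if (any(dt >= t_end)) stop("d_schedule times must precede t_end")
  }
  w <- if (!is.null(controller)) controller$window else rate_window
  ptr <- sim_from_network(net, controller, plasticity, rate_window = w)
  res <- sim_run(ptr, t_end, pt, pn - 1L, dt, dv, snapshot_every)
  st <- sim_state(ptr)
  net$neurons$threshold <- st$threshold
  net$neurons$charge <- st$charge
  net$neurons$last_fire <- ifelse(is.finite(st$last_fire), st$last_fire,
                                  NA_real_)
  if (nrow(net$synapses) > 0) net$synapses$weight <- st$weight
  collect_trace(res, net, w, controller)
}

#' Measured firing rate over a window
#'
#' Counts network firing events with time in the half-open window
#' `(t - w, t]`.
#'
#' @param trace an `affect_trace` (or a data frame with a `time` column of
#'   firing times).
#' @param t window end time, >= `w`.
#' @param w window length.
#' @return nonnegative integer count.
#' @export
measured_firing_rate <- function(trace, t, w) {
  if (t < w) stop("window end time must be at least the window length")
  times <- if (inherits(trace, "affect_trace")) trace$firings$time
           else trace$time
  sum(times > t - w & times <= t)
}

#' @export
print.affect_trace <- function(x, ...) {
  cat("<affect_trace> ", nrow(x$firings), " firings, ",
      nrow(x$rates), " rate windows (w = ", x$window, ")\n", sep = "")
  if (nrow(x$rates) > 0) {
    tail_n <- min(5, nrow(x$rates))
    cat("  final windows:\n")
    print(utils::tail(x$rates, tail_n), row.names = FALSE)
  }
  invisible(x)
}
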
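#' Define an affective (rate-control) system
#'
#' The affective system plays the role of a neuromodulatory feedback loop: it
#' measures the network firing rate `f` — the number of firings in a window
#' of `window` simulation-time units divided by the window length, so `f` is
#' in firings per unit time and cannot exceed the neuron count (each neuron
#' fires at most once per time unit with the default refractory period of
#' one) — compares it with the desired firing rate `d`, and broadcasts a
#' threshold change to every neuron.  Two variants exist:
#'
#' * **simple** — the threshold change is proportional to the instantaneous
#'   error, `delta = alpha * e(t)` with `e(t) = f(t) - d(t)`;
#' * **complex** — the error is first smoothed by a geometric (exponential)
#'   average, `ebar(t) = lambda * ebar(t - w) + (1 - lambda) * e(t)`, and
#'   `delta = alpha * ebar(t)`.
#'
#' The two variants coincide when `lambda = 0`.  Positive error (firing above
#' desire) raises thresholds, making neurons less likely to fire.
#'
#' @param d desired firing rate, in firings per unit time.
#' @param alpha proportional gain (default 0.001: the rate error is bounded
#'   by the neuron count, 1000 for the default network, so this bounds
#'   single-step threshold changes to magnitude one).
#' @param lambda decay rate of the geometric error average, in `[0, 1)`.
#' @param window window length between threshold adjustments (default 10).
#' @param type `"simple"` or `"complex"`.
#' @return list of class `affective_system`.
#' @export
affective_system <- function(d, alpha = 0.001, lambda = 0, window = 10,
                             type = c("simple", "complex")) {
  type <- match.arg(type)
  if (!is.numeric(d) || length(d) != 1 || d < 0)
    stop("d must be a nonnegative scalar")
  if (lambda < 0 || lambda >= 1) stop("lambda must lie in [0, 1)")
  if (window <= 0) stop("window must be positive")
  structure(list(d = d, alpha = alpha, lambda = lambda, window = window,
                 type = type, smoothed_error = 0),
            class = "affective_system")
}

#' Firing-rate error
#'
#' The error between the measured network firing rate `f` over a window and
#' the desired rate `d`: `e = f - d`.  The sign convention makes the error
#' positive when the network fires more than desired, so the proportional
#' threshold change raises thresholds to suppress firing.
#'
#' @param f measured firing rate (firings per unit time), >= 0.
#' @param d desired firing rate.
#' @return the signed error.
#' @export
firing_rate_error <- function(f, d) {
  if (any(f < 0)) stop("measured rate must be nonnegative")
  f - d
}

#' Geometrically averaged error
#'
#' One step of the exponential error average used by the complex affective
#' system: `ebar' = lambda * prev + (1 - lambda) * e`.  `lambda` controls how
#' much errors from earlier windows influence the present threshold change;
#' `lambda = 0` reduces to the instantaneous error.
#'
#' @param prev previous smoothed error (0 at the start of a simulation).
#' @param e current error from [firing_rate_error()].
#' @param lambda decay rate in `[0, 1)`.
#' @return the updated smoothed error.
#' @export
smoothed_error <- function(prev, e, lambda) {
  if (lambda < 0 || lambda >= 1) stop("lambda must lie in [0, 1)")
  lambda * prev + (1 - lambda) * e
}

#' Proportional threshold change
#'
#' `delta = alpha * err`, where `err` is the instantaneous error (simple
#' system) or the geometrically averaged error (complex system).
#'
#' @param err error term.
#' @param alpha proportional gain.
#' @return the network-wide threshold change.
#' @export
threshold_delta <- function(err, alpha) {
  alpha * err
}

#' Broadcast a threshold change to every neuron
#'
#' Adds `delta` to each neuron's threshold.  Thresholds are bounded to
#' `[-1, 1]`; the change has no effect on a neuron for which it would violate
#' either bound (that neuron's threshold is left unchanged, not clipped).
#' When all neurons share one threshold — as in the rate-control experiments,
#' where every threshold starts at 0.5 — they all remain identical.
#'
#' @param net an `affect_network`.
#' @param delta threshold change from [threshold_delta()].
#' @return the updated network.
#' @export
apply_threshold_change <- function(net, delta) {
  th <- net$neurons$threshold + delta
  ok <- th >= -1 & th <= 1
  net$neurons$threshold[ok] <- th[ok]
  net
}
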
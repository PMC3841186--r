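#' Plasticity parameters
#'
#' LTP and LTD change a synapse weight by a fixed step: up when charge
#' carried by the synapse causes the postsynaptic neuron to fire (LTP), down
#' when the charge arrives during the postsynaptic refractory period (LTD).
#' Each synapse has a single plasticity refractory clock shared by LTP and
#' LTD, which prevents weight changes from occurring too rapidly.
#'
#' @param step weight increment, > 0 (default 0.001).
#' @param refractory minimum simulation time between accepted weight changes
#'   on one synapse (default 10).
#' @return list of class `plasticity_params`.
#' @export
plasticity_params <- function(step = 0.001, refractory = 10) {
  if (!is.numeric(step) || step <= 0) stop("step must be > 0")
  if (!is.numeric(refractory) || refractory < 0)
    stop("refractory must be >= 0")
  structure(list(step = step, refractory = refractory),
            class = "plasticity_params")
}

plasticity_eligible <- function(synapse, time, params) {
  is.na(synapse$last_plasticity) ||
    (time - synapse$last_plasticity) >= params$refractory
}

apply_plasticity <- function(synapse, time, params, direction) {
  if (plasticity_eligible(synapse, time, params)) {
    synapse$weight <- clamp_unit(synapse$weight + direction * params$step)
    synapse$last_plasticity <- time
  }
  synapse
}

#' Long-term potentiation of a synapse
#'
#' Applied when the charge arrival carried by this synapse is the one that
#' pushed the postsynaptic neuron over threshold.  The weight increases by
#' `params$step`, clamped to 1, unless the synapse is still inside its
#' plasticity refractory period, in which case nothing changes.
#'
#' @param synapse list or one-row data frame with fields `weight` and
#'   `last_plasticity` (`NA` if the weight has never changed).
#' @param time time of the triggering charge arrival.
#' @param params a [plasticity_params()] object.
#' @return the updated synapse record.
#' @export
apply_ltp <- function(synapse, time, params = plasticity_params()) {
  apply_plasticity(synapse, time, params, +1)
}

#' Long-term depression of a synapse
#'
#' Applied when charge carried by this synapse arrives while the postsynaptic
#' neuron is inside its refractory period.  The weight decreases by
#' `params$step`, clamped to -1, under the same per-synapse refractory gating
#' as [apply_ltp()] (LTP and LTD share one clock).
#'
#' @inheritParams apply_ltp
#' @return the updated synapse record.
#' @export
apply_ltd <- function(synapse, time, params = plasticity_params()) {
  apply_plasticity(synapse, time, params, -1)
}
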
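#' @useDynLib affectnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rexp
#' @importFrom utils head modifyList
NULL

clamp_unit <- function(x) pmin(1, pmax(-1, x))

#' Construct a spiking network model
#'
#' A network is a set of integrate-and-fire neurons placed on a discrete
#' three-dimensional grid, connected by directed, weighted synapses.  Charge
#' travels along a synapse at one grid unit per unit of simulation time, so a
#' synapse's propagation delay equals the Euclidean distance between its
#' endpoint neurons.  Charge and threshold values are bounded to `[-1, 1]`.
#'
#' @param neurons data frame with columns `id` (1..n), `x`, `y`, `z` (grid
#'   coordinates, integral multiples of the granularity), `threshold`,
#'   `refractory` (simulation-time units), `is_input`, `is_output` (logical).
#'   Optional columns `charge` (default 0) and `last_fire` (default `NA`,
#'   meaning the neuron has never fired).
#' @param synapses data frame with columns `pre`, `post` (neuron ids) and
#'   `weight` in `[-1, 1]`.  `distance` is computed from neuron positions if
#'   absent.
#' @param grid list with `M` (three positive axis magnitudes; coordinates lie
#'   in `[-M, M)`) and granularity `g`.
#' @param plasticity list with `step` (weight increment for LTP/LTD) and
#'   `refractory` (minimum time between weight changes on one synapse).
#' @return An object of class `affect_network`.
#' @export
new_network <- function(neurons, synapses,
                        grid = list(M = c(100, 100, 100), g = 1),
                        plasticity = list(step = 0.001, refractory = 10)) {
  neurons <- as.data.frame(neurons)
  synapses <- as.data.frame(synapses)
  if (is.null(neurons$charge)) neurons$charge <- 0
  if (is.null(neurons$last_fire)) neurons$last_fire <- NA_real_
  if (is.null(neurons$is_input)) neurons$is_input <- FALSE
  if (is.null(neurons$is_output)) neurons$is_output <- FALSE
  if (nrow(synapses) > 0 &&
      (any(synapses$pre < 1) || any(synapses$pre > nrow(neurons)) ||
       any(synapses$post < 1) || any(synapses$post > nrow(neurons))))
    stop("synapse endpoints must reference existing neurons")
  if (nrow(synapses) > 0 && is.null(synapses$distance)) {
    pos <- as.matrix(neurons[, c("x", "y", "z")])
    synapses$distance <- sqrt(rowSums(
      (pos[synapses$pre, , drop = FALSE] - pos[synapses$post, , drop = FALSE])^2))
  }
  if (nrow(synapses) > 0 && is.null(synapses$last_plasticity))
    synapses$last_plasticity <- NA_real_
  net <- structure(list(neurons = neurons, synapses = synapses,
                        grid = grid, plasticity = plasticity),
                   class = "affect_network")
  validate_network(net)
  net
}

#' Validate network invariants
#'
#' Checks that all charges, thresholds and weights lie in `[-1, 1]`, that no
#' two neurons share a grid position, that every position is an on-grid
#' integral multiple of the granularity inside the axis bounds, that synapse
#' endpoints reference existing neurons, and that stored synapse distances
#' match the geometry of their endpoints.
#'
#' @param net an `affect_network`.
#' @return `net`, invisibly; errors describe the first violated invariant.
#' @export
validate_network <- function(net) {
  nn <- net$neurons
  sy <- net$synapses
  g <- net$grid$g
  M <- net$grid$M
  if (!identical(as.integer(nn$id), seq_len(nrow(nn))))
    stop("neuron ids must be 1..n in order")
  pos <- as.matrix(nn[, c("x", "y", "z")])
  if (any(abs(pos / g - round(pos / g)) > 1e-9))
    stop("neuron coordinates must be integral multiples of the granularity")
  if (any(pos < -rep(M, each = nrow(pos))) ||
      any(pos >= rep(M, each = nrow(pos))))
    stop("neuron coordinates must lie in [-M, M) on each axis")
  if (anyDuplicated(pos))
    stop("no two neurons may share a position")
  if (any(nn$threshold < -1 | nn$threshold > 1))
    stop("thresholds must lie in [-1, 1]")
  if (any(nn$charge < -1 | nn$charge > 1))
    stop("charges must lie in [-1, 1]")
  if (any(nn$refractory < 0))
    stop("refractory periods must be nonnegative")
  if (nrow(sy) > 0) {
    if (any(sy$pre < 1 | sy$pre > nrow(nn) | sy$post < 1 | sy$post > nrow(nn)))
      stop("synapse endpoints must reference existing neurons")
    if (any(sy$weight < -1 | sy$weight > 1))
      stop("synapse weights must lie in [-1, 1]")
    d <- sqrt(rowSums((pos[sy$pre, , drop = FALSE] -
                         pos[sy$post, , drop = FALSE])^2))
    if (any(abs(d - sy$distance) > 1e-8))
      stop("synapse distances must equal the distance between their endpoints")
  }
  invisible(net)
}

#' Euclidean distance between two grid positions
#'
#' Simulation time is defined by charge propagation: charge covers one grid
#' unit per unit of time, so this distance is also the synaptic delay between
#' neurons at the two positions.
#'
#' @param a,b numeric 3-vectors of grid coordinates.
#' @param grid optional grid definition; when supplied, both positions are
#'   checked to be on-grid.
#' @return nonnegative scalar distance.
#' @export
#' @examples
#' neuron_distance(c(0, 0, 0), c(0, 0, 1))  # one unit of simulation time
neuron_distance <- function(a, b, grid = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3 || length(b) != 3 || !all(is.finite(c(a, b))))
    stop("positions must be finite 3-vectors")
  if (!is.null(grid)) {
    for (p in list(a, b)) {
      if (any(abs(p / grid$g - round(p / grid$g)) > 1e-9) ||
          any(p < -grid$M) || any(p >= grid$M))
        stop("position is off-grid")
    }
  }
  sqrt(sum((a - b)^2))
}

is_refractory <- function(last_fire, refractory, time) {
  !is.na(last_fire) && (time - last_fire) < refractory
}

#' Add charge to a neuron
#'
#' Charge is accumulated (and clamped to `[-1, 1]`) until the neuron's
#' threshold is reached.  If the clamped charge reaches the threshold and the
#' neuron is outside its refractory period, the neuron fires: its charge is
#' reset to zero and its firing time recorded.  During the refractory period
#' the neuron accumulates charge but cannot fire.
#'
#' @param net an `affect_network`.
#' @param id neuron id.
#' @param amount finite charge increment (may be negative).
#' @param time current simulation time.
#' @return list with `fired` (logical), `new_charge` and the updated
#'   `network`.
#' @export
add_charge <- function(net, id, amount, time = 0) {
  if (!is.numeric(id) || length(id) != 1 || is.na(id) ||
      id < 1 || id > nrow(net$neurons))
    stop("unknown neuron id: ", id)
  if (!is.finite(amount)) stop("charge amount must be finite")
  nn <- net$neurons
  ch <- clamp_unit(nn$charge[id] + amount)
  refr <- is_refractory(nn$last_fire[id], nn$refractory[id], time)
  fired <- !refr && ch >= nn$threshold[id]
  if (fired) {
    nn$charge[id] <- 0
    nn$last_fire[id] <- time
  } else {
    nn$charge[id] <- ch
  }
  net$neurons <- nn
  list(fired = fired, new_charge = nn$charge[id], network = net)
}

#' Enumerate the charge arrivals caused by a firing
#'
#' When a neuron fires, one unit of its outgoing weight is dispatched along
#' each outgoing synapse; the charge arrives after a delay equal to the
#' synapse distance (charge travels one grid unit per unit time, with no
#' myelination).
#'
#' @param net an `affect_network`.
#' @param id the firing neuron; it must be outside its refractory period at
#'   `time` (firing inside the refractory period is a contract violation).
#' @param time firing time.
#' @return data frame with one row per outgoing synapse: `post`,
#'   `arrival_time` (= `time` + distance) and `amount` (= synapse weight).
#' @export
fire_neuron <- function(net, id, time = 0) {
  if (id < 1 || id > nrow(net$neurons)) stop("unknown neuron id: ", id)
  nn <- net$neurons
  if (is_refractory(nn$last_fire[id], nn$refractory[id], time) &&
      !isTRUE(all.equal(nn$last_fire[id], time)))
    stop("neuron ", id, " is inside its refractory period at time ", time)
  out <- net$synapses[net$synapses$pre == id, , drop = FALSE]
  data.frame(post = out$post,
             arrival_time = time + out$distance,
             amount = out$weight)
}

#' @export
print.affect_network <- function(x, ...) {
  cat("<affect_network> ", nrow(x$neurons), " neurons, ",
      nrow(x$synapses), " synapses\n", sep = "")
  cat("  grid: M = (", paste(x$grid$M, collapse = ", "),
      "), granularity ", x$grid$g, "\n", sep = "")
  cat("  inputs: ", sum(x$neurons$is_input),
      ", outputs: ", sum(x$neurons$is_output), "\n", sep = "")
  cat("  threshold range: [", min(x$neurons$threshold), ", ",
      max(x$neurons$threshold), "]\n", sep = "")
  invisible(x)
}
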
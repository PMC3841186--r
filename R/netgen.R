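#' Parameters for random network generation
#'
#' The default realization matches the rate-control study conditions: 1000
#' neurons at distinct uniformly random sites of a 200 x 200 x 200 grid
#' (coordinates integral in `[-100, 100)`), 10000 directed synapses placed
#' with higher likelihood between spatially close neurons, initial threshold
#' 0.5 for every neuron, refractory period 1, and synapse weights i.i.d.
#' uniform on `[-1, 1]`.
#'
#' @param n_neurons number of neurons (default 1000).
#' @param n_synapses number of distinct directed synapses (default 10000).
#' @param grid grid definition (`M`, `g`); default 200 sites per axis.
#' @param threshold initial threshold shared by every neuron (default 0.5).
#' @param refractory neuron refractory period (default 1).
#' @param tau proximity scale of synapse placement: a directed pair `(i, j)`
#'   is sampled with probability proportional to `exp(-dist(i, j) / tau)`
#'   (default 20 grid units).
#' @param n_inputs number of input neurons, chosen uniformly at random
#'   (default 1).
#' @param n_outputs number of output neurons (default 0).
#' @param plasticity [plasticity_params()] stored with the network.
#' @return list of class `generation_params`.
#' @export
generation_params <- function(n_neurons = 1000, n_synapses = 10000,
                              grid = list(M = c(100, 100, 100), g = 1),
                              threshold = 0.5, refractory = 1, tau = 20,
                              n_inputs = 1, n_outputs = 0,
                              plasticity = plasticity_params()) {
  sites <- prod(2 * grid$M / grid$g)
  if (n_neurons > sites)
    stop("n_neurons exceeds the number of grid sites (", sites, ")")
  if (n_synapses > n_neurons * (n_neurons - 1))
    stop("n_synapses exceeds the number of distinct directed pairs")
  structure(list(n_neurons = n_neurons, n_synapses = n_synapses, grid = grid,
                 threshold = threshold, refractory = refractory, tau = tau,
                 n_inputs = n_inputs, n_outputs = n_outputs,
                 plasticity = plasticity),
            class = "generation_params")
}

#' Generate a random network realization
#'
#' Neuron positions are sampled uniformly without replacement from the grid
#' sites.  Synapses are distinct directed pairs `(i, j)`, `i != j`, sampled
#' without replacement with probability proportional to
#' `exp(-dist(i, j) / tau)`, so spatially close neurons are more likely to be
#' connected (sampling uses exponential keys, which realizes the weighted
#' draw without enumerating an acceptance loop).  Self-synapses and duplicate
#' directed pairs are excluded.  Weights are i.i.d. uniform on `[-1, 1]`.
#'
#' @param params a [generation_params()] object.
#' @param seed optional integer seed fixing all randomness.
#' @return a validated `affect_network`.
#' @export
generate_network <- function(params = generation_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_neurons
  g <- params$grid$g
  M <- params$grid$M
  per_axis <- as.integer(round(2 * M / g))

  site <- sample(prod(per_axis), n) - 1
  ix <- site %% per_axis[1]
  iy <- (site %/% per_axis[1]) %% per_axis[2]
  iz <- site %/% (per_axis[1] * per_axis[2])
  pos <- cbind(x = ix * g - M[1], y = iy * g - M[2], z = iz * g - M[3])

  m <- params$n_synapses
  dmat <- as.matrix(stats::dist(pos))
  logp <- -dmat / params$tau
  # weighted sampling without replacement: smallest exponential keys win
  keys <- matrix(rexp(n * n), n, n) / exp(logp)
  diag(keys) <- Inf
  picked <- order(keys)[seq_len(m)]
  pre <- ((picked - 1) %% n) + 1
  post <- ((picked - 1) %/% n) + 1

  inputs <- if (params$n_inputs > 0) sample(n, params$n_inputs) else integer()
  remaining <- setdiff(seq_len(n), inputs)
  outputs <- if (params$n_outputs > 0)
    remaining[sample(length(remaining), params$n_outputs)] else integer()

  neurons <- data.frame(id = seq_len(n), x = pos[, 1], y = pos[, 2],
                        z = pos[, 3], threshold = params$threshold,
                        refractory = params$refractory,
                        is_input = seq_len(n) %in% inputs,
                        is_output = seq_len(n) %in% outputs)
  synapses <- data.frame(pre = pre, post = post,
                         weight = runif(m, -1, 1),
                         distance = dmat[cbind(pre, post)])
  new_network(neurons, synapses, grid = params$grid,
              plasticity = params$plasticity)
}

#' Exogenous input pulse times
#'
#' Generates the times at which the environment pulses the input neuron: a
#' homogeneous Poisson process with the given rate, i.e. inter-arrival gaps
#' i.i.d. exponential with mean `1 / rate` (default mean 10).
#'
#' @param rate mean pulses per unit time (default 0.1).
#' @param t_end generate pulses on `[0, t_end]`.
#' @param seed optional integer seed.
#' @return sorted numeric vector of pulse times, all `<= t_end`.
#' @export
input_pulse_times <- function(rate = 0.1, t_end = 10000, seed = NULL) {
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (t_end <= 0) return(numeric())
  times <- numeric()
  last <- 0
  repeat {
    chunk <- max(100L, ceiling(1.2 * rate * (t_end - last)))
    gaps <- rexp(chunk, rate)
    new <- last + cumsum(gaps)
    times <- c(times, new)
    last <- times[length(times)]
    if (last > t_end) break
  }
  times[times <= t_end]
}
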
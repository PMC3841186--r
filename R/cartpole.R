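#' Cart-pole physics parameters
#'
#' Standard bang-bang cart-pole constants: a 1.0 kg cart on a finite track
#' with a 0.1 kg pole of half-length 0.5 m, gravity 9.8 m/s^2, applied force
#' magnitude 10 N, Euler integration at 0.02 s, track bound +-2.4 m and
#' failure angle +-0.209 rad (about 12 degrees).
#'
#' @param m_cart,m_pole masses (kg).
#' @param half_length pole half-length (m).
#' @param gravity m/s^2.
#' @param force force magnitude (N); actions are `-force`, `0`, `+force`.
#' @param dt integration step (s).
#' @param x_limit,theta_limit failure bounds on `|x|` and `|theta|`.
#' @return list of class `pole_physics`.
#' @export
cartpole_physics <- function(m_cart = 1.0, m_pole = 0.1, half_length = 0.5,
                             gravity = 9.8, force = 10, dt = 0.02,
                             x_limit = 2.4, theta_limit = 0.209) {
  stopifnot(dt > 0, force > 0)
  structure(list(m_cart = m_cart, m_pole = m_pole, half_length = half_length,
                 gravity = gravity, force = force, dt = dt,
                 x_limit = x_limit, theta_limit = theta_limit),
            class = "pole_physics")
}

#' Cart-pole state
#'
#' @param x cart position (m).
#' @param x_dot cart velocity (m/s).
#' @param theta pole angle from vertical (rad).
#' @param theta_dot angular velocity (rad/s).
#' @return named numeric vector of class `cartpole_state`.
#' @export
cartpole_state <- function(x = 0, x_dot = 0, theta = 0, theta_dot = 0) {
  s <- c(x = x, x_dot = x_dot, theta = theta, theta_dot = theta_dot)
  if (any(!is.finite(s))) stop("state variables must be finite")
  structure(s, class = "cartpole_state")
}

#' One Euler step of the cart-pole dynamics
#'
#' The standard pole-on-a-cart equations of motion: with total mass
#' `m = m_cart + m_pole`,
#' `theta_dd = (g sin(theta) + cos(theta) (-F - m_pole l theta_d^2
#' sin(theta)) / m) / (l (4/3 - m_pole cos^2(theta) / m))` and
#' `x_dd = (F + m_pole l (theta_d^2 sin(theta) - theta_dd cos(theta))) / m`,
#' integrated by one explicit Euler step of `dt`.
#'
#' @param state a [cartpole_state()].
#' @param force applied force, one of `-physics$force`, `0`,
#'   `+physics$force`.
#' @param physics a [cartpole_physics()].
#' @return the next [cartpole_state()].
#' @export
step_dynamics <- function(state, force, physics = cartpole_physics()) {
  if (!force %in% c(-physics$force, 0, physics$force))
    stop("force must be one of -F, 0, +F")
  th <- state[["theta"]]; thd <- state[["theta_dot"]]
  m <- physics$m_cart + physics$m_pole
  l <- physics$half_length
  ct <- cos(th); st <- sin(th)
  theta_dd <- (physics$gravity * st +
                 ct * (-force - physics$m_pole * l * thd^2 * st) / m) /
    (l * (4 / 3 - physics$m_pole * ct^2 / m))
  x_dd <- (force + physics$m_pole * l * (thd^2 * st - theta_dd * ct)) / m
  dt <- physics$dt
  cartpole_state(x = state[["x"]] + dt * state[["x_dot"]],
                 x_dot = state[["x_dot"]] + dt * x_dd,
                 theta = th + dt * thd,
                 theta_dot = thd + dt * theta_dd)
}

#' Default input-encoding ranges
#'
#' Each state variable is split into three ranges by two cutpoints; one input
#' neuron corresponds to each range (12 input neurons in total).  Intervals
#' are left-closed: a value equal to a cutpoint belongs to the range whose
#' lower endpoint it is.
#'
#' @param x,x_dot,theta,theta_dot length-2 numeric cutpoints per variable.
#' @return list of cutpoints.
#' @export
default_encoder <- function(x = c(-0.8, 0.8), x_dot = c(-0.5, 0.5),
                            theta = c(-0.05, 0.05),
                            theta_dot = c(-0.2, 0.2)) {
  list(x = x, x_dot = x_dot, theta = theta, theta_dot = theta_dot)
}

#' Encode a cart-pole state as active input neurons
#'
#' Maps each of the four state variables to one of its three ranges and
#' returns the indices (1..12) of the four input neurons to pulse: variable
#' `v` in range `r` activates index `3 (v - 1) + r`.
#'
#' @param state a [cartpole_state()].
#' @param encoder cutpoint list from [default_encoder()].
#' @return integer vector of 4 active indices out of 12, one per variable.
#' @export
encode_state <- function(state, encoder = default_encoder()) {
  vars <- c("x", "x_dot", "theta", "theta_dot")
  idx <- integer(4)
  for (v in seq_along(vars)) {
    cuts <- encoder[[vars[v]]]
    val <- state[[vars[v]]]
    r <- if (val < cuts[1]) 1L else if (val < cuts[2]) 2L else 3L
    idx[v] <- 3L * (v - 1L) + r
  }
  idx
}

#' Decode output firing counts into a bang-bang action
#'
#' The output neuron that fired the most in the decision window determines
#' the action; if neither fired, no force is applied.  A tie also yields no
#' force.
#'
#' @param count_neg firings of the `-F` output neuron.
#' @param count_pos firings of the `+F` output neuron.
#' @param force force magnitude.
#' @return `-force`, `0` or `+force`.
#' @export
decode_action <- function(count_neg, count_pos, force = 10) {
  stopifnot(count_neg >= 0, count_pos >= 0)
  if (count_neg > count_pos) -force
  else if (count_pos > count_neg) force
  else 0
}

#' Generation parameters for a cart-pole network
#'
#' Small grids and networks are used for the control task (about 25 neurons
#' and a couple hundred synapses).  The first 12 neurons are the input
#' neurons (three ranges for each of four state variables) and the next two
#' are the output neurons (`-F`, `+F`); they sit at fixed grid positions so
#' that genomes remain compatible under crossover.
#'
#' @param n_hidden number of hidden neurons beyond the 14 interface neurons.
#' @param n_synapses number of synapses.
#' @param grid grid definition (default M = 5, g = 1: 10 sites per axis).
#' @param tau proximity scale for synapse placement.
#' @return list of class `generation_params` extended with interface info.
#' @export
cartpole_gen_params <- function(n_hidden = 11, n_synapses = 220,
                                grid = list(M = c(5, 5, 5), g = 1),
                                tau = 5) {
  generation_params(n_neurons = n_hidden + 14, n_synapses = n_synapses,
                    grid = grid, tau = tau, n_inputs = 0, n_outputs = 0)
}

cartpole_interface_positions <- function(grid) {
  M <- grid$M; g <- grid$g
  # 12 inputs in two rows of six on the z = -M face, 2 outputs on z = M - g
  i <- 0:11
  data.frame(x = c((i %% 6) * g - M[1], -M[1], -M[1] + g),
             y = c((i %/% 6) * g - M[2], rep(-M[2], 2)),
             z = c(rep(-M[3], 12), rep(M[3] - g, 2)))
}

#' Generate a random cart-pole genome
#'
#' A genome is a network plus its evolved desired firing rate.  The 12 input
#' and 2 output neurons occupy fixed positions shared by every genome;
#' hidden neurons and all synapses are random as in [generate_network()].
#'
#' @param params a [cartpole_gen_params()] object.
#' @param seed optional integer seed.
#' @param d initial desired firing rate (default: uniform on
#'   `[0, n_neurons]`).
#' @return list of class `affect_genome` with fields `network` and `d`.
#' @export
cartpole_genome <- function(params = cartpole_gen_params(), seed = NULL,
                            d = NULL) {
  if (!is.null(seed)) set.seed(seed)
  net <- generate_network(params)
  iface <- cartpole_interface_positions(params$grid)
  # overwrite the first 14 neurons' positions with the fixed interface sites
  occupied <- paste(net$neurons$x, net$neurons$y, net$neurons$z)
  for (i in seq_len(14)) {
    key <- paste(iface$x[i], iface$y[i], iface$z[i])
    hit <- match(key, occupied)
    if (!is.na(hit) && hit > 14) {
      # swap the colliding hidden neuron to the interface slot's old site
      net$neurons[c(i, hit), c("x", "y", "z")] <-
        net$neurons[c(hit, i), c("x", "y", "z")]
      occupied <- paste(net$neurons$x, net$neurons$y, net$neurons$z)
    }
    net$neurons[i, c("x", "y", "z")] <- iface[i, ]
    occupied[i] <- key
  }
  net$neurons$is_input <- c(rep(TRUE, 12), rep(FALSE, nrow(net$neurons) - 12))
  net$neurons$is_output <- seq_len(nrow(net$neurons)) %in% c(13L, 14L)
  pos <- as.matrix(net$neurons[, c("x", "y", "z")])
  net$synapses$distance <- sqrt(rowSums(
    (pos[net$synapses$pre, , drop = FALSE] -
       pos[net$synapses$post, , drop = FALSE])^2))
  validate_network(net)
  if (is.null(d)) d <- runif(1, 0, nrow(net$neurons))
  new_genome(net, d)
}

#' Run one cart-pole episode
#'
#' The control loop: encode the state and pulse the four active input
#' neurons, simulate the network for `window_time` units of network time
#' (with the affective system adjusting thresholds every `controller$window`
#' units when enabled), count the output-neuron firings in that window,
#' decode the bang-bang action, and advance the physics by one 0.02 s step.
#' Network charges, pending events and controller state persist across
#' decision windows within the episode.  The episode ends at failure
#' (`|x| > x_limit` or `|theta| > theta_limit`) or after `max_time` seconds.
#'
#' @param genome an `affect_genome`.
#' @param affective logical: operate the affective system during the episode?
#' @param initial initial [cartpole_state()].
#' @param max_time episode cap in seconds (default 300).
#' @param window_time network time simulated per control decision
#'   (default 200).
#' @param physics a [cartpole_physics()].
#' @param encoder cutpoints from [default_encoder()].
#' @param controller affective parameters used when `affective` is `TRUE`
#'   (its `d` is taken from the genome).
#' @return balanced duration in seconds.
#' @export
run_episode <- function(genome, affective = TRUE,
                        initial = cartpole_state(theta = 0.05),
                        max_time = 300, window_time = 200,
                        physics = cartpole_physics(),
                        encoder = default_encoder(),
                        controller = affective_system(d = 1)) {
  stopifnot(inherits(genome, "affect_genome"))
  net <- genome$network
  ctrl <- NULL
  if (affective) {
    controller$d <- genome$d
    ctrl <- controller
  }
  ptr <- sim_from_network(net, ctrl, plasticity = TRUE,
                          rate_window = controller$window)
  out_ids <- which(net$neurons$is_output) - 1L  # 0-based for the engine
  inp_ids <- which(net$neurons$is_input)
  state <- initial
  t_net <- 0
  elapsed <- 0
  n_steps <- ceiling(max_time / physics$dt)
  for (k in seq_len(n_steps)) {
    active <- inp_ids[encode_state(state, encoder)]
    res <- sim_run(ptr, t_net + window_time,
                   rep(t_net, 4), as.integer(active) - 1L,
                   numeric(), numeric(), 0)
    cn <- sum(res$firing_neuron == out_ids[1])
    cp <- sum(res$firing_neuron == out_ids[2])
    force <- decode_action(cn, cp, physics$force)
    state <- step_dynamics(state, force, physics)
    t_net <- t_net + window_time
    if (abs(state[["x"]]) > physics$x_limit ||
        abs(state[["theta"]]) > physics$theta_limit)
      return(elapsed + physics$dt)
    elapsed <- elapsed + physics$dt
  }
  elapsed
}

#' Default six fitness starting conditions
#'
#' Six `(x, theta)` pairs with zero linear and angular velocity, spanning
#' cart offsets and pole tilts in both directions.
#'
#' @return data frame with columns `x`, `theta`.
#' @export
fitness_conditions <- function() {
  data.frame(x = c(-1.5, 1.5, 0, 0, -1.0, 1.0),
             theta = c(0, 0, -0.1, 0.1, 0.05, -0.05))
}

#' Six-condition fitness of a genome
#'
#' Mean balancing time over the six starting conditions, each episode capped
#' at `max_time` seconds.  A genome is fully trained when every episode
#' reaches the cap.
#'
#' @param genome an `affect_genome`.
#' @param conditions data frame `(x, theta)` (default [fitness_conditions()]).
#' @param max_time per-episode cap (default 300 s).
#' @param ... passed to [run_episode()].
#' @return mean balance time in seconds.
#' @export
fitness_six <- function(genome, conditions = fitness_conditions(),
                        max_time = 300, ...) {
  times <- vapply(seq_len(nrow(conditions)), function(i) {
    run_episode(genome,
                initial = cartpole_state(x = conditions$x[i],
                                         theta = conditions$theta[i]),
                max_time = max_time, ...)
  }, numeric(1))
  mean(pmin(times, max_time))
}

#' Generalization grid of balancing times
#'
#' Evaluates a genome from random starts drawn in each cell of a 21 x 6 grid
#' of `(x, theta)` ranges: `x` cells of width 0.2 from `x_start` (default
#' -2.2, so the last cell ends at 1.8) and `theta` cells of width 0.05 with
#' lower edges from -0.15 to 0.1.  Ten uniform random starting conditions
#' per cell (with zero velocities) give 1260 episodes in total.
#'
#' @param genome an `affect_genome`.
#' @param seed integer seed for the random starts.
#' @param n_per_cell starts per cell (default 10).
#' @param x_start lower edge of the first `x` cell (default -2.2).
#' @param max_time per-episode cap in seconds.
#' @param ... passed to [run_episode()].
#' @return data frame with one row per cell: `x_lo`, `theta_lo`,
#'   `mean_time`.
#' @export
generalization_grid <- function(genome, seed = 1, n_per_cell = 10,
                                x_start = -2.2, max_time = 300, ...) {
  set.seed(seed)
  x_lo <- x_start + 0.2 * (0:20)
  th_lo <- -0.15 + 0.05 * (0:5)
  cells <- expand.grid(x_lo = x_lo, theta_lo = th_lo)
  cells$mean_time <- vapply(seq_len(nrow(cells)), function(i) {
    xs <- runif(n_per_cell, cells$x_lo[i], cells$x_lo[i] + 0.2)
    ths <- runif(n_per_cell, cells$theta_lo[i], cells$theta_lo[i] + 0.05)
    mean(vapply(seq_len(n_per_cell), function(j) {
      min(run_episode(genome,
                      initial = cartpole_state(x = xs[j], theta = ths[j]),
                      max_time = max_time, ...), max_time)
    }, numeric(1)))
  }, numeric(1))
  cells
}
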
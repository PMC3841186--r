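#' Construct a genome
#'
#' A genome couples a network with its desired firing rate `d`, which is an
#' evolved trait: training searches over topology, weights, thresholds and
#' the setpoint the affective system should hold during operation.
#'
#' @param network an `affect_network`.
#' @param d desired firing rate, in `[0, n_neurons]`.
#' @return list of class `affect_genome`.
#' @export
new_genome <- function(network, d) {
  stopifnot(inherits(network, "affect_network"))
  n <- nrow(network$neurons)
  if (d < 0 || d > n)
    stop("d must lie in [0, number of neurons]")
  structure(list(network = network, d = d), class = "affect_genome")
}

#' Evolutionary-algorithm configuration
#'
#' @param pop_size population size (>= 2; default 50).
#' @param tournament tournament size for parent selection (default 5).
#' @param p_crossover probability that a selected pair is recombined
#'   (default 0.9).
#' @param p_mutation probability that each child is mutated (default 0.9).
#' @param mutation_weights named sampling weights over the mutation menu:
#'   `add_neuron`, `delete_neuron`, `add_synapse`, `delete_synapse`,
#'   `perturb_weight`, `perturb_threshold`, `resample_d` (default uniform).
#' @param perturb_scale half-width of the uniform weight/threshold
#'   perturbation (default 0.1).
#' @param max_epochs generation cap (default 100).
#' @param elitism number of best individuals copied unchanged (default 1).
#' @return list of class `ea_config`.
#' @export
ea_config <- function(pop_size = 50, tournament = 5, p_crossover = 0.9,
                      p_mutation = 0.9,
                      mutation_weights = c(add_neuron = 1, delete_neuron = 1,
                                           add_synapse = 1,
                                           delete_synapse = 1,
                                           perturb_weight = 1,
                                           perturb_threshold = 1,
                                           resample_d = 1),
                      perturb_scale = 0.1, max_epochs = 100, elitism = 1) {
  stopifnot(pop_size >= 2, tournament >= 1, tournament <= pop_size,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1,
            elitism >= 0, elitism < pop_size)
  structure(list(pop_size = pop_size, tournament = tournament,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 mutation_weights = mutation_weights,
                 perturb_scale = perturb_scale, max_epochs = max_epochs,
                 elitism = elitism),
            class = "ea_config")
}

#' Tournament selection
#'
#' Samples `k` distinct candidates uniformly at random and returns the index
#' of the fittest among them (ties broken by the lowest index).
#'
#' @param fitnesses numeric vector of population fitnesses.
#' @param k tournament size, `<= length(fitnesses)`.
#' @return index of the selected parent.
#' @export
tournament_select <- function(fitnesses, k) {
  n <- length(fitnesses)
  if (n == 0) stop("population is empty")
  if (k > n) stop("tournament size exceeds population size")
  cand <- sort(sample.int(n, k))
  cand[which.max(fitnesses[cand])]
}

genome_positions <- function(net) as.matrix(net$neurons[, c("x", "y", "z")])

rebuild_network <- function(neurons, synapses, template) {
  neurons$id <- seq_len(nrow(neurons))
  rownames(neurons) <- NULL
  rownames(synapses) <- NULL
  pos <- as.matrix(neurons[, c("x", "y", "z")])
  if (nrow(synapses) > 0) {
    synapses$distance <- sqrt(rowSums(
      (pos[synapses$pre, , drop = FALSE] -
         pos[synapses$post, , drop = FALSE])^2))
  }
  new_network(neurons, synapses, grid = template$grid,
              plasticity = template$plasticity)
}

# Map a parent's synapses onto a child: endpoints that survived keep their
# neuron; a dangling endpoint is reattached to the nearest child neuron on
# the far side of the cut plane.  `map` gives child index per parent neuron
# (NA = lost).
reattach_synapses <- function(parent, map, child_neurons, axis, cut,
                              keep_low) {
  sy <- parent$synapses
  if (nrow(sy) == 0) return(sy[0, ])
  cpos <- as.matrix(child_neurons[, c("x", "y", "z")])
  far <- if (keep_low) which(cpos[, axis] >= cut) else
    which(cpos[, axis] < cut)
  nearest_far <- function(p) {
    if (length(far) == 0) return(NA_integer_)
    d <- colSums((t(cpos[far, , drop = FALSE]) - p)^2)
    far[which.min(d)]
  }
  ppos <- genome_positions(parent)
  pre <- map[sy$pre]; post <- map[sy$post]
  keep <- !(is.na(pre) & is.na(post))
  sy <- sy[keep, , drop = FALSE]
  pre <- pre[keep]; post <- post[keep]
  for (j in which(is.na(pre))) pre[j] <- nearest_far(ppos[sy$pre[j], ])
  for (j in which(is.na(post))) post[j] <- nearest_far(ppos[sy$post[j], ])
  sy$pre <- pre; sy$post <- post
  sy[!is.na(sy$pre) & !is.na(sy$post) & sy$pre != sy$post, , drop = FALSE]
}

#' Spatial-plane crossover of two genomes
#'
#' Splits both parents by one random axis-aligned plane through the grid and
#' exchanges the two sides: child 1 keeps parent A's neurons below the cut
#' and parent B's neurons at or above it (child 2 is the complement).
#' Interface neurons (inputs/outputs, which sit at identical positions in
#' every genome) are inherited as a block and never split.  Synapses follow
#' their endpoints; a synapse whose far endpoint was lost is reattached to
#' the nearest child neuron on the far side of the plane, and duplicate or
#' self pairs are dropped.  Both children receive the parents' average
#' desired firing rate, clamped to `[0, n_neurons]`.
#'
#' @param a,b parent `affect_genome`s (same grid).
#' @return list of two child `affect_genome`s.
#' @export
crossover <- function(a, b) {
  stopifnot(inherits(a, "affect_genome"), inherits(b, "affect_genome"))
  grid <- a$network$grid
  axis <- sample.int(3, 1)
  cut <- (sample.int(round(2 * grid$M[axis] / grid$g) - 1, 1) -
            grid$M[axis] / grid$g) * grid$g
  make_child <- function(low, high, keep_low_from_low = TRUE) {
    nl <- low$network; nh <- high$network
    iface_l <- nl$neurons$is_input | nl$neurons$is_output
    iface_h <- nh$neurons$is_input | nh$neurons$is_output
    posl <- genome_positions(nl); posh <- genome_positions(nh)
    keep_l <- which(iface_l | posl[, axis] < cut)
    keep_h <- which(!iface_h & posh[, axis] >= cut)
    # drop high-side neurons that collide with a kept low-side position
    keyl <- apply(posl[keep_l, , drop = FALSE], 1, paste, collapse = ",")
    keyh <- apply(posh[keep_h, , drop = FALSE], 1, paste, collapse = ",")
    keep_h <- keep_h[!keyh %in% keyl]
    neurons <- rbind(nl$neurons[keep_l, ], nh$neurons[keep_h, ])
    map_l <- rep(NA_integer_, nrow(nl$neurons))
    map_l[keep_l] <- seq_along(keep_l)
    map_h <- rep(NA_integer_, nrow(nh$neurons))
    map_h[keep_h] <- length(keep_l) + seq_along(keep_h)
    sy <- rbind(reattach_synapses(nl, map_l, neurons, axis, cut, TRUE),
                reattach_synapses(nh, map_h, neurons, axis, cut, FALSE))
    sy <- sy[!duplicated(sy[, c("pre", "post")]), , drop = FALSE]
    net <- rebuild_network(neurons, sy, nl)
    d <- min(max((low$d + high$d) / 2, 0), nrow(neurons))
    new_genome(net, d)
  }
  list(make_child(a, b), make_child(b, a))
}

free_grid_site <- function(net) {
  g <- net$grid$g; M <- net$grid$M
  occupied <- paste(net$neurons$x, net$neurons$y, net$neurons$z)
  for (i in 1:100) {
    p <- vapply(1:3, function(k)
      (sample.int(round(2 * M[k] / g), 1) - 1) * g - M[k], numeric(1))
    if (!paste(p[1], p[2], p[3]) %in% occupied) return(p)
  }
  NULL
}

#' Mutate a genome
#'
#' Applies one mutation sampled from the menu: add a neuron (placed at a
#' free grid site with one random incoming and one random outgoing synapse),
#' delete a hidden neuron and its synapses, add or delete a synapse, perturb
#' one weight or one threshold by a uniform amount in
#' `[-perturb_scale, perturb_scale]` (clamped to `[-1, 1]`), or resample the
#' desired firing rate uniformly on `[0, n_neurons]`.  An infeasible
#' mutation (e.g. deleting from a network with no hidden neurons) causes the
#' mutation type to be resampled.
#'
#' @param genome an `affect_genome`.
#' @param config an [ea_config()].
#' @return the mutated genome (validates all network invariants).
#' @export
mutate_genome <- function(genome, config = ea_config()) {
  net <- genome$network
  d <- genome$d
  menu <- names(config$mutation_weights)
  wts <- as.numeric(config$mutation_weights)
  for (attempt in 1:20) {
    type <- sample(menu, 1, prob = wts)
    n <- nrow(net$neurons)
    m <- nrow(net$synapses)
    hidden <- which(!(net$neurons$is_input | net$neurons$is_output))
    done <- switch(type,
      add_neuron = {
        p <- free_grid_site(net)
        if (is.null(p) || n < 1) FALSE else {
          nn <- net$neurons[1, ]
          nn$id <- n + 1L
          nn[, c("x", "y", "z")] <- as.list(p)
          nn$threshold <- runif(1, -1, 1)
          nn$charge <- 0; nn$last_fire <- NA_real_
          nn$is_input <- FALSE; nn$is_output <- FALSE
          neurons <- rbind(net$neurons, nn)
          from <- sample.int(n, 1); to <- sample.int(n, 1)
          sy <- rbind(net$synapses,
                      data.frame(pre = c(from, n + 1L),
                                 post = c(n + 1L, to),
                                 weight = runif(2, -1, 1),
                                 distance = 0,
                                 last_plasticity = NA_real_))
          net <- rebuild_network(neurons, sy, net)
          TRUE
        }
      },
      delete_neuron = {
        if (length(hidden) == 0) FALSE else {
          kill <- hidden[sample.int(length(hidden), 1)]
          keep <- setdiff(seq_len(n), kill)
          map <- rep(NA_integer_, n); map[keep] <- seq_along(keep)
          sy <- net$synapses
          sy <- sy[sy$pre != kill & sy$post != kill, , drop = FALSE]
          sy$pre <- map[sy$pre]; sy$post <- map[sy$post]
          net <- rebuild_network(net$neurons[keep, ], sy, net)
          d <- min(d, length(keep))
          TRUE
        }
      },
      add_synapse = {
        if (m >= n * (n - 1)) FALSE else {
          repeat {
            pr <- sample.int(n, 1); po <- sample.int(n, 1)
            if (pr != po &&
                !any(net$synapses$pre == pr & net$synapses$post == po))
              break
          }
          sy <- rbind(net$synapses,
                      data.frame(pre = pr, post = po,
                                 weight = runif(1, -1, 1), distance = 0,
                                 last_plasticity = NA_real_))
          net <- rebuild_network(net$neurons, sy, net)
          TRUE
        }
      },
      delete_synapse = {
        if (m == 0) FALSE else {
          net <- rebuild_network(net$neurons,
                                 net$synapses[-sample.int(m, 1), ,
                                              drop = FALSE], net)
          TRUE
        }
      },
      perturb_weight = {
        if (m == 0) FALSE else {
          j <- sample.int(m, 1)
          net$synapses$weight[j] <- clamp_unit(
            net$synapses$weight[j] +
              runif(1, -config$perturb_scale, config$perturb_scale))
          TRUE
        }
      },
      perturb_threshold = {
        j <- sample.int(n, 1)
        net$neurons$threshold[j] <- clamp_unit(
          net$neurons$threshold[j] +
            runif(1, -config$perturb_scale, config$perturb_scale))
        TRUE
      },
      resample_d = {
        d <- runif(1, 0, n)
        TRUE
      })
    if (done) break
  }
  new_genome(net, d)
}

#' Evolve genomes against a fitness function
#'
#' Generational loop with tournament selection, spatial crossover, the
#' mutation menu, and elitism.  Each epoch evaluates the population, logs
#' best and mean fitness, and stops when `success` holds for the best
#' fitness or after `max_epochs` generations.
#'
#' @param init either a list of `affect_genome`s (the initial population) or
#'   a function `function(i)` returning the i-th initial genome.
#' @param fitness_fn function mapping a genome to a numeric fitness
#'   (larger is better).
#' @param config an [ea_config()].
#' @param success predicate on the best fitness (default: never, so the
#'   loop runs to `max_epochs`).
#' @param seed integer seed fixing the whole trajectory.
#' @return list with `best` (best-ever genome), `best_fitness`, `converged`
#'   flag, `epochs` used, and an `epoch_log` data frame.
#' @export
evolve <- function(init, fitness_fn, config = ea_config(),
                   success = function(f) FALSE, seed = 1) {
  set.seed(seed)
  pop <- if (is.function(init)) lapply(seq_len(config$pop_size), init)
         else init
  stopifnot(length(pop) == config$pop_size)
  best <- NULL
  best_fit <- -Inf
  log <- data.frame(epoch = integer(), best = numeric(), mean = numeric())
  for (epoch in seq_len(config$max_epochs)) {
    fits <- vapply(pop, fitness_fn, numeric(1))
    if (max(fits) > best_fit) {
      best_fit <- max(fits)
      best <- pop[[which.max(fits)]]
    }
    log <- rbind(log, data.frame(epoch = epoch, best = best_fit,
                                 mean = mean(fits)))
    if (success(best_fit)) {
      return(list(best = best, best_fitness = best_fit, converged = TRUE,
                  epochs = epoch, epoch_log = log))
    }
    elite <- order(fits, decreasing = TRUE)[seq_len(config$elitism)]
    nxt <- pop[elite]
    while (length(nxt) < config$pop_size) {
      i <- tournament_select(fits, config$tournament)
      j <- tournament_select(fits, config$tournament)
      children <- if (runif(1) < config$p_crossover)
        crossover(pop[[i]], pop[[j]]) else list(pop[[i]], pop[[j]])
      for (ch in children) {
        if (length(nxt) >= config$pop_size) break
        if (runif(1) < config$p_mutation) ch <- mutate_genome(ch, config)
        nxt[[length(nxt) + 1]] <- ch
      }
    }
    pop <- nxt
  }
  list(best = best, best_fitness = best_fit, converged = FALSE,
       epochs = config$max_epochs, epoch_log = log)
}
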
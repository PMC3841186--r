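#' Save a network to JSON
#'
#' The schema has three top-level members: `grid` (`M`, `g`), `plasticity`
#' (`step`, `refractory`) and the `neurons` / `synapses` tables written
#' column-wise.  Floating-point values are written at full precision so the
#' save/load round trip is lossless.
#'
#' @param net an `affect_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "affect_network"))
  obj <- list(
    format = "affectnet-network",
    version = 1L,
    grid = list(M = net$grid$M, g = net$grid$g),
    plasticity = list(step = net$plasticity$step,
                      refractory = net$plasticity$refractory),
    neurons = as.list(net$neurons),
    synapses = as.list(net$synapses)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Load a network from JSON
#'
#' @param path a file written by [save_network()].
#' @return a validated `affect_network`.
#' @export
load_network <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse network file '", path, "': ",
                         conditionMessage(e)))
  for (field in c("grid", "neurons", "synapses"))
    if (is.null(obj[[field]]))
      stop("network file '", path, "' is missing member $", field)
  neurons <- as.data.frame(obj$neurons)
  # columns that are all-null in JSON come back logical; restore types
  for (col in c("threshold", "charge", "refractory", "last_fire"))
    if (!is.null(neurons[[col]])) neurons[[col]] <- as.numeric(neurons[[col]])
  neurons$id <- as.integer(neurons$id)
  synapses <- if (length(obj$synapses) == 0 ||
                  length(obj$synapses$pre) == 0) {
    data.frame(pre = integer(), post = integer(), weight = numeric(),
               distance = numeric(), last_plasticity = numeric())
  } else as.data.frame(obj$synapses)
  for (col in c("weight", "distance", "last_plasticity"))
    if (!is.null(synapses[[col]])) synapses[[col]] <- as.numeric(synapses[[col]])
  net <- new_network(neurons, synapses,
                     grid = list(M = as.numeric(obj$grid$M),
                                 g = as.numeric(obj$grid$g)),
                     plasticity = list(
                       step = obj$plasticity$step,
                       refractory = obj$plasticity$refractory))
  net
}

#' Write a simulation trace to CSV files
#'
#' Writes `firings.csv` (time, neuron) and `rates.csv` (time, rate, desired,
#' threshold), plus `weight_histogram.csv` (time, bin_lo, count) when the
#' trace carries weight snapshots.  Rows are in time order; files with no
#' rows still carry the header.
#'
#' @param trace an `affect_trace`.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_trace <- function(trace, dir) {
  stopifnot(inherits(trace, "affect_trace"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(file.path(dir, "firings.csv"), file.path(dir, "rates.csv"))
  utils::write.csv(trace$firings, files[1], row.names = FALSE)
  utils::write.csv(trace$rates, files[2], row.names = FALSE)
  if (!is.null(trace$snapshots)) {
    k <- length(trace$snapshots$time)
    lo <- seq(-1, 0.9, by = 0.1)
    hist_df <- data.frame(
      time = rep(trace$snapshots$time, each = 20),
      bin_lo = rep(lo, k),
      count = as.vector(trace$snapshots$hist))
    f <- file.path(dir, "weight_histogram.csv")
    utils::write.csv(hist_df, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a run configuration
#'
#' Reads a YAML or JSON configuration with any of the sections `generation`,
#' `controller`, `plasticity`, `d_schedule`, `simulation`, `ea`, `cartpole`.
#' Unknown top-level keys are rejected so that a typo cannot silently fall
#' back to defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return named list of configuration sections.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("generation", "controller", "plasticity", "d_schedule",
               "simulation", "ea", "cartpole", "seed", "out")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg
}

#' Build experiment objects from a configuration list
#'
#' Maps configuration sections onto [generation_params()],
#' [affective_system()] and [plasticity_params()], applying defaults for
#' anything unspecified.
#'
#' @param cfg list from [read_run_config()].
#' @return list with `gen`, `controller`, `d_schedule`, `t_end`, `seed`.
#' @export
config_to_experiment <- function(cfg) {
  gen <- do.call(generation_params, as.list(cfg$generation %||% list()))
  controller <- if (!is.null(cfg$controller))
    do.call(affective_system, as.list(cfg$controller)) else NULL
  if (!is.null(cfg$plasticity))
    gen$plasticity <- do.call(plasticity_params, as.list(cfg$plasticity))
  d_schedule <- if (!is.null(cfg$d_schedule))
    as.data.frame(cfg$d_schedule) else NULL
  list(gen = gen, controller = controller, d_schedule = d_schedule,
       t_end = cfg$simulation$t_end %||% 10000,
       seed = cfg$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a replay manifest
#'
#' Records the configuration, seed and package version of a run so it can be
#' replayed bit-identically.
#'
#' @param dir output directory.
#' @param config configuration list (may be `NULL`).
#' @param seed integer seed used.
#' @return path of the manifest, invisibly.
#' @export
write_manifest <- function(dir, config, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(package = "affectnet",
         version = as.character(utils::packageVersion("affectnet")),
         seed = seed, config = config),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
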
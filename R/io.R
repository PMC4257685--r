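# Plain-text exporters and the run configuration document.

# 32-bit rolling hash of a character scalar, reported in run logs so a result
# directory can be matched to its exact configuration
config_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  sprintf("%08x", h)
}

#' Export a scenario run as plain-text files
#'
#' Writes into `dir`: `hr_trace.csv` (time_seconds, H_scaled),
#' `hr_by_interval.csv`, `activity_map.tsv` (neurons x intervals, row order
#' branch/level/index), `on_mask.tsv`, `summary.json`, `config.yaml` and
#' `run_log.txt` (seed and configuration hash).
#'
#' @param result a `vns_scenario`.
#' @param dir output directory (created if missing).
#' @param write_map also write the full activity map (can be large); default
#'   `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(result, dir, write_map = TRUE) {
  stopifnot(inherits(result, "vns_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$hr_trace, file.path(dir, "hr_trace.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(interval = seq_along(result$hr_by_interval),
               H_scaled = result$hr_by_interval,
               vns_on = result$on_mask),
    file.path(dir, "hr_by_interval.csv"), row.names = FALSE)
  if (write_map) {
    map <- as.data.frame(result$activity_map)
    names(map) <- paste0("k", seq_len(ncol(map)))
    utils::write.table(cbind(result$network$neurons[, c("id", "branch",
                                                        "level", "index")],
                             map),
                       file.path(dir, "activity_map.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  s <- summary(result)
  s$level_means <- as.list(stats::setNames(
    s$level_means$mean_activity,
    paste(s$level_means$branch, s$level_means$level, sep = "_L")))
  jsonlite::write_json(s, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- result$config_snapshot
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  writeLines(c(sprintf("scenario: %s", result$scenario_name),
               sprintf("seed: %d", cfg$seed),
               sprintf("config_hash: %s",
                       config_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE)))),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Export an activity difference map as TSV
#'
#' @param diff_map matrix from [activity_difference_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_difference_map <- function(diff_map, path) {
  utils::write.table(diff_map, path, sep = "\t", row.names = FALSE,
                     col.names = paste0("k", seq_len(ncol(diff_map))),
                     quote = FALSE)
  invisible(path)
}

#' Read / write a full run configuration
#'
#' One YAML document covering the parameter set, network build arguments,
#' demand settings and the stimulation protocol; [run_config()] builds a
#' validated default, [read_config()]/[write_config()] round-trip it.
#'
#' @param parameters a [vns_parameters()] object.
#' @param network_args list of arguments for [neuron_population()] /
#'   [default_network()].
#' @param demand list with `base_level`, `noise_sd`.
#' @param protocol a [vns_protocol()].
#' @param scenario scenario name.
#' @param seed integer seed.
#' @return a plain list (class `vns_config`).
#' @export
run_config <- function(parameters = vns_parameters(),
                       network_args = list(n_per_level = 600),
                       demand = list(base_level = 0.2, noise_sd = 0.02),
                       protocol = vns_protocol(),
                       scenario = "custom", seed = 1) {
  structure(list(scenario = scenario, seed = seed,
                 parameters = unclass(validate_parameters(parameters)),
                 network = network_args, demand = demand,
                 protocol = unclass(protocol)),
            class = "vns_config")
}

#' @rdname run_config
#' @param config a `vns_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(
    parameters = do.call(vns_parameters, raw$parameters),
    network_args = raw$network,
    demand = raw$demand,
    protocol = do.call(vns_protocol, raw$protocol),
    scenario = raw$scenario %||% "custom",
    seed = raw$seed %||% 1)
  cfg
}

#' Run a scenario from a configuration document
#'
#' @param config a `vns_config` (or a YAML path).
#' @param seed optional seed overriding the config's.
#' @param ... further overrides for [run_scenario()].
#' @return a `vns_scenario`.
#' @export
run_from_config <- function(config, seed = NULL, ...) {
  if (is.character(config)) config <- read_config(config)
  seed <- if (is.null(seed)) config$seed else seed
  args <- list(scenario = "custom", seed = seed,
               protocol = do.call(vns_protocol, config$protocol),
               parameters = do.call(vns_parameters, config$parameters),
               demand_base = config$demand$base_level,
               demand_sd = config$demand$noise_sd)
  args <- utils::modifyList(args, c(config$network, list(...)))
  do.call(run_scenario, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
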
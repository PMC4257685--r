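# Scenario runner for the four stimulation regimes, response classification,
# activity maps, and the baseline-vs-subthreshold difference map.
#
# The per-interval loop is: stimulation state -> effective sensitivities and
# a_r -> network update (with delayed heart rate and demand) -> mean cardiac
# activities -> three drive steps -> move -> continuous within-interval
# heart-rate integration.

SCENARIOS <- c("baseline", "subthreshold", "sympathetic_threshold",
               "parasympathetic_threshold", "custom")

#' Stimulation-intensity presets of the four regimes
#'
#' The model states relative, not absolute, intensities: subthreshold is a
#' minimal indirect stimulation with the direct component OFF; the
#' sympathetic threshold raises the indirect intensities until stimulation-
#' locked tachycardia emerges; the parasympathetic threshold keeps those
#' indirect intensities and turns the direct component on until bradycardia
#' dominates. The numerical values here were calibrated once against the
#' default network and demand so that the regime ordering
#' (none / tachycardia / bradycardia) holds across seeds, and are exposed so
#' users can explore other points of the intensity plane.
#'
#' @param scenario one of `"baseline"`, `"subthreshold"`,
#'   `"sympathetic_threshold"`, `"parasympathetic_threshold"`.
#' @param on_seconds,off_seconds,n_cycles duty-cycle geometry passed through
#'   to [vns_protocol()]; defaults 14 s ON / 108 s OFF (122 s cycle), 5
#'   cycles.
#' @return a [vns_protocol()].
#' @export
#' @examples
#' scenario_preset("sympathetic_threshold")
scenario_preset <- function(scenario, on_seconds = 14, off_seconds = 108,
                            n_cycles = 5) {
  scenario <- match.arg(scenario, setdiff(SCENARIOS, "custom"))
  intens <- switch(scenario,
    baseline = c(0, 0, 0),
    subthreshold = c(0.002, 0.005, 0),
    sympathetic_threshold = c(0.015, 0.08, 0),
    parasympathetic_threshold = c(0.015, 0.08, 0.3))
  vns_protocol(on_seconds = on_seconds, off_seconds = off_seconds,
               n_cycles = n_cycles,
               delta_H_sens = intens[1], delta_D_sens = intens[2],
               direct_increment = intens[3])
}

#' Run one stimulation scenario
#'
#' Simulates `warmup` unstimulated intervals followed by the protocol's full
#' duty cycle, returning the heart-rate trace, the per-interval network
#' activity map, the ON mask and the response classification. Identical
#' arguments always produce identical results; all stochasticity enters
#' through the seeded demand trace.
#'
#' @param scenario a preset name (see [scenario_preset()]) or `"custom"`.
#' @param seed integer seed; fixes class placement and the demand noise. Runs
#'   with the same seed share the same network and demand realisation, so
#'   scenario differences are exact ablations.
#' @param protocol a [vns_protocol()]; required for `"custom"`, otherwise
#'   defaults to the scenario preset.
#' @param n_per_level neurons per hierarchy level (default 600; smaller
#'   values give proportionally scaled networks for quick exploration).
#' @param warmup unstimulated lead-in intervals excluded from
#'   classification; default 200.
#' @param n_cycles duty cycles simulated; default 5.
#' @param parameters a [vns_parameters()] object; default `vns_parameters()`.
#' @param network optionally a pre-built `vns_network` (overrides
#'   `n_per_level`).
#' @param demand_base,demand_sd demand trace level and noise (see
#'   [generate_demand()]).
#' @param H0 initial scaled heart rate; default 0.2.
#' @param init_activity initial neuron activity; default 0.5.
#' @param margin classification margin in scaled heart-rate units; default
#'   0.02.
#' @return an object of class `vns_scenario` with elements `scenario_name`,
#'   `hr_trace` (data.frame time_seconds, H_scaled), `hr_by_interval`,
#'   `activity_map` (neurons x intervals), `on_mask`, `warmup`,
#'   `classification`, `drives` (per-interval S, P_ind, P_dir), `demand`,
#'   `network`, `config_snapshot`.
#' @export
#' @examples
#' res <- run_scenario("baseline", seed = 1, n_per_level = 30, warmup = 20,
#'                     n_cycles = 1)
#' res$classification
run_scenario <- function(scenario = "baseline", seed = 1, protocol = NULL,
                         n_per_level = 600, warmup = 200, n_cycles = 5,
                         parameters = NULL, network = NULL,
                         demand_base = 0.2, demand_sd = 0.02,
                         H0 = 0.2, init_activity = 0.5, margin = 0.02) {
  scenario <- match.arg(scenario, SCENARIOS)
  if (is.null(protocol)) {
    if (scenario == "custom")
      stop("scenario 'custom' requires an explicit 'protocol'", call. = FALSE)
    protocol <- scenario_preset(scenario, n_cycles = n_cycles)
  }
  if (is.null(parameters)) parameters <- vns_parameters()
  p <- validate_parameters(parameters)
  if (is.null(network)) {
    network <- default_network(seed = seed, n_per_level = n_per_level)$network
  }
  if (H0 < 0 || H0 > 1) stop("field 'H0' must lie in [0,1]", call. = FALSE)

  mask <- c(rep(FALSE, warmup), build_schedule(protocol, p$interval_duration))
  if (scenario == "baseline") mask[] <- FALSE   # same run length, no ON phase
  K <- length(mask)
  demand <- generate_demand(K, base_level = demand_base, noise_sd = demand_sd,
                            seed = seed)

  # effective (ON-phase) population and parameters, computed once: the
  # stimulation mechanisms are stateless across cycles
  net_on <- apply_indirect_stimulation(network, protocol, TRUE)
  p_on <- apply_direct_stimulation(p, protocol, TRUE)

  n <- nrow(network$neurons)
  state <- network_state(network, activity = init_activity)
  S <- P_ind <- P_dir <- 0
  H <- H0
  hr_by_interval <- numeric(K)
  hist <- numeric(K + 1); hist[1] <- H0
  activity_map <- matrix(NA_real_, nrow = n, ncol = K)
  drives <- matrix(NA_real_, nrow = K, ncol = 3,
                   dimnames = list(NULL, c("S", "P_ind", "P_dir")))
  samples <- matrix(NA_real_, nrow = p$n_samples, ncol = K)

  for (k in seq_len(K)) {
    on <- mask[k]
    net_k <- if (on) net_on else network
    p_k <- if (on) p_on else p
    H_d <- delayed_heart_rate(hist[seq_len(k)], p$tau_delay)
    state <- update_network(state, net_k, H_d, demand$values[k])
    activity_map[, k] <- state$activity
    xs <- mean_cardiac_activity(state, network, "sympathetic")
    xp <- mean_cardiac_activity(state, network, "parasympathetic_indirect")
    S <- step_sympathetic_drive(S, xs, p_k)
    P_ind <- step_indirect_parasym_drive(P_ind, xp, p_k)
    P_dir <- step_direct_parasym_drive(P_dir, H, demand$values[k], p_k)
    drives[k, ] <- c(S, P_ind, P_dir)
    move <- compute_move(S, P_ind, P_dir, p_k)
    Ht <- integrate_interval(H, move, p_k)
    samples[, k] <- Ht
    H <- Ht[p$n_samples]
    hr_by_interval[k] <- H
    hist[k + 1] <- H
  }

  post <- seq_len(K) > warmup
  classification <- classify_response(hr_by_interval[post], mask[post],
                                      margin = margin)
  hr_trace <- data.frame(
    time_seconds = rep(seq_len(K) - 1, each = p$n_samples) *
      p$interval_duration +
      seq_len(p$n_samples) / p$n_samples * p$interval_duration,
    H_scaled = as.vector(samples))

  structure(list(
    scenario_name = scenario,
    hr_trace = hr_trace,
    hr_by_interval = hr_by_interval,
    activity_map = activity_map,
    on_mask = mask,
    warmup = warmup,
    classification = classification,
    drives = as.data.frame(drives),
    demand = demand,
    network = network,
    config_snapshot = list(
      scenario = scenario, seed = seed, n_per_level = n_per_level,
      warmup = warmup, protocol = unclass(protocol),
      parameters = unclass(p), demand_base = demand_base,
      demand_sd = demand_sd, H0 = H0, init_activity = init_activity,
      margin = margin)),
    class = "vns_scenario")
}

#' Classify the stimulation-locked heart-rate response
#'
#' Compares mean scaled heart rate during ON and OFF phases:
#' `delta = mean(H | ON) - mean(H | OFF)`. Responses are `"tachycardia"` when
#' `delta > margin`, `"bradycardia"` when `delta < -margin`, otherwise
#' `"none"`. With no ON (or no OFF) intervals the response is `"none"` —
#' there is no stimulation contrast to classify.
#'
#' @param hr_by_interval per-interval scaled heart rate.
#' @param on_mask logical ON mask, same length.
#' @param margin classification margin in scaled units; default 0.02, above
#'   the ON/OFF mean differences produced by baseline oscillation alone.
#' @return `"none"`, `"tachycardia"` or `"bradycardia"`.
#' @export
#' @examples
#' classify_response(c(0.5, 0.5, 0.3, 0.3), c(TRUE, TRUE, FALSE, FALSE))
classify_response <- function(hr_by_interval, on_mask, margin = 0.02) {
  if (length(hr_by_interval) != length(on_mask))
    stop("hr_by_interval and on_mask lengths differ", call. = FALSE)
  if (!any(on_mask) || all(on_mask)) return("none")
  delta <- mean(hr_by_interval[on_mask]) - mean(hr_by_interval[!on_mask])
  if (delta > margin) "tachycardia"
  else if (delta < -margin) "bradycardia"
  else "none"
}

#' ON-minus-OFF heart-rate contrast of a scenario
#'
#' `mean(H | ON) - mean(H | OFF)` over the post-warm-up intervals; `NA` when
#' the scenario has no ON intervals (baseline).
#'
#' @param result a `vns_scenario`.
#' @return scalar contrast in scaled heart-rate units, or `NA`.
#' @export
hr_on_off_delta <- function(result) {
  post <- seq_along(result$on_mask) > result$warmup
  m <- result$on_mask[post]
  h <- result$hr_by_interval[post]
  if (!any(m) || all(m)) return(NA_real_)
  mean(h[m]) - mean(h[!m])
}

#' Elementwise difference of two activity maps
#'
#' `a$activity_map - b$activity_map`, the map that exposes network-level
#' effects of a stimulation condition relative to another (e.g. subthreshold
#' minus baseline) even when heart rate is indistinguishable. Entries lie in
#' \[-1, 1\].
#'
#' @param a,b `vns_scenario` results from the same network configuration and
#'   run length.
#' @return matrix (neurons x intervals).
#' @export
activity_difference_map <- function(a, b) {
  if (!identical(dim(a$activity_map), dim(b$activity_map)))
    stop("activity maps have different dimensions: ",
         paste(dim(a$activity_map), collapse = "x"), " vs ",
         paste(dim(b$activity_map), collapse = "x"), call. = FALSE)
  a$activity_map - b$activity_map
}

#' @export
print.vns_scenario <- function(x, ...) {
  cat(sprintf("<vns_scenario> '%s': %d neurons x %d intervals (%d warm-up)\n",
              x$scenario_name, nrow(x$activity_map), ncol(x$activity_map),
              x$warmup))
  d <- hr_on_off_delta(x)
  cat(sprintf("  classification: %s (ON-OFF delta %s)\n", x$classification,
              if (is.na(d)) "n/a" else sprintf("%+.4f", d)))
  invisible(x)
}

#' Summarise a scenario run
#'
#' @param object a `vns_scenario`.
#' @param ... unused.
#' @return list with ON/OFF heart-rate means, their difference, the
#'   classification, and post-warm-up mean activities per (branch, level).
#' @export
summary.vns_scenario <- function(object, ...) {
  post <- seq_along(object$on_mask) > object$warmup
  m <- object$on_mask[post]
  h <- object$hr_by_interval[post]
  nn <- object$network$neurons
  amap <- object$activity_map[, post, drop = FALSE]
  lv <- expand.grid(branch = BRANCHES, level = 1:3,
                    stringsAsFactors = FALSE)
  lv$mean_activity <- vapply(seq_len(nrow(lv)), function(i) {
    sel <- nn$branch == lv$branch[i] & nn$level == lv$level[i]
    if (!any(sel)) return(NA_real_)
    mean(amap[sel, , drop = FALSE])
  }, numeric(1))
  list(scenario = object$scenario_name,
       classification = object$classification,
       hr_mean_on = if (any(m)) mean(h[m]) else NA_real_,
       hr_mean_off = if (any(!m)) mean(h[!m]) else NA_real_,
       hr_delta = hr_on_off_delta(object),
       level_means = lv,
       n_neurons = nrow(nn),
       n_intervals = length(object$on_mask),
       seed = object$config_snapshot$seed)
}

#' Run the four-regime scenario suite
#'
#' Runs baseline, subthreshold, sympathetic-threshold and parasympathetic-
#' threshold scenarios under one shared seed (identical network and demand
#' realisation, so condition differences are exact ablations) and computes
#' the subthreshold-minus-baseline activity difference map.
#'
#' @param seed shared integer seed.
#' @param ... further arguments to [run_scenario()] (`n_per_level`, `warmup`,
#'   `n_cycles`, ...).
#' @return list with one `vns_scenario` per regime plus `diff_map`
#'   (subthreshold minus baseline).
#' @export
run_suite <- function(seed = 1, ...) {
  res <- lapply(setdiff(SCENARIOS, "custom"), run_scenario, seed = seed, ...)
  names(res) <- setdiff(SCENARIOS, "custom")
  res$diff_map <- activity_difference_map(res$subthreshold, res$baseline)
  res
}
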
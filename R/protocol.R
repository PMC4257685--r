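# VNS duty-cycle scheduling and the two stimulation mechanisms.
#
# Indirect stimulation acts on the network: while ON, heart-rate neurons lose
# sensitivity to (delayed) heart rate and blood-demand neurons gain
# sensitivity to demand, in both branches simultaneously. Direct stimulation
# acts on the motor pathway: while ON, the move coefficient a_r of the direct
# parasympathetic drive is raised. Both are phase-level, non-accumulating
# modifications: OFF intervals restore the baseline values exactly.

#' Define a VNS stimulation protocol
#'
#' The duty cycle mirrors intermittent clinical/experimental stimulation:
#' each cycle is `on_seconds` of stimulation followed by `off_seconds` of
#' rest (the experimental cycle was 14 s ON + 108 s OFF = 122 s).
#'
#' @param on_seconds duration of the ON phase, > 0.
#' @param off_seconds duration of the OFF phase, >= 0.
#' @param n_cycles number of cycles, >= 1.
#' @param delta_H_sens decrease applied to `beta_H` of every heart-rate
#'   neuron while ON (floored so sensitivities never go below 0), >= 0.
#' @param delta_D_sens increase applied to `beta_D` of every blood-demand
#'   neuron while ON, >= 0.
#' @param direct_increment additive increase of the move coefficient `a_r`
#'   while ON, >= 0.
#' @return an object of class `vns_protocol`.
#' @export
#' @examples
#' vns_protocol(delta_H_sens = 0.05, delta_D_sens = 0.05)
vns_protocol <- function(on_seconds = 14, off_seconds = 108, n_cycles = 5,
                         delta_H_sens = 0, delta_D_sens = 0,
                         direct_increment = 0) {
  if (!is.numeric(on_seconds) || on_seconds <= 0)
    stop("protocol field 'on_seconds' must be > 0", call. = FALSE)
  if (!is.numeric(off_seconds) || off_seconds < 0)
    stop("protocol field 'off_seconds' must be >= 0", call. = FALSE)
  if (n_cycles < 1)
    stop("protocol field 'n_cycles' must be >= 1", call. = FALSE)
  if (delta_H_sens < 0 || delta_D_sens < 0 || direct_increment < 0)
    stop("stimulation intensities must be >= 0", call. = FALSE)
  structure(list(on_seconds = on_seconds, off_seconds = off_seconds,
                 n_cycles = as.integer(n_cycles),
                 delta_H_sens = delta_H_sens, delta_D_sens = delta_D_sens,
                 direct_increment = direct_increment),
            class = "vns_protocol")
}

#' @export
print.vns_protocol <- function(x, ...) {
  cat(sprintf("<vns_protocol> %g s ON / %g s OFF (cycle %g s) x %d cycles\n",
              x$on_seconds, x$off_seconds, x$on_seconds + x$off_seconds,
              x$n_cycles))
  cat(sprintf("  indirect: delta_H_sens=%g delta_D_sens=%g | direct: +a_r %g\n",
              x$delta_H_sens, x$delta_D_sens, x$direct_increment))
  invisible(x)
}

#' Build the per-interval ON mask of a protocol
#'
#' Expands the duty cycle into a logical vector with one element per
#' discrete interval: each cycle's first `on_seconds` are ON, the remaining
#' `off_seconds` OFF; total length `n_cycles * (on + off) / interval_duration`
#' intervals.
#'
#' @param protocol a [vns_protocol()].
#' @param interval_duration seconds per interval; must divide both phase
#'   durations within rounding tolerance.
#' @return logical vector, `TRUE` where VNS is ON.
#' @export
#' @examples
#' mask <- build_schedule(vns_protocol(on_seconds = 14, off_seconds = 108,
#'                                     n_cycles = 1), 1)
#' length(mask)   # 122
#' sum(mask)      # 14
build_schedule <- function(protocol, interval_duration = 1) {
  stopifnot(inherits(protocol, "vns_protocol"), interval_duration > 0)
  n_on <- protocol$on_seconds / interval_duration
  n_off <- protocol$off_seconds / interval_duration
  if (abs(n_on - round(n_on)) > 1e-8 || abs(n_off - round(n_off)) > 1e-8)
    stop("interval_duration must divide the ON and OFF phase durations",
         call. = FALSE)
  rep(rep(c(TRUE, FALSE), times = c(round(n_on), round(n_off))),
      times = protocol$n_cycles)
}

#' Apply indirect VNS to the neuron population
#'
#' While ON, every heart-rate neuron's `beta_H` is reduced by
#' `delta_H_sens` (floored at 0) and every blood-demand neuron's `beta_D` is
#' increased by `delta_D_sens`, across both the sympathetic and the
#' parasympathetic branch. While OFF the baseline population is returned
#' unchanged, so the modification never accumulates across cycles.
#'
#' @param network the baseline `vns_network`.
#' @param protocol a [vns_protocol()].
#' @param on logical, is VNS ON this interval?
#' @return a `vns_network` with effective sensitivities for this interval.
#' @export
apply_indirect_stimulation <- function(network, protocol, on) {
  if (!on || (protocol$delta_H_sens == 0 && protocol$delta_D_sens == 0))
    return(network)
  nn <- network$neurons
  hr <- nn$class == "heart_rate"
  bd <- nn$class == "blood_demand"
  nn$beta_H[hr] <- pmax(nn$beta_H[hr] - protocol$delta_H_sens, 0)
  nn$beta_D[bd] <- nn$beta_D[bd] + protocol$delta_D_sens
  network$neurons <- nn
  network
}

#' Apply direct VNS to the parameter set
#'
#' While ON, the move coefficient of the direct parasympathetic pathway
#' becomes `a_r + direct_increment`; while OFF the baseline `a_r` is
#' restored. Non-accumulating: every ON interval sees the same effective
#' value.
#'
#' @param p the baseline [vns_parameters()].
#' @param protocol a [vns_protocol()].
#' @param on logical, is VNS ON this interval?
#' @return a `vns_parameters` object with the effective `a_r`.
#' @export
apply_direct_stimulation <- function(p, protocol, on) {
  if (on) p$a_r <- p$a_r + protocol$direct_increment
  p
}
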
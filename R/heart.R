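# Continuous within-interval heart-rate dynamics and the delayed-feedback
# lookup. Heart rate is the scaled quantity H in [0,1]: H = 1 at the
# prescribed maximum rate, H = 0 at the prescribed base rate.

#' Integrate the heart-rate system over one interval
#'
#' Within an interval the scaled heart rate is a continuous function of time
#' governed by a first-order linear system with time constant `tau_H`
#' (seconds): it relaxes from `H_start` toward the move-determined target
#' `H_start + move`. The closed-form solution
#' `H(t) = target + (H_start - target) * exp(-t / tau_H)` is evaluated on a
#' uniform grid of `n_samples` points spanning the interval (the last sample
#' is at the interval end and becomes the next interval's starting rate);
#' every sample is clipped to \[0,1\].
#'
#' @param H_start scaled heart rate at the start of the interval, in \[0,1\].
#' @param move the per-interval heart-rate increment from [compute_move()].
#' @param p a [vns_parameters()] object (`tau_H`, `interval_duration`).
#' @param n_samples number of within-interval samples, >= 1; defaults to
#'   `p$n_samples`.
#' @return numeric vector of `n_samples` clipped samples of `H(t)`.
#' @export
#' @examples
#' integrate_interval(0.3, move = 0.1, p = vns_parameters(), n_samples = 5)
integrate_interval <- function(H_start, move, p, n_samples = p$n_samples) {
  stopifnot(H_start >= 0, H_start <= 1, is.finite(move), n_samples >= 1)
  target <- H_start + move
  t <- seq_len(n_samples) / n_samples * p$interval_duration
  H <- target + (H_start - target) * exp(-t / p$tau_H)
  pmin(pmax(H, 0), 1)
}

#' Delayed scaled heart rate
#'
#' Returns the interval-start heart rate `tau_delay` whole intervals before
#' the current one: `H_{k - tau_delay}`, with no sub-interval interpolation.
#' During warm-up (fewer than `tau_delay` intervals of history) the earliest
#' recorded rate is used, i.e. the history is padded with the initial value.
#'
#' @param history numeric vector of interval-start rates
#'   `(H_0, H_1, ..., H_k)`, oldest first; the last element is the current
#'   interval's rate.
#' @param tau_delay delay in whole intervals, >= 0.
#' @return scalar delayed rate in \[0,1\].
#' @export
#' @examples
#' delayed_heart_rate(0.01 * 0:20, tau_delay = 5)   # 0.15
delayed_heart_rate <- function(history, tau_delay) {
  stopifnot(length(history) >= 1, tau_delay >= 0)
  history[max(1L, length(history) - as.integer(tau_delay))]
}
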
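# Functional forms of the heart-rate control model, written down once.
#
# Every equation of the model is evaluated through one of the pure functions in
# this file; the rest of the package (and the brute-force oracles in the test
# suite) reference these forms and nothing else.  Sign conventions are fixed by
# the model's qualitative behaviour, which the forms must reproduce:
#
#   * sympathetic efferent drive raises heart rate, both parasympathetic drives
#     lower it (tachycardia under sympathetic dominance, bradycardia when the
#     direct parasympathetic pathway dominates);
#   * the per-neuron increments are deviations of the driving input from the
#     mean activity M of the entire network, which acts as a shared reference:
#     delayed heart rate above M inhibits a sympathetic heart-rate neuron and
#     excites a parasympathetic one, so the heart-rate class closes a delayed
#     negative-feedback loop on rate (the source of the baseline oscillation);
#   * blood demand above M excites a sympathetic blood-demand neuron and
#     inhibits a parasympathetic one, so demand recruits the sympathetic
#     hierarchy. Because blood-demand neurons concentrate at the central
#     level, a stimulated increase of their sensitivity perturbs the network
#     from the top and reaches the cardiac output through networking.
#
# All neuron activities, the scaled heart rate H and blood demand D live in
# [0,1].  Per-interval neuron increments:
#
#   sympathetic     heart-rate  neuron:  dA = -beta_H * (H_d - M)
#   parasympathetic heart-rate  neuron:  dA = +beta_H * (H_d - M)
#   sympathetic     blood-demand neuron: dA = +beta_D * (D   - M)
#   parasympathetic blood-demand neuron: dA = -beta_D * (D   - M)
#   networking (any neuron i):           dA = sum_J w_iJ * (A_J - A_i)
#
# where H_d is heart rate delayed by tau_delay intervals and M is the mean
# activity over the entire network at the current interval.  A neuron carries a
# single response class, so exactly one of beta_H, beta_D is non-zero.
#
# Efferent drives relax with first-order dynamics toward input-dependent fixed
# points (one exact exponential step per interval, factor exp(-1/tau)):
#
#   S*     = g_s * (mean cardiac sympathetic activity        - ref_s)
#   P_ind* = g_p * (mean cardiac indirect parasym. activity  - ref_p)
#   P_dir* = g_r * (beta_H_direct * H_k + beta_D_direct * D_k - ref_r)
#
# The heart-rate move is the net of the three drives,
#
#   dH_k = a_s * S  -  a_p * P_ind  -  a_r * P_dir
#
# and within each interval the scaled heart rate relaxes continuously toward
# the target H_k + dH_k with time constant tau_H (first-order linear system),
# samples clipped to [0,1].

#' Branch sign convention
#'
#' Returns +1 for indirect-parasympathetic neurons and -1 for sympathetic
#' neurons. This single sign carries the branch opposition of the heart-rate
#' and blood-demand increments.
#'
#' @param branch character vector, `"sympathetic"` or
#'   `"parasympathetic_indirect"`.
#' @return numeric vector of +/- 1.
#' @keywords internal
branch_sign <- function(branch) {
  ifelse(branch == "parasympathetic_indirect", 1, -1)
}

#' Heart-rate-driven activity increment of a neuron
#'
#' Increment contributed by delayed heart rate to the state of activity of a
#' heart-rate neuron: `-beta_H * (H_d - M)` for a sympathetic neuron,
#' `+beta_H * (H_d - M)` for an indirect-parasympathetic neuron, where `M` is
#' the mean activity over the entire network. Sympathetic and parasympathetic
#' responses to the same heart-rate error are opposed, closing a delayed
#' negative-feedback loop on rate.
#'
#' @param branch `"sympathetic"` or `"parasympathetic_indirect"` (vectorised).
#' @param beta_H heart-rate sensitivity, >= 0 (zero for blood-demand neurons).
#' @param H_delayed scaled heart rate delayed by `tau_delay` intervals, in
#'   \[0,1\].
#' @param network_mean mean activity over the entire network at the current
#'   interval.
#' @return activity increment (dimensionless).
#' @export
#' @examples
#' heart_rate_delta("sympathetic", 0.1, H_delayed = 0.6, network_mean = 0.4)
heart_rate_delta <- function(branch, beta_H, H_delayed, network_mean) {
  stopifnot(all(H_delayed >= 0 & H_delayed <= 1))
  branch_sign(branch) * beta_H * (H_delayed - network_mean)
}

#' Blood-demand-driven activity increment of a neuron
#'
#' Increment contributed by prevailing blood demand to the state of activity of
#' a blood-demand neuron: `+beta_D * (D - M)` for a sympathetic neuron,
#' `-beta_D * (D - M)` for an indirect-parasympathetic neuron — demand above
#' the shared network-mean reference recruits the sympathetic branch.
#'
#' @param branch `"sympathetic"` or `"parasympathetic_indirect"` (vectorised).
#' @param beta_D blood-demand sensitivity, >= 0 (zero for heart-rate neurons).
#' @param D blood demand at the current interval, in \[0,1\].
#' @param network_mean mean activity over the entire network.
#' @return activity increment (dimensionless).
#' @export
blood_demand_delta <- function(branch, beta_D, D, network_mean) {
  stopifnot(all(D >= 0 & D <= 1))
  -branch_sign(branch) * beta_D * (D - network_mean)
}

#' Fixed point of a first-order efferent drive
#'
#' The input-dependent fixed point toward which a drive relaxes:
#' `gain * (input - ref)`.
#'
#' @param input forcing input (a mean cardiac activity, or the
#'   sensitivity-weighted heart-rate/demand combination of the direct pathway).
#' @param gain pathway gain, >= 0.
#' @param ref pathway reference level.
#' @return the fixed-point drive value.
#' @keywords internal
drive_fixed_point <- function(input, gain, ref) {
  gain * (input - ref)
}

#' One exact first-order relaxation step
#'
#' Advances `x` one interval toward `target` with time constant `tau`
#' (in intervals), using the exact exponential-decay factor `exp(-1/tau)`.
#' Unconditionally stable for any `tau > 0`.
#'
#' @param x current value.
#' @param target fixed point for this interval.
#' @param tau time constant in intervals, > 0.
#' @return the value after one interval.
#' @keywords internal
relax_step <- function(x, target, tau) {
  stopifnot(tau > 0)
  a <- exp(-1 / tau)
  target + (x - target) * a
}
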
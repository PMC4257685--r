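# The three efferent drives and the heart-rate move.
#
# Each drive is a first-order system advanced one interval at a time with the
# exact exponential-decay update (see relax_step); under constant input it
# contracts toward the fixed point gain * (input - ref). Drives are not
# clipped — only activities and the scaled heart rate are range-limited.

#' One interval of the sympathetic efferent drive
#'
#' Relaxes the sympathetic drive `S` toward
#' `g_s * (mean_cardiac_symp - ref_s)` with time constant `tau_s` intervals,
#' where `mean_cardiac_symp` is the mean activity of sympathetic neurons at
#' the cardiac level.
#'
#' @param S_prev drive value at the previous interval.
#' @param mean_cardiac_symp mean cardiac sympathetic activity in \[0,1\].
#' @param p a [vns_parameters()] object.
#' @return the drive value after one interval.
#' @export
step_sympathetic_drive <- function(S_prev, mean_cardiac_symp, p) {
  stopifnot(is.finite(S_prev), is.finite(mean_cardiac_symp))
  relax_step(S_prev, drive_fixed_point(mean_cardiac_symp, p$g_s, p$ref_s),
             p$tau_s)
}

#' One interval of the indirect parasympathetic efferent drive
#'
#' As [step_sympathetic_drive()] with `(g_p, tau_p, ref_p)` and the mean
#' activity of indirect-parasympathetic neurons at the cardiac level — the
#' output of the multi-synapse pathway through the network.
#'
#' @param P_prev drive value at the previous interval.
#' @param mean_cardiac_parasym mean cardiac indirect-parasympathetic activity.
#' @param p a [vns_parameters()] object.
#' @return the drive value after one interval.
#' @export
step_indirect_parasym_drive <- function(P_prev, mean_cardiac_parasym, p) {
  stopifnot(is.finite(P_prev), is.finite(mean_cardiac_parasym))
  relax_step(P_prev, drive_fixed_point(mean_cardiac_parasym, p$g_p, p$ref_p),
             p$tau_p)
}

#' One interval of the direct parasympathetic efferent drive
#'
#' The direct pathway bypasses the network: its drive relaxes toward
#' `g_r * (beta_H_direct * H_k + beta_D_direct * D_k - ref_r)` with time
#' constant `tau_r`, forced by prevailing heart rate and blood demand.
#'
#' @param P_prev drive value at the previous interval.
#' @param H_k prevailing scaled heart rate in \[0,1\].
#' @param D_k prevailing blood demand in \[0,1\].
#' @param p a [vns_parameters()] object.
#' @return the drive value after one interval.
#' @export
step_direct_parasym_drive <- function(P_prev, H_k, D_k, p) {
  stopifnot(is.finite(P_prev), H_k >= 0, H_k <= 1, D_k >= 0, D_k <= 1)
  input <- p$beta_H_direct * H_k + p$beta_D_direct * D_k
  relax_step(P_prev, drive_fixed_point(input, p$g_r, p$ref_r), p$tau_r)
}

#' Heart-rate move: the net of the three efferent contributions
#'
#' `dH_k = a_s * S - a_p * P_ind - a_r * P_dir`: the sympathetic contribution
#' raises heart rate; the indirect and direct parasympathetic contributions
#' lower it. Linear in each move coefficient, so direct VNS (which raises
#' `a_r`) scales the bradycardic pull of the direct pathway.
#'
#' @param S sympathetic drive.
#' @param P_ind indirect parasympathetic drive.
#' @param P_dir direct parasympathetic drive.
#' @param p a [vns_parameters()] object (supplies `a_s`, `a_p`, `a_r`).
#' @return the scaled heart-rate increment for this interval.
#' @export
#' @examples
#' compute_move(S = 0.4, P_ind = 0.1, P_dir = 0.2, p = vns_parameters())
compute_move <- function(S, P_ind, P_dir, p) {
  stopifnot(is.finite(S), is.finite(P_ind), is.finite(P_dir))
  p$a_s * S - p$a_p * P_ind - p$a_r * P_dir
}
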
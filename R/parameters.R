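#' Model parameter set
#'
#' Bundles every scalar constant of the heart-rate control algorithm: the
#' gains, time constants and reference levels of the three efferent pathways,
#' the move coefficients, the direct-pathway sensitivities, the within-interval
#' heart-rate system constants and the heart-rate feedback delay.
#'
#' Defaults place the baseline heart rate in the lower third of its scaled
#' \[0,1\] range, with visible but non-saturating oscillation. Reference
#' levels default to 0 so that all three drives are non-negative whenever
#' their forcing inputs are (activities and rates live in \[0,1\]), keeping
#' the move decomposition interpretable: the sympathetic term raises heart
#' rate, both parasympathetic terms lower it.
#'
#' @param g_s,g_p,g_r pathway gains (sympathetic, indirect parasympathetic,
#'   direct parasympathetic), dimensionless, >= 0.
#' @param tau_s,tau_p,tau_r pathway time constants in intervals, > 0.
#' @param ref_s,ref_p,ref_r pathway reference levels in \[0,1\].
#' @param a_s,a_p,a_r move coefficients weighting the three drives in the
#'   per-interval heart-rate move. Direct VNS acts on `a_r`.
#' @param beta_H_direct,beta_D_direct sensitivities of the direct
#'   parasympathetic pathway to prevailing heart rate and blood demand, >= 0.
#' @param tau_H within-interval heart-rate time constant, seconds, > 0.
#' @param tau_delay heart-rate feedback delay, whole intervals, >= 0.
#' @param interval_duration seconds per discrete interval, > 0.
#' @param n_samples within-interval samples of the continuous heart-rate
#'   trajectory, >= 1.
#' @return an object of class `vns_parameters` (a validated list).
#' @export
#' @examples
#' p <- vns_parameters()
#' p$tau_s
vns_parameters <- function(g_s = 1, g_p = 1, g_r = 1,
                           tau_s = 5, tau_p = 5, tau_r = 5,
                           ref_s = 0, ref_p = 0, ref_r = 0,
                           a_s = 0.1, a_p = 0.1, a_r = 0.1,
                           beta_H_direct = 0.5, beta_D_direct = 0.5,
                           tau_H = 0.5, tau_delay = 3,
                           interval_duration = 1, n_samples = 20) {
  p <- list(g_s = g_s, g_p = g_p, g_r = g_r,
            tau_s = tau_s, tau_p = tau_p, tau_r = tau_r,
            ref_s = ref_s, ref_p = ref_p, ref_r = ref_r,
            a_s = a_s, a_p = a_p, a_r = a_r,
            beta_H_direct = beta_H_direct, beta_D_direct = beta_D_direct,
            tau_H = tau_H, tau_delay = tau_delay,
            interval_duration = interval_duration, n_samples = n_samples)
  class(p) <- "vns_parameters"
  validate_parameters(p)
}

#' @keywords internal
validate_parameters <- function(p) {
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", field, "' must be a single finite number",
           call. = FALSE)
    v
  }
  for (f in c("tau_s", "tau_p", "tau_r", "tau_H", "interval_duration"))
    if (num1(f) <= 0) stop("parameter '", f, "' must be > 0", call. = FALSE)
  for (f in c("g_s", "g_p", "g_r", "beta_H_direct", "beta_D_direct"))
    if (num1(f) < 0) stop("parameter '", f, "' must be >= 0", call. = FALSE)
  for (f in c("ref_s", "ref_p", "ref_r"))
    if (num1(f) < 0 || num1(f) > 1)
      stop("parameter '", f, "' must lie in [0,1]", call. = FALSE)
  if (num1("tau_delay") < 0)
    stop("parameter 'tau_delay' must be >= 0", call. = FALSE)
  if (num1("n_samples") < 1)
    stop("parameter 'n_samples' must be >= 1", call. = FALSE)
  p$tau_delay <- as.integer(round(p$tau_delay))
  p$n_samples <- as.integer(round(p$n_samples))
  p
}

#' @export
print.vns_parameters <- function(x, ...) {
  cat("<vns_parameters>\n")
  cat(sprintf("  gains      g_s=%g g_p=%g g_r=%g\n", x$g_s, x$g_p, x$g_r))
  cat(sprintf("  taus       tau_s=%g tau_p=%g tau_r=%g (intervals)\n",
              x$tau_s, x$tau_p, x$tau_r))
  cat(sprintf("  refs       ref_s=%g ref_p=%g ref_r=%g\n",
              x$ref_s, x$ref_p, x$ref_r))
  cat(sprintf("  move       a_s=%g a_p=%g a_r=%g\n", x$a_s, x$a_p, x$a_r))
  cat(sprintf("  direct     beta_H=%g beta_D=%g\n",
              x$beta_H_direct, x$beta_D_direct))
  cat(sprintf("  heart      tau_H=%gs delay=%d intervals, %gs/interval, %d samples\n",
              x$tau_H, x$tau_delay, x$interval_duration, x$n_samples))
  invisible(x)
}
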
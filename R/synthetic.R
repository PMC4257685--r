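# Synthetic inputs: the blood-demand trace and the canonical / toy network
# fixtures. Every scenario runs from these; no external data are needed.

#' Generate a synthetic blood-demand trace
#'
#' Low constant demand plus low-level Gaussian noise, the regime in which the
#' baseline heart rate shows its characteristic noisy oscillation:
#' `D_k = clip(base_level + eps_k, 0, 1)` with
#' `eps_k ~ N(0, noise_sd^2)` i.i.d. from the seeded generator.
#'
#' @param n_intervals trace length, >= 1.
#' @param base_level constant demand level in \[0,1\]; default 0.2.
#' @param noise_sd noise standard deviation, >= 0; default 0.02.
#' @param seed integer seed; the same arguments always give the same trace.
#' @return an object of class `vns_demand`: the clipped `values` plus the
#'   generating arguments.
#' @export
#' @examples
#' d <- generate_demand(100, seed = 1)
#' range(d$values)
generate_demand <- function(n_intervals, base_level = 0.2, noise_sd = 0.02,
                            seed = 1) {
  if (n_intervals < 1) stop("n_intervals must be >= 1", call. = FALSE)
  if (base_level < 0 || base_level > 1)
    stop("base_level must lie in [0,1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  values <- with_seed(seed, base_level + stats::rnorm(n_intervals, 0, noise_sd))
  structure(list(values = pmin(pmax(values, 0), 1),
                 base_level = base_level, noise_sd = noise_sd, seed = seed),
            class = "vns_demand")
}

#' The canonical network and parameter configuration
#'
#' Builds the full-size configuration: 600 neurons at each of the three
#' levels (1800 total), of which 100 at the cardiac level form the
#' indirect-parasympathetic population; response classes placed per the
#' default level fractions (heart-rate neurons mainly at the cardiac level,
#' blood-demand neurons mainly at the central level). All placement and
#' wiring is reproducible from the seed.
#'
#' @param seed integer seed for class placement.
#' @param n_per_level total neurons per level; default 600. Non-default
#'   values scale the cardiac parasympathetic population proportionally
#'   (1/6 of the level).
#' @param ... further arguments passed to [neuron_population()]
#'   (`hr_fractions`, `beta_H`, `beta_D`, `m`, `w0`).
#' @return list with elements `network` (a `vns_network`) and `parameters`
#'   (a [vns_parameters()] object).
#' @export
#' @examples
#' cfg <- default_network(seed = 1, n_per_level = 60)
#' nrow(cfg$network$neurons)   # 180
default_network <- function(seed = 1, n_per_level = 600, ...) {
  n_par <- round(n_per_level / 6)   # 100 of 600 at the cardiac level
  net <- neuron_population(
    n_sympathetic = c(n_per_level - n_par, n_per_level, n_per_level),
    n_parasympathetic = c(n_par, 0, 0),
    seed = seed, ...)
  list(network = net, parameters = vns_parameters())
}

#' A 12-neuron toy network for brute-force checks
#'
#' Two neurons per branch-level combination (2 branches x 3 levels x 2 = 12),
#' one heart-rate and one blood-demand neuron in each pair, with the default
#' nearest-neighbour wiring. Small enough that every update can be verified
#' by direct per-neuron arithmetic.
#'
#' @param seed integer seed (class placement is deterministic here, the seed
#'   only fixes the draw order).
#' @param beta_H,beta_D,m,w0 passed to [neuron_population()].
#' @return a `vns_network` of 12 neurons.
#' @export
toy_network <- function(seed = 1, beta_H = 0.015, beta_D = 0.015, m = 2,
                        w0 = 0.05) {
  neuron_population(n_sympathetic = c(2, 2, 2),
                    n_parasympathetic = c(2, 2, 2),
                    hr_fractions = c(0.5, 0.5, 0.5),
                    beta_H = beta_H, beta_D = beta_D, m = m, w0 = w0,
                    seed = seed)
}
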
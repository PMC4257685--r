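# Shared fixtures, built in code at test time.

# a hand-specified two-neuron network: one sympathetic heart-rate neuron with
# a single weighted edge to one parasympathetic blood-demand neuron
two_neuron_net <- function(w = 0.5, beta_H = 0.1, beta_D = 0.1) {
  neurons <- data.frame(
    id = 1:2, level = c(1L, 1L), index = 1:2,
    branch = c("sympathetic", "parasympathetic_indirect"),
    class = c("heart_rate", "blood_demand"),
    beta_H = c(beta_H, 0), beta_D = c(0, beta_D),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = 1L, to = 2L, weight = w)
  vnsnet:::as_vns_network(neurons, edges)
}

# independent transcription of the update rule, used as the oracle against
# update_network(); deliberately written as scalar arithmetic (neighbour
# contributions accumulate in increasing-identifier order so the comparison
# is exact to the last bit)
oracle_step <- function(net, x, H_d, D) {
  nn <- net$neurons
  M <- mean(x)
  vapply(seq_len(nrow(nn)), function(i) {
    s <- if (nn$branch[i] == "sympathetic") -1 else 1
    d_h <- s * nn$beta_H[i] * (H_d - M)
    d_d <- -s * nn$beta_D[i] * (D - M)
    e <- net$edges[net$edges$from == nn$id[i], , drop = FALSE]
    e <- e[order(e$to), , drop = FALSE]
    wx <- 0; wtot <- 0
    for (j in seq_len(nrow(e))) {
      wx <- wx + e$weight[j] * x[e$to[j]]
      wtot <- wtot + e$weight[j]
    }
    d_n <- wx - wtot * x[i]
    min(max(((x[i] + d_h) + d_d) + d_n, 0), 1)
  }, numeric(1))
}

expected_class <- c(subthreshold = "none",
                    sympathetic_threshold = "tachycardia",
                    parasympathetic_threshold = "bradycardia")
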
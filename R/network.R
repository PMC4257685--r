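# Neuron population, topology, and the per-interval state update.
#
# A population is a `vns_network`: a node table (one row per neuron), an edge
# list (directed neighbour links with weights), and a cached sparse weight
# matrix used by the vectorised update. Neurons are ordered by
# (branch, level, index) with the sympathetic block first, so exported
# activity maps have a deterministic row order.

BRANCHES <- c("sympathetic", "parasympathetic_indirect")
CLASSES  <- c("heart_rate", "blood_demand")

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the given seed, then restores the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Build a hierarchical neuron population
#'
#' Constructs the three-level network: `n_sympathetic[l]` sympathetic and
#' `n_parasympathetic[l]` indirect-parasympathetic neurons at level `l`
#' (1 = cardiac, 2 = intrathoracic, 3 = central). Each neuron carries one
#' response class — heart-rate or blood-demand — drawn so that a fraction
#' `hr_fractions[l]` of each level's neurons respond to (delayed) heart rate
#' and the remainder to blood demand; heart-rate neurons sit mainly low in
#' the hierarchy, blood-demand neurons mainly at the central level.
#'
#' Topology: each neuron is linked to its `m` nearest same-branch indices
#' within its level (circular index distance) and to the `m` nearest
#' same-branch indices in each adjacent level (proportional index alignment),
#' all with uniform weight `w0`. Neurons never link across more than one
#' level.
#'
#' @param n_sympathetic integer vector, sympathetic neurons per level.
#' @param n_parasympathetic integer vector, indirect-parasympathetic neurons
#'   per level.
#' @param hr_fractions fraction of heart-rate-class neurons per level.
#' @param beta_H,beta_D sensitivities given to heart-rate / blood-demand
#'   neurons respectively (the other sensitivity is exactly 0).
#' @param m neighbours per (level, direction); default 2.
#' @param w0 uniform networking weight; default 0.05.
#' @param seed integer seed controlling the response-class placement.
#' @return an object of class `vns_network`.
#' @export
#' @examples
#' net <- neuron_population(n_sympathetic = c(10, 10, 10),
#'                          n_parasympathetic = c(4, 0, 0), seed = 1)
#' nrow(net$neurons)
neuron_population <- function(n_sympathetic = c(500, 600, 600),
                              n_parasympathetic = c(100, 0, 0),
                              hr_fractions = c(0.8, 0.5, 0.2),
                              beta_H = 0.015, beta_D = 0.015,
                              m = 2, w0 = 0.05, seed = 1) {
  stopifnot(length(n_sympathetic) == 3, length(n_parasympathetic) == 3,
            all(n_sympathetic >= 0), all(n_parasympathetic >= 0),
            length(hr_fractions) == 3,
            all(hr_fractions >= 0 & hr_fractions <= 1),
            beta_H >= 0, beta_D >= 0, m >= 0, is.finite(w0))

  rows <- list()
  for (branch in BRANCHES) {
    counts <- if (branch == "sympathetic") n_sympathetic else n_parasympathetic
    for (level in 1:3) {
      n <- counts[level]
      if (n == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        level = level, index = seq_len(n), branch = branch,
        stringsAsFactors = FALSE)
    }
  }
  neurons <- do.call(rbind, rows)
  neurons$id <- seq_len(nrow(neurons))

  # response-class placement: seeded draw of which indices are heart-rate
  neurons$class <- with_seed(seed, {
    cls <- character(nrow(neurons))
    for (level in 1:3) {
      sel <- which(neurons$level == level)
      n_hr <- round(hr_fractions[level] * length(sel))
      hr_ids <- if (n_hr > 0) sample(sel, n_hr) else integer(0)
      cls[sel] <- "blood_demand"
      cls[hr_ids] <- "heart_rate"
    }
    cls
  })
  neurons$beta_H <- ifelse(neurons$class == "heart_rate", beta_H, 0)
  neurons$beta_D <- ifelse(neurons$class == "blood_demand", beta_D, 0)
  neurons <- neurons[, c("id", "level", "index", "branch", "class",
                         "beta_H", "beta_D")]

  edges <- build_edges(neurons, m = m, w0 = w0)
  as_vns_network(neurons, edges)
}

# m nearest neighbour indices of position p among 1..n (excluding `exclude`),
# deterministic tie-break toward the smaller index
nearest_indices <- function(p, n, m, exclude = NA) {
  if (n == 0 || m == 0) return(integer(0))
  cand <- setdiff(seq_len(n), exclude)
  if (!length(cand)) return(integer(0))
  d <- abs(cand - p)
  d <- pmin(d, n - d)           # circular distance
  cand[order(d, cand)][seq_len(min(m, length(cand)))]
}

build_edges <- function(neurons, m, w0) {
  from <- integer(0); to <- integer(0)
  for (branch in BRANCHES) {
    lvl_ids <- lapply(1:3, function(l)
      neurons$id[neurons$branch == branch & neurons$level == l])
    for (l in 1:3) {
      ids <- lvl_ids[[l]]
      n <- length(ids)
      if (n == 0) next
      for (i in seq_len(n)) {
        nb <- ids[nearest_indices(i, n, m, exclude = i)]
        for (dl in c(-1L, 1L)) {
          l2 <- l + dl
          if (l2 < 1 || l2 > 3) next
          ids2 <- lvl_ids[[l2]]
          n2 <- length(ids2)
          if (n2 == 0) next
          p <- (i - 0.5) / n * n2 + 0.5   # aligned position in the other level
          nb <- c(nb, ids2[nearest_indices(p, n2, m)])
        }
        from <- c(from, rep.int(ids[i], length(nb)))
        to <- c(to, nb)
      }
    }
  }
  data.frame(from = from, to = to,
             weight = rep.int(w0, length(from)))
}

as_vns_network <- function(neurons, edges) {
  n <- nrow(neurons)
  validate_neurons(neurons, edges)
  W <- Matrix::sparseMatrix(i = edges$from, j = edges$to, x = edges$weight,
                            dims = c(n, n))
  net <- list(neurons = neurons, edges = edges, W = W,
              wdeg = Matrix::rowSums(W),
              sign = branch_sign(neurons$branch))
  class(net) <- "vns_network"
  net
}

validate_neurons <- function(neurons, edges) {
  stopifnot(all(neurons$id == seq_len(nrow(neurons))))
  if (!all(neurons$branch %in% BRANCHES))
    stop("unknown branch value in neuron table", call. = FALSE)
  if (!all(neurons$class %in% CLASSES))
    stop("unknown response class in neuron table", call. = FALSE)
  bad <- neurons$class == "heart_rate" & neurons$beta_D != 0 |
         neurons$class == "blood_demand" & neurons$beta_H != 0
  if (any(bad))
    stop("neuron(s) ", paste(neurons$id[bad], collapse = ", "),
         ": a heart-rate neuron must have beta_D = 0 and a blood-demand ",
         "neuron beta_H = 0", call. = FALSE)
  if (any(neurons$beta_H < 0) || any(neurons$beta_D < 0))
    stop("sensitivities must be >= 0", call. = FALSE)
  if (nrow(edges)) {
    if (!all(is.finite(edges$weight)))
      stop("networking weights must be finite", call. = FALSE)
    unknown <- !(edges$to %in% neurons$id) | !(edges$from %in% neurons$id)
    if (any(unknown))
      stop("edge(s) reference unknown neuron identifiers: rows ",
           paste(which(unknown), collapse = ", "), call. = FALSE)
    dl <- abs(neurons$level[edges$from] - neurons$level[edges$to])
    if (any(dl > 1))
      stop("neighbours must lie at the same or an adjacent level; offending ",
           "neuron(s): ", paste(unique(edges$from[dl > 1]), collapse = ", "),
           call. = FALSE)
  }
  invisible(neurons)
}

#' @export
print.vns_network <- function(x, ...) {
  n <- nrow(x$neurons)
  cat(sprintf("<vns_network> %d neurons (%d sympathetic, %d parasympathetic), %d edges\n",
              n, sum(x$neurons$branch == "sympathetic"),
              sum(x$neurons$branch == "parasympathetic_indirect"),
              nrow(x$edges)))
  tab <- table(level = x$neurons$level, class = x$neurons$class)
  print(tab)
  invisible(x)
}

#' Create a network activity state
#'
#' @param network a `vns_network`.
#' @param activity initial activity, a scalar recycled to all neurons or a
#'   vector of per-neuron values in \[0,1\].
#' @param k interval index, >= 0.
#' @return an object of class `vns_state`: interval index `k` and the
#'   per-neuron `activity` vector.
#' @export
network_state <- function(network, activity = 0.5, k = 0L) {
  n <- nrow(network$neurons)
  activity <- rep_len(as.numeric(activity), n)
  stopifnot(all(activity >= 0 & activity <= 1), k >= 0)
  structure(list(k = as.integer(k), activity = activity),
            class = "vns_state")
}

#' Mean activity over the entire network
#'
#' The arithmetic mean over all neurons of both branches, the quantity that
#' enters every heart-rate and blood-demand increment.
#'
#' @param state a `vns_state`.
#' @return scalar in \[0,1\].
#' @export
network_mean <- function(state) mean(state$activity)

#' Networking increment of one neuron
#'
#' The weighted sum over the neuron's neighbours J of
#' `w_iJ * (activity_J - activity_i)`, evaluated at the state's interval.
#' Zero for a neuron with no neighbours.
#'
#' @param network a `vns_network`.
#' @param state a `vns_state`.
#' @param id neuron identifier.
#' @return scalar activity increment.
#' @export
networking_delta <- function(network, state, id) {
  stopifnot(length(id) == 1L)
  if (!id %in% network$neurons$id)
    stop("networking_delta: unknown neuron identifier ", id, call. = FALSE)
  e <- network$edges[network$edges$from == id, , drop = FALSE]
  if (!nrow(e)) return(0)
  if (any(e$to > length(state$activity)))
    stop("neuron ", id, ": neighbour identifier(s) ",
         paste(e$to[e$to > length(state$activity)], collapse = ", "),
         " do not resolve in the state", call. = FALSE)
  sum(e$weight * (state$activity[e$to] - state$activity[id]))
}

#' Advance the whole network one interval
#'
#' Synchronous update: every neuron's new activity is its old activity plus
#' the sum of its heart-rate, blood-demand and networking increments, all
#' evaluated on interval-`k` values, then clipped to \[0,1\]. The interval
#' index advances by 1. Deterministic given identical inputs.
#'
#' @param state a `vns_state`.
#' @param network a `vns_network` (its `beta_H`/`beta_D` columns are the
#'   effective sensitivities for this interval, i.e. after any stimulation).
#' @param H_delayed delayed scaled heart rate in \[0,1\].
#' @param D blood demand in \[0,1\].
#' @return the new `vns_state`.
#' @export
update_network <- function(state, network, H_delayed, D) {
  stopifnot(inherits(state, "vns_state"),
            H_delayed >= 0, H_delayed <= 1, D >= 0, D <= 1)
  x <- state$activity
  M <- mean(x)
  nn <- network$neurons
  d_h <- network$sign * nn$beta_H * (H_delayed - M)
  d_d <- -network$sign * nn$beta_D * (D - M)
  d_net <- as.numeric(network$W %*% x) - network$wdeg * x
  structure(list(k = state$k + 1L,
                 activity = pmin(pmax(x + d_h + d_d + d_net, 0), 1)),
            class = "vns_state")
}

#' Mean activity of cardiac-level neurons of one branch
#'
#' The forcing input of the sympathetic (over the N_s cardiac sympathetic
#' neurons) and indirect parasympathetic (over the N_p cardiac parasympathetic
#' neurons) efferent drives.
#'
#' @param state a `vns_state`.
#' @param network a `vns_network`.
#' @param branch `"sympathetic"` or `"parasympathetic_indirect"`.
#' @return scalar in \[0,1\].
#' @export
mean_cardiac_activity <- function(state, network, branch) {
  branch <- match.arg(branch, BRANCHES)
  sel <- network$neurons$level == 1L & network$neurons$branch == branch
  if (!any(sel))
    stop("no ", branch, " neurons at the cardiac level", call. = FALSE)
  mean(state$activity[sel])
}

#' Write / read a network as plain TSV
#'
#' `write_network_tsv()` writes `<stem>_nodes.tsv` (one row per neuron:
#' id, level, index, branch, class, beta_H, beta_D) and `<stem>_edges.tsv`
#' (from, to, weight). `read_network_tsv()` rebuilds the `vns_network`,
#' re-validating all invariants.
#'
#' @param network a `vns_network`.
#' @param stem path stem for the two files.
#' @return `write_network_tsv()` the stem, invisibly; `read_network_tsv()`
#'   a `vns_network`.
#' @export
write_network_tsv <- function(network, stem) {
  utils::write.table(network$neurons, paste0(stem, "_nodes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(network$edges, paste0(stem, "_edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(stem) {
  neurons <- utils::read.table(paste0(stem, "_nodes.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
  edges <- utils::read.table(paste0(stem, "_edges.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  as_vns_network(neurons, edges)
}
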
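#' Construct a discrete Bayesian network
#'
#' A `bn_network` holds a directed acyclic graph over discrete variables,
#' per-node state spaces, and (optionally) the conditional probability
#' tables (CPTs). CPTs are stored as a tibble with one row per
#' `(node, parent configuration j, state k)` triple, the tidy format used
#' throughout the package.
#'
#' Parent configurations are indexed `j = 1, ..., q_i` by a mixed-radix
#' encoding of the parent states in declared parent order, with the first
#' parent most significant. States are indexed `k = 1, ..., r_i`; state
#' labels default to `"0", "1", ...`.
#'
#' @param nodes Character vector of variable names.
#' @param parents Named list mapping each node to a character vector of its
#'   parents (possibly empty). Missing nodes get no parents.
#' @param cardinalities Named integer vector of state counts (each >= 2).
#' @param states Optional named list of state-label character vectors.
#' @param cpt Optional tibble with columns `node`, `j`, `k`, `prob` giving
#'   the true parameters; each row `(node, j)` must sum to 1.
#' @return An object of class `bn_network` with fields `nodes`, `parents`,
#'   `cardinalities`, `states`, `q` (parent-configuration counts),
#'   `order` (a topological order) and `cpt`.
#' @examples
#' net <- bn_network(
#'   nodes = c("BT", "IS", "C"),
#'   parents = list(C = c("BT", "IS")),
#'   cardinalities = c(BT = 2, IS = 2, C = 2)
#' )
#' net$q[["C"]] # 4 parent configurations
#' @export
bn_network <- function(nodes, parents = list(), cardinalities, states = NULL,
                       cpt = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("duplicate node names")
  parents <- modifyList(setNames(rep(list(character()), length(nodes)), nodes),
                        as.list(parents))
  parents <- parents[nodes]
  bad <- setdiff(unlist(parents), nodes)
  if (length(bad)) abort(paste0("unknown parent(s): ", toString(bad)))
  cardinalities <- setNames(as.integer(cardinalities[nodes]), nodes)
  if (anyNA(cardinalities)) abort("cardinality missing for some node")
  if (any(cardinalities < 2)) {
    abort(paste0("cardinality < 2 for node(s): ",
                 toString(nodes[cardinalities < 2])))
  }
  if (is.null(states)) {
    states <- lapply(cardinalities, function(r) as.character(seq_len(r) - 1L))
  }
  states <- states[nodes]
  stopifnot(all(lengths(states) == cardinalities))

  ord <- topo_order(nodes, parents)
  q <- vapply(nodes, function(nd) {
    as.integer(prod(cardinalities[parents[[nd]]]))
  }, integer(1))

  net <- structure(
    list(nodes = nodes, parents = parents, cardinalities = cardinalities,
         states = states, q = setNames(q, nodes), order = ord, cpt = NULL),
    class = "bn_network"
  )
  if (!is.null(cpt)) net <- set_cpt(net, cpt)
  net
}

# Kahn's algorithm; reports a cycle by name on failure.
topo_order <- function(nodes, parents) {
  indeg <- vapply(parents, length, integer(1))
  ord <- character(0)
  ready <- nodes[indeg == 0]
  indeg <- setNames(indeg, nodes)
  children <- lapply(setNames(nodes, nodes), function(nd) {
    nodes[vapply(parents, function(p) nd %in% p, logical(1))]
  })
  while (length(ready)) {
    nd <- ready[[1]]
    ready <- ready[-1]
    ord <- c(ord, nd)
    for (ch in children[[nd]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(ord) < length(nodes)) {
    abort(paste0("cycle detected among nodes: ",
                 toString(setdiff(nodes, ord))))
  }
  ord
}

#' Attach (true) parameters to a network
#'
#' @param net A [bn_network()].
#' @param cpt Tibble with columns `node`, `j`, `k`, `prob`.
#' @return The network with validated `cpt`.
#' @export
set_cpt <- function(net, cpt) {
  cpt <- as_tibble(cpt)
  mats <- cpt_to_matrices(net, cpt)
  check_prob_rows(mats)
  net$cpt <- matrices_to_cpt(net, mats)
  net
}

#' @export
print.bn_network <- function(x, ...) {
  cat("<bn_network> ", length(x$nodes), " nodes\n", sep = "")
  for (nd in x$nodes) {
    cat("  ", nd, " (r=", x$cardinalities[[nd]], ", q=", x$q[[nd]], ")",
        if (length(x$parents[[nd]]))
          paste0(" <- ", paste(x$parents[[nd]], collapse = ", ")) else "",
        "\n", sep = "")
  }
  cat("  parameters:", if (is.null(x$cpt)) "absent" else "present", "\n")
  invisible(x)
}

#' Map between parent states and configuration indices
#'
#' `config_index()` encodes a named vector of 1-based parent state indices
#' into the configuration index `j`; `parent_config()` decodes `j` back.
#' The first declared parent is the most significant digit.
#'
#' @param net A [bn_network()].
#' @param node Node name.
#' @param parent_states Named integer vector of 1-based state indices, one
#'   per parent of `node`.
#' @return `config_index()`: integer `j`; `parent_config()`: named integer
#'   vector of parent state indices.
#' @export
config_index <- function(net, node, parent_states) {
  ps <- net$parents[[node]]
  if (!length(ps)) return(1L)
  s <- parent_states[ps]
  if (anyNA(s)) abort("parent state missing in 'parent_states'")
  r <- net$cardinalities[ps]
  if (any(s < 1L | s > r)) abort("parent state index out of range")
  j <- 0L
  for (m in seq_along(ps)) j <- j * r[[m]] + (s[[m]] - 1L)
  j + 1L
}

#' @rdname config_index
#' @param j Configuration index in `1..q_i`.
#' @export
parent_config <- function(net, node, j) {
  ps <- net$parents[[node]]
  if (!length(ps)) return(setNames(integer(0), character(0)))
  r <- net$cardinalities[ps]
  rem <- as.integer(j) - 1L
  s <- integer(length(ps))
  for (m in rev(seq_along(ps))) {
    s[m] <- rem %% r[[m]] + 1L
    rem <- rem %/% r[[m]]
  }
  setNames(s, ps)
}

# Human-readable label "BT=1,IS=0" for reports.
config_label <- function(net, node, j) {
  sts <- parent_config(net, node, j)
  if (!length(sts)) return("(root)")
  paste(vapply(names(sts), function(p) {
    paste0(p, "=", net$states[[p]][sts[[p]]])
  }, character(1)), collapse = ",")
}

#' Exact joint distribution of a network
#'
#' Enumerates all joint outcomes and multiplies CPT entries; intended for
#' small networks (the outcome count must not exceed `max_outcomes`).
#'
#' @param net A [bn_network()] with parameters attached.
#' @param params Optional cpt tibble to use instead of `net$cpt`.
#' @param max_outcomes Guard on the joint state-space size.
#' @return Tibble with one integer state-index column per node and a `p`
#'   column summing to 1.
#' @export
joint_distribution <- function(net, params = NULL, max_outcomes = 1e6) {
  cpt <- params %||% net$cpt
  if (is.null(cpt)) abort("network has no parameters; supply 'params'")
  mats <- cpt_to_matrices(net, cpt)
  n_out <- prod(as.numeric(net$cardinalities))
  if (n_out > max_outcomes) abort("joint state space too large to enumerate")
  grid <- do.call(expand.grid, c(lapply(net$cardinalities, seq_len),
                                 KEEP.OUT.ATTRS = FALSE))
  names(grid) <- net$nodes
  p <- rep(1, nrow(grid))
  for (nd in net$nodes) {
    j <- config_index_vec(net, nd, grid)
    p <- p * mats[[nd]][cbind(j, grid[[nd]])]
  }
  out <- as_tibble(grid)
  out$p <- p
  out
}

# Vectorized configuration index over a data frame of state-index columns.
config_index_vec <- function(net, node, data) {
  ps <- net$parents[[node]]
  if (!length(ps)) return(rep(1L, nrow(data)))
  r <- net$cardinalities[ps]
  j <- rep(0, nrow(data))
  for (m in seq_along(ps)) j <- j * r[[m]] + (data[[ps[m]]] - 1L)
  as.integer(j + 1L)
}

#' Joint Kullback-Leibler divergence between true and estimated parameters
#'
#' Computes `KL(P* || P-hat)` between the joint distributions induced by the
#' network's true parameters and an estimated parameter set on the same
#' structure, via the factorized form
#' `sum_i sum_j P*(pa_i = j) sum_k t*_ijk log(t*_ijk / t-hat_ijk)`,
#' with parent-configuration marginals obtained by exact enumeration of the
#' true joint. If the estimate places probability 0 where the truth is
#' positive (with positive parent mass), the divergence is `Inf`.
#'
#' @param true_net A [bn_network()] with true parameters attached.
#' @param est Estimated parameters: a cpt tibble for the same structure.
#' @param type `"joint"` (default) for the joint-distribution divergence, or
#'   `"row_mean"` for the unweighted mean of per-row divergences.
#' @return A nonnegative scalar (possibly `Inf`).
#' @export
joint_kl <- function(true_net, est, type = c("joint", "row_mean")) {
  type <- match.arg(type)
  if (is.null(true_net$cpt)) abort("true_net has no parameters")
  tm <- cpt_to_matrices(true_net, true_net$cpt)
  em <- cpt_to_matrices(true_net, est)
  check_prob_rows(em, tol = 1e-6, what = "estimate")

  row_kl <- function(p, q) {
    pos <- p > 0
    if (any(q[pos] <= 0)) return(Inf)
    sum(p[pos] * log(p[pos] / q[pos]))
  }

  if (type == "row_mean") {
    kls <- unlist(lapply(true_net$nodes, function(nd) {
      vapply(seq_len(true_net$q[[nd]]),
             function(j) row_kl(tm[[nd]][j, ], em[[nd]][j, ]), numeric(1))
    }))
    return(mean(kls))
  }

  joint <- joint_distribution(true_net)
  total <- 0
  for (nd in true_net$nodes) {
    j <- config_index_vec(true_net, nd, joint)
    w <- vapply(seq_len(true_net$q[[nd]]),
                function(jj) sum(joint$p[j == jj]), numeric(1))
    for (jj in which(w > 0)) {
      kl <- row_kl(tm[[nd]][jj, ], em[[nd]][jj, ])
      if (!is.finite(kl)) return(Inf)
      total <- total + w[jj] * kl
    }
  }
  total
}

#' Sample-complexity lower bound for ML parameter learning
#'
#' Evaluates the lower bound on the number of complete samples needed for
#' maximum-likelihood parameter learning of a binary network with `n` nodes
#' and at most `k` parents per node to reach error rate `eps` with
#' confidence `1 - delta`:
#' `288 n^2 2^k / eps^2 * ln^2(1 + 3n/eps) * ln((1 + 3n/eps) / (eps delta))`.
#' The grouping of the final logarithm follows the reading
#' `ln((1 + 3n/eps) / (eps delta))`.
#'
#' @param n Number of nodes (>= 1).
#' @param k Maximum number of parents (>= 0).
#' @param eps Error rate (> 0).
#' @param delta Confidence complement in (0, 1).
#' @return The bound (a positive real, typically very large).
#' @export
dasgupta_sample_bound <- function(n, k, eps, delta) {
  if (n < 1 || k < 0) abort("need n >= 1 and k >= 0")
  if (eps <= 0 || delta <= 0 || delta >= 1) {
    abort("need eps > 0 and 0 < delta < 1")
  }
  u <- 1 + 3 * n / eps
  288 * n^2 * 2^k / eps^2 * log(u)^2 * log(u / (eps * delta))
}
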
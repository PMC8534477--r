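#' Forward (ancestral) sampling from a network
#'
#' Draws complete records in topological order, each node sampled from its
#' CPT row given the already-sampled parent states.
#'
#' @param net A [bn_network()] with parameters attached.
#' @param n Number of records (>= 0).
#' @param seed Integer seed; sampling is reproducible given the seed.
#' @return Dataset tibble: one integer column of 1-based state indices per
#'   node, `n` rows.
#' @export
forward_sample <- function(net, n, seed) {
  if (is.null(net$cpt)) abort("forward_sample needs true parameters on net")
  n <- as.integer(n)
  if (n < 0) abort("n must be >= 0")
  mats <- cpt_to_matrices(net, net$cpt)
  cols <- setNames(rep(list(integer(n)), length(net$nodes)), net$nodes)
  if (n > 0) {
    withr::with_seed(as.integer(seed), {
      df <- as.data.frame(cols)
      for (nd in net$order) {
        j <- config_index_vec(net, nd, df)
        u <- runif(n)
        cum <- t(apply(mats[[nd]], 1, cumsum))
        # row-wise inverse-CDF lookup
        df[[nd]] <- vapply(seq_len(n), function(i) {
          1L + sum(u[i] > cum[j[i], ] + 1e-15)
        }, integer(1))
        df[[nd]] <- pmin(df[[nd]], net$cardinalities[[nd]])
      }
      cols <- as.list(df)
    })
  }
  as_tibble(cols[net$nodes])
}

#' Sufficient statistics of a complete dataset
#'
#' Tallies `N_ijk`, the number of records where node `i` is in state `k`
#' and its parents are in configuration `j`. The returned table is
#' complete: every `(node, j, k)` triple appears, zeros included.
#'
#' @param data Dataset tibble of 1-based state indices.
#' @param net A [bn_network()].
#' @return Count tibble with columns `node`, `j`, `k`, `n`.
#' @export
count_sufficient_stats <- function(data, net) {
  for (nd in net$nodes) {
    v <- data[[nd]]
    if (is.null(v)) abort(paste0("dataset lacks column '", nd, "'"))
    bad <- which(v < 1L | v > net$cardinalities[[nd]] | v != as.integer(v))
    if (length(bad)) {
      abort(paste0("out-of-range state for node '", nd, "' at record ",
                   bad[1]))
    }
  }
  rows <- lapply(net$nodes, function(nd) {
    q <- net$q[[nd]]; r <- net$cardinalities[[nd]]
    m <- matrix(0L, q, r)
    if (nrow(data) > 0) {
      j <- config_index_vec(net, nd, data)
      tab <- table(factor(j, levels = seq_len(q)),
                   factor(data[[nd]], levels = seq_len(r)))
      m <- matrix(as.integer(tab), q, r)
    }
    tibble(node = nd,
           j = rep(seq_len(q), times = r),
           k = rep(seq_len(r), each = q),
           n = as.vector(m))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$node, .data$j, .data$k)
}

# Row sums N_ij as a tibble (node, j, n_ij).
row_totals <- function(counts) {
  dplyr::summarise(dplyr::group_by(counts, .data$node, .data$j),
                   n_ij = sum(.data$n), .groups = "drop")
}
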
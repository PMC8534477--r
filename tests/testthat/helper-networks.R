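# Shared builders for small fixture networks.

# Two-node chain A -> B with hand-set binary CPTs.
chain2_net <- function(pa = 0.3, pb_given_a = c(0.9, 0.2)) {
  net <- bn_network(c("A", "B"), parents = list(B = "A"),
                    cardinalities = c(A = 2, B = 2))
  cpt <- dplyr::bind_rows(
    tibble::tibble(node = "A", j = 1L, k = 1:2, prob = c(pa, 1 - pa)),
    tibble::tibble(node = "B", j = rep(1:2, 2), k = rep(1:2, each = 2),
                   prob = c(pb_given_a, 1 - pb_given_a))
  )
  set_cpt(net, cpt)
}

# Single binary node with a given marginal.
single_net <- function(p = 0.5) {
  net <- bn_network("X", cardinalities = c(X = 2))
  set_cpt(net, tibble::tibble(node = "X", j = 1L, k = 1:2,
                              prob = c(p, 1 - p)))
}

# A dataset tibble whose sufficient statistics for node C match the
# worked brain-tumor example (record order is irrelevant for counting).
brain_tumor_dataset <- function() {
  ex <- brain_tumor_example()
  rows <- list()
  for (i in seq_len(nrow(ex$counts))) {
    r <- ex$counts[i, ]
    if (r$n == 0) next
    cfg <- parent_config(ex$net, "C", r$j)
    rows[[length(rows) + 1]] <- tibble::tibble(
      BT = rep(cfg[["BT"]], r$n), IS = rep(cfg[["IS"]], r$n),
      C = rep(r$k, r$n)
    )
  }
  dplyr::bind_rows(rows)
}

# Random counts for a single row of cardinality r.
random_row_counts <- function(r, n_max = 20) {
  as.integer(stats::rmultinom(1, sample.int(n_max, 1), rdirich(r)))
}

rdirich <- function(r, conc = 1) {
  g <- stats::rgamma(r, conc)
  g / sum(g)
}
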
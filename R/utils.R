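# Internal helpers shared across modules.

# Draw a sub-seed stream from one user-facing seed without touching the
# global RNG state outside withr::with_seed. Values stay below 2^31 - 1.
seed_stream <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Dirichlet draw via normalized gammas; conc may be scalar or length-r.
rdirichlet1 <- function(r, conc) {
  g <- rgamma(r, shape = rep_len(conc, r), rate = 1)
  if (all(g == 0)) g[sample.int(r, 1)] <- 1 # pathological underflow guard
  g / sum(g)
}

# Convert a cpt tibble (node, j, k, prob-ish column) into a per-node list of
# q_i x r_i matrices, and back. Matrices are the internal compute format.
cpt_to_matrices <- function(net, cpt, value_col = "prob") {
  stopifnot(all(c("node", "j", "k") %in% names(cpt)))
  out <- lapply(net$nodes, function(nd) {
    q <- net$q[[nd]]
    r <- net$cardinalities[[nd]]
    m <- matrix(NA_real_, q, r)
    sub <- cpt[cpt$node == nd, ]
    m[cbind(sub$j, sub$k)] <- sub[[value_col]]
    if (anyNA(m)) abort(paste0("incomplete CPT rows for node '", nd, "'"))
    m
  })
  setNames(out, net$nodes)
}

matrices_to_cpt <- function(net, mats, value_col = "prob") {
  rows <- lapply(net$nodes, function(nd) {
    m <- mats[[nd]]
    tibble(
      node = nd,
      j = rep(seq_len(nrow(m)), times = ncol(m)),
      k = rep(seq_len(ncol(m)), each = nrow(m)),
      !!value_col := as.vector(m)
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$node, .data$j, .data$k)
}

# Single-node q x r matrix from a (possibly partial) tidy table.
node_matrix <- function(tbl, net, node, value_col = "prob") {
  q <- net$q[[node]]
  r <- net$cardinalities[[node]]
  m <- matrix(NA_real_, q, r)
  sub <- tbl[tbl$node == node, ]
  m[cbind(sub$j, sub$k)] <- sub[[value_col]]
  if (anyNA(m)) abort(paste0("incomplete table for node '", node, "'"))
  m
}

check_prob_rows <- function(mats, tol = 1e-9, what = "ParameterSet") {
  for (nd in names(mats)) {
    m <- mats[[nd]]
    if (any(m < -tol) || any(m > 1 + tol)) {
      abort(paste0(what, ": entries outside [0,1] for node '", nd, "'"))
    }
    s <- rowSums(m)
    if (any(abs(s - 1) > tol)) {
      abort(paste0(what, ": CPT rows of node '", nd,
                   "' do not sum to 1 (max dev ",
                   format(max(abs(s - 1))), ")"))
    }
  }
  invisible(TRUE)
}
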
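# Cross-validated selection of global and local equivalent sample sizes.

# Fold membership for N records: k-fold random partition, falling back to
# leave-one-out when N < 10 (with a warning when the caller asked for
# k-fold explicitly).
make_folds <- function(n, folds, seed) {
  if (n < 10 && folds < n) {
    inform("fewer than 10 records: falling back to leave-one-out CV")
    folds <- n
  }
  folds <- min(folds, n)
  withr::with_seed(as.integer(seed),
                   sample(rep_len(seq_len(folds), n)))
}

#' Select the global ESS of each node by cross-validation
#'
#' For every node, every candidate equivalent sample size is scored by the
#' summed held-out log-likelihood of the MAP estimates
#' `(N_ijk + a * prior_ijk) / (N_ij + a)` fit on the training folds; the
#' candidate with the highest score wins, ties going to the smallest
#' candidate (weakest prior influence).
#'
#' @param data Dataset tibble.
#' @param net A [bn_network()].
#' @param prior cpt tibble from [elicit_prior()].
#' @param candidates Integer candidate grid (default `1:50`).
#' @param folds Number of CV folds (default 5); leave-one-out below 10
#'   records.
#' @param seed Integer seed controlling the fold split.
#' @return Tibble `(node, ess)` with attribute `trace`, a tibble
#'   `(node, candidate, loglik)` of the CV surface.
#' @export
cross_validate_global_ess <- function(data, net, prior, candidates = 1:50,
                                      folds = 5, seed = 1) {
  if (!length(candidates)) abort("empty candidate grid")
  if (!nrow(data)) abort("empty dataset")
  candidates <- sort(unique(as.numeric(candidates)))
  pm <- cpt_to_matrices(net, prior)
  fold_id <- make_folds(nrow(data), folds, seed)

  trace <- list()
  picks <- list()
  for (nd in net$nodes) {
    j_all <- config_index_vec(net, nd, data)
    k_all <- data[[nd]]
    q <- net$q[[nd]]; r <- net$cardinalities[[nd]]
    score <- numeric(length(candidates))
    for (f in sort(unique(fold_id))) {
      te <- fold_id == f
      Ntr <- matrix(0, q, r)
      tb <- table(factor(j_all[!te], levels = seq_len(q)),
                  factor(k_all[!te], levels = seq_len(r)))
      Ntr[] <- as.numeric(tb)
      rowtot <- rowSums(Ntr)
      njk <- Ntr[cbind(j_all[te], k_all[te])]
      nj <- rowtot[j_all[te]]
      p <- pm[[nd]][cbind(j_all[te], k_all[te])]
      for (ci in seq_along(candidates)) {
        a <- candidates[ci]
        th <- (njk + a * p) / (nj + a)
        score[ci] <- score[ci] + sum(log(pmax(th, 1e-300)))
      }
    }
    best <- candidates[which.max(score)] # which.max takes first = smallest
    picks[[nd]] <- tibble(node = nd, ess = best)
    trace[[nd]] <- tibble(node = nd, candidate = candidates,
                          loglik = score)
  }
  out <- dplyr::bind_rows(picks)
  attr(out, "trace") <- dplyr::bind_rows(trace)
  out
}

# CV of a single node's single parent configuration over a candidate grid,
# scored on held-out records falling in that configuration.
cv_local_ess <- function(data, net, node, j, prior_row, candidates,
                         folds, seed) {
  j_all <- config_index_vec(net, node, data)
  k_all <- data[[node]]
  fold_id <- make_folds(nrow(data), folds, seed)
  r <- net$cardinalities[[node]]
  score <- numeric(length(candidates))
  any_test <- FALSE
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    sel <- te & (j_all == j)
    if (!any(sel)) next
    any_test <- TRUE
    ntr <- tabulate(k_all[!te & (j_all == j)], nbins = r)
    nj <- sum(ntr)
    njk <- ntr[k_all[sel]]
    p <- prior_row[k_all[sel]]
    for (ci in seq_along(candidates)) {
      a <- candidates[ci]
      th <- (njk + a * p) / (nj + a)
      score[ci] <- score[ci] + sum(log(pmax(th, 1e-300)))
    }
  }
  if (!any_test) return(candidates[1]) # no signal: smallest admissible
  candidates[which.max(score)]
}

#' Assign local ESS values under constraint-derived bounds
#'
#' Implements the local-ESS procedure: configurations without constraints
#' inherit the global ESS; configurations whose global ESS already meets
#' the constraint-derived lower bound also inherit it; the remaining
#' configurations are cross-validated over integer candidates starting at
#' the ceiling of their bound. Afterwards the resulting MAP estimates are
#' re-checked against the constraints, and any violated cross constraint
#' (whose bound was derived assuming equal ESS on both sides) triggers a
#' joint escalation of the two configurations' ESS along the grid until
#' satisfied or the grid is exhausted.
#'
#' @param net A [bn_network()].
#' @param data Dataset tibble.
#' @param prior cpt tibble from [elicit_prior()].
#' @param cs Constraint tibble.
#' @param global Tibble `(node, ess)` from [cross_validate_global_ess()].
#' @param bounds Bound tibble from [derive_local_bounds()].
#' @param max_candidate Largest candidate ESS (default 50).
#' @param folds,seed CV protocol controls.
#' @return Tibble `(node, j, ess, bound, source)` with attribute `global`;
#'   `source` records how each value was chosen
#'   (`"global"`, `"cv"`, `"bound"`, or `"escalated"`).
#' @export
assign_local_ess <- function(net, data, prior, cs, global, bounds,
                             max_candidate = 50, folds = 5, seed = 1) {
  eb <- effective_bounds(bounds)
  pm <- cpt_to_matrices(net, prior)
  counts <- count_sufficient_stats(data, net)
  seeds <- seed_stream(seed, 2L)

  rows <- list()
  for (nd in net$nodes) {
    g <- global$ess[global$node == nd]
    if (!length(g)) abort(paste0("no global ESS for node '", nd, "'"))
    for (j in seq_len(net$q[[nd]])) {
      b <- eb[eb$node == nd & eb$j == j, ]
      if (!nrow(b)) {
        rows[[length(rows) + 1]] <- tibble(node = nd, j = j, ess = g,
                                           bound = 0, source = "global")
        next
      }
      if (b$unsatisfiable) {
        warn(paste0("unsatisfiable constraint bound at node '", nd,
                    "', configuration ", j,
                    "; falling back to the maximal candidate"))
        rows[[length(rows) + 1]] <- tibble(node = nd, j = j,
                                           ess = max_candidate,
                                           bound = Inf, source = "bound")
        next
      }
      lo <- ceiling(b$bound - 1e-9)
      if (g >= lo) {
        rows[[length(rows) + 1]] <- tibble(node = nd, j = j, ess = g,
                                           bound = b$bound,
                                           source = "global")
      } else if (lo > max_candidate) {
        warn(paste0("bound ", round(b$bound, 2), " exceeds the candidate",
                    " grid at node '", nd, "', configuration ", j))
        rows[[length(rows) + 1]] <- tibble(node = nd, j = j,
                                           ess = as.numeric(lo),
                                           bound = b$bound,
                                           source = "bound")
      } else {
        cand <- seq.int(max(lo, 1L), max_candidate)
        pick <- cv_local_ess(data, net, nd, j, pm[[nd]][j, ], cand,
                             folds, seeds[1])
        rows[[length(rows) + 1]] <- tibble(node = nd, j = j,
                                           ess = as.numeric(pick),
                                           bound = b$bound, source = "cv")
      }
    }
  }
  ess <- dplyr::bind_rows(rows)

  # Post-hoc guarantee pass for cross constraints: the bound assumed equal
  # ESS on both configurations; unequal assignments can still violate.
  est <- map_estimate(counts, prior, ess)
  for (pass in 1:3) {
    viol <- check_satisfaction(est, cs, net)
    cross_viol <- viol[viol$type == "cross", ]
    if (!nrow(cross_viol)) break
    for (vid in cross_viol$id) {
      r <- cs[cs$id == vid, ]
      i1 <- which(ess$node == r$node & ess$j == r$j)
      i2 <- which(ess$node == r$node & ess$j == r$j2)
      a <- max(ess$ess[c(i1, i2)])
      repeat {
        ess$ess[c(i1, i2)] <- a
        ess$source[c(i1, i2)] <- "escalated"
        est <- map_estimate(counts, prior, ess)
        if (!nrow(check_satisfaction(est, cs[cs$id == vid, ], net)) ||
            a >= max_candidate) break
        a <- a + 1
      }
    }
  }
  attr(ess, "global") <- global
  ess
}
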
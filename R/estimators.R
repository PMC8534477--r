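#' Baseline and MAP parameter estimators
#'
#' `ml_estimate()` is the purely data-driven maximum-likelihood estimate
#' `N_ijk / N_ij` (rows with no observations fall back to uniform, with a
#' message). `map_estimate()` is the Dirichlet-prior MAP estimate
#' `(N_ijk + a_ij * prior_ijk) / (N_ij + a_ij)`; `map_uniform()` is its
#' uniform-prior special case with ESS 1, the classic MAP baseline.
#'
#' @param counts Count tibble from [count_sufficient_stats()].
#' @param prior cpt tibble of prior means.
#' @param ess Equivalent sample size: a single number (applied
#'   everywhere), a tibble `(node, ess)` of global values, or a tibble
#'   `(node, j, ess)` of local values.
#' @return cpt tibble (`node`, `j`, `k`, `prob`); every row sums to 1.
#' @examples
#' counts <- tibble::tibble(node = "X", j = 1L, k = 1:2, n = c(1L, 6L))
#' prior <- tibble::tibble(node = "X", j = 1L, k = 1:2, prob = c(0.8, 0.2))
#' map_estimate(counts, prior, ess = 5) # 0.42 / 0.58
#' @name estimators
NULL

# Minimal network-shape stand-in derived from a counts/cpt tibble, for
# operations that only need (nodes, q, r), not the graph.
shape_from_table <- function(tbl) {
  agg <- dplyr::summarise(dplyr::group_by(tbl, .data$node),
                          q = max(.data$j), r = max(.data$k),
                          .groups = "drop")
  list(nodes = agg$node,
       q = setNames(as.integer(agg$q), agg$node),
       cardinalities = setNames(as.integer(agg$r), agg$node))
}

#' @rdname estimators
#' @export
ml_estimate <- function(counts) {
  shp <- shape_from_table(counts)
  nm <- cpt_to_matrices(shp, counts, value_col = "n")
  mats <- lapply(setNames(shp$nodes, shp$nodes), function(nd) {
    m <- nm[[nd]]
    tot <- rowSums(m)
    empty <- tot == 0
    if (any(empty)) {
      inform(paste0("node '", nd, "': ", sum(empty),
                    " unobserved row(s) set to uniform"))
      m[empty, ] <- 1
      tot[empty] <- ncol(m)
    }
    m / tot
  })
  matrices_to_cpt(shp, mats)
}

# Resolve the flexible 'ess' argument into per-(node, j) values.
resolve_ess <- function(ess, shp) {
  grid <- dplyr::bind_rows(lapply(shp$nodes, function(nd) {
    tibble(node = nd, j = seq_len(shp$q[[nd]]))
  }))
  if (is.numeric(ess) && length(ess) == 1) {
    grid$ess <- as.numeric(ess)
    return(grid)
  }
  ess <- as_tibble(ess)
  if (!"j" %in% names(ess)) {
    out <- dplyr::left_join(grid, ess[c("node", "ess")], by = "node")
  } else {
    out <- dplyr::left_join(grid, ess[c("node", "j", "ess")],
                            by = c("node", "j"))
  }
  if (anyNA(out$ess)) abort("ess missing for some (node, configuration)")
  out
}

#' @rdname estimators
#' @export
map_estimate <- function(counts, prior, ess) {
  shp <- shape_from_table(counts)
  nm <- cpt_to_matrices(shp, counts, value_col = "n")
  pm <- cpt_to_matrices(shp, prior)
  ev <- resolve_ess(ess, shp)
  if (any(ev$ess <= 0)) abort("ess values must be positive")
  mats <- lapply(setNames(shp$nodes, shp$nodes), function(nd) {
    m <- nm[[nd]]
    a <- ev$ess[ev$node == nd][order(ev$j[ev$node == nd])]
    (m + a * pm[[nd]]) / (rowSums(m) + a)
  })
  matrices_to_cpt(shp, mats)
}

#' @rdname estimators
#' @export
map_uniform <- function(counts, ess = 1) {
  shp <- shape_from_table(counts)
  prior <- matrices_to_cpt(shp, lapply(
    setNames(shp$nodes, shp$nodes),
    function(nd) matrix(1 / shp$cardinalities[[nd]], shp$q[[nd]],
                        shp$cardinalities[[nd]])
  ))
  map_estimate(counts, prior, ess)
}

# --- constrained optimization machinery -----------------------------------

# Reduce the full-space linear system over a node's flattened CPT (j-major,
# dim q*r) to the free coordinates (all k < r per row), substituting
# x_{j,r} = 1 - sum_{k<r} x_{j,k}.
reduce_system <- function(A, b, q, r) {
  if (!nrow(A)) return(list(A = matrix(0, 0, q * (r - 1)), b = numeric(0)))
  keep <- as.vector(vapply(seq_len(q), function(j) {
    (j - 1L) * r + seq_len(r - 1L)
  }, integer(r - 1L)))
  last <- (seq_len(q) - 1L) * r + r
  Ared <- A[, keep, drop = FALSE]
  for (j in seq_len(q)) {
    cols <- (j - 1L) * (r - 1L) + seq_len(r - 1L)
    Ared[, cols] <- Ared[, cols] - A[, last[j]]
  }
  list(A = Ared, b = b - rowSums(A[, last, drop = FALSE]))
}

expand_reduced <- function(x, q, r) {
  m <- matrix(x, q, r - 1L, byrow = TRUE)
  cbind(m, 1 - rowSums(m))
}

# Maximize a concave objective over one node's constraint polytope with
# constrOptim (log-barrier on the linear inequalities), in reduced simplex
# coordinates. 'fn'/'gr' take and return full q x r matrices; 'gr' is the
# gradient wrt theta.
solve_node_concave <- function(poly, fn, gr, start_full) {
  q <- poly$q; r <- poly$r
  red_le <- reduce_system(rbind(poly$A_le, -poly$A_ge),
                          c(poly$b_le, -poly$b_ge), q, r)
  # nonnegativity of free coords and of the substituted last coords
  d_red <- q * (r - 1L)
  nn_free <- -diag(d_red)
  last_rows <- t(vapply(seq_len(q), function(j) {
    a <- numeric(d_red)
    a[(j - 1L) * (r - 1L) + seq_len(r - 1L)] <- 1
    a
  }, numeric(d_red)))
  ui <- rbind(-red_le$A, -nn_free, -last_rows)
  ci <- c(-red_le$b, numeric(d_red), rep(-1, q))

  x0 <- as.vector(t(start_full[, seq_len(r - 1L), drop = FALSE]))
  # the log-barrier needs a strictly interior start; if the witness sits
  # on a face, pull it towards the uniform center until margins open up
  unif <- as.vector(t(matrix(1 / r, q, r)[, seq_len(r - 1L),
                                          drop = FALSE]))
  margin <- function(x) min(ui %*% x - ci)
  if (margin(x0) < 1e-10) {
    for (lam in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
      cand <- (1 - lam) * x0 + lam * unif
      if (margin(cand) >= 1e-10) { x0 <- cand; break }
    }
    if (margin(x0) < 1e-10) {
      abort("could not find a strictly interior starting point")
    }
  }

  obj <- function(x) -fn(expand_reduced(x, q, r))
  grad <- function(x) {
    g <- gr(expand_reduced(x, q, r)) # q x r gradient wrt theta
    gred <- g[, seq_len(r - 1L), drop = FALSE] - g[, r]
    -as.vector(t(gred))
  }
  # note: a very tight inner reltol lets BFGS land exactly on a face,
  # which breaks the next barrier iteration; keep the default reltol
  res <- constrOptim(x0, f = obj, grad = grad, ui = ui, ci = ci,
                     method = "BFGS", outer.iterations = 50,
                     outer.eps = 1e-7, control = list(maxit = 500))
  expand_reduced(res$par, q, r)
}

#' Constrained maximum-likelihood estimation
#'
#' Maximizes the multinomial log-likelihood of each node's CPT subject to
#' the expert constraints and the simplex conditions — a concave program
#' with linear constraints, solved per node (cross constraints couple the
#' node's rows, so the node's full CPT is optimized jointly). Nodes
#' without constraints reduce to the closed-form ML estimate.
#'
#' @inheritParams estimators
#' @param cs Constraint tibble.
#' @param net A [bn_network()].
#' @return cpt tibble.
#' @export
cml_estimate <- function(counts, cs, net) {
  feas <- feasibility(cs, net)
  if (!feas$feasible) {
    abort(paste0("infeasible constraints on node(s): ",
                 toString(feas$infeasible_nodes)))
  }
  nm <- cpt_to_matrices(net, counts, value_col = "n")
  ml <- suppressMessages(ml_estimate(counts))
  mlm <- cpt_to_matrices(net, ml)
  wm <- cpt_to_matrices(net, feas$witness)
  mats <- list()
  for (nd in net$nodes) {
    if (!any(cs$node == nd)) {
      mats[[nd]] <- mlm[[nd]]
      next
    }
    poly <- node_polytope(cs, net, nd)
    N <- nm[[nd]]
    fn <- function(th) sum(N * log(pmax(th, 1e-300)))
    gr <- function(th) N / pmax(th, 1e-300)
    mats[[nd]] <- solve_node_concave(poly, fn, gr, wm[[nd]])
  }
  matrices_to_cpt(net, mats)
}

#' (Constrained) maximum-entropy estimation
#'
#' Maximizes the summed entropy of the CPT rows subject to the expert
#' constraints, the simplex conditions, and a likelihood slab
#' `loglik(theta) >= max_loglik - me_epsilon * N` (with `max_loglik` the
#' constrained maximum and `N` the dataset size), so the estimate is the
#' most non-committal one whose fit is within `me_epsilon` nats per record
#' of the best achievable. Solved per node by bisection on the Lagrange
#' multiplier of the likelihood constraint; `me_epsilon -> Inf` recovers
#' the uniform distribution, `me_epsilon -> 0` the (constrained) ML
#' estimate. `me_estimate()` is the unconstrained special case.
#'
#' @inheritParams cml_estimate
#' @param me_epsilon Likelihood slack in nats per record (default 0.05).
#' @return cpt tibble.
#' @export
cme_estimate <- function(counts, cs, net, me_epsilon = 0.05) {
  feas <- feasibility(cs, net)
  if (!feas$feasible) {
    abort(paste0("infeasible constraints on node(s): ",
                 toString(feas$infeasible_nodes)))
  }
  nm <- cpt_to_matrices(net, counts, value_col = "n")
  n_records <- sum(nm[[net$nodes[1]]])
  cmlm <- cpt_to_matrices(net, cml_estimate(counts, cs, net))
  wm <- cpt_to_matrices(net, feas$witness)
  mats <- list()
  for (nd in net$nodes) {
    N <- nm[[nd]]
    poly <- node_polytope(cs, net, nd)
    loglik <- function(th) sum(N * log(pmax(th, 1e-300)))
    entropy <- function(th) -sum(th * log(pmax(th, 1e-300)))
    target <- loglik(cmlm[[nd]]) - me_epsilon * n_records

    solve_mu <- function(mu) {
      fn <- function(th) entropy(th) + mu * loglik(th)
      gr <- function(th) -(log(pmax(th, 1e-300)) + 1) +
        mu * N / pmax(th, 1e-300)
      solve_node_concave(poly, fn, gr, wm[[nd]])
    }

    th <- solve_mu(0)
    if (loglik(th) < target - 1e-9) {
      mu_lo <- 0; mu_hi <- 1
      while (loglik(solve_mu(mu_hi)) < target && mu_hi < 1e6) {
        mu_lo <- mu_hi; mu_hi <- mu_hi * 4
      }
      for (it in 1:30) {
        mid <- (mu_lo + mu_hi) / 2
        if (loglik(solve_mu(mid)) >= target) mu_hi <- mid else mu_lo <- mid
        if (mu_hi - mu_lo < 1e-6 * (1 + mu_hi)) break
      }
      th <- solve_mu(mu_hi)
    }
    mats[[nd]] <- th
  }
  matrices_to_cpt(net, mats)
}

#' @rdname cme_estimate
#' @export
me_estimate <- function(counts, net, me_epsilon = 0.05) {
  cme_estimate(counts, empty_constraint_set(), net,
               me_epsilon = me_epsilon)
}
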
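#' ESS lower bounds derived from parameter constraints
#'
#' With an elicited prior row and observed counts, the MAP estimate
#' `(N_ijk + a * prior) / (N_ij + a)` moves monotonically from the
#' data-driven estimate towards the prior as the equivalent sample size
#' `a` grows. When the prior satisfies a constraint that the data violate,
#' the constraint pins down a minimal `a`; these functions return that
#' lower bound. A bound of `0` means the constraint holds for every
#' `a >= 0`; `Inf` means no equivalent sample size can enforce it
#' (unsatisfiable: the prior itself sits on the violating side).
#'
#' `ess_bound_range()` handles `lower <= theta-hat <= upper` for one entry
#' (the bound is the max of the two one-sided requirements);
#' `ess_bound_intra()` handles `theta-hat_k1 <= theta-hat_k2` within one
#' row (shared `N_ij` and `a` cancel); `ess_bound_cross()` handles
#' `theta-hat_j1k <= theta-hat_j2k` across two parent configurations
#' under a common `a`, which yields a quadratic inequality
#' `A a^2 + B a + C <= 0` with
#' `A = prior_j1k - prior_j2k`,
#' `B = N_j1k - N_j2k + N_j2 * prior_j1k - N_j1 * prior_j2k`,
#' `C = N_j2 * N_j1k - N_j1 * N_j2k`; all leading-coefficient sign cases
#' are solved in closed form and the smallest feasible `a >= 0` is
#' returned.
#'
#' @param n_ijk,n_ij Count of the constrained entry and its row total.
#' @param prior Elicited prior probability of the constrained entry.
#' @param lower,upper Range-constraint bounds.
#' @return A nonnegative scalar bound (`Inf` when unsatisfiable).
#' @examples
#' ess_bound_range(1, 7, prior = 0.80, lower = 0.6, upper = 1) # 16
#' @name ess_bounds
NULL

#' @rdname ess_bounds
#' @export
ess_bound_range <- function(n_ijk, n_ij, prior, lower = 0, upper = 1) {
  eps <- 1e-12
  bound <- 0
  # lower side: a (prior - lower) >= lower * N_ij - N_ijk
  need <- lower * n_ij - n_ijk
  if (prior - lower > eps) {
    bound <- max(bound, need / (prior - lower))
  } else if (need > eps) {
    return(Inf) # prior at/below the lower bound while data violate it
  }
  # upper side: a (upper - prior) >= N_ijk - upper * N_ij
  need <- n_ijk - upper * n_ij
  if (upper - prior > eps) {
    bound <- max(bound, need / (upper - prior))
  } else if (need > eps) {
    return(Inf)
  }
  max(bound, 0)
}

#' @rdname ess_bounds
#' @param n_ijk1,n_ijk2 Counts of the lesser and greater state (same row).
#' @param prior_k1,prior_k2 Prior probabilities of the two states.
#' @export
ess_bound_intra <- function(n_ijk1, n_ijk2, prior_k1, prior_k2) {
  eps <- 1e-12
  diff_n <- n_ijk2 - n_ijk1        # >= 0 means data already ordered
  diff_p <- prior_k1 - prior_k2    # < 0 means prior ordered
  if (diff_p < -eps) return(max(0, diff_n / diff_p))
  if (diff_n >= -eps) return(0)    # data ordered; prior tied or reversed
  Inf                              # both prior and data violate
}

#' @rdname ess_bounds
#' @param n_ij1k,n_ij1 Count and row total of the lesser configuration.
#' @param n_ij2k,n_ij2 Count and row total of the greater configuration.
#' @param prior_j1k,prior_j2k Prior probabilities of the shared state
#'   under the two configurations.
#' @export
ess_bound_cross <- function(n_ij1k, n_ij1, n_ij2k, n_ij2,
                            prior_j1k, prior_j2k) {
  eps <- 1e-12
  A <- prior_j1k - prior_j2k
  B <- n_ij1k - n_ij2k + n_ij2 * prior_j1k - n_ij1 * prior_j2k
  C <- n_ij2 * n_ij1k - n_ij1 * n_ij2k

  if (abs(A) <= eps) {                   # linear: B a + C <= 0
    if (abs(B) <= eps) return(if (C <= eps) 0 else Inf)
    if (B < 0) return(max(0, -C / B))
    return(if (C <= eps) 0 else Inf)     # B > 0: only small a work
  }
  disc <- B^2 - 4 * A * C
  if (A < 0) {                           # opens down: <= 0 outside roots
    if (disc <= 0) return(0)
    s <- sqrt(disc)
    r1 <- (-B + s) / (2 * A)             # smaller root (A < 0)
    r2 <- (-B - s) / (2 * A)             # larger root
    if (r1 > r2) { tmp <- r1; r1 <- r2; r2 <- tmp }
    if (r1 >= -eps) return(0)
    return(max(0, r2))
  }
  # A > 0: opens up, <= 0 between roots (if any)
  if (disc < 0) return(Inf)
  s <- sqrt(disc)
  r1 <- (-B - s) / (2 * A)
  r2 <- (-B + s) / (2 * A)
  if (r2 < -eps) return(Inf)
  max(0, r1)
}

#' Derive local ESS bounds for every constraint
#'
#' Dispatches each constraint to its bound operation using the observed
#' counts and the elicited prior. A cross constraint couples two parent
#' configurations and contributes its bound to both.
#'
#' @param counts Count tibble from [count_sufficient_stats()].
#' @param prior cpt tibble from [elicit_prior()].
#' @param cs Constraint tibble.
#' @param net A [bn_network()].
#' @return Tibble with columns `constraint_id`, `type`, `node`, `j`,
#'   `bound` (possibly `Inf`), one row per affected parent configuration.
#' @export
derive_local_bounds <- function(counts, prior, cs, net) {
  needed <- unique(cs$node)
  nm <- lapply(setNames(needed, needed),
               function(nd) node_matrix(counts, net, nd, "n"))
  pm <- lapply(setNames(needed, needed),
               function(nd) node_matrix(prior, net, nd, "prob"))
  rows <- list()
  add <- function(id, type, node, j, bound) {
    rows[[length(rows) + 1]] <<- tibble(constraint_id = id, type = type,
                                        node = node, j = as.integer(j),
                                        bound = bound)
  }
  for (i in seq_len(nrow(cs))) {
    r <- cs[i, ]
    N <- nm[[r$node]]; P <- pm[[r$node]]
    if (r$type == "range") {
      b <- ess_bound_range(N[r$j, r$k], sum(N[r$j, ]), P[r$j, r$k],
                           r$lower, r$upper)
      add(r$id, r$type, r$node, r$j, b)
    } else if (r$type == "intra") {
      b <- ess_bound_intra(N[r$j, r$k], N[r$j, r$k2],
                           P[r$j, r$k], P[r$j, r$k2])
      add(r$id, r$type, r$node, r$j, b)
    } else if (r$type == "cross") {
      b <- ess_bound_cross(N[r$j, r$k], sum(N[r$j, ]),
                           N[r$j2, r$k], sum(N[r$j2, ]),
                           P[r$j, r$k], P[r$j2, r$k])
      add(r$id, r$type, r$node, r$j, b)
      add(r$id, r$type, r$node, r$j2, b)
    }
  }
  if (!length(rows)) {
    return(tibble(constraint_id = integer(), type = character(),
                  node = character(), j = integer(), bound = double()))
  }
  dplyr::bind_rows(rows)
}

# Effective bound per (node, j): max over all bounds naming that
# configuration; Inf bounds are flagged but excluded from the max (the
# caller falls back to the maximal candidate with a warning).
effective_bounds <- function(bounds) {
  if (!nrow(bounds)) {
    return(tibble(node = character(), j = integer(), bound = double(),
                  unsatisfiable = logical()))
  }
  dplyr::summarise(
    dplyr::group_by(bounds, .data$node, .data$j),
    unsatisfiable = any(!is.finite(.data$bound)),
    bound = if (any(is.finite(.data$bound)))
      max(.data$bound[is.finite(.data$bound)]) else 0,
    .groups = "drop"
  )
}
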
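# Hit-and-run sampling of the constraint polytope and prior elicitation.

# One hit-and-run chain over the polytope of a single node. x0 must be
# feasible. Directions are isotropic Gaussian projected onto the tangent
# space of the row-sum equalities; the step is uniform on the feasible
# chord, which makes the stationary distribution uniform over the
# polytope. Returns a matrix of retained points (rows).
hit_and_run <- function(poly, x0, n_keep, tau, burn_in = 100,
                        max_retries = 50) {
  d <- poly$d
  A <- rbind(poly$A_le, -poly$A_ge)            # all as a' x <= b
  b <- c(poly$b_le, -poly$b_ge)
  x <- x0
  kept <- matrix(NA_real_, n_keep, d)
  n_kept <- 0L
  tau_cur <- tau
  halvings <- 0L
  retries <- 0L

  step <- function(x) {
    for (try in 1:20) {
      dir <- project_directions(rnorm(d), poly$blocks)
      nn <- sqrt(sum(dir^2))
      if (nn < 1e-12) next
      dir <- dir / nn
      # chord limits from nonnegativity ...
      lo <- -Inf; hi <- Inf
      pos <- dir > 1e-14; neg <- dir < -1e-14
      if (any(neg)) hi <- min(hi, min(-x[neg] / dir[neg]))
      if (any(pos)) lo <- max(lo, max(-x[pos] / dir[pos]))
      # ... and from the declared inequalities
      if (nrow(A)) {
        s <- as.vector(A %*% dir)
        gap <- b - as.vector(A %*% x)
        up <- s > 1e-14; dn <- s < -1e-14
        if (any(up)) hi <- min(hi, min(gap[up] / s[up]))
        if (any(dn)) lo <- max(lo, max(gap[dn] / s[dn]))
      }
      if (!is.finite(lo) || !is.finite(hi) || hi - lo < 1e-12) next
      eps <- 1e-9 * (hi - lo)
      t <- runif(1, lo + eps, hi - eps)
      return(x + t * dir)
    }
    x # degenerate polytope: stay put
  }

  for (i in seq_len(burn_in)) x <- step(x)
  prev <- NULL
  while (n_kept < n_keep) {
    x <- step(x)
    if (!is.null(prev) && tau_cur > 0 &&
        sqrt(sum((x - prev)^2)) < tau_cur) {
      retries <- retries + 1L
      if (retries > max_retries) {
        halvings <- halvings + 1L
        retries <- 0L
        if (halvings > 10L) {
          warn("diversity separation unreachable; dropping it")
          tau_cur <- 0
        } else {
          tau_cur <- tau_cur / 2
        }
      }
      next
    }
    retries <- 0L
    n_kept <- n_kept + 1L
    kept[n_kept, ] <- x
    prev <- x
  }
  kept
}

#' Sample feasible parameter points for one node
#'
#' Draws points uniformly from the constraint polytope of one node
#' (declared constraints intersected with the probability simplex of each
#' CPT row) by hit-and-run, started at the polytope's Chebyshev center
#' after a burn-in. Consecutive retained points are kept at Euclidean
#' distance at least `tau` from one another (candidates closer than that
#' are rejected); if the polytope is too small for the requested
#' separation, `tau` is halved up to 10 times, then dropped with a
#' warning.
#'
#' @param net A [bn_network()].
#' @param cs Constraint tibble (may be empty: bare-simplex sampling).
#' @param node Node name.
#' @param n_samples Number of retained points.
#' @param tau Diversity separation (default 0.1).
#' @param burn_in Burn-in steps from the Chebyshev-center start.
#' @param seed Integer seed.
#' @return Matrix with `n_samples` rows; columns are the flattened CPT of
#'   `node` in `(j, k)` order (`j`-major).
#' @export
sample_feasible_points <- function(net, cs, node, n_samples, tau = 0.1,
                                   burn_in = 100, seed = 1) {
  cs <- cs %||% empty_constraint_set()
  poly <- node_polytope(cs, net, node)
  cc <- chebyshev_center(poly)
  if (is.null(cc)) {
    abort(paste0("constraint polytope of node '", node,
                 "' is infeasible; cannot elicit a prior"))
  }
  withr::with_seed(as.integer(seed),
                   hit_and_run(poly, cc$center, n_samples, tau, burn_in))
}

#' Elicit an informative Dirichlet prior from parameter constraints
#'
#' For each node, samples `n_samples` parameter points uniformly from the
#' constraint polytope and averages them coordinate-wise; the mean of a
#' convex set lies in the set, so the elicited prior satisfies every
#' constraint it was derived from. Nodes without constraints are sampled
#' over the bare simplex (one code path), yielding an approximately
#' uniform prior.
#'
#' @param net A [bn_network()].
#' @param cs Constraint tibble (may be empty).
#' @param n_samples Points retained per node (default 100).
#' @param tau Diversity separation between consecutive retained points
#'   (default 0.1).
#' @param burn_in Hit-and-run burn-in (default 100).
#' @param seed Integer seed; elicitation is reproducible given the seed.
#' @return cpt tibble (`node`, `j`, `k`, `prob`) with attributes
#'   `n_samples`, `tau` and `seed`.
#' @export
elicit_prior <- function(net, cs = NULL, n_samples = 100, tau = 0.1,
                         burn_in = 100, seed = 1) {
  cs <- cs %||% empty_constraint_set()
  seeds <- seed_stream(seed, length(net$nodes))
  mats <- list()
  for (i in seq_along(net$nodes)) {
    nd <- net$nodes[i]
    pts <- sample_feasible_points(net, cs, nd, n_samples, tau = tau,
                                  burn_in = burn_in, seed = seeds[i])
    m <- colMeans(pts)
    mats[[nd]] <- matrix(m, net$q[[nd]], net$cardinalities[[nd]],
                         byrow = TRUE)
    # guard against drift from accumulated float error
    mats[[nd]] <- mats[[nd]] / rowSums(mats[[nd]])
  }
  prior <- matrices_to_cpt(net, mats)
  attr(prior, "n_samples") <- n_samples
  attr(prior, "tau") <- tau
  attr(prior, "seed") <- seed
  prior
}

# Uniform prior (1/r_i everywhere), the MAP baseline's prior.
uniform_prior <- function(net) {
  mats <- lapply(setNames(net$nodes, net$nodes), function(nd) {
    matrix(1 / net$cardinalities[[nd]], net$q[[nd]],
           net$cardinalities[[nd]])
  })
  matrices_to_cpt(net, mats)
}
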
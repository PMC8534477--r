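#' Expert parameter constraints
#'
#' Constraints on CPT entries come in three convex kinds, all linear in the
#' parameters:
#' * **range** — `lower <= theta_ijk <= upper` for one entry;
#' * **intra** — `theta_ijk <= theta_ijk'` within one CPT row (same parent
#'   configuration, different child states);
#' * **cross** — `theta_ijk <= theta_ij'k` across parent configurations of
#'   the same node for the same child state (monotonic-influence
#'   constraints).
#'
#' A constraint set is a tibble with columns `id`, `type`, `node`, `j`,
#' `k`, `lower`, `upper`, `j2`, `k2`. For `intra`, `(j, k)` is the lesser
#' entry and `k2` the greater state; for `cross`, `j` is the lesser
#' configuration and `j2` the greater one. Constraints never span nodes.
#' Simplex conditions (rows summing to 1, nonnegativity) are implicit and
#' always enforced alongside the declared constraints.
#'
#' @param node Node name.
#' @param j,j2 Parent-configuration indices (1-based).
#' @param k,k2 State indices (1-based).
#' @param lower,upper Probability bounds, `0 <= lower <= upper <= 1`.
#' @return A one-row constraint tibble.
#' @name constraints
NULL

constraint_row <- function(type, node, j, k, lower = NA_real_,
                           upper = NA_real_, j2 = NA_integer_,
                           k2 = NA_integer_) {
  tibble(id = NA_integer_, type = type, node = node,
         j = as.integer(j), k = as.integer(k),
         lower = lower, upper = upper,
         j2 = as.integer(j2), k2 = as.integer(k2))
}

#' @rdname constraints
#' @export
range_constraint <- function(node, j, k, lower, upper) {
  if (!(lower >= 0 && lower <= upper && upper <= 1)) {
    abort("range constraint needs 0 <= lower <= upper <= 1")
  }
  constraint_row("range", node, j, k, lower = lower, upper = upper)
}

#' @rdname constraints
#' @param lesser_state,greater_state State indices with
#'   `theta(lesser) <= theta(greater)`.
#' @export
intra_constraint <- function(node, j, lesser_state, greater_state) {
  if (lesser_state == greater_state) {
    abort("intra constraint needs two distinct states")
  }
  constraint_row("intra", node, j, lesser_state, k2 = greater_state)
}

#' @rdname constraints
#' @param lesser_config,greater_config Parent-configuration indices with
#'   `theta(lesser) <= theta(greater)`.
#' @param state Shared child state index.
#' @export
cross_constraint <- function(node, lesser_config, greater_config, state) {
  if (lesser_config == greater_config) {
    abort("cross constraint needs two distinct parent configurations")
  }
  constraint_row("cross", node, lesser_config, state, j2 = greater_config)
}

#' Assemble and validate a constraint set
#'
#' Binds individual constraints, checks every coordinate against the
#' network, deduplicates (with a warning), and assigns stable ids.
#'
#' @param ... One-row constraint tibbles (or tibbles of them).
#' @param net A [bn_network()] to validate against.
#' @return A validated constraint tibble.
#' @export
constraint_set <- function(..., net) {
  cs <- dplyr::bind_rows(...)
  if (nrow(cs) == 0) return(empty_constraint_set())
  validate_constraints(cs, net)
}

empty_constraint_set <- function() {
  tibble(id = integer(), type = character(), node = character(),
         j = integer(), k = integer(), lower = double(), upper = double(),
         j2 = integer(), k2 = integer())
}

validate_constraints <- function(cs, net) {
  cs <- as_tibble(cs)
  for (i in seq_len(nrow(cs))) {
    r <- cs[i, ]
    if (!r$node %in% net$nodes) {
      abort(paste0("constraint ", i, ": unknown node '", r$node, "'"))
    }
    q <- net$q[[r$node]]; rr <- net$cardinalities[[r$node]]
    if (r$j < 1 || r$j > q) abort(paste0("constraint ", i, ": j out of range"))
    if (r$k < 1 || r$k > rr) abort(paste0("constraint ", i, ": k out of range"))
    if (r$type == "range" &&
        !(r$lower >= 0 && r$lower <= r$upper && r$upper <= 1)) {
      abort(paste0("constraint ", i, ": invalid range bounds"))
    }
    if (r$type == "intra") {
      if (is.na(r$k2) || r$k2 < 1 || r$k2 > rr || r$k2 == r$k) {
        abort(paste0("constraint ", i, ": invalid intra states"))
      }
    }
    if (r$type == "cross") {
      if (is.na(r$j2) || r$j2 < 1 || r$j2 > q || r$j2 == r$j) {
        abort(paste0("constraint ", i, ": invalid cross configurations"))
      }
    }
  }
  key <- do.call(paste, c(cs[c("type", "node", "j", "k", "lower", "upper",
                               "j2", "k2")], sep = "\r"))
  if (anyDuplicated(key)) {
    warn(paste0("dropping ", sum(duplicated(key)), " duplicate constraint(s)"))
    cs <- cs[!duplicated(key), ]
  }
  cs$id <- seq_len(nrow(cs))
  cs
}

#' Parse / serialize constraints in the YAML/JSON DSL
#'
#' The on-disk DSL is a `constraints:` list whose entries name nodes,
#' parent states and child states by *label*, e.g.
#' ```yaml
#' constraints:
#' - type: cross
#'   node: C
#'   state: "1"
#'   lesser:  {BT: "0", IS: "0"}
#'   greater: {BT: "1", IS: "1"}
#' - type: range
#'   node: C
#'   config: {BT: "0", IS: "0"}
#'   state: "0"
#'   lower: 0.6
#'   upper: 1.0
#' - type: intra
#'   node: C
#'   config: {BT: "1", IS: "1"}
#'   lesser_state: "0"
#'   greater_state: "1"
#' ```
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param net A [bn_network()] used to resolve labels and validate.
#' @return `parse_constraints()`: a validated constraint tibble.
#' @export
parse_constraints <- function(path, net) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- spec$constraints %||% list()
  if (!length(entries)) return(empty_constraint_set())

  state_idx <- function(node, label, where) {
    idx <- match(as.character(label), net$states[[node]])
    if (is.na(idx)) {
      abort(paste0("constraint ", where, ": unknown state '", label,
                   "' for node '", node, "'"))
    }
    idx
  }
  cfg_idx <- function(node, cfg, where) {
    ps <- net$parents[[node]]
    s <- setNames(vapply(ps, function(p) {
      if (is.null(cfg[[p]])) {
        abort(paste0("constraint ", where, ": parent '", p,
                     "' missing from configuration"))
      }
      state_idx(p, cfg[[p]], where)
    }, integer(1)), ps)
    config_index(net, node, s)
  }

  rows <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    nd <- as.character(e$node)
    if (!nd %in% net$nodes) {
      abort(paste0("constraint ", i, ": unknown node '", nd, "'"))
    }
    switch(as.character(e$type),
      range = range_constraint(nd, cfg_idx(nd, e$config, i),
                               state_idx(nd, e$state, i),
                               as.numeric(e$lower), as.numeric(e$upper)),
      intra = intra_constraint(nd, cfg_idx(nd, e$config, i),
                               state_idx(nd, e$lesser_state, i),
                               state_idx(nd, e$greater_state, i)),
      cross = cross_constraint(nd, cfg_idx(nd, e$lesser, i),
                               cfg_idx(nd, e$greater, i),
                               state_idx(nd, e$state, i)),
      abort(paste0("constraint ", i, ": unknown type '", e$type, "'"))
    )
  })
  validate_constraints(dplyr::bind_rows(rows), net)
}

#' @rdname parse_constraints
#' @param cs Constraint tibble.
#' @export
write_constraints <- function(cs, net, path) {
  cfg_labels <- function(node, j) {
    sts <- parent_config(net, node, j)
    as.list(setNames(vapply(names(sts), function(p) {
      net$states[[p]][sts[[p]]]
    }, character(1)), names(sts)))
  }
  entries <- lapply(seq_len(nrow(cs)), function(i) {
    r <- cs[i, ]
    switch(r$type,
      range = list(type = "range", node = r$node,
                   config = cfg_labels(r$node, r$j),
                   state = net$states[[r$node]][r$k],
                   lower = r$lower, upper = r$upper),
      intra = list(type = "intra", node = r$node,
                   config = cfg_labels(r$node, r$j),
                   lesser_state = net$states[[r$node]][r$k],
                   greater_state = net$states[[r$node]][r$k2]),
      cross = list(type = "cross", node = r$node,
                   state = net$states[[r$node]][r$k],
                   lesser = cfg_labels(r$node, r$j),
                   greater = cfg_labels(r$node, r$j2))
    )
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(constraints = entries), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(list(constraints = entries), path)
  }
  invisible(path)
}

#' Check a parameter set against a constraint set
#'
#' Pure check: evaluates every constraint on the supplied parameters and
#' reports the violated ones with their margins (the amount by which the
#' inequality fails). An empty result means all constraints hold within
#' `tol`.
#'
#' @param params cpt tibble (columns `node`, `j`, `k`, `prob`).
#' @param cs Constraint tibble.
#' @param net A [bn_network()].
#' @param tol Nonnegative slack treated as satisfaction (default `1e-9`).
#' @return Tibble of violations: `id`, `type`, `node`, `margin`,
#'   `description`.
#' @export
check_satisfaction <- function(params, cs, net, tol = 1e-9) {
  needed <- unique(cs$node)
  mats <- lapply(setNames(needed, needed),
                 function(nd) node_matrix(params, net, nd, "prob"))
  out <- list()
  for (i in seq_len(nrow(cs))) {
    r <- cs[i, ]
    m <- mats[[r$node]]
    viol <- NA_real_; desc <- ""
    if (r$type == "range") {
      v <- m[r$j, r$k]
      viol <- max(r$lower - v, v - r$upper, 0)
      desc <- sprintf("theta(%s | %s = state %d) = %.4g outside [%g, %g]",
                      r$node, "j", r$j, v, r$lower, r$upper)
    } else if (r$type == "intra") {
      viol <- max(m[r$j, r$k] - m[r$j, r$k2], 0)
      desc <- sprintf("theta[j=%d,k=%d] > theta[j=%d,k=%d] on %s",
                      r$j, r$k, r$j, r$k2, r$node)
    } else if (r$type == "cross") {
      viol <- max(m[r$j, r$k] - m[r$j2, r$k], 0)
      desc <- sprintf("theta[j=%d,k=%d] > theta[j=%d,k=%d] on %s",
                      r$j, r$k, r$j2, r$k, r$node)
    }
    if (viol > tol) {
      out[[length(out) + 1]] <- tibble(id = r$id, type = r$type,
                                       node = r$node, margin = viol,
                                       description = desc)
    }
  }
  if (!length(out)) {
    return(tibble(id = integer(), type = character(), node = character(),
                  margin = double(), description = character()))
  }
  dplyr::bind_rows(out)
}

# --- polytope geometry ----------------------------------------------------

# Linear description of the constraint polytope of one node, over the
# flattened CPT vector x with index v = (j - 1) * r + k.
# Returns list(d, blocks, ineq = tibble(kind, a (list), b)) where each
# inequality reads a' x <= b; 'kind' tags the origin for LP assembly
# ("upper" rows have b >= 0, "lower" rows are stored as a' x >= b).
node_polytope <- function(cs, net, node) {
  q <- net$q[[node]]; r <- net$cardinalities[[node]]
  d <- q * r
  vidx <- function(j, k) (j - 1L) * r + k
  blocks <- lapply(seq_len(q), function(j) vidx(j, seq_len(r)))
  A_le <- list(); b_le <- numeric(0)   # a' x <= b
  A_ge <- list(); b_ge <- numeric(0)   # a' x >= b  (b >= 0 by construction)
  sub <- cs[cs$node == node, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    rr <- sub[i, ]
    if (rr$type == "range") {
      a <- numeric(d); a[vidx(rr$j, rr$k)] <- 1
      A_le[[length(A_le) + 1]] <- a; b_le <- c(b_le, rr$upper)
      A_ge[[length(A_ge) + 1]] <- a; b_ge <- c(b_ge, rr$lower)
    } else if (rr$type == "intra") {
      a <- numeric(d)
      a[vidx(rr$j, rr$k)] <- 1; a[vidx(rr$j, rr$k2)] <- -1
      A_le[[length(A_le) + 1]] <- a; b_le <- c(b_le, 0)
    } else if (rr$type == "cross") {
      a <- numeric(d)
      a[vidx(rr$j, rr$k)] <- 1; a[vidx(rr$j2, rr$k)] <- -1
      A_le[[length(A_le) + 1]] <- a; b_le <- c(b_le, 0)
    }
  }
  list(d = d, q = q, r = r, blocks = blocks,
       A_le = if (length(A_le)) do.call(rbind, A_le) else
         matrix(0, 0, d),
       b_le = b_le,
       A_ge = if (length(A_ge)) do.call(rbind, A_ge) else
         matrix(0, 0, d),
       b_ge = b_ge)
}

# Projection onto the tangent space of the row-sum equalities: subtract the
# per-block mean. Used both by the Chebyshev LP (projected norms) and the
# hit-and-run direction sampler.
project_directions <- function(v, blocks) {
  for (bl in blocks) v[bl] <- v[bl] - mean(v[bl])
  v
}

# Chebyshev center of the node polytope: the largest ball inscribed within
# the affine hull of the simplex equalities, so inequality margins use the
# norms of the constraint normals projected onto that subspace. Returns
# list(center, radius) or NULL if the LP is infeasible.
chebyshev_center <- function(poly) {
  d <- poly$d
  pn <- function(a) sqrt(sum(project_directions(a, poly$blocks)^2))
  # variables: (x_1..x_d, rho); maximize rho subject to A x + ||Pa|| rho <= b
  nn <- diag(d)
  A <- rbind(
    if (nrow(poly$A_le)) cbind(poly$A_le, apply(poly$A_le, 1, pn)),
    if (nrow(poly$A_ge)) cbind(-poly$A_ge, apply(poly$A_ge, 1, pn)),
    cbind(-nn, apply(nn, 1, pn))
  )
  b <- c(poly$b_le, -poly$b_ge, numeric(d))
  Aeq <- cbind(t(vapply(poly$blocks, function(bl) {
    a <- numeric(d); a[bl] <- 1; a
  }, numeric(d))), 0)
  beq <- rep(1, length(poly$blocks))
  # the solver breaks pivot ties at random and can stall on a feasible
  # problem; retry under fixed sub-seeds before declaring infeasibility
  for (attempt in 1:25) {
    res <- tryCatch(
      withr::with_seed(190000 + attempt, suppressWarnings(
        pracma::linprog(cc = c(numeric(d), 1), A = A, b = b,
                        Aeq = Aeq, beq = beq, maximize = TRUE,
                        maxiter = 1000, bigM = 1000)
      )),
      error = function(e) NULL
    )
    if (!is.null(res) && res$errno >= 0 && !anyNA(res$x)) {
      x <- res$x[seq_len(d)]
      # accept only genuinely feasible output
      ok <- all(x >= -1e-9) &&
        (!nrow(poly$A_le) || all(poly$A_le %*% x <= poly$b_le + 1e-9)) &&
        (!nrow(poly$A_ge) || all(poly$A_ge %*% x >= poly$b_ge - 1e-9))
      if (ok) {
        return(list(center = unname(x), radius = unname(res$fval)))
      }
    }
  }
  NULL
}

#' Feasibility of a constraint set
#'
#' Determines per node whether the constraint polytope (declared
#' constraints plus simplex conditions) is nonempty, via linear
#' programming, and returns a feasible witness parameter set when it is.
#' Nodes without constraints contribute uniform rows to the witness.
#'
#' @param cs Constraint tibble.
#' @param net A [bn_network()].
#' @return List with `feasible` (logical), `witness` (cpt tibble or
#'   `NULL`), and `infeasible_nodes` (character).
#' @export
feasibility <- function(cs, net) {
  mats <- list()
  bad <- character(0)
  for (nd in net$nodes) {
    poly <- node_polytope(cs, net, nd)
    if (!nrow(poly$A_le) && !nrow(poly$A_ge)) {
      mats[[nd]] <- matrix(1 / poly$r, poly$q, poly$r)
      next
    }
    cc <- chebyshev_center(poly)
    if (is.null(cc)) {
      bad <- c(bad, nd)
      mats[[nd]] <- matrix(1 / poly$r, poly$q, poly$r)
    } else {
      # flattening is j-major: v = (j-1)*r + k, so fill by row
      mats[[nd]] <- matrix(cc$center, poly$q, poly$r, byrow = TRUE)
    }
  }
  if (length(bad)) {
    return(list(feasible = FALSE, witness = NULL, infeasible_nodes = bad))
  }
  list(feasible = TRUE, witness = matrices_to_cpt(net, mats),
       infeasible_nodes = character(0))
}
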
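#' Control parameters for CaMAP fitting
#'
#' @param max_ess Largest candidate equivalent sample size (default 50).
#' @param folds Cross-validation folds (default 5; leave-one-out below 10
#'   records).
#' @param tau Diversity separation of the polytope sampler (default 0.1).
#' @param n_prior_samples Polytope samples averaged into the prior
#'   (default 100).
#' @param burn_in Hit-and-run burn-in steps (default 100).
#' @param me_epsilon Likelihood slack of the entropy baselines (default
#'   0.05 nats/record).
#' @param smoothing_floor Floor applied to ML estimates before KL
#'   evaluation in the benchmark (default 1e-12).
#' @param seed Integer seed for all randomized steps.
#' @return A list of class `camap_control`.
#' @export
camap_control <- function(max_ess = 50, folds = 5, tau = 0.1,
                          n_prior_samples = 100, burn_in = 100,
                          me_epsilon = 0.05, smoothing_floor = 1e-12,
                          seed = 1) {
  stopifnot(max_ess >= 1, folds >= 2, tau > 0, n_prior_samples >= 1,
            burn_in >= 0, me_epsilon > 0, smoothing_floor > 0)
  structure(list(max_ess = max_ess, folds = folds, tau = tau,
                 n_prior_samples = n_prior_samples, burn_in = burn_in,
                 me_epsilon = me_epsilon,
                 smoothing_floor = smoothing_floor,
                 seed = as.integer(seed)),
            class = "camap_control")
}

#' Constraint-adjusted MAP estimation
#'
#' The full pipeline: elicit an informative prior by uniform sampling of
#' the constraint polytope, derive ESS lower bounds from the constraints,
#' select the global ESS of each node by cross-validation, assign local
#' ESS values per parent configuration (cross-validated above their
#' bounds where needed), and form the MAP estimates
#' `(N_ijk + a_ij * prior_ijk) / (N_ij + a_ij)`. A final satisfaction
#' check records any residual violations.
#'
#' @param net A [bn_network()].
#' @param data Complete dataset tibble (see [forward_sample()],
#'   [read_dataset()]).
#' @param cs Constraint tibble; `NULL` or empty degenerates to MAP with a
#'   sampled (approximately uniform) prior and a cross-validated global
#'   ESS.
#' @param control A [camap_control()].
#' @param prior Optional pinned prior (cpt tibble) bypassing elicitation.
#' @param ess Optional pinned ESS assignment (any form accepted by
#'   [map_estimate()]) bypassing selection.
#' @return An object of class `camap_fit`: list with `params`, `prior`,
#'   `ess`, `bounds`, `global_ess`, `violations`, `cv_trace`, `net`,
#'   `control`.
#' @export
camap_fit <- function(net, data, cs = NULL, control = camap_control(),
                      prior = NULL, ess = NULL) {
  cs <- cs %||% empty_constraint_set()
  if (nrow(cs)) {
    feas <- feasibility(cs, net)
    if (!feas$feasible) {
      abort(paste0("infeasible constraints on node(s): ",
                   toString(feas$infeasible_nodes)))
    }
  }
  seeds <- seed_stream(control$seed, 3L)
  counts <- count_sufficient_stats(data, net)

  if (is.null(prior)) {
    prior <- elicit_prior(net, cs, n_samples = control$n_prior_samples,
                          tau = control$tau, burn_in = control$burn_in,
                          seed = seeds[1])
  }
  bounds <- derive_local_bounds(counts, prior, cs, net)

  global <- NULL; trace <- NULL
  if (is.null(ess)) {
    global <- cross_validate_global_ess(data, net, prior,
                                        candidates = seq_len(control$max_ess),
                                        folds = control$folds,
                                        seed = seeds[2])
    trace <- attr(global, "trace")
    ess <- assign_local_ess(net, data, prior, cs, global, bounds,
                            max_candidate = control$max_ess,
                            folds = control$folds, seed = seeds[3])
  }
  params <- map_estimate(counts, prior, ess)
  violations <- check_satisfaction(params, cs, net)
  if (nrow(violations)) {
    warn(paste0(nrow(violations),
                " constraint(s) remain violated after estimation"))
  }

  structure(
    list(params = params, prior = prior, ess = ess, bounds = bounds,
         global_ess = global, violations = violations, cv_trace = trace,
         counts = counts, net = net, cs = cs, control = control),
    class = "camap_fit"
  )
}

#' @export
print.camap_fit <- function(x, ...) {
  cat("<camap_fit> ", length(x$net$nodes), " nodes, ",
      sum(x$counts$n[x$counts$node == x$net$nodes[1]]), " records, ",
      nrow(x$cs), " constraints\n", sep = "")
  if (!is.null(x$global_ess)) {
    cat("  global ESS:",
        paste(x$global_ess$node, x$global_ess$ess, sep = "=",
              collapse = ", "), "\n")
  }
  cat("  violations remaining:", nrow(x$violations), "\n")
  invisible(x)
}

#' Tidy a CaMAP fit into one row per CPT entry
#'
#' @param x A `camap_fit`.
#' @param ... Unused.
#' @return Tibble with `node`, `parent_config` (label), `state` (label),
#'   `j`, `k`, `estimate`, `prior`, `ess`, `n`.
#' @method tidy camap_fit
#' @export
tidy.camap_fit <- function(x, ...) {
  net <- x$net
  out <- x$params
  names(out)[names(out) == "prob"] <- "estimate"
  out$prior <- x$prior$prob[match(
    paste(out$node, out$j, out$k),
    paste(x$prior$node, x$prior$j, x$prior$k))]
  out$n <- x$counts$n[match(
    paste(out$node, out$j, out$k),
    paste(x$counts$node, x$counts$j, x$counts$k))]
  if (is.data.frame(x$ess)) {
    ev <- resolve_ess(x$ess, shape_from_table(x$params))
    out$ess <- ev$ess[match(paste(out$node, out$j),
                            paste(ev$node, ev$j))]
  } else {
    out$ess <- as.numeric(x$ess)
  }
  out$parent_config <- vapply(seq_len(nrow(out)), function(i) {
    config_label(net, out$node[i], out$j[i])
  }, character(1))
  out$state <- vapply(seq_len(nrow(out)), function(i) {
    net$states[[out$node[i]]][out$k[i]]
  }, character(1))
  out[c("node", "parent_config", "state", "j", "k", "estimate",
        "prior", "ess", "n")]
}

#' One-row summary of a CaMAP fit
#'
#' @param x A `camap_fit`.
#' @param ... Unused.
#' @return Tibble with record/constraint counts, residual violations,
#'   training log-likelihood of the estimates and the mean global ESS.
#' @method glance camap_fit
#' @export
glance.camap_fit <- function(x, ...) {
  pm <- cpt_to_matrices(x$net, x$params)
  nm <- cpt_to_matrices(x$net, x$counts, value_col = "n")
  ll <- sum(vapply(x$net$nodes, function(nd) {
    sum(nm[[nd]] * log(pmax(pm[[nd]], 1e-300)))
  }, numeric(1)))
  tibble(
    n_obs = sum(x$counts$n[x$counts$node == x$net$nodes[1]]),
    n_constraints = nrow(x$cs),
    n_violations = nrow(x$violations),
    loglik = ll,
    mean_global_ess = if (is.null(x$global_ess)) NA_real_
                      else mean(x$global_ess$ess)
  )
}

#' Plot the ESS cross-validation surface of a fit
#'
#' @param object A `camap_fit` produced with ESS selection (not pinned).
#' @param ... Unused.
#' @return A ggplot: held-out log-likelihood against candidate ESS, one
#'   panel per node.
#' @method autoplot camap_fit
#' @export
autoplot.camap_fit <- function(object, ...) {
  tr <- object$cv_trace
  if (is.null(tr)) abort("fit has no CV trace (ESS was pinned)")
  picks <- object$global_ess
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$candidate,
                                   y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = picks,
                        ggplot2::aes(xintercept = .data$ess),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~node, scales = "free_y") +
    ggplot2::labs(x = "candidate ESS",
                  y = "held-out log-likelihood") +
    ggplot2::theme_minimal()
}
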
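# Synthetic networks, constraint generation from truth, and the benchmark
# harness comparing the six estimators by joint KL divergence.

profile_concentration <- c(strongly_skewed = 0.1, skewed = 0.5,
                           uniform = 5, strongly_uniform = 50)

#' Generate a random test network
#'
#' Builds a random DAG (each node picks up to `max_parents` parents among
#' its predecessors in a random order) and fills every CPT row with a
#' draw from a symmetric Dirichlet whose concentration encodes the
#' uniformity profile: `strongly_skewed` (0.1) through
#' `strongly_uniform` (50); `combined` mixes skewed and uniform rows.
#'
#' @param profile One of `"strongly_skewed"`, `"skewed"`, `"uniform"`,
#'   `"strongly_uniform"`, `"combined"`.
#' @param n_nodes Number of nodes (default 5).
#' @param max_parents Maximum parents per node (default 2).
#' @param cardinality State count per node (default 2).
#' @param seed Integer seed.
#' @return A [bn_network()] with true parameters attached.
#' @export
make_test_network <- function(profile = c("combined", "strongly_skewed",
                                          "skewed", "uniform",
                                          "strongly_uniform"),
                              n_nodes = 5, max_parents = 2,
                              cardinality = 2, seed = 1) {
  profile <- match.arg(profile)
  stopifnot(n_nodes >= 1)
  withr::with_seed(as.integer(seed), {
    nodes <- paste0("X", seq_len(n_nodes))
    ord <- sample(nodes)
    parents <- setNames(rep(list(character()), n_nodes), nodes)
    for (i in seq_along(ord)) {
      avail <- ord[seq_len(i - 1)]
      if (!length(avail)) next
      np <- sample.int(min(max_parents, length(avail)) + 1L, 1L) - 1L
      if (np > 0) parents[[ord[i]]] <- sample(avail, np)
    }
    net <- bn_network(nodes, parents,
                      setNames(rep(cardinality, n_nodes), nodes))
    mats <- lapply(setNames(nodes, nodes), function(nd) {
      q <- net$q[[nd]]; r <- net$cardinalities[[nd]]
      t(vapply(seq_len(q), function(j) {
        conc <- if (profile == "combined") {
          sample(profile_concentration[c("strongly_skewed",
                                         "strongly_uniform")], 1)
        } else {
          profile_concentration[[profile]]
        }
        rdirichlet1(r, conc)
      }, numeric(r)))
    })
    set_cpt(net, matrices_to_cpt(net, mats))
  })
}

#' Generate constraints from true parameters
#'
#' Emulates an expert who knows the truth approximately: range
#' constraints `[max(0, t* - tau1), min(1, t* + tau2)]` with `tau1, tau2`
#' drawn uniformly from `tau_range`, and ordering constraints (intra
#' within a row, cross across configurations for a shared state) emitted
#' only where the true gap is at least `gap`. Per node, at most
#' `max_per_node` constraints are retained by seeded subsampling of the
#' candidate pool. The output is always satisfied by the true parameters.
#'
#' @param net A [bn_network()] with true parameters.
#' @param max_per_node Maximum constraints retained per node (default 3).
#' @param tau_range Range-width distribution (default `c(0.15, 0.25)`,
#'   i.e. "around 0.2").
#' @param gap Minimal true gap for ordering constraints (default 0.2).
#' @param seed Integer seed.
#' @return A validated constraint tibble.
#' @export
generate_constraints_from_truth <- function(net, max_per_node = 3,
                                            tau_range = c(0.15, 0.25),
                                            gap = 0.2, seed = 1) {
  if (is.null(net$cpt)) abort("network has no true parameters")
  mats <- cpt_to_matrices(net, net$cpt)
  withr::with_seed(as.integer(seed), {
    all_rows <- list()
    for (nd in net$nodes) {
      m <- mats[[nd]]
      q <- nrow(m); r <- ncol(m)
      cand <- list()
      for (j in seq_len(q)) {
        for (k in seq_len(r)) {
          cand[[length(cand) + 1]] <- list(type = "range", j = j, k = k)
          for (k2 in seq_len(r)) {
            if (k2 != k && m[j, k2] - m[j, k] >= gap) {
              cand[[length(cand) + 1]] <-
                list(type = "intra", j = j, k = k, k2 = k2)
            }
          }
          for (j2 in seq_len(q)) {
            if (j2 != j && m[j2, k] - m[j, k] >= gap) {
              cand[[length(cand) + 1]] <-
                list(type = "cross", j = j, k = k, j2 = j2)
            }
          }
        }
      }
      if (!length(cand)) next
      keep <- cand[sample.int(length(cand), min(max_per_node,
                                                length(cand)))]
      for (cc in keep) {
        row <- switch(cc$type,
          range = {
            t1 <- runif(1, tau_range[1], tau_range[2])
            t2 <- runif(1, tau_range[1], tau_range[2])
            range_constraint(nd, cc$j, cc$k,
                             max(0, m[cc$j, cc$k] - t1),
                             min(1, m[cc$j, cc$k] + t2))
          },
          intra = intra_constraint(nd, cc$j, cc$k, cc$k2),
          cross = cross_constraint(nd, cc$j, cc$j2, cc$k)
        )
        all_rows[[length(all_rows) + 1]] <- row
      }
    }
    if (!length(all_rows)) return(empty_constraint_set())
    validate_constraints(dplyr::bind_rows(all_rows), net)
  })
}

#' Benchmark the estimators on synthetic networks
#'
#' For each replicate: draw a network with known truth, forward-sample a
#' dataset, generate constraints from the truth, keep a seeded subset per
#' constraint fraction, fit the requested estimators, and record the
#' joint KL divergence to the truth. Sample-size grids reuse prefixes of
#' one maximal dataset per replicate, and fraction grids reuse one
#' nested, shuffled constraint order, so conditions are paired within a
#' replicate. ML and CML estimates can put probability zero on events the
#' truth allows, so they are floored at `control$smoothing_floor` (and
#' renormalized) before KL evaluation, flagged in the `floored` column;
#' all other estimators smooth by construction.
#'
#' @param profiles Network profiles (see [make_test_network()]).
#' @param sample_sizes Dataset sizes (default 20).
#' @param fractions Constraint fractions in `[0, 1]` (default `c(0, 1)`).
#' @param replicates Replicates per condition (default 30).
#' @param algorithms Subset of `"ml"`, `"cml"`, `"me"`, `"cme"`, `"map"`,
#'   `"camap"`.
#' @param n_nodes,max_parents,cardinality Network shape (defaults 5, 2,
#'   2: small enough for exact joint KL).
#' @param max_per_node Constraint budget per node (default 3).
#' @param control A [camap_control()].
#' @param seed Integer master seed.
#' @return Tibble of class `camap_benchmark`: one row per
#'   `(profile, n, fraction, replicate, algorithm)` with the `kl`
#'   divergence; failed fits are recorded with `NA` and a warning.
#' @export
run_benchmark <- function(profiles = "combined", sample_sizes = 20,
                          fractions = c(0, 1), replicates = 30,
                          algorithms = c("ml", "cml", "me", "cme", "map",
                                         "camap"),
                          n_nodes = 5, max_parents = 2, cardinality = 2,
                          max_per_node = 3, control = camap_control(),
                          seed = 1) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  seeds <- matrix(seed_stream(seed, replicates * 4), nrow = replicates)
  out <- list()
  for (prof in profiles) {
    for (rep_i in seq_len(replicates)) {
      net <- make_test_network(prof, n_nodes, max_parents, cardinality,
                               seed = seeds[rep_i, 1])
      data_all <- forward_sample(net, max(sample_sizes),
                                 seed = seeds[rep_i, 2])
      cs_full <- generate_constraints_from_truth(
        net, max_per_node = max_per_node, seed = seeds[rep_i, 3])
      cs_order <- withr::with_seed(seeds[rep_i, 4],
                                   sample.int(max(nrow(cs_full), 1)))
      for (n_i in sample_sizes) {
        data <- data_all[seq_len(n_i), , drop = FALSE]
        counts <- count_sufficient_stats(data, net)
        for (fr in fractions) {
          n_keep <- round(fr * nrow(cs_full))
          cs <- if (n_keep > 0) {
            validate_constraints(cs_full[sort(cs_order[seq_len(n_keep)]), ],
                                 net)
          } else {
            empty_constraint_set()
          }
          ctl <- control
          ctl$seed <- seeds[rep_i, 4]
          for (alg in algorithms) {
            kl <- tryCatch({
              est <- switch(alg,
                ml = suppressMessages(ml_estimate(counts)),
                map = map_uniform(counts, ess = 1),
                me = me_estimate(counts, net,
                                 me_epsilon = control$me_epsilon),
                cme = cme_estimate(counts, cs, net,
                                   me_epsilon = control$me_epsilon),
                cml = cml_estimate(counts, cs, net),
                camap = suppressMessages(
                  camap_fit(net, data, cs, control = ctl))$params
              )
              if (alg %in% c("ml", "cml")) {
                est <- floor_params(est, control$smoothing_floor)
              }
              joint_kl(net, est)
            }, error = function(e) {
              warn(paste0("replicate ", rep_i, " (", alg, ", fraction ",
                          fr, ") failed: ", conditionMessage(e)))
              NA_real_
            })
            out[[length(out) + 1]] <- tibble(
              profile = prof, n = n_i, fraction = fr,
              replicate = rep_i, algorithm = alg, kl = kl,
              floored = alg %in% c("ml", "cml")
            )
          }
        }
      }
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("camap_benchmark", class(res))
  attr(res, "seed") <- seed
  res
}

# Floor-and-renormalize zero entries (used for ML before KL evaluation).
floor_params <- function(params, floor = 1e-12) {
  shp <- shape_from_table(params)
  mats <- cpt_to_matrices(shp, params)
  mats <- lapply(mats, function(m) {
    m <- pmax(m, floor)
    m / rowSums(m)
  })
  matrices_to_cpt(shp, mats)
}

#' Summarize a benchmark: mean KL per condition
#'
#' @param object A `camap_benchmark`.
#' @param ... Unused.
#' @return Tibble with mean and standard error of the KL divergence per
#'   `(profile, n, fraction, algorithm)`.
#' @export
summary.camap_benchmark <- function(object, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(object), .data$profile, .data$n,
                    .data$fraction, .data$algorithm),
    mean_kl = mean(.data$kl, na.rm = TRUE),
    se_kl = stats::sd(.data$kl, na.rm = TRUE) /
      sqrt(sum(is.finite(.data$kl))),
    n_rep = sum(is.finite(.data$kl)),
    .groups = "drop"
  )
}

#' Plot benchmark results
#'
#' @param object A `camap_benchmark`.
#' @param x_var `"n"` (sample size) or `"fraction"` (constraint
#'   fraction); defaults to whichever varies.
#' @param ... Unused.
#' @return A ggplot of mean KL (log scale) against `x_var`, colored by
#'   algorithm, faceted by profile.
#' @method autoplot camap_benchmark
#' @export
autoplot.camap_benchmark <- function(object, x_var = NULL, ...) {
  sm <- summary(object)
  if (is.null(x_var)) {
    x_var <- if (length(unique(sm$fraction)) > 1) "fraction" else "n"
  }
  ggplot2::ggplot(sm, ggplot2::aes(x = .data[[x_var]], y = .data$mean_kl,
                                   color = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~profile) +
    ggplot2::labs(x = if (x_var == "n") "sample size"
                  else "constraint fraction",
                  y = "mean joint KL divergence") +
    ggplot2::theme_minimal()
}
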
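# Dense alpha-grid oracle: smallest alpha on the grid for which the MAP
# estimates satisfy the given constraint, or Inf if none does.
grid_bound_range <- function(n_ijk, n_ij, prior, lower, upper,
                             grid = seq(0, 200, by = 1e-3)) {
  th <- (n_ijk + grid * prior) / (n_ij + grid)
  ok <- th >= lower - 1e-12 & th <= upper + 1e-12
  if (!any(ok)) return(Inf)
  g <- grid[ok][1]
  if (!all(ok[grid >= g])) return(NA_real_) # not one-sided: flag
  g
}

grid_bound_cross <- function(n1k, n1, n2k, n2, p1, p2,
                             grid = seq(0, 200, by = 1e-3)) {
  lhs <- (n1k + grid * p1) / (n1 + grid)
  rhs <- (n2k + grid * p2) / (n2 + grid)
  ok <- lhs <= rhs + 1e-12
  if (!any(ok)) return(Inf)
  grid[ok][1]
}

test_that("range bound reproduces the worked value and degenerate cases", {
  expect_equal(ess_bound_range(1, 7, prior = 0.80, lower = 0.6, upper = 1),
               16)
  # data and prior both inside the range: no ESS needed
  expect_equal(ess_bound_range(4, 10, prior = 0.5, lower = 0.3,
                               upper = 0.7), 0)
  # prior on the violating side of the bound: no finite ESS exists
  expect_identical(ess_bound_range(1, 10, prior = 0.5, lower = 0.6,
                                   upper = 1), Inf)
})

test_that("range bound matches a dense grid scan on random instances", {
  withr::with_seed(101, {
    for (i in 1:50) {
      n_ij <- sample.int(30, 1)
      n_ijk <- sample.int(n_ij + 1, 1) - 1L
      lower <- runif(1, 0, 0.4)
      upper <- runif(1, 0.6, 1)
      prior <- runif(1, lower + 0.01, upper - 0.01)
      b <- ess_bound_range(n_ijk, n_ij, prior, lower, upper)
      g <- grid_bound_range(n_ijk, n_ij, prior, lower, upper)
      if (is.finite(b) && b <= 190) {
        expect_lt(abs(b - g), 2e-3 * (1 + b)) # grid step dominates small b
      } else {
        expect_true(is.na(g) || g > 190 || is.infinite(g))
      }
    }
  })
})

test_that("intra bound solves the row-ordering inequality", {
  b <- ess_bound_intra(5, 2, prior_k1 = 0.2, prior_k2 = 0.6)
  expect_equal(b, 7.5)
  # at alpha = bound the two estimates tie exactly
  th1 <- (5 + b * 0.2) / (7 + b)
  th2 <- (2 + b * 0.6) / (7 + b)
  expect_equal(th1, th2, tolerance = 1e-12)

  expect_equal(ess_bound_intra(2, 5, 0.2, 0.6), 0)
  expect_identical(ess_bound_intra(5, 2, 0.4, 0.4), Inf)
})

test_that("cross bound reproduces the worked 5.49 and closed-form cases", {
  # lesser config (BT=0,IS=0): counts (3 of 3); greater (BT=1,IS=1):
  # counts (0 of 9); priors 0.01 vs 0.95
  b <- ess_bound_cross(3, 3, 0, 9, 0.01, 0.95)
  expect_equal(round(b, 2), 5.49)

  # equal priors, data already ordered: linear case, satisfied everywhere
  expect_equal(ess_bound_cross(1, 5, 3, 5, 0.5, 0.5), 0)
  # equal priors, data violating: alpha cancels, unsatisfiable
  expect_identical(ess_bound_cross(4, 5, 1, 5, 0.5, 0.5), Inf)
})

test_that("cross bound matches a dense grid scan on random instances", {
  withr::with_seed(202, {
    for (i in 1:50) {
      n1 <- sample.int(25, 1); n1k <- sample.int(n1 + 1, 1) - 1L
      n2 <- sample.int(25, 1); n2k <- sample.int(n2 + 1, 1) - 1L
      p1 <- runif(1, 0.02, 0.6)
      p2 <- runif(1, p1 + 0.05, 1) # prior respects the ordering
      b <- ess_bound_cross(n1k, n1, n2k, n2, p1, p2)
      g <- grid_bound_cross(n1k, n1, n2k, n2, p1, p2)
      if (is.finite(b) && b <= 190) {
        expect_lt(abs(b - g), 2e-3 * (1 + b)) # grid step dominates small b
      } else {
        expect_true(g > 190 || is.infinite(g))
      }
    }
  })
})

test_that("local bounds aggregate per configuration with cross coupling", {
  ex <- brain_tumor_example()
  bounds <- derive_local_bounds(ex$counts, ex$prior, ex$constraints,
                                ex$net)
  # each cross constraint contributes its bound to both configurations
  expect_equal(nrow(bounds), 10)
  eff <- camap:::effective_bounds(bounds)
  expect_equal(round(eff$bound[eff$j == 1], 2), 5.49)

  empty <- derive_local_bounds(ex$counts, ex$prior,
                               ex$constraints[0, ], ex$net)
  expect_equal(nrow(empty), 0)
})

test_that("adding a constraint never lowers an effective bound", {
  withr::with_seed(77, {
    for (rep in 1:5) {
      net <- make_test_network("combined", n_nodes = 3, seed = rep + 10)
      cs <- generate_constraints_from_truth(net, max_per_node = 4,
                                            seed = rep + 20)
      if (nrow(cs) < 2) next
      data <- forward_sample(net, 15, seed = rep)
      counts <- count_sufficient_stats(data, net)
      prior <- elicit_prior(net, cs, n_samples = 40, seed = rep)
      full <- camap:::effective_bounds(
        derive_local_bounds(counts, prior, cs, net))
      sub <- camap:::effective_bounds(
        derive_local_bounds(counts, prior, cs[-nrow(cs), ], net))
      merged <- dplyr::left_join(sub, full, by = c("node", "j"),
                                 suffix = c("_sub", "_full"))
      expect_true(all(merged$bound_full >= merged$bound_sub - 1e-9))
    }
  })
})

test_that("global ESS cross-validation is deterministic and handles one candidate", {
  net <- chain2_net()
  data <- forward_sample(net, 30, seed = 5)
  prior <- elicit_prior(net, NULL, n_samples = 50, seed = 6)

  one <- cross_validate_global_ess(data, net, prior, candidates = 7,
                                   seed = 1)
  expect_true(all(one$ess == 7))

  g1 <- cross_validate_global_ess(data, net, prior, seed = 2)
  g2 <- cross_validate_global_ess(data, net, prior, seed = 2)
  expect_identical(g1$ess, g2$ess)

  # the argmax beats (or ties) the weakest-prior candidate by construction
  tr <- attr(g1, "trace")
  for (nd in net$nodes) {
    sub <- tr[tr$node == nd, ]
    expect_gte(max(sub$loglik), sub$loglik[sub$candidate == 1])
  }
})

test_that("an informative prior earns a larger ESS than a misleading one", {
  net <- single_net(0.9)
  data <- forward_sample(net, 40, seed = 9)
  good <- tibble::tibble(node = "X", j = 1L, k = 1:2, prob = c(0.9, 0.1))
  bad <- tibble::tibble(node = "X", j = 1L, k = 1:2, prob = c(0.1, 0.9))
  g_good <- cross_validate_global_ess(data, net, good, seed = 3)$ess
  g_bad <- cross_validate_global_ess(data, net, bad, seed = 3)$ess
  expect_gt(g_good, g_bad)
})

test_that("local ESS assignment follows the bound/global/CV rules", {
  ex <- brain_tumor_example()
  data <- brain_tumor_dataset()
  global <- tibble::tibble(node = c("BT", "IS", "C"), ess = c(3, 3, 3))
  unif <- camap:::uniform_prior(ex$net)
  prior_full <- dplyr::bind_rows(ex$prior, unif[unif$node != "C", ])

  # no bounds: every configuration inherits the global value
  none <- assign_local_ess(ex$net, data, prior_full, ex$constraints[0, ],
                           global,
                           derive_local_bounds(ex$counts, ex$prior,
                                               ex$constraints[0, ],
                                               ex$net),
                           seed = 1)
  expect_true(all(none$ess == 3))
  expect_true(all(none$source == "global"))

  # with the worked constraints, global 3 is below every bound, so all
  # four configurations of C get at least their bound's ceiling
  bounds <- derive_local_bounds(ex$counts, ex$prior, ex$constraints,
                                ex$net)
  la <- assign_local_ess(ex$net, data, prior_full, ex$constraints, global,
                         bounds, seed = 1)
  cc <- la[la$node == "C", ]
  expect_true(all(cc$ess >= ceiling(cc$bound - 1e-9)))
  expect_gte(cc$ess[cc$j == 1], 6) # bound 5.49 -> grid starts at 6

  est <- map_estimate(count_sufficient_stats(data, ex$net), prior_full, la)
  expect_equal(nrow(check_satisfaction(est, ex$constraints, ex$net)), 0)
})

test_that("assigned ESS yields constraint-satisfying estimates on random instances", {
  withr::with_seed(303, {
    for (rep in 1:8) {
      net <- make_test_network("combined", n_nodes = 4, seed = rep)
      data <- forward_sample(net, 20, seed = rep + 50)
      cs <- generate_constraints_from_truth(net, seed = rep + 100)
      fit <- suppressMessages(suppressWarnings(
        camap_fit(net, data, cs, control = camap_control(seed = rep))))
      finite <- camap:::effective_bounds(fit$bounds)
      finite <- finite[!finite$unsatisfiable, ]
      if (nrow(finite)) {
        ids <- fit$bounds$constraint_id[is.finite(fit$bounds$bound)]
        viol <- check_satisfaction(fit$params,
                                   fit$cs[fit$cs$id %in% ids, ], net)
        expect_equal(nrow(viol), 0)
      }
    }
  })
})
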
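test_that("maximum likelihood is the count ratio with uniform fallback", {
  counts <- tibble::tibble(node = "X", j = 1L, k = 1:2, n = c(1L, 6L))
  expect_equal(ml_estimate(counts)$prob, c(1 / 7, 6 / 7))

  counts2 <- tibble::tibble(node = "X", j = 1L, k = 1:2, n = c(9L, 1L))
  expect_equal(ml_estimate(counts2)$prob, c(0.9, 0.1))

  empty <- tibble::tibble(node = "X", j = 1L, k = 1:2, n = c(0L, 0L))
  expect_message(est <- ml_estimate(empty), "unobserved")
  expect_equal(est$prob, c(0.5, 0.5))
})

test_that("MAP estimation reproduces the printed worked values", {
  counts <- tibble::tibble(node = "X", j = 1L, k = 1:2, n = c(1L, 6L))
  prior <- tibble::tibble(node = "X", j = 1L, k = 1:2, prob = c(0.8, 0.2))
  expect_equal(round(map_estimate(counts, prior, ess = 5)$prob[1], 2),
               0.42)

  counts2 <- tibble::tibble(node = "X", j = 1L, k = 1:2, n = c(0L, 3L))
  prior2 <- tibble::tibble(node = "X", j = 1L, k = 1:2,
                           prob = c(0.99, 0.01))
  expect_equal(round(map_estimate(counts2, prior2, ess = 50)$prob[1], 2),
               0.93)
})

test_that("MAP limits: tiny ESS gives ML, empty rows give the prior", {
  counts <- tibble::tibble(node = "X", j = 1L, k = 1:2, n = c(3L, 9L))
  prior <- tibble::tibble(node = "X", j = 1L, k = 1:2, prob = c(0.7, 0.3))
  expect_equal(map_estimate(counts, prior, ess = 1e-9)$prob,
               c(0.25, 0.75), tolerance = 1e-9)

  none <- tibble::tibble(node = "X", j = 1L, k = 1:2, n = c(0L, 0L))
  expect_equal(map_estimate(none, prior, ess = 12)$prob, c(0.7, 0.3))
})

test_that("MAP interpolates between data and prior, monotonically in ESS", {
  withr::with_seed(404, {
    for (i in 1:20) {
      r <- sample(2:4, 1)
      n <- random_row_counts(r)
      p <- rdirich(r)
      counts <- tibble::tibble(node = "X", j = 1L, k = seq_len(r), n = n)
      prior <- tibble::tibble(node = "X", j = 1L, k = seq_len(r),
                              prob = p)
      ml <- n / max(sum(n), 1)
      alphas <- c(0.5, 2, 10, 80)
      ests <- vapply(alphas, function(a) {
        map_estimate(counts, prior, ess = a)$prob
      }, numeric(r))
      for (ci in seq_along(alphas)) {
        lo <- pmin(ml, p) - 1e-12
        hi <- pmax(ml, p) + 1e-12
        expect_true(all(ests[, ci] >= lo & ests[, ci] <= hi))
      }
      # each coordinate moves monotonically towards its prior value
      for (kk in seq_len(r)) {
        d <- ests[kk, ] - p[kk]
        expect_true(all(diff(abs(d)) <= 1e-12))
      }
    }
  })
})

test_that("uniform-prior MAP matches its closed form and the general form", {
  counts <- tibble::tibble(node = "X", j = 1L, k = 1:2, n = c(0L, 0L))
  expect_equal(map_uniform(counts)$prob, c(0.5, 0.5))

  counts2 <- tibble::tibble(node = "X", j = 1L, k = 1:2, n = c(3L, 0L))
  expect_equal(map_uniform(counts2)$prob, c(3.5 / 4, 0.5 / 4))

  prior <- tibble::tibble(node = "X", j = 1L, k = 1:2, prob = c(0.5, 0.5))
  expect_equal(map_uniform(counts2)$prob,
               map_estimate(counts2, prior, ess = 1)$prob)
})

test_that("constrained ML activates binding constraints", {
  net <- bn_network("X", cardinalities = c(X = 2))
  counts <- tibble::tibble(node = "X", j = 1L, k = 1:2, n = c(1L, 7L))

  expect_equal(cml_estimate(counts, camap:::empty_constraint_set(),
                            net)$prob,
               c(1 / 8, 7 / 8))

  cs <- constraint_set(range_constraint("X", 1, 1, 0.6, 1), net = net)
  est <- cml_estimate(counts, cs, net)
  expect_equal(est$prob[1], 0.6, tolerance = 1e-3)

  bad <- constraint_set(range_constraint("X", 1, 1, 0.7, 1),
                        range_constraint("X", 1, 1, 0, 0.3), net = net)
  expect_error(cml_estimate(counts, bad, net), "infeasible")
})

test_that("constrained ML beats random feasible probes", {
  ex <- brain_tumor_example()
  data <- brain_tumor_dataset()
  counts <- count_sufficient_stats(data, ex$net)
  est <- cml_estimate(counts, ex$constraints, ex$net)
  expect_equal(nrow(check_satisfaction(est, ex$constraints, ex$net,
                                       tol = 1e-6)), 0)

  N <- camap:::node_matrix(counts, ex$net, "C", "n")
  ll <- function(m) sum(N * log(pmax(m, 1e-300)))
  sol <- camap:::node_matrix(est, ex$net, "C")
  probes <- sample_feasible_points(ex$net, ex$constraints, "C", 300,
                                   tau = 0, seed = 9)
  best_probe <- max(apply(probes, 1, function(v) {
    ll(matrix(v, 4, 2, byrow = TRUE))
  }))
  expect_gte(ll(sol) + 1e-6, best_probe)
})

test_that("entropy baseline hits its two documented limits", {
  net <- bn_network("X", cardinalities = c(X = 2))
  counts <- tibble::tibble(node = "X", j = 1L, k = 1:2, n = c(1L, 7L))

  expect_equal(me_estimate(counts, net, me_epsilon = 1e9)$prob,
               c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(me_estimate(counts, net, me_epsilon = 1e-9)$prob,
               c(1 / 8, 7 / 8), tolerance = 0.02)

  mid <- me_estimate(counts, net)$prob
  expect_true(mid[1] > 1 / 8 && mid[1] < 0.5)
})

test_that("constrained maximum entropy beats feasible probes in the slab", {
  net <- bn_network("X", cardinalities = c(X = 2))
  counts <- tibble::tibble(node = "X", j = 1L, k = 1:2, n = c(2L, 8L))
  cs <- constraint_set(range_constraint("X", 1, 2, 0.5, 1), net = net)
  eps <- 0.05
  est <- cme_estimate(counts, cs, net, me_epsilon = eps)
  expect_equal(nrow(check_satisfaction(est, cs, net, tol = 1e-6)), 0)

  N <- c(2, 8)
  ll <- function(p) sum(N * log(p))
  H <- function(p) -sum(p * log(p))
  target <- ll(cml_estimate(counts, cs, net)$prob) - eps * 10
  expect_gte(ll(est$prob), target - 1e-6)

  probes <- seq(0.01, 0.5, by = 0.001) # theta_1 grid inside the range cs
  ok <- vapply(probes, function(p) ll(c(p, 1 - p)) >= target, logical(1))
  if (any(ok)) {
    best <- max(vapply(probes[ok], function(p) H(c(p, 1 - p)), numeric(1)))
    expect_gte(H(est$prob) + 1e-4, best)
  }
})

test_that("the full CaMAP pipeline reproduces the worked example when pinned", {
  ex <- brain_tumor_example()
  data <- brain_tumor_dataset()
  prior_full <- dplyr::bind_rows(
    ex$prior,
    dplyr::filter(camap:::uniform_prior(ex$net), node != "C")
  )
  ess_full <- dplyr::bind_rows(
    ex$local_ess,
    tibble::tibble(node = c("BT", "IS"), j = 1L, ess = ex$global_ess)
  )
  fit <- camap_fit(ex$net, data, ex$constraints, prior = prior_full,
                   ess = ess_full)
  got <- fit$params[fit$params$node == "C", ]
  expect_equal(round(got$prob[got$k == 1], 2), c(0.93, 0.62, 0.58, 0.19))
  expect_equal(round(got$prob[got$k == 2], 2), c(0.07, 0.38, 0.42, 0.81))
  expect_equal(nrow(fit$violations), 0)
})

test_that("an empty constraint set degenerates to MAP with a sampled prior", {
  net <- chain2_net()
  data <- forward_sample(net, 25, seed = 8)
  fit <- suppressMessages(camap_fit(net, data, NULL,
                                    control = camap_control(seed = 2)))
  # all local ESS inherit the cross-validated global values
  expect_true(all(fit$ess$source == "global"))
  counts <- count_sufficient_stats(data, net)
  manual <- map_estimate(counts, fit$prior, fit$global_ess)
  expect_equal(fit$params$prob, manual$prob, tolerance = 1e-12)
})

test_that("tidy and glance summarize a fit", {
  net <- chain2_net()
  data <- forward_sample(net, 25, seed = 8)
  fit <- suppressMessages(camap_fit(net, data, NULL,
                                    control = camap_control(seed = 2)))
  td <- tidy(fit)
  expect_equal(nrow(td), 6) # 2 + 4 CPT entries
  expect_true(all(c("estimate", "prior", "ess", "n") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 25L)
  expect_equal(gl$n_violations, 0L)
  expect_s3_class(autoplot(fit), "ggplot")
})
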
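test_that("network construction validates structure and cardinalities", {
  ex <- brain_tumor_example()
  expect_equal(length(ex$net$nodes), 3)
  expect_equal(ex$net$q[["C"]], 4L)
  expect_equal(ex$net$cardinalities[["C"]], 2L)

  solo <- bn_network("X", cardinalities = c(X = 2))
  expect_equal(solo$q[["X"]], 1L)

  expect_error(
    bn_network(c("A", "B"), parents = list(A = "B", B = "A"),
               cardinalities = c(A = 2, B = 2)),
    "cycle"
  )
  expect_error(bn_network("A", cardinalities = c(A = 1)), "cardinality")
})

test_that("configuration indexing is mixed-radix with first parent most significant", {
  ex <- brain_tumor_example()
  expect_equal(config_index(ex$net, "C", c(BT = 1L, IS = 1L)), 1L)
  expect_equal(config_index(ex$net, "C", c(BT = 1L, IS = 2L)), 2L)
  expect_equal(config_index(ex$net, "C", c(BT = 2L, IS = 1L)), 3L)
  expect_equal(config_index(ex$net, "C", c(BT = 2L, IS = 2L)), 4L)
  for (j in 1:4) {
    expect_equal(config_index(ex$net, "C", parent_config(ex$net, "C", j)), j)
  }
})

test_that("JSON and BIF round-trips preserve a parameterized network", {
  net <- make_test_network("skewed", n_nodes = 5, max_parents = 1, seed = 42)
  for (fmt in c("json", "bif")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_network(net, path)
    back <- read_network(path)
    expect_identical(back$nodes, net$nodes)
    expect_identical(back$parents[back$nodes], net$parents[net$nodes])
    expect_identical(back$cardinalities, net$cardinalities)
    expect_equal(back$cpt$prob, net$cpt$prob, tolerance = 1e-12)
  }
})

test_that("datasets round-trip through labeled CSV", {
  net <- chain2_net()
  data <- forward_sample(net, 25, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(data, net, path)
  expect_identical(read_dataset(path, net), data)
})

test_that("forward sampling is reproducible and matches the CPT", {
  net <- single_net(0.5)
  expect_equal(nrow(forward_sample(net, 0, seed = 1)), 0L)

  d1 <- forward_sample(net, 10000, seed = 7)
  d2 <- forward_sample(net, 10000, seed = 7)
  expect_identical(d1, d2)
  freq <- mean(d1$X == 1L)
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / 10000))

  degenerate <- single_net(1)
  dd <- forward_sample(degenerate, 50, seed = 1)
  expect_true(all(dd$X == 1L))
})

test_that("forward-sample joint frequencies pass a goodness-of-fit check", {
  net <- chain2_net(pa = 0.4, pb_given_a = c(0.7, 0.1))
  data <- forward_sample(net, 50000, seed = 123)
  jd <- joint_distribution(net)
  obs <- table(factor(data$A, 1:2), factor(data$B, 1:2))
  expc <- matrix(0, 2, 2)
  expc[cbind(jd$A, jd$B)] <- jd$p
  pval <- stats::chisq.test(as.vector(obs), p = as.vector(expc))$p.value
  expect_gt(pval, 0.001)
})

test_that("sufficient statistics match the worked example and a naive tally", {
  ex <- brain_tumor_example()
  counts <- count_sufficient_stats(brain_tumor_dataset(), ex$net)
  cc <- counts[counts$node == "C", ]
  expect_equal(cc$n[cc$j == 4 & cc$k == 1], 9L) # C=0 | BT=1, IS=1
  expect_equal(cc$n[cc$j == 3 & cc$k == 2], 4L) # C=1 | BT=1, IS=0
  row_sums <- tapply(cc$n, cc$j, sum)
  expect_equal(as.vector(row_sums), c(3L, 1L, 7L, 9L))

  empty <- count_sufficient_stats(
    tibble::tibble(BT = integer(), IS = integer(), C = integer()), ex$net)
  expect_true(all(empty$n == 0L))

  net <- chain2_net()
  data <- forward_sample(net, 1000, seed = 3)
  counts2 <- count_sufficient_stats(data, net)
  naive <- 0L
  for (i in seq_len(nrow(counts2))) {
    r <- counts2[i, ]
    cfg <- parent_config(net, r$node, r$j)
    sel <- data[[r$node]] == r$k
    for (p in names(cfg)) sel <- sel & data[[p]] == cfg[[p]]
    expect_equal(r$n, sum(sel))
    naive <- naive + sum(sel)
  }
  expect_equal(naive, 2000L) # every record tallied once per node
})

test_that("out-of-range states are reported with the record number", {
  net <- single_net()
  bad <- tibble::tibble(X = c(1L, 3L))
  expect_error(count_sufficient_stats(bad, net), "record 2")
})

test_that("joint KL is zero at truth, positive under perturbation, infinite at excluded support", {
  net <- chain2_net()
  expect_equal(joint_kl(net, net$cpt), 0)

  bump <- net$cpt
  bump$prob[bump$node == "B" & bump$j == 1] <- c(0.8, 0.2)
  expect_gt(joint_kl(net, bump), 0)

  zero <- net$cpt
  zero$prob[zero$node == "B" & zero$j == 1] <- c(0, 1)
  expect_identical(joint_kl(net, zero), Inf)
})

test_that("factorized joint KL equals exhaustive enumeration", {
  net <- chain2_net(pa = 0.25, pb_given_a = c(0.85, 0.4))
  # cpt tibbles are ordered (node, j, k); B rows are (0.6, 0.4), (0.3, 0.7)
  est <- dplyr::mutate(net$cpt, prob = c(0.5, 0.5, 0.6, 0.4, 0.3, 0.7))
  jd <- joint_distribution(net)
  em <- list(A = matrix(c(0.5, 0.5), 1), B = matrix(c(0.6, 0.3, 0.4, 0.7), 2))
  phat <- em$A[1, jd$A] * em$B[cbind(jd$A, jd$B)]
  oracle <- sum(jd$p * log(jd$p / phat))
  expect_equal(joint_kl(net, est), oracle, tolerance = 1e-12)
})

test_that("row-mean KL option averages per-row divergences", {
  net <- chain2_net()
  est <- dplyr::mutate(net$cpt, prob = c(0.5, 0.5, 0.8, 0.2, 0.3, 0.7))
  tm <- list(A = c(0.3, 0.7), B1 = c(0.9, 0.1), B2 = c(0.2, 0.8))
  rows <- list(list(tm$A, c(0.5, 0.5)), list(tm$B1, c(0.8, 0.2)),
               list(tm$B2, c(0.3, 0.7)))
  oracle <- mean(vapply(rows, function(pq) {
    sum(pq[[1]] * log(pq[[1]] / pq[[2]]))
  }, numeric(1)))
  expect_equal(joint_kl(net, est, type = "row_mean"), oracle,
               tolerance = 1e-12)
})

test_that("sample-complexity bound matches direct arithmetic and is monotone", {
  n <- 2; k <- 1; eps <- 0.2; delta <- 0.05
  u <- 1 + 3 * n / eps
  oracle <- 288 * n^2 * 2^k / eps^2 * log(u)^2 * log(u / (eps * delta))
  expect_equal(dasgupta_sample_bound(n, k, eps, delta), oracle)

  expect_equal(dasgupta_sample_bound(n, k + 1, eps, delta), 2 * oracle)

  eps_grid <- seq(0.05, 1, by = 0.05)
  vals <- vapply(eps_grid, function(e) {
    dasgupta_sample_bound(3, 2, e, 0.05)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))

  expect_error(dasgupta_sample_bound(2, 1, -0.1, 0.05), "eps")
})
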
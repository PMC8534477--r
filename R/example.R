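#' The brain-tumor worked example
#'
#' A three-node binary network (Brain Tumour `BT` and Increased Serum
#' calcium `IS` are parents of Coma `C`) with the ingredients of the
#' package's worked illustration: sufficient statistics for node `C` from
#' a hypothetical 20-patient dataset, the five monotonic-influence
#' (cross) constraints encoding that a tumor and raised serum calcium
#' each make coma more likely, an elicited prior for `C` (printed at two
#' decimals), and the cross-validated local ESS values. Configurations
#' are ordered `(BT=0,IS=0)`, `(BT=0,IS=1)`, `(BT=1,IS=0)`, `(BT=1,IS=1)`
#' (j = 1..4); state `k = 1` is `C = 0`.
#'
#' @return List with `net` ([bn_network()]), `counts` (node `C` only),
#'   `constraints`, `prior` (node `C` only), `local_ess`
#'   (tibble `(node, j, ess)`) and `global_ess` (3).
#' @examples
#' ex <- brain_tumor_example()
#' map_estimate(ex$counts, ex$prior, ex$local_ess)
#' @export
brain_tumor_example <- function() {
  net <- bn_network(
    nodes = c("BT", "IS", "C"),
    parents = list(C = c("BT", "IS")),
    cardinalities = c(BT = 2, IS = 2, C = 2)
  )
  # N(C = k | BT, IS); j-major order (0,0), (0,1), (1,0), (1,1)
  counts <- tibble(
    node = "C",
    j = rep(1:4, times = 2),
    k = rep(1:2, each = 4),
    n = c(0L, 1L, 3L, 9L,  # C = 0
          3L, 0L, 4L, 0L)  # C = 1
  )
  # P(C = 1 | ...) increases with either cause present
  constraints <- constraint_set(
    cross_constraint("C", lesser_config = 1, greater_config = 2, state = 2),
    cross_constraint("C", lesser_config = 1, greater_config = 3, state = 2),
    cross_constraint("C", lesser_config = 1, greater_config = 4, state = 2),
    cross_constraint("C", lesser_config = 2, greater_config = 4, state = 2),
    cross_constraint("C", lesser_config = 3, greater_config = 4, state = 2),
    net = net
  )
  prior <- tibble(
    node = "C",
    j = rep(1:4, times = 2),
    k = rep(1:2, each = 4),
    prob = c(0.99, 0.56, 0.60, 0.05,
             0.01, 0.44, 0.40, 0.95)
  )
  local_ess <- tibble(node = "C", j = 1:4, ess = c(50, 6, 50, 50))
  list(net = net, counts = counts, constraints = constraints,
       prior = prior, local_ess = local_ess, global_ess = 3)
}
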
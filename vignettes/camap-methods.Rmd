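---
title: "Constraint-adjusted MAP estimation: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-adjusted MAP estimation: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camap)
```

## The model

A discrete Bayesian network over variables $X_1, \dots, X_n$ factorizes the
joint distribution as $P(x) = \prod_i \theta_{i\,j(x)\,x_i}$, where
$\theta_{ijk}$ is the probability that node $i$ takes state $k$ given that
its parents are in joint configuration $j$ (of $q_i$ possible ones), and
each CPT row $\theta_{ij\cdot}$ lies on the $(r_i-1)$-simplex. Given
complete data with sufficient statistics $N_{ijk}$ (row sums $N_{ij}$), the
log-likelihood separates over rows, the ML estimate is $N_{ijk}/N_{ij}$,
and the conjugate Dirichlet prior with mean $\theta^{\mathrm{prior}}_{ij\cdot}$
and total mass $\alpha_{ij}$ (the *equivalent sample size*, ESS) gives the
MAP estimate

$$\hat\theta_{ijk} = \frac{N_{ijk} + \alpha_{ij}\,\theta^{\mathrm{prior}}_{ijk}}
                         {N_{ij} + \alpha_{ij}}.$$

The estimate is a convex combination of the data frequency and the prior
mean with weights $N_{ij}$ and $\alpha_{ij}$ — every entry moves
monotonically towards its prior value as $\alpha_{ij}$ grows, a property
the ESS bounds below rely on and that the test suite checks directly.

Expert knowledge enters as convex, linear constraints on CPT entries:
ranges on a single entry, orderings within a row ("state $k$ is at most as
likely as $k'$"), and orderings across parent configurations for a shared
state ("the effect is more likely under the stronger cause" — monotonic
influences). Constraints never span nodes, matching the per-node
decomposition of the likelihood; the simplex conditions are always
appended implicitly. Inequalities are treated as non-strict: strict
versions have no meaning for the linear programs and samplers involved,
and any interior prior satisfies them strictly anyway.

## Prior elicitation by polytope sampling

For each node, the declared constraints intersected with the simplex of
every row form a convex polytope over the node's flattened CPT (dimension
$q_i r_i$). The prior mean is the coordinate-wise average of
`n_samples` points drawn approximately uniformly from this polytope;
because the polytope is convex, the average itself satisfies every
constraint — the package re-checks this after every elicitation.

Sampling uses hit-and-run: from a current interior point, draw an
isotropic Gaussian direction, project it onto the affine hull of the
row-sum equalities, intersect the line with the polytope, and jump to a
uniform point of the resulting chord. The chain starts at the polytope's
Chebyshev center (computed by linear programming with constraint normals
projected onto the same affine hull, so the inscribed ball is measured in
the right subspace) and discards `burn_in = 100` steps. A diversity rule
keeps consecutive *retained* points at Euclidean distance at least
`tau = 0.1` by rejecting closer candidates; when a polytope is too small
for that separation, `tau` is halved up to ten times and finally dropped
with a warning. On a one-dimensional polytope (any binary row) the chord
resample makes retained draws essentially independent, which is what the
closed-form checks in the tests exploit: an unconstrained binary row
averages to $1/2$, and a row constrained to $[0.6, 1]$ averages to the
midpoint $0.8$.

Defaults: `n_samples = 100`, `tau = 0.1`, `burn_in = 100`. Nodes without
constraints run through the same code path on the bare simplex, yielding
an approximately uniform prior; this is why the pipeline degrades
gracefully to (sampled-prior) MAP when no constraints are supplied.
Elicited priors for strongly constrained rows are *means over the
polytope*, so they are moderate by construction; an expert system that
wants extreme priors would need tighter constraints, not more samples.

## ESS bounds and selection

When the prior satisfies a constraint but the data violate it, the MAP
estimate satisfies it only for a sufficiently large ESS. Solving the MAP
expression against each constraint type gives the minimal ESS in closed
form:

* **Range** $l \le \hat\theta \le u$: each side is linear in $\alpha$;
  the bound is the larger of the two one-sided requirements (e.g.
  $\alpha \ge (N_{ij} l - N_{ijk}) / (\theta^{\mathrm{prior}}_{ijk} - l)$
  for the lower side), zero when the data already guarantee it, and
  infinite (unsatisfiable) when the prior itself sits on the violating
  side.
* **Intra** $\hat\theta_{k_1} \le \hat\theta_{k_2}$: the shared row total
  and ESS cancel, leaving
  $\alpha \ge (N_{ijk_2} - N_{ijk_1}) / (\theta^{\mathrm{prior}}_{k_1} -
  \theta^{\mathrm{prior}}_{k_2})$ when the prior is strictly ordered.
* **Cross** $\hat\theta_{ij_1k} \le \hat\theta_{ij_2k}$: with a common
  ESS on both configurations the inequality becomes a quadratic
  $A\alpha^2 + B\alpha + C \le 0$ with $A$ the prior gap, $C$ the
  cross-multiplied count gap, and the mixed term in $B$; all leading-sign
  cases are solved in closed form and the smallest feasible
  $\alpha \ge 0$ is returned (floating comparisons at $10^{-12}$).

A dense $\alpha$-grid oracle verifies on random instances that each bound
is *tight*: the constraint holds at $\alpha = B$ and fails at
$B - 0.01$ whenever $B > 0$.

Selection proceeds in two stages. The **global** ESS of each node is
chosen from the integer candidates `1..max_ess` (default 50) by
cross-validation: 5 random folds (leave-one-out below 10 records), scored
by the summed held-out log-likelihood of the MAP estimates fit on the
training folds, ties going to the smallest candidate (weakest prior
influence — the minimal-regularization convention, since no tie-break is
canonical). **Local** ESS values then follow three rules: configurations
without constraints inherit the global value; configurations whose global
value already meets their maximal bound inherit it too; the rest are
cross-validated over candidates starting at the ceiling of their bound
(scored on held-out records falling in that configuration). A bound above
`max_ess` is honored anyway — constraint satisfaction outranks the grid —
with a warning, and an unsatisfiable bound falls back to `max_ess`.

Because the cross-constraint bound assumes *equal* ESS on both sides but
the assignment may end up unequal, a post-hoc pass re-checks all
constraints on the final estimates and jointly escalates the two
configurations of any violated cross constraint along the grid until it
holds or the grid is exhausted; residual violations are reported in the
fit's diagnostics rather than silently accepted.

## Estimators

* `ml_estimate()` — $N_{ijk}/N_{ij}$; unobserved rows fall back to
  uniform with a message.
* `map_uniform()` — the MAP baseline: prior $1/r_i$, ESS 1.
* `cml_estimate()` — constrained ML: the multinomial log-likelihood is
  concave and the constraints linear, so each node's full CPT (cross
  constraints couple its rows) is maximized with a log-barrier method in
  reduced simplex coordinates (the last state of each row substituted
  out). A numerical note: the inner BFGS runs at its default relative
  tolerance, because an overly tight tolerance lets iterates land exactly
  on a face and break the next barrier step.
* `cme_estimate()` / `me_estimate()` — entropy baselines. The literature
  offers several formalizations; this package maximizes the summed row
  entropy subject to the constraints and a likelihood slab
  $\ell(\theta) \ge \ell^{*} - \varepsilon N$, where $\ell^{*}$ is the
  *constrained* maximum (so the slab is never empty) and
  $\varepsilon$ = `me_epsilon` (default 0.05 nats/record). It is solved
  by bisection on the Lagrange multiplier of the slab with the same
  concave inner solver. The two limits pin the definition down:
  $\varepsilon \to \infty$ gives the uniform distribution,
  $\varepsilon \to 0$ the (constrained) ML estimate. This is a documented
  reconstruction of the baseline's *behavior*, not a reproduction of any
  particular implementation.
* `camap_fit()` — the full pipeline: feasibility check, prior
  elicitation, bound derivation, global CV, local assignment, MAP
  estimation, satisfaction report. A `prior` or `ess` argument pins that
  stage, which is how the worked example is reproduced exactly.

Feasibility of a constraint set is decided per node by linear
programming; an infeasible set aborts the fit with the offending nodes
named — the package never relaxes expert constraints silently. The LP
solver breaks pivot ties at random and can stall on degenerate bases, so
the package retries it under fixed sub-seeds and validates the returned
point before trusting it; a genuine infeasibility is declared only after
all retries agree.

## Evaluation

Accuracy against a known truth is the Kullback–Leibler divergence between
joint distributions, computed in factorized form
$\sum_i \sum_j P^*(\mathrm{pa}_i = j) \, \mathrm{KL}(\theta^*_{ij\cdot}
\,\|\, \hat\theta_{ij\cdot})$ with parent marginals obtained by exact
enumeration of the true joint (networks are kept small enough that this
is trivial). The factorized value is tested to agree with brute-force
enumeration over all joint outcomes to $10^{-9}$. A `row_mean` variant
(the unweighted mean of per-row divergences) is available since reported
divergences in the literature are sometimes of that form. If an estimate
places probability zero where the truth is positive the divergence is
reported as `Inf`; in the benchmark, ML and CML — the two estimators that
can produce exact zeros — are floored at $10^{-12}$ and renormalized
before evaluation, and flagged as such in the output.

The `dasgupta_sample_bound()` helper evaluates the classical
sample-complexity lower bound for ML parameter learning of binary
networks, for context on why 10–50 records is far inside the
small-sample regime; typeset statements of the bound are ambiguous about
the grouping of its final logarithm, and the reading
$\ln((1 + 3n/\varepsilon)/(\varepsilon\delta))$ is adopted here.

## The synthetic benchmark

Real expert networks are not redistributable, so the harness emulates the
study conditions with synthetic stand-ins:

* **Networks** — `make_test_network()`: 5 binary nodes, at most 2 parents
  (small enough for exact joint KL), random DAG, CPT rows drawn from a
  symmetric Dirichlet whose concentration encodes the uniformity profile:
  0.1 (strongly skewed), 0.5 (skewed), 5 (uniform), 50 (strongly
  uniform); the `combined` profile mixes strongly-skewed and
  strongly-uniform rows and is the default benchmark condition.
* **Constraints** — `generate_constraints_from_truth()`: an expert who
  knows the truth approximately. Range widths are drawn uniformly from
  $[0.15, 0.25]$ ("around 0.2"; no distribution is canonical, so a
  symmetric uniform is used and configurable); ordering constraints are
  emitted only where the true gap is at least 0.2; at most 3 constraints
  per node are kept by seeded subsampling. Generated sets are satisfied
  by the truth by construction, hence always feasible.
* **Protocol** — `run_benchmark()`: per replicate one network, one
  maximal dataset (sample-size grids reuse prefixes), one shuffled
  constraint order (fraction grids take nested subsets), so conditions
  are paired within replicates; everything is driven by one master seed
  and is bit-reproducible. The package's own acceptance checks run 30
  replicates at 20 records on the `combined` profile — a desk-scale
  problem size chosen so the full directional comparison (constraints
  help CaMAP; CaMAP beats floored ML; uniform-prior MAP is at most
  marginally better when no constraints exist) is stable without being
  wasteful; larger replicate counts only tighten the same comparisons.

What passing these tests shows — and what it does not: the generator
produces small binary networks with exactly calibrated constraints and
complete, perfectly sampled data. It does not emulate misspecified or
inconsistent expert knowledge, non-binary variables at scale, missing
data, or structure uncertainty, so benchmark results speak to the
method's behavior under its own assumptions, not to robustness against
violated ones.

## Degenerate inputs and numerical choices

* Rows with no observations: ML falls back to uniform (logged); MAP-type
  estimators return the prior row, which is the correct $N_{ij} = 0$
  limit.
* Constraint satisfaction is checked with tolerance $10^{-9}$;
  feasibility witnesses are validated against the constraints before
  use.
* Hit-and-run chords shorter than $10^{-12}$ trigger direction
  resampling, so degenerate (lower-dimensional) polytopes do not stall
  the sampler.
* All randomized steps (sampling, folds, subsampling, the LP's pivot
  ties) derive from explicit seeds; fits and benchmarks are
  bit-reproducible given the seed.
* State and configuration indices are 1-based throughout, the natural R
  convention; configuration $j$ encodes parent states in declared order
  with the first parent most significant. Default state *labels* are
  `"0", "1", ...`, matching the binary conventions of the worked
  example.

## Known limitations

* Exact joint enumeration limits KL evaluation to small networks
  (guarded at $10^6$ outcomes); larger networks would need an inference
  engine, which is out of scope.
* Cross-constraint bounds are derived under equal ESS on the two
  configurations; the post-hoc escalation pass covers the unequal case
  but may hit the candidate ceiling, in which case the violation is
  reported rather than resolved.
* The hit-and-run prior is approximately uniform over the polytope; for
  very elongated polytopes the fixed burn-in may undercover the extremes.
  The diversity rule mitigates but does not eliminate autocorrelation in
  more than one dimension.
* Complete data only; no missing-data (EM) support, and no structure
  learning — the DAG is always given.
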
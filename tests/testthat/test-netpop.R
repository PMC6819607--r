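test_that("required_tie_counts inverts the homophily index", {
  # pi = 0.5, hx = 1 -> equal within and between ties
  q <- required_tie_counts(0.5, 1.0, 1000)
  expect_equal(unname(q["t_ii"]), unname(q["t_ij"]))
  # algebraic inversions: ratio r = hx / (2 pi (1 - pi)) - 1
  q <- required_tie_counts(0.5, 1.5, 3000)
  expect_equal(q[["t_ii"]] / q[["t_ij"]], 2.0, tolerance = 1e-3)
  q <- required_tie_counts(0.1, 1.5, 75000)
  expect_equal(q[["t_ii"]] / q[["t_ij"]], 1.5 / 0.18 - 1, tolerance = 1e-3)
  # round trip: plugging quotas back recovers hx to the resolution of the
  # integer quota grid (one between-tie moves the index by ~hx / t_ij;
  # a 1/total_edges bound is not attainable when t_ij << total_edges)
  for (pi in c(0.1, 0.3, 0.5)) for (hx in c(1, 1.1, 1.25, 1.5)) {
    E <- 23750
    q <- required_tie_counts(pi, hx, E)
    expect_equal(sum(q), E)
    expect_lt(abs(realized_homophily(pi, q["t_ii"], q["t_ij"]) - hx),
              hx / q[["t_ij"]])
  }
  expect_error(required_tie_counts(0.5, 0.3, 100), "infeasible homophily")
  expect_error(required_tie_counts(1.2, 1, 100), "strictly between")
})

test_that("group assignment has exact counts and the stated covariates", {
  set.seed(4)
  av <- assign_groups_and_covariates(10, 0.5)
  expect_equal(sum(av$group), 5)
  av <- assign_groups_and_covariates(20000, 0.3)
  expect_equal(sum(av$group), 6000)
  expect_lt(abs(mean(av$X_predict[av$group == 1]) -
                  mean(av$X_predict[av$group == 0]) - 2), 0.1)
  expect_lt(abs(stats::cor(av$X_NULL, av$group)), 0.03)
  # degree-balanced variant keeps exact counts and fixes omega ~ 1
  d <- sample_degrees(20000)
  av <- assign_groups_and_covariates(20000, 0.1, degrees = d)
  expect_equal(sum(av$group), 2000)
  expect_lt(abs(mean(d[av$group == 0]) / mean(d[av$group == 1]) - 1), 0.04)
})

test_that("wire_network: 4 degree-1 nodes, parity forces an even split", {
  # with two degree-1 nodes per group, exhaustive enumeration of perfect
  # matchings shows the only simple outcomes are 2 within-group edges or
  # 2 between-group edges; a (1 within, 1 between) quota is repaired by
  # moving one tie between pools
  for (s in 1:20) {
    set.seed(s)
    e <- wire_network(rep(1L, 4), c(1L, 1L, 0L, 0L),
                      c(t_ii = 1L, t_ij = 1L))
    expect_equal(nrow(e), 2L)
    expect_true(attr(e, "t_ij") %in% c(0L, 2L))
    expect_equal(tabulate(c(e), nbins = 4), rep(1L, 4))
  }
})

test_that("wire_network rejects infeasible quotas and odd stub totals", {
  expect_error(
    wire_network(c(1L, 1L, 5L, 5L), c(1L, 1L, 0L, 0L),
                 c(t_ii = 0L, t_ij = 6L)),
    "infeasible tie quota")
  expect_error(
    wire_network(c(1L, 1L, 1L), c(1L, 0L, 0L), c(t_ii = 1L, t_ij = 1L)),
    "even")
})

test_that("wire_network preserves degrees and honours quotas", {
  set.seed(5)
  n <- 400
  d <- sample_degrees(n, small_degree_spec())
  if (sum(d) %% 2) d[1] <- d[1] + 1L
  g <- as.integer(seq_len(n) <= n / 2)
  E <- sum(d) %/% 2
  q <- required_tie_counts(0.5, 1.3, E)
  e <- wire_network(d, g, q)
  # exact degree conservation (nothing dropped on this easy sequence)
  expect_equal(attr(e, "dropped"), 0L)
  expect_equal(tabulate(c(e), nbins = n), as.integer(d))
  expect_equal(sum(tabulate(c(e), nbins = n)), 2L * nrow(e))
  # simple graph: no loops, no duplicate edges
  expect_true(all(e[, 1] != e[, 2]))
  key <- pmin(e[, 1], e[, 2]) * 2^26 + pmax(e[, 1], e[, 2])
  expect_false(any(duplicated(key)))
  # realized between-group count within parity repair of the quota
  expect_lte(abs(attr(e, "t_ij") - q[["t_ij"]]), 1L)
})

test_that("igraph agrees that wired networks are simple", {
  skip_if_not_installed("igraph")
  set.seed(6)
  pop <- small_population(pi = 0.3, hx = 1.25, N = 500)
  g <- igraph::graph_from_edgelist(pop$edges, directed = FALSE)
  expect_true(igraph::is_simple(g))
  expect_equal(igraph::degree(g), pop$degree, ignore_attr = TRUE)
})

test_that("build_population meets its declared invariants", {
  for (s in 1:4) {
    pi <- c(0.1, 0.3, 0.5, 0.3)[s]
    hx <- c(1.0, 1.25, 1.5, 1.1)[s]
    set.seed(s)
    pop <- build_population(pi, hx, N = 2000, spec = small_degree_spec())
    expect_lt(abs(pop$hx_realized - hx), 0.02)
    expect_lt(abs(pop$prevalence_realized - pi), 1 / pop$N + 1e-12)
    expect_lt(abs(pop$omega_realized - 1), 0.05)
    expect_equal(sum(pop$degree), 2 * nrow(pop$edges))
    # homophily recomputed from stored tie counts matches the field
    expect_equal(realized_homophily(pop$prevalence_realized, pop$t_ii,
                                    pop$t_ij),
                 pop$hx_realized)
  }
})

test_that("population generation is deterministic given the seed", {
  set.seed(123)
  a <- build_population(0.3, 1.25, N = 800, spec = small_degree_spec())
  set.seed(123)
  b <- build_population(0.3, 1.25, N = 800, spec = small_degree_spec())
  expect_identical(a$edges, b$edges)
  expect_identical(a$group, b$group)
  expect_identical(a$X_predict, b$X_predict)
})

test_that("tiny-population tie quotas match exhaustive stub accounting", {
  # 8 nodes of degree 1, 4 per group: with t_ij = 2 the only simple
  # outcome has exactly 2 between edges and 2 within edges, and realized
  # homophily equals the quota-implied value
  for (s in 1:10) {
    set.seed(s)
    e <- wire_network(rep(1L, 8), rep(c(1L, 0L), each = 4),
                      c(t_ii = 2L, t_ij = 2L))
    expect_equal(nrow(e), 4L)
    expect_equal(attr(e, "t_ij"), 2L)
    g <- rep(c(1L, 0L), each = 4)
    between <- sum(g[e[, 1]] != g[e[, 2]])
    expect_equal(between, 2L)
  }
})

test_that("population parameters recover the Gaussian-discriminant truth", {
  set.seed(7)
  pop <- build_population(0.5, 1.0, N = 6000, spec = small_degree_spec())
  pp <- population_parameters(pop)
  expect_true(pp$converged)
  # equal-variance Gaussians with means 2 and 0 imply a logistic slope of
  # 2, i.e. OR -> e^2 ~ 7.39; allow finite-N jitter
  expect_lt(abs(pp$logit_coef - 2), 0.25)
  # no association for the null covariate
  df <- data.frame(y = pop$group, x = pop$X_NULL)
  or_null <- exp(stats::coef(stats::glm(y ~ x, stats::binomial(), df))[2])
  expect_lt(abs(or_null - 1), 0.15)
})

test_that("population serialization round-trips", {
  pop <- small_population(N = 300)
  dir <- withr::local_tempdir()
  write_population(pop, dir)
  back <- read_population(dir)
  expect_equal(back$degree, pop$degree)
  expect_equal(back$edges, pop$edges, ignore_attr = TRUE)
  expect_equal(back$hx_realized, pop$hx_realized)
  expect_equal(back$X_predict, pop$X_predict, tolerance = 1e-12)
})
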
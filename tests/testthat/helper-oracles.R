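# Independent oracles and small fixtures shared across test files.

# Newton-Raphson GLM oracle (canonical links), written without glm.fit:
# the reference for point estimates and model-based SEs.
nr_glm_oracle <- function(X, y, w = rep(1, length(y)),
                          family = c("binomial", "poisson"),
                          tol = 1e-12) {
  family <- match.arg(family)
  beta <- numeric(ncol(X))
  for (i in 1:200) {
    eta <- drop(X %*% beta)
    mu <- if (family == "binomial") stats::plogis(eta) else exp(eta)
    v <- if (family == "binomial") mu * (1 - mu) else mu
    score <- drop(crossprod(X, w * (y - mu)))
    info <- crossprod(X, X * (w * v))
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, se = sqrt(diag(solve(info))))
}

# brute-force cluster sandwich: explicit sum of outer products of cluster
# scores between two explicit bread inverses
bf_sandwich_oracle <- function(X, y, w, mu, v, cluster) {
  B <- crossprod(X, X * (w * v))
  U <- rowsum((w * (y - mu)) * X, cluster)
  Binv <- solve(B)
  Binv %*% crossprod(as.matrix(U)) %*% Binv
}

# independent dense GEE solver: builds the full block-diagonal working
# covariance and iterates to convergence (no code shared with fit_gee)
dense_gee_oracle <- function(X, y, cluster, family = "binomial",
                             corstr = "exchangeable", maxit = 100) {
  n <- length(y); p <- ncol(X)
  beta <- numeric(p)
  idx <- split(seq_len(n), cluster)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- if (family == "binomial") stats::plogis(eta) else exp(eta)
    v <- if (family == "binomial") mu * (1 - mu) else mu
    e <- (y - mu) / sqrt(v)
    phi <- sum(e^2) / (n - p)
    num <- 0; npairs <- 0
    for (i in idx) {
      if (length(i) < 2) next
      ee <- outer(e[i], e[i])
      num <- num + (sum(ee) - sum(diag(ee))) / 2
      npairs <- npairs + length(i) * (length(i) - 1) / 2
    }
    alpha <- if (npairs > p) num / ((npairs - p) * phi) else 0
    alpha <- max(0, min(alpha, 0.95))
    Vfull <- matrix(0, n, n)
    for (i in idx) {
      R <- (1 - alpha) * diag(length(i)) + alpha
      Vfull[i, i] <- outer(sqrt(v[i]), sqrt(v[i])) * R
    }
    D <- X * v
    lhs <- t(D) %*% solve(Vfull, D)
    rhs <- t(D) %*% solve(Vfull, y - mu)
    step <- solve(lhs, rhs)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  list(beta = beta, alpha = alpha)
}

# fast small-degree specification for cheap test populations
small_degree_spec <- function() {
  degree_spec(size = c(8L, 16L), prob = 0.5, weight = c(0.6, 0.4))
}

# small primary-style population (N defaults to 600)
small_population <- function(pi = 0.3, hx = 1.2, N = 600, seed = 99) {
  set.seed(seed)
  build_population(pi, hx, N = N, spec = small_degree_spec())
}

# hand-constructed population from an explicit edge list
manual_population <- function(edges, group = NULL, N = max(edges)) {
  edges <- matrix(as.integer(edges), ncol = 2, byrow = TRUE)
  if (is.null(group)) group <- rep(0L, N)
  set.seed(1)
  rdsregsim:::.new_population(
    N = as.integer(N),
    degree = tabulate(c(edges[, 1], edges[, 2]), nbins = N),
    group = as.integer(group),
    X_predict = stats::rnorm(N), X_NULL = stats::rnorm(N),
    edges = edges, pi = mean(group), hx = 1)
}

# a synthetic rds_sample data frame with controllable fields, for
# estimator and model-frame tests
manual_sample <- function(id, recruiter, wave, degree, group,
                          X_predict = NULL, X_NULL = NULL,
                          seed_of = NULL) {
  n <- length(id)
  if (is.null(X_predict)) X_predict <- stats::rnorm(n, 2 * group)
  if (is.null(X_NULL)) X_NULL <- stats::rnorm(n)
  if (is.null(seed_of)) {
    seed_of <- integer(n)
    for (i in seq_len(n))
      seed_of[i] <- if (is.na(recruiter[i])) id[i]
                    else seed_of[match(recruiter[i], id)]
  }
  out <- data.frame(id = id, seed = seed_of, recruiter = recruiter,
                    wave = wave, degree = degree, group = group,
                    X_predict = X_predict, X_NULL = X_NULL)
  attr(out, "n_waves") <- max(wave)
  attr(out, "n_seeds") <- sum(is.na(recruiter))
  attr(out, "n_reseeds") <- 0L
  class(out) <- c("rds_sample", "data.frame")
  out
}

# forest/invariant checker used by several files
expect_valid_rds_sample <- function(s, pop, config) {
  expect_false(anyDuplicated(s$id) > 0)
  expect_equal(nrow(s), config$target_n)
  seeds <- s$id[is.na(s$recruiter)]
  expect_true(all(s$wave[is.na(s$recruiter)] == 0))
  nonseed <- s[!is.na(s$recruiter), , drop = FALSE]
  if (nrow(nonseed)) {
    # single recruiter sampled earlier, wave arithmetic
    ridx <- match(nonseed$recruiter, s$id)
    expect_false(anyNA(ridx))
    expect_true(all(ridx < match(nonseed$id, s$id)))
    expect_equal(nonseed$wave, s$wave[ridx] + 1L)
    # coupon bound
    expect_true(all(table(nonseed$recruiter) <= config$coupons))
    # recruiter-recruit pairs are population edges
    key <- function(u, v) pmin(u, v) * 2^26 + pmax(u, v)
    ek <- key(pop$edges[, 1], pop$edges[, 2])
    expect_true(all(key(nonseed$recruiter, nonseed$id) %in% ek))
    # seed labels propagate along chains
    expect_equal(nonseed$seed, s$seed[ridx])
  }
  invisible(TRUE)
}
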
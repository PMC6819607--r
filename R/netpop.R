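#' Homophily from tie counts
#'
#' Population homophily is quantified as
#' `Hx = 2 * pi * (1 - pi) * (T_ii / T_ij + 1)` where `T_ii` and `T_ij`
#' are the numbers of within-group (both groups pooled) and between-group
#' ties.  Under proportionate (random) mixing with equal group activity
#' the expression equals 1 for any prevalence `pi`.
#'
#' @param pi outcome prevalence, the proportion of the population in G1.
#' @param t_ii,t_ij within- and between-group tie counts.
#' @return The homophily index, a non-negative real.
#' @export
realized_homophily <- function(pi, t_ii, t_ij) {
  if (t_ij <= 0) return(Inf)
  2 * pi * (1 - pi) * (t_ii / t_ij + 1)
}

#' Tie-count quotas for a target homophily
#'
#' Inverts the homophily index for a fixed number of edges: the required
#' ratio of within- to between-group ties is
#' `r = hx / (2 * pi * (1 - pi)) - 1`, and the between-group quota is the
#' nearest integer to `total_edges / (1 + r)`.
#'
#' @param pi outcome prevalence in (0, 1).
#' @param hx target homophily; must satisfy `hx >= 2 * pi * (1 - pi)`,
#'   otherwise the implied ratio would be negative.
#' @param total_edges total number of edges to apportion.
#'
#' @return Named integer-valued vector with elements `t_ii` and `t_ij`,
#'   summing to `total_edges`.
#' @export
required_tie_counts <- function(pi, hx, total_edges) {
  stopifnot(length(pi) == 1, length(hx) == 1, length(total_edges) == 1)
  if (!is.finite(pi) || pi <= 0 || pi >= 1)
    stop("`pi` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.finite(hx) || hx < 0)
    stop("`hx` must be a non-negative real", call. = FALSE)
  r <- hx / (2 * pi * (1 - pi)) - 1
  if (r < 0)
    stop(sprintf(
      "infeasible homophily: hx = %.3f is below the minimum 2*pi*(1-pi) = %.3f",
      hx, 2 * pi * (1 - pi)), call. = FALSE)
  # choose the integer quota whose implied homophily is closest to hx;
  # integer rounding moves the recovered index by about hx / (2 * t_ij)
  cand <- unique(pmax(1, pmin(total_edges,
                              c(floor(total_edges / (1 + r)),
                                ceiling(total_edges / (1 + r))))))
  err <- abs(vapply(cand, function(t)
    realized_homophily(pi, total_edges - t, t), numeric(1)) - hx)
  t_ij <- cand[which.min(err)]
  c(t_ii = total_edges - t_ij, t_ij = t_ij)
}

#' Assign group membership and covariates
#'
#' Exactly `round(n * pi)` individuals are placed in G1.  The continuous
#' predictor `X_predict` is drawn from N(2, 1) for members of G1 and
#' N(0, 1) for members of G2; `X_NULL` is pure N(0, 1) noise,
#' independent of everything else.
#'
#' When `degrees` is supplied, G1 membership is balanced across the
#' degree-sorted order (one exact-count draw per consecutive block of ten
#' individuals in degree rank).  This fixes the relative activity
#' `omega` (ratio of mean degree between groups) at 1 by construction,
#' which a simple random assignment only achieves in expectation -- with
#' a heavy-tailed degree distribution the realized ratio would otherwise
#' fluctuate well beyond the declared tolerance.
#'
#' @param n population size.
#' @param pi outcome prevalence in (0, 1).
#' @param degrees optional integer vector of network degrees used to
#'   balance the assignment (see Details).
#'
#' @return A list with elements `group` (integer 0/1), `X_predict` and
#'   `X_NULL` (numeric vectors of length `n`).
#' @export
assign_groups_and_covariates <- function(n, pi, degrees = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be >= 2", call. = FALSE)
  if (!is.finite(pi) || pi <= 0 || pi >= 1)
    stop("`pi` must lie strictly between 0 and 1", call. = FALSE)
  n1 <- round(n * pi)
  group <- integer(n)
  if (is.null(degrees)) {
    group[sample.int(n, n1)] <- 1L
  } else {
    if (length(degrees) != n)
      stop("`degrees` must have length `n`", call. = FALSE)
    ord <- order(degrees, stats::runif(n))    # random tie-break
    block <- ceiling(seq_along(ord) / 10)     # block of each position in `ord`
    # exact count per block via cumulative rounding of the quota; the
    # final cumulative value is n * pi, so the counts sum to n1 exactly
    quota <- diff(c(0, round(cumsum(tabulate(block) * pi))))
    r <- stats::ave(stats::runif(n), block, FUN = rank)
    group[ord[r <= quota[block]]] <- 1L
  }
  list(group = group,
       X_predict = stats::rnorm(n, mean = 2 * group, sd = 1),
       X_NULL = stats::rnorm(n))
}

# pair a shuffled stub vector into a 2-column edge matrix
.pair_stubs <- function(stubs) {
  m <- length(stubs) %/% 2L
  if (m == 0L) return(matrix(integer(0), 0, 2))
  cbind(stubs[seq_len(m)], stubs[m + seq_len(m)])
}

# Degree-preserving repair of self-loops and duplicate edges within one
# stub pool.  `between` pools keep column sides fixed (col 1 in G1,
# col 2 in G2); within pools are orientation-free.  A conflicting edge is
# swapped with a random partner edge only when neither replacement edge
# is a self-loop, already present, or proposed twice within the same
# round -- with a heavy-tailed degree sequence, unconditional swaps would
# merely re-create multi-edges at the configuration model's natural rate
# instead of converging.  Returns the repaired matrix plus the number of
# edges that had to be dropped (normally zero).
.repair_pool <- function(edges, between, max_rounds = 500L,
                         stall_rounds = 40L) {
  if (nrow(edges) < 2L) {
    drop <- edges[, 1] == edges[, 2]
    return(list(edges = edges[!drop, , drop = FALSE], dropped = sum(drop)))
  }
  key <- function(u, v) {
    if (between) u * 2^26 + v
    else pmin(u, v) * 2^26 + pmax(u, v)
  }
  best <- Inf; since_best <- 0L
  for (round in seq_len(max_rounds)) {
    k <- key(edges[, 1], edges[, 2])
    bad <- which(edges[, 1] == edges[, 2] | duplicated(k))
    if (length(bad) == 0L)
      return(list(edges = edges, dropped = 0L))
    # give up when no progress has been made for a while: the remaining
    # conflicts are then structural (a node needing more distinct
    # partners than its pool offers), not bad luck
    if (length(bad) < best) { best <- length(bad); since_best <- 0L }
    else if ((since_best <- since_best + 1L) >= stall_rounds) break
    partner <- sample.int(nrow(edges), length(bad), replace = TRUE)
    # the swap must be a permutation of stub slots: partners have to be
    # unique and disjoint from the bad set, otherwise stubs would be
    # duplicated or lost
    ok <- !(partner %in% bad) & !duplicated(partner) & partner != bad
    bad <- bad[ok]; partner <- partner[ok]
    if (length(bad) == 0L) next
    # proposed replacements: (u_bad, v_partner) and (u_partner, v_bad)
    new1 <- key(edges[bad, 1], edges[partner, 2])
    new2 <- key(edges[partner, 1], edges[bad, 2])
    valid <- !(new1 %in% k) & !(new2 %in% k) & new1 != new2
    if (!between)
      valid <- valid & edges[bad, 1] != edges[partner, 2] &
        edges[partner, 1] != edges[bad, 2]
    # no two proposals in the same round may introduce the same edge
    pk <- c(new1, new2)
    dup <- duplicated(pk) | duplicated(pk, fromLast = TRUE)
    valid <- valid & !(dup[seq_along(new1)] |
                         dup[length(new1) + seq_along(new2)])
    bad <- bad[valid]; partner <- partner[valid]
    if (length(bad) == 0L) next
    tmp <- edges[bad, 2]
    edges[bad, 2] <- edges[partner, 2]
    edges[partner, 2] <- tmp
  }
  k <- key(edges[, 1], edges[, 2])
  bad <- edges[, 1] == edges[, 2] | duplicated(k)
  list(edges = edges[!bad, , drop = FALSE], dropped = sum(bad))
}

#' Wire a network with fixed degrees, groups and tie quotas
#'
#' Configuration-model stub matching within three pools: `t_ij` stubs of
#' each group are paired across groups, the remaining stubs are paired
#' within their own group.  Self-loops and multi-edges are then removed
#' by degree-preserving edge swaps inside each pool, which also preserves
#' the within/between tie counts.  A stubborn conflict that survives the
#' swap rounds is dropped (bounded by the repair budget of 0.1% of
#' edges); in practice the swaps converge and nothing is dropped.
#'
#' @param degrees integer vector of stub counts per node; the total must
#'   be even.
#' @param groups integer 0/1 group membership per node.
#' @param tie_quotas named vector with elements `t_ii` and `t_ij`, e.g.
#'   from [required_tie_counts()].  The between-group quota may be
#'   adjusted by one tie to repair stub parity.
#' @param repair_budget maximum fraction of edges that may be dropped
#'   when conflicts are structurally unresolvable (e.g. a node requiring
#'   more distinct partners than its pool offers).
#'
#' @return Integer matrix with two columns (`u`, `v`), one row per edge,
#'   1-based node ids, with attributes `t_ij` (realized between-group
#'   count) and `dropped` (edges removed by the repair budget).
#' @export
wire_network <- function(degrees, groups, tie_quotas,
                         repair_budget = 1e-3) {
  degrees <- as.integer(degrees)
  groups <- as.integer(groups)
  stopifnot(length(degrees) == length(groups))
  if (any(degrees < 1L)) stop("all degrees must be >= 1", call. = FALSE)
  if (sum(degrees) %% 2L != 0L)
    stop("total degree must be even (repair parity before wiring)",
         call. = FALSE)
  t_ij <- as.integer(tie_quotas[["t_ij"]])
  s1 <- sum(degrees[groups == 1L])
  s2 <- sum(degrees[groups == 0L])
  if (t_ij > min(s1, s2))
    stop(sprintf(paste0(
      "infeasible tie quota: t_ij = %d exceeds the available stubs ",
      "min(S1, S2) = %d"), t_ij, min(s1, s2)), call. = FALSE)
  if ((s1 - t_ij) %% 2L != 0L) {
    # move one tie between pools; S1 and S2 have the same parity
    t_ij <- if (t_ij + 1L <= min(s1, s2)) t_ij + 1L else t_ij - 1L
  }
  if (s1 - t_ij < 0L || s2 - t_ij < 0L)
    stop("infeasible tie quota after parity repair", call. = FALSE)

  ids <- seq_along(degrees)
  stubs1 <- sample(rep.int(ids[groups == 1L], degrees[groups == 1L]))
  stubs2 <- sample(rep.int(ids[groups == 0L], degrees[groups == 0L]))

  if (t_ij > 0L) {
    between <- cbind(stubs1[seq_len(t_ij)], stubs2[seq_len(t_ij)])
    rem1 <- stubs1[-seq_len(t_ij)]
    rem0 <- stubs2[-seq_len(t_ij)]
  } else {
    between <- matrix(integer(0), 0, 2)
    rem1 <- stubs1
    rem0 <- stubs2
  }
  within1 <- .pair_stubs(rem1)
  within0 <- .pair_stubs(rem0)

  rb <- .repair_pool(between, between = TRUE)
  r1 <- .repair_pool(within1, between = FALSE)
  r0 <- .repair_pool(within0, between = FALSE)
  dropped <- rb$dropped + r1$dropped + r0$dropped
  total <- nrow(between) + nrow(within1) + nrow(within0)
  if (dropped > max(10, repair_budget * total))
    stop("network repair exceeded its budget: ", dropped,
         " conflicting edges could not be rewired", call. = FALSE)

  edges <- rbind(rb$edges, r1$edges, r0$edges)
  storage.mode(edges) <- "integer"
  realized <- tabulate(c(edges[, 1], edges[, 2]), nbins = length(degrees))
  if (sum(abs(realized - degrees)) != 2L * dropped)
    stop("internal error: edge swaps did not preserve the degree sequence",
         call. = FALSE)
  colnames(edges) <- c("u", "v")
  attr(edges, "t_ij") <- nrow(rb$edges)
  attr(edges, "dropped") <- dropped
  edges
}

# adjacency list from an edge matrix
.adjacency <- function(edges, n) {
  adj <- vector("list", n)
  ends <- c(edges[, 1], edges[, 2])
  nbrs <- c(edges[, 2], edges[, 1])
  ord <- order(ends)
  split_idx <- split(nbrs[ord], ends[ord])
  adj[as.integer(names(split_idx))] <- split_idx
  empty <- vapply(adj, is.null, logical(1))
  adj[empty] <- list(integer(0))
  adj
}

.new_population <- function(N, degree, group, X_predict, X_NULL, edges,
                            pi, hx, extra = list()) {
  g1 <- group[edges[, 1]] + group[edges[, 2]]
  t_ij <- sum(g1 == 1L)
  t_ii <- nrow(edges) - t_ij
  hx_real <- realized_homophily(pi, t_ii, t_ij)
  omega <- mean(degree[group == 0L]) / mean(degree[group == 1L])
  structure(
    c(list(
      N = N, degree = degree, group = group,
      X_predict = X_predict, X_NULL = X_NULL, edges = edges,
      adjacency = .adjacency(edges, N),
      pi = pi, hx = hx,
      prevalence_realized = mean(group),
      hx_realized = hx_real, omega_realized = omega,
      t_ii = t_ii, t_ij = t_ij
    ), extra),
    class = "networked_population"
  )
}

#' Generate a networked population with controlled prevalence and
#' homophily
#'
#' Composes [sample_degrees()], [assign_groups_and_covariates()],
#' [required_tie_counts()] and [wire_network()] into a single simple
#' undirected graph over `N` individuals.  Group labels are balanced
#' across degrees so the relative activity `omega` is 1; the homophily of
#' the wiring is controlled through the tie quotas.  Generation fails
#' with an error if the realized homophily deviates from the declared
#' value by more than 0.02 -- it never silently degrades.
#'
#' @param pi outcome prevalence (proportion in G1).
#' @param hx target homophily (see [realized_homophily()]).
#' @param N population size; the reference study uses 10,000.
#' @param spec degree distribution, a [degree_spec()].
#'
#' @return A `networked_population`: per-node `degree`, `group`,
#'   `X_predict`, `X_NULL`; the edge list; an adjacency list; and the
#'   declared and realized population parameters (`pi`, `hx`,
#'   `hx_realized`, `omega_realized`, `t_ii`, `t_ij`).
#' @export
build_population <- function(pi, hx, N = 10000, spec = default_degree_spec()) {
  N <- as.integer(N)
  degree <- sample_degrees(N, spec)
  if (sum(degree) %% 2L != 0L) {
    i <- sample.int(N, 1L)
    degree[i] <- degree[i] + 1L          # parity repair, one stub
  }
  av <- assign_groups_and_covariates(N, pi, degrees = degree)
  quotas <- required_tie_counts(pi, hx, sum(degree) %/% 2L)
  edges <- wire_network(degree, av$group, quotas)
  realized_degree <- tabulate(c(edges[, 1], edges[, 2]), nbins = N)
  pop <- .new_population(N, realized_degree, av$group, av$X_predict,
                         av$X_NULL, edges, pi, hx)
  if (abs(pop$hx_realized - hx) > 0.02)
    stop(sprintf("realized homophily %.4f deviates from declared %.3f",
                 pop$hx_realized, hx), call. = FALSE)
  if (abs(pop$omega_realized - 1) > 0.05)
    stop(sprintf("realized relative activity %.3f deviates from 1",
                 pop$omega_realized), call. = FALSE)
  pop
}

#' Generate a population with correlated degree and outcome
#'
#' Secondary populations fix the prevalence at 10% and assign G1
#' membership as a function of network degree: `extreme_pos`
#' (`extreme_neg`) places the top (bottom) decile of degrees in G1;
#' `moderate_pos` (`moderate_neg`) walks deciles from the top (bottom),
#' assigning 50% more members to G1 than expected under independence
#' (15% of each decile) until 10% of the population is in G1.  The
#' realized degree-outcome correlation `rho` is measured and recorded,
#' not targeted.
#'
#' Because G1 then holds a fixed share of the stubs, the between-group
#' tie quota implied by the declared homophily can exceed the stubs
#' available in the smaller-activity group (this always happens for the
#' negative-correlation modes).  The quota is clipped to the feasible
#' range and the realized homophily recorded; the declared value is kept
#' as metadata.
#'
#' @param mode one of `"extreme_pos"`, `"extreme_neg"`,
#'   `"moderate_pos"`, `"moderate_neg"`.
#' @param hx declared homophily (the reference study uses 1.25 and 1.5).
#' @param N population size.
#' @param spec degree distribution.
#'
#' @return A `networked_population` with additional fields `mode`,
#'   `rho` (realized degree-outcome correlation) and `hx_clipped`
#'   (logical, whether the tie quota had to be clipped).
#' @export
build_correlated_population <- function(mode = c("extreme_pos", "extreme_neg",
                                                 "moderate_pos", "moderate_neg"),
                                        hx, N = 10000,
                                        spec = default_degree_spec()) {
  mode <- match.arg(mode)
  pi <- 0.1
  N <- as.integer(N)
  degree <- sample_degrees(N, spec)
  if (sum(degree) %% 2L != 0L) {
    i <- sample.int(N, 1L)
    degree[i] <- degree[i] + 1L
  }
  n1 <- round(N * pi)
  ord <- order(degree, stats::runif(N),
               decreasing = grepl("pos", mode))
  group <- integer(N)
  if (grepl("extreme", mode)) {
    group[ord[seq_len(n1)]] <- 1L
  } else {
    # walk deciles, over-assigning by 50% relative to expectation
    per_decile <- round(1.5 * pi * N / 10)
    deciles <- split(ord, ceiling(seq_len(N) / (N / 10)))
    left <- n1
    for (dec in deciles) {
      if (left <= 0) break
      k <- min(per_decile, left, length(dec))
      group[sample(dec, k)] <- 1L
      left <- left - k
    }
  }
  X_predict <- stats::rnorm(N, mean = 2 * group, sd = 1)
  X_NULL <- stats::rnorm(N)

  total_edges <- sum(degree) %/% 2L
  quotas <- required_tie_counts(pi, hx, total_edges)
  s1 <- sum(degree[group == 1L]); s2 <- sum(degree[group == 0L])
  clipped <- FALSE
  if (quotas[["t_ij"]] > min(s1, s2)) {
    clipped <- TRUE
    quotas <- c(t_ii = total_edges - min(s1, s2), t_ij = min(s1, s2))
  }
  # extreme assignments push the within-group pools to the simple-graph
  # boundary (a top-decile hub may need more distinct same-group
  # neighbours than the group holds), so allow a wider repair budget;
  # dropped edges are recorded on the edge matrix
  edges <- wire_network(degree, group, quotas, repair_budget = 0.01)
  realized_degree <- tabulate(c(edges[, 1], edges[, 2]), nbins = N)
  .new_population(N, realized_degree, group, X_predict, X_NULL, edges,
                  pi, hx,
                  extra = list(mode = mode,
                               rho = stats::cor(realized_degree, group),
                               hx_clipped = clipped,
                               edges_dropped = attr(edges, "dropped")))
}

#' @export
print.networked_population <- function(x, ...) {
  cat(sprintf(
    "Networked population: N = %d, %d edges\n", x$N, nrow(x$edges)))
  cat(sprintf("  prevalence: declared %.3f, realized %.4f\n",
              x$pi, x$prevalence_realized))
  cat(sprintf("  homophily:  declared %.3f, realized %.4f%s\n",
              x$hx, x$hx_realized,
              if (isTRUE(x$hx_clipped)) " (tie quota clipped)" else ""))
  cat(sprintf("  relative activity omega = %.3f; degree: median %d, mean %.1f\n",
              x$omega_realized, stats::median(x$degree), mean(x$degree)))
  if (!is.null(x$mode))
    cat(sprintf("  degree-outcome mode %s, rho = %.3f\n", x$mode, x$rho))
  invisible(x)
}

#' Full-population regression parameters
#'
#' The "true" risk parameters against which sample-based estimates are
#' judged: unweighted, unclustered generalized linear fits of group
#' membership on `X_predict` over the complete population.  The logit
#' link gives the population odds ratio, the log link the population
#' relative risk, both per unit increase in the predictor.
#'
#' @param pop a `networked_population`.
#' @return An object of class `population_parameters` with elements
#'   `odds_ratio`, `relative_risk`, the link-scale coefficients and
#'   convergence flags.
#' @export
population_parameters <- function(pop) {
  stopifnot(inherits(pop, "networked_population"))
  df <- data.frame(y = pop$group, x = pop$X_predict)
  logit <- stats::glm(y ~ x, family = stats::binomial(), data = df)
  pois <- suppressWarnings(
    stats::glm(y ~ x, family = stats::poisson(), data = df))
  structure(list(
    odds_ratio = unname(exp(stats::coef(logit)[["x"]])),
    relative_risk = unname(exp(stats::coef(pois)[["x"]])),
    logit_coef = unname(stats::coef(logit)[["x"]]),
    log_coef = unname(stats::coef(pois)[["x"]]),
    converged = logit$converged && pois$converged
  ), class = "population_parameters")
}

#' @export
print.population_parameters <- function(x, ...) {
  cat(sprintf("Population parameters: OR = %.3f, RR = %.3f%s\n",
              x$odds_ratio, x$relative_risk,
              if (!x$converged) " (non-converged!)" else ""))
  invisible(x)
}
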
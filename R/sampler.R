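#' Respondent-driven sampling configuration
#'
#' Defaults reproduce the reference design: ten uniformly drawn seeds,
#' three coupons per participant, 50% non-response in both groups and a
#' target sample size of 500.
#'
#' @param n_seeds number of initial seeds.
#' @param coupons maximum number of recruitment offers per participant.
#' @param response_prob probability that an offer is accepted; identical
#'   in both outcome groups.
#' @param target_n number of participants to enrol.
#' @param allow_reseed if `TRUE` (default) a stalled sample draws a fresh
#'   uniform seed instead of failing; every reseed is logged in the
#'   sample metadata.
#'
#' @return An object of class `rds_config`.
#' @export
rds_config <- function(n_seeds = 10L, coupons = 3L, response_prob = 0.5,
                       target_n = 500L, allow_reseed = TRUE) {
  n_seeds <- as.integer(n_seeds); coupons <- as.integer(coupons)
  target_n <- as.integer(target_n)
  if (coupons < 1L) stop("`coupons` must be >= 1", call. = FALSE)
  if (n_seeds < 1L) stop("`n_seeds` must be >= 1", call. = FALSE)
  if (!is.finite(response_prob) || response_prob <= 0 || response_prob > 1)
    stop("`response_prob` must lie in (0, 1]", call. = FALSE)
  if (target_n < n_seeds)
    stop("`target_n` must be at least `n_seeds`", call. = FALSE)
  structure(list(n_seeds = n_seeds, coupons = coupons,
                 response_prob = response_prob, target_n = target_n,
                 allow_reseed = isTRUE(allow_reseed)),
            class = "rds_config")
}

#' Draw seeds uniformly at random
#'
#' @param pop a `networked_population`.
#' @param k number of distinct seeds to draw.
#' @return Integer vector of `k` node ids.
#' @export
draw_seeds <- function(pop, k) {
  stopifnot(inherits(pop, "networked_population"))
  k <- as.integer(k)
  if (k > pop$N)
    stop("cannot draw more seeds than there are nodes", call. = FALSE)
  sample.int(pop$N, k)
}

#' Draw one respondent-driven sample
#'
#' Breadth-wise chain-referral sampling: each enrolled participant offers
#' up to `coupons` coupons to uniformly chosen not-yet-sampled
#' neighbours; each offer is accepted independently with probability
#' `response_prob` (a declined offer consumes the coupon, and the invitee
#' remains eligible for later offers from others).  Accepted recruits
#' join the next wave; no node is ever enrolled twice.  Sampling stops
#' when `target_n` participants are enrolled, truncating the final wave
#' in randomized enrolment order.  If every chain dies out first, a fresh
#' uniform seed is drawn when `allow_reseed` is on, otherwise the sample
#' fails with a dead-chain error.
#'
#' @param pop a `networked_population`.
#' @param config an [rds_config()].
#' @param seeds optional vector of node ids to use as the initial seeds
#'   instead of drawing them uniformly (useful for diagnostics and for
#'   reproducing hand-enumerable cases).
#'
#' @return An object of class `rds_sample`: a data frame with one row per
#'   participant (`id`, `seed`, `recruiter` -- `NA` for seeds, `wave`,
#'   `degree`, `group`, `X_predict`, `X_NULL`) carrying attributes
#'   `n_waves`, `recruits_per_seed`, `n_seeds` (seeds drawn, including
#'   reseeds), `n_reseeds` and `productive_seeds`.
#' @export
rds_sample <- function(pop, config = rds_config(), seeds = NULL) {
  stopifnot(inherits(pop, "networked_population"))
  if (!inherits(config, "rds_config"))
    stop("`config` must be an rds_config", call. = FALSE)
  n <- config$target_n
  if (n > pop$N)
    stop("`target_n` exceeds the population size", call. = FALSE)
  adj <- pop$adjacency
  sampled <- logical(pop$N)

  id <- integer(n); seed_of <- integer(n); recruiter <- rep(NA_integer_, n)
  wave <- integer(n)
  n_enrolled <- 0L
  n_reseeds <- 0L

  enrol <- function(ids, seeds, recs, w) {
    keep <- seq_len(min(length(ids), n - n_enrolled))
    idx <- n_enrolled + keep
    id[idx] <<- ids[keep]; seed_of[idx] <<- seeds[keep]
    recruiter[idx] <<- recs[keep]; wave[idx] <<- w[keep]
    n_enrolled <<- n_enrolled + length(keep)
  }

  seeds0 <- if (is.null(seeds)) draw_seeds(pop, min(config$n_seeds, n))
            else as.integer(seeds)
  sampled[seeds0] <- TRUE
  ord <- sample.int(length(seeds0))
  enrol(seeds0[ord], seeds0[ord], rep(NA_integer_, length(seeds0)),
        rep(0L, length(seeds0)))
  total_seeds <- length(seeds0)

  current <- seeds0                      # recruiters of the ongoing wave
  cur_seed <- seeds0
  cur_wave <- 0L

  while (n_enrolled < n) {
    nxt_id <- integer(0); nxt_seed <- integer(0); nxt_rec <- integer(0)
    for (j in sample.int(length(current))) {   # random recruiter order
      r <- current[j]
      un <- adj[[r]]
      un <- un[!sampled[un]]
      if (length(un) == 0L) next
      offers <- if (length(un) > config$coupons)
        un[sample.int(length(un), config$coupons)] else un
      accepted <- offers[stats::runif(length(offers)) <= config$response_prob]
      if (length(accepted) == 0L) next
      sampled[accepted] <- TRUE
      nxt_id <- c(nxt_id, accepted)
      nxt_seed <- c(nxt_seed, rep(cur_seed[j], length(accepted)))
      nxt_rec <- c(nxt_rec, rep(r, length(accepted)))
    }
    if (length(nxt_id) == 0L) {
      # dead chains
      candidates <- which(!sampled)
      if (!config$allow_reseed || length(candidates) == 0L)
        stop("dead-chain: recruitment exhausted before reaching target_n ",
             "(", n_enrolled, " of ", n, " enrolled)", call. = FALSE)
      s <- candidates[sample.int(length(candidates), 1L)]
      sampled[s] <- TRUE
      enrol(s, s, NA_integer_, 0L)
      n_reseeds <- n_reseeds + 1L
      total_seeds <- total_seeds + 1L
      current <- s; cur_seed <- s; cur_wave <- 0L
      next
    }
    ord <- sample.int(length(nxt_id))    # randomized enrolment order
    enrol(nxt_id[ord], nxt_seed[ord], nxt_rec[ord],
          rep(cur_wave + 1L, length(ord)))
    current <- nxt_id; cur_seed <- nxt_seed
    cur_wave <- cur_wave + 1L
  }

  out <- data.frame(
    id = id, seed = seed_of, recruiter = recruiter, wave = wave,
    degree = pop$degree[id], group = pop$group[id],
    X_predict = pop$X_predict[id], X_NULL = pop$X_NULL[id]
  )
  productive <- length(unique(out$seed[!is.na(out$recruiter)]))
  attr(out, "n_waves") <- max(out$wave)
  attr(out, "n_seeds") <- total_seeds
  attr(out, "n_reseeds") <- n_reseeds
  attr(out, "productive_seeds") <- productive
  attr(out, "recruits_per_seed") <-
    if (productive > 0) (nrow(out) - total_seeds) / productive else NA_real_
  attr(out, "population") <- Filter(Negate(is.null),
                                    list(pi = pop$pi, hx = pop$hx,
                                         mode = pop$mode))
  class(out) <- c("rds_sample", "data.frame")
  out
}

#' Correlation between sampling frequency and degree
#'
#' Draws `n_samples` independent RDS samples, counts the number of
#' samples each node appears in, and returns the Pearson correlation
#' between that inclusion frequency and network degree over all nodes.
#' A confirmation that the sampler includes participants roughly in
#' proportion to their connectedness.
#'
#' @param pop a `networked_population`.
#' @param n_samples number of replicate samples (>= 2).
#' @param config an [rds_config()].
#'
#' @return The Pearson correlation (a single number).
#' @export
sampling_frequency_correlation <- function(pop, n_samples,
                                           config = rds_config()) {
  if (n_samples < 2) stop("`n_samples` must be >= 2", call. = FALSE)
  freq <- integer(pop$N)
  for (b in seq_len(n_samples)) {
    s <- rds_sample(pop, config)
    freq[s$id] <- freq[s$id] + 1L
  }
  if (stats::sd(freq) == 0 || stats::sd(pop$degree) == 0)
    stop("undefined correlation: sampling frequency or degree is constant",
         call. = FALSE)
  stats::cor(freq, pop$degree)
}

#' @export
print.rds_sample <- function(x, ...) {
  cat(sprintf(
    "RDS sample: n = %d, %d seeds (%d reseeds), %d waves, %.1f recruits per productive seed\n",
    nrow(x), attr(x, "n_seeds"), attr(x, "n_reseeds"),
    attr(x, "n_waves"), attr(x, "recruits_per_seed")))
  cat(sprintf("  sample prevalence %.3f, mean degree %.1f\n",
              mean(x$group), mean(x$degree)))
  invisible(x)
}
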
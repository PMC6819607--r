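#' Volz-Heckathorn (RDS-II) sampling weights
#'
#' Inverse-degree weights normalized to mean one over the sample:
#' `w_i = (1/d_i) / mean_j(1/d_j)`, so the weights sum to the sample
#' size.  The scale cancels in Hajek-type prevalence estimators and in
#' weighted-GLM point estimates, but matters for model-based standard
#' errors of weighted fits, where the mean-one convention makes the
#' weights act as frequency-style multipliers.
#'
#' @param degrees vector of reported network degrees, all `>= 1`.
#' @return Numeric vector of positive weights with mean exactly 1.
#' @export
rds2_weights <- function(degrees) {
  degrees <- as.numeric(degrees)
  if (length(degrees) == 0L || any(!is.finite(degrees)) || any(degrees < 1))
    stop("all degrees must be finite and >= 1", call. = FALSE)
  inv <- 1 / degrees
  inv / mean(inv)
}

.new_prevalence <- function(estimator, point, se, ci, method, extra = list()) {
  ci <- pmin(pmax(ci, 0), 1)
  structure(c(list(estimator = estimator, point = point, se = se,
                   ci = ci, method = method), extra),
            class = "prevalence_estimate")
}

.wald_ci <- function(p, se, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(p - z * se, p + z * se)
}

# sandwich variance of a (possibly weighted) Hajek mean; with unit
# weights this is the usual binomial variance p(1-p)/n.  Equivalent to a
# weighted intercept-only logistic fit with robust variance.
.hajek_var <- function(y, w) {
  p <- sum(w * y) / sum(w)
  sum((w * (y - p))^2) / sum(w)^2
}

#' Naive sample prevalence
#'
#' The unweighted sample proportion in G1 with a Wald confidence
#' interval (truncated to `[0, 1]`).  Seeds are included.
#'
#' @param sample an `rds_sample` (or any data frame with a 0/1 `group`
#'   column).
#' @param conf confidence level.
#' @return A `prevalence_estimate`.
#' @export
naive_prevalence <- function(sample, conf = 0.95) {
  y <- sample$group
  n <- length(y)
  if (n < 1L) stop("empty sample", call. = FALSE)
  p <- mean(y)
  se <- sqrt(p * (1 - p) / n)
  .new_prevalence("naive", p, se, .wald_ci(p, se, conf), "wald")
}

#' Volz-Heckathorn (RDS-II) prevalence
#'
#' Hajek ratio estimator with inverse-degree weights:
#' `sum(w * y) / sum(w)`.  The default interval is the design-robust one
#' (weighted intercept-only model with sandwich variance); with equal
#' degrees the estimate collapses to the naive proportion.
#'
#' @inheritParams naive_prevalence
#' @return A `prevalence_estimate`.
#' @export
rds2_prevalence <- function(sample, conf = 0.95) {
  w <- rds2_weights(sample$degree)
  y <- sample$group
  p <- sum(w * y) / sum(w)
  se <- sqrt(.hajek_var(y, w))
  .new_prevalence("rds2", p, se, .wald_ci(p, se, conf), "design_robust")
}

#' Salganik-Heckathorn (RDS-I) prevalence
#'
#' Reciprocity-based estimator built from the cross-group recruitment
#' proportions and the harmonic mean degree of each group:
#' `P(G1) = S01 * D0 / (S10 * D1 + S01 * D0)` where `Sgh` is the
#' proportion of recruitments made by members of group `g` that landed on
#' members of group `h`, and `Dg` is the multiplicity (harmonic mean)
#' degree estimate of group `g`.  Requires recruiter-recruit pairs with
#' both outcomes observed; fails with an error when there are no
#' cross-group recruitments.
#'
#' @inheritParams naive_prevalence
#' @return A `prevalence_estimate` (standard error via a seed-chain
#'   bootstrap is available through [prevalence_interval()]; the point
#'   estimator itself carries a Wald-style interval computed from the
#'   naive variance as a pragmatic default).
#' @export
rds1_prevalence <- function(sample, conf = 0.95) {
  rec <- sample[!is.na(sample$recruiter), , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no recruiter-recruit pairs in sample", call. = FALSE)
  rec_group <- sample$group[match(rec$recruiter, sample$id)]
  cross <- table(factor(rec_group, levels = c(1, 0)),
                 factor(rec$group, levels = c(1, 0)))
  s10 <- cross["1", "0"] / sum(cross["1", ])   # G1 recruiter -> G2 recruit
  s01 <- cross["0", "1"] / sum(cross["0", ])   # G2 recruiter -> G1 recruit
  if (cross["1", "0"] + cross["0", "1"] == 0)
    stop("no cross-group recruitments: RDS-I estimate undefined",
         call. = FALSE)
  d1 <- sum(sample$group == 1) / sum(1 / sample$degree[sample$group == 1])
  d0 <- sum(sample$group == 0) / sum(1 / sample$degree[sample$group == 0])
  p <- (s01 * d0) / (s10 * d1 + s01 * d0)
  if (!is.finite(p))
    stop("RDS-I estimate undefined: a group made no recruitments or is ",
         "absent from the sample", call. = FALSE)
  n <- nrow(sample)
  se <- sqrt(p * (1 - p) / n)
  .new_prevalence("rds1", unname(p), se, .wald_ci(p, se, conf), "wald",
                  extra = list(cross_table = cross,
                               mean_degree = c(G1 = d1, G2 = d0)))
}

#' Confidence interval for a prevalence estimator
#'
#' Computes a 95% (by default) interval for the chosen estimator by one
#' of three methods: `wald` (normal approximation on the proportion
#' scale), `design_robust` (sandwich variance of the weighted or
#' unweighted Hajek mean, equivalent to an intercept-only logistic fit
#' with robust variance) or `salganik_bootstrap` (resampling whole seed
#' chains with replacement, percentile interval).  A bootstrap on a
#' sample with a single seed chain is flagged in the result.
#'
#' @param sample an `rds_sample`.
#' @param estimator `"naive"`, `"rds1"` or `"rds2"`.
#' @param method interval construction, see Details.
#' @param conf confidence level.
#' @param n_boot bootstrap resamples for `salganik_bootstrap`.
#' @return A `prevalence_estimate` with the requested interval.
#' @export
prevalence_interval <- function(sample,
                                estimator = c("naive", "rds2", "rds1"),
                                method = c("wald", "design_robust",
                                           "salganik_bootstrap"),
                                conf = 0.95, n_boot = 1000L) {
  estimator <- match.arg(estimator)
  method <- match.arg(method)
  point_fun <- switch(estimator,
    naive = function(s) mean(s$group),
    rds2 = function(s) {
      w <- rds2_weights(s$degree); sum(w * s$group) / sum(w)
    },
    rds1 = function(s) rds1_prevalence(s)$point)
  p <- point_fun(sample)

  if (method == "wald") {
    se <- sqrt(p * (1 - p) / nrow(sample))
    return(.new_prevalence(estimator, p, se, .wald_ci(p, se, conf), method))
  }
  if (method == "design_robust") {
    w <- if (estimator == "naive") rep(1, nrow(sample))
         else rds2_weights(sample$degree)
    se <- sqrt(.hajek_var(sample$group, w))
    return(.new_prevalence(estimator, p, se, .wald_ci(p, se, conf), method))
  }
  # seed-chain bootstrap
  chains <- split(seq_len(nrow(sample)), sample$seed)
  single_chain <- length(chains) < 2L
  boot <- vapply(seq_len(n_boot), function(b) {
    take <- sample.int(length(chains), length(chains), replace = TRUE)
    point_fun(sample[unlist(chains[take], use.names = FALSE), , drop = FALSE])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
  .new_prevalence(estimator, p, stats::sd(boot), ci, method,
                  extra = list(single_chain_warning = single_chain))
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("%s prevalence: %.4f (SE %.4f), %s 95%% CI [%.4f, %.4f]\n",
              x$estimator, x$point, x$se, x$method, x$ci[1], x$ci[2]))
  invisible(x)
}
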
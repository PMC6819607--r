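#' Declare one regression model variant
#'
#' A declarative description of a regression model to be fit to an RDS
#' sample: the error family, whether inverse-degree (RDS-II) weights are
#' applied, how clustering is handled and which variance estimator is
#' reported.
#'
#' Clustering options: `none` ignores the recruitment structure;
#' `recruiter_outcome_covariate` adds the recruiter's observed outcome as
#' a model covariate; `gee_independence_recruiter` /
#' `gee_exchangeable_recruiter` solve generalized estimating equations
#' with the stated working correlation within immediate-recruiter
#' clusters; `gee_ar1_chain` uses a first-order autoregressive working
#' correlation indexed by wave distance within each seed chain;
#' `glmm_seed_intercept` fits a random intercept per seed (requires
#' \pkg{lme4}).  GEE variants require a sandwich variance; the GLMM uses
#' its model-based variance.
#'
#' @param family `"binomial_logit"` or `"poisson_log"`.
#' @param weighting `"none"` or `"rds2"`.
#' @param clustering see Details.
#' @param variance `"model_based"`, `"sandwich_classical"`,
#'   `"sandwich_firores"`, `"sandwich_firoeeq"` or `"sandwich_mbn"`.
#' @param label optional display label (e.g. the model number of the
#'   reference table).
#'
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("binomial_logit", "poisson_log"),
                       weighting = c("none", "rds2"),
                       clustering = c("none", "recruiter_outcome_covariate",
                                      "gee_independence_recruiter",
                                      "gee_exchangeable_recruiter",
                                      "gee_ar1_chain", "glmm_seed_intercept"),
                       variance = c("model_based", "sandwich_classical",
                                    "sandwich_firores", "sandwich_firoeeq",
                                    "sandwich_mbn"),
                       label = NULL) {
  family <- match.arg(family)
  weighting <- match.arg(weighting)
  clustering <- match.arg(clustering)
  variance <- match.arg(variance)
  if (startsWith(clustering, "gee_") && variance == "model_based")
    stop("GEE variants require a sandwich variance estimator", call. = FALSE)
  if (clustering == "glmm_seed_intercept" && variance != "model_based")
    stop("the seed-intercept GLMM uses its model-based variance",
         call. = FALSE)
  if (is.null(label))
    label <- paste(substr(family, 1, 4), weighting, clustering, variance,
                   sep = "/")
  structure(list(family = family, weighting = weighting,
                 clustering = clustering, variance = variance,
                 label = label),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec [%s]: %s, weights=%s, clustering=%s, variance=%s\n",
              x$label, x$family, x$weighting, x$clustering, x$variance))
  invisible(x)
}

# family helpers (canonical links only)
.fam <- function(family) {
  switch(family,
         binomial_logit = stats::binomial(),
         poisson_log = stats::poisson(),
         stop("unknown family: ", family, call. = FALSE))
}

#' Build the regression frame for one model variant
#'
#' Drops all wave-0 participants (seeds and reseeds are excluded from
#' regression because the recruiter's outcome is undefined for them),
#' attaches the outcome, the chosen predictor, mean-one RDS-II weights if
#' the model is weighted, the recruiter's observed outcome when used as a
#' covariate, and the cluster identifiers needed by the GEE variants.
#'
#' @param sample an `rds_sample`.
#' @param predictor `"X_predict"` or `"X_NULL"`.
#' @param spec a [model_spec()].
#'
#' @return A data frame with columns `y`, `x`, `wave`, `cluster_recruiter`,
#'   `cluster_seed`, plus `w` (weights) and `recruiter_y` when required.
#' @export
prepare_regression_data <- function(sample,
                                    predictor = c("X_predict", "X_NULL"),
                                    spec) {
  predictor <- match.arg(predictor)
  stopifnot(inherits(spec, "model_spec"))
  keep <- !is.na(sample$recruiter)          # excludes every wave-0 seed
  if (!any(keep))
    stop("no non-seed participants left after exclusions", call. = FALSE)
  df <- data.frame(
    y = sample$group[keep],
    x = sample[[predictor]][keep],
    wave = sample$wave[keep],
    cluster_recruiter = sample$recruiter[keep],
    cluster_seed = sample$seed[keep]
  )
  if (spec$weighting == "rds2")
    df$w <- rds2_weights(sample$degree[keep])
  if (spec$clustering == "recruiter_outcome_covariate")
    df$recruiter_y <- sample$group[match(sample$recruiter[keep], sample$id)]
  df
}

.design_matrix <- function(frame, spec) {
  if (spec$clustering == "recruiter_outcome_covariate")
    cbind(`(Intercept)` = 1, x = frame$x, recruiter_y = frame$recruiter_y)
  else
    cbind(`(Intercept)` = 1, x = frame$x)
}

.fit_result <- function(spec, slope, se, converged, n, extra = list()) {
  if (!converged || !is.finite(se) || se <= 1e-10 || se > 1e3) {
    converged <- FALSE
    ci <- c(NA_real_, NA_real_); p <- NA_real_
  } else {
    ci <- slope + c(-1, 1) * stats::qnorm(0.975) * se
    p <- 2 * stats::pnorm(-abs(slope / se))
  }
  structure(c(list(spec = spec, slope = slope, se = se,
                   ci = ci, ci_exp = exp(ci), estimate_exp = exp(slope),
                   p = p, converged = converged, n = n), extra),
            class = "rds_fit")
}

#' @export
print.rds_fit <- function(x, ...) {
  cat(sprintf("[%s] slope %.4f (SE %.4f), exp %.3f [%.3f, %.3f], p = %.4g%s\n",
              x$spec$label, x$slope, x$se, x$estimate_exp,
              x$ci_exp[1], x$ci_exp[2], x$p,
              if (!x$converged) " NOT CONVERGED" else ""))
  invisible(x)
}

#' Fit a (possibly weighted) generalized linear model
#'
#' Iteratively reweighted least squares for the declared family.  With
#' RDS-II weighting the mean-one weights enter the score and the
#' information as frequency-style multipliers, and the model-based
#' standard error is the inverse weighted information -- the convention
#' under which weighted regression exhibits its characteristic leverage
#' problems on RDS data.  Sandwich variances are available through the
#' `variance` field of the spec (clusters default to independent
#' observations for plain GLMs).
#'
#' @param frame a model frame from [prepare_regression_data()].
#' @param spec a [model_spec()] with `clustering` equal to `"none"` or
#'   `"recruiter_outcome_covariate"`.
#'
#' @return An `rds_fit` with the slope of `x` on the link scale, its
#'   standard error, Wald 95% confidence limits (link and exponentiated
#'   scales), the two-sided p-value, a convergence flag, and the fitted
#'   means (`$fitted`) for accuracy computations.
#' @export
fit_glm <- function(frame, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$clustering %in% c("none", "recruiter_outcome_covariate"))
    stop("fit_glm handles only unclustered or recruiter-covariate specs; ",
         "use fit_gee / fit_glmm_seed_intercept", call. = FALSE)
  X <- .design_matrix(frame, spec)
  y <- frame$y
  w <- if (is.null(frame[["w"]])) rep(1, length(y)) else frame[["w"]]
  fam <- .fam(spec$family)
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, weights = w, family = fam,
                   control = stats::glm.control(epsilon = 1e-12,
                                                maxit = 100)),
    warning = function(cnd) {
      if (grepl("non-integer", conditionMessage(cnd)))
        invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  mu <- fit$fitted.values
  info <- crossprod(X * sqrt(fit$weights))   # glm.fit weights = w * v
  vc <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  converged <- isTRUE(fit$converged) && !is.null(vc) && all(is.finite(beta))
  if (spec$variance == "model_based" || !converged) {
    se <- if (!is.null(vc)) sqrt(vc[2, 2]) else NA_real_
  } else {
    cl <- .cluster_ids(frame, spec, n = length(y))
    sw <- .sandwich_glm(X, y, w, mu, fam, cl,
                        flavor = sub("^sandwich_", "", spec$variance))
    se <- sqrt(sw[2, 2])
  }
  .fit_result(spec, unname(beta[2]), se, converged, length(y),
              extra = list(fitted = mu, y = y, beta = beta, X = X, w = w))
}

# cluster ids for sandwich variances of plain GLMs
.cluster_ids <- function(frame, spec, n) {
  switch(spec$clustering,
         none = seq_len(n),
         recruiter_outcome_covariate = seq_len(n),
         gee_independence_recruiter = frame$cluster_recruiter,
         gee_exchangeable_recruiter = frame$cluster_recruiter,
         gee_ar1_chain = frame$cluster_seed)
}

#' In-sample prediction accuracy of a fitted model
#'
#' The proportion of participants whose outcome is correctly predicted by
#' thresholding the fitted mean at 0.5 (the fitted rate for Poisson
#' models is thresholded identically):
#' `(1/n) * sum(I(p >= 0.5 & y = 1) + I(p < 0.5 & y = 0))`, reported in
#' percent.
#'
#' @param fit an `rds_fit` carrying fitted values.
#' @param frame optional model frame; defaults to the outcomes stored in
#'   the fit.
#' @return Accuracy in percent.
#' @export
prediction_accuracy <- function(fit, frame = NULL) {
  y <- if (!is.null(frame)) frame$y else fit$y
  p <- fit$fitted
  if (is.null(p) || is.null(y))
    stop("fit does not carry fitted values", call. = FALSE)
  100 * mean((p >= 0.5 & y == 1) | (p < 0.5 & y == 0))
}
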
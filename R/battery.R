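#' Headline model battery
#'
#' The four generalized linear models used for the secondary analysis and
#' for the headline weighting contrast: unweighted and RDS-II-weighted
#' binomial (logit) and Poisson (log) regression, all with model-based
#' standard errors and no clustering control.
#'
#' @return A named list of [model_spec()]s (labels `glm1`, `glm2`,
#'   `glm24`, `glm25`, numbered as in the reference table).
#' @export
headline_battery <- function() {
  list(
    glm1  = model_spec("binomial_logit", "none", "none", "model_based",
                       label = "glm1"),
    glm2  = model_spec("binomial_logit", "rds2", "none", "model_based",
                       label = "glm2"),
    glm24 = model_spec("poisson_log", "none", "none", "model_based",
                       label = "glm24"),
    glm25 = model_spec("poisson_log", "rds2", "none", "model_based",
                       label = "glm25")
  )
}

#' Extended model battery
#'
#' Adds to the headline battery the recruiter-outcome-covariate GLMs, the
#' GEE variants (independence within recruiter with classical sandwich;
#' exchangeable within recruiter with the classical and small-sample
#' corrected sandwiches) and, when \pkg{lme4} is available at fit time,
#' the random-seed-intercept GLMMs.
#'
#' @param include_glmm include the seed-intercept GLMM specs.
#' @return A named list of [model_spec()]s.
#' @export
extended_battery <- function(include_glmm = FALSE) {
  out <- c(headline_battery(), list(
    glm3  = model_spec("binomial_logit", "none",
                       "recruiter_outcome_covariate", "model_based",
                       label = "glm3"),
    glm4  = model_spec("binomial_logit", "rds2",
                       "recruiter_outcome_covariate", "model_based",
                       label = "glm4"),
    glm26 = model_spec("poisson_log", "none",
                       "recruiter_outcome_covariate", "model_based",
                       label = "glm26"),
    glm27 = model_spec("poisson_log", "rds2",
                       "recruiter_outcome_covariate", "model_based",
                       label = "glm27"),
    gee16 = model_spec("binomial_logit", "none",
                       "gee_independence_recruiter", "sandwich_classical",
                       label = "gee16"),
    gee17 = model_spec("binomial_logit", "rds2",
                       "gee_independence_recruiter", "sandwich_classical",
                       label = "gee17"),
    gee20 = model_spec("binomial_logit", "none",
                       "gee_exchangeable_recruiter", "sandwich_classical",
                       label = "gee20"),
    gee21 = model_spec("binomial_logit", "none",
                       "gee_exchangeable_recruiter", "sandwich_firores",
                       label = "gee21"),
    gee22 = model_spec("binomial_logit", "none",
                       "gee_exchangeable_recruiter", "sandwich_firoeeq",
                       label = "gee22"),
    gee23 = model_spec("binomial_logit", "none",
                       "gee_exchangeable_recruiter", "sandwich_mbn",
                       label = "gee23"),
    gee30 = model_spec("poisson_log", "none",
                       "gee_independence_recruiter", "sandwich_classical",
                       label = "gee30"),
    gee31 = model_spec("poisson_log", "rds2",
                       "gee_independence_recruiter", "sandwich_classical",
                       label = "gee31")
  ))
  if (include_glmm)
    out <- c(out, list(
      glmm11 = model_spec("binomial_logit", "none", "glmm_seed_intercept",
                          "model_based", label = "glmm11"),
      glmm28 = model_spec("poisson_log", "none", "glmm_seed_intercept",
                          "model_based", label = "glmm28")
    ))
  out
}

.fit_dispatch <- function(frame, spec) {
  if (startsWith(spec$clustering, "gee_")) fit_gee(frame, spec)
  else if (spec$clustering == "glmm_seed_intercept")
    fit_glmm_seed_intercept(frame, spec)
  else fit_glm(frame, spec)
}

.fit_row <- function(fit, spec, predictor) {
  acc <- if (identical(predictor, "X_predict") && fit$converged &&
             !is.null(fit$fitted))
    prediction_accuracy(fit) else NA_real_
  data.frame(
    label = spec$label, family = spec$family, weighting = spec$weighting,
    clustering = spec$clustering, variance = spec$variance,
    predictor = predictor,
    slope = fit$slope, se = fit$se,
    ci_lo = fit$ci_exp[1], ci_hi = fit$ci_exp[2],
    estimate_exp = fit$estimate_exp, p = fit$p,
    converged = fit$converged, accuracy = acc, n = fit$n,
    stringsAsFactors = FALSE
  )
}

.failed_row <- function(spec, predictor, n) {
  data.frame(
    label = spec$label, family = spec$family, weighting = spec$weighting,
    clustering = spec$clustering, variance = spec$variance,
    predictor = predictor,
    slope = NA_real_, se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
    estimate_exp = NA_real_, p = NA_real_, converged = FALSE,
    accuracy = NA_real_, n = n, stringsAsFactors = FALSE
  )
}

#' Fit a battery of model variants to one RDS sample
#'
#' Each spec is fit twice: once with the pure-noise predictor `X_NULL`
#' (for the type-I error rate) and once with the group-shifted predictor
#' `X_predict` (for coverage, bias and accuracy).  Individual fit
#' failures are recorded as non-converged rows, never fatal.
#'
#' @param sample an `rds_sample`.
#' @param specs a list of [model_spec()]s, e.g. [headline_battery()].
#' @param predictors the predictors to evaluate.
#'
#' @return A data frame with `2 * length(specs)` rows (one per spec and
#'   predictor) of slope inference: link-scale slope, standard error,
#'   exponentiated estimate and confidence limits, p-value, convergence
#'   flag, prediction accuracy (for `X_predict` fits) and sample size.
#' @export
run_model_battery <- function(sample, specs = headline_battery(),
                              predictors = c("X_NULL", "X_predict")) {
  stopifnot(length(specs) >= 1L)
  rows <- vector("list", length(specs) * length(predictors))
  k <- 0L
  for (spec in specs) {
    for (predictor in predictors) {
      k <- k + 1L
      rows[[k]] <- tryCatch({
        frame <- prepare_regression_data(sample, predictor, spec)
        .fit_row(.fit_dispatch(frame, spec), spec, predictor)
      }, error = function(e) .failed_row(spec, predictor, nrow(sample)))
    }
  }
  do.call(rbind, rows)
}
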
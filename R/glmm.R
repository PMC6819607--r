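#' Random-intercept-by-seed generalized linear mixed model
#'
#' Fits the declared family with a random intercept for each seed chain
#' via \pkg{lme4} (adaptive Gauss-Hermite quadrature through the Laplace
#' default).  Inference is reported for the fixed slope.  A variance
#' component estimated on the boundary (singular fit) is flagged; the
#' model-based standard error is retained in that case, since with a zero
#' variance component the fit collapses to the plain GLM.
#'
#' @param frame a model frame from [prepare_regression_data()].
#' @param spec a [model_spec()] with `clustering = "glmm_seed_intercept"`.
#'
#' @return An `rds_fit` with `$boundary` indicating a singular variance
#'   component.
#' @export
fit_glmm_seed_intercept <- function(frame, spec) {
  stopifnot(inherits(spec, "model_spec"),
            spec$clustering == "glmm_seed_intercept")
  if (!requireNamespace("lme4", quietly = TRUE))
    stop("fit_glmm_seed_intercept requires the lme4 package",
         call. = FALSE)
  if (length(unique(frame$cluster_seed)) < 2L)
    stop("at least two seed clusters are required", call. = FALSE)
  fam <- .fam(spec$family)
  form <- if (is.null(frame$recruiter_y))
    y ~ x + (1 | cluster_seed)
  else
    y ~ x + recruiter_y + (1 | cluster_seed)
  args <- list(formula = form, data = frame, family = fam)
  if (!is.null(frame[["w"]])) args$weights <- frame[["w"]]
  fit <- try(suppressWarnings(suppressMessages(
    do.call(lme4::glmer, args))), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(.fit_result(spec, NA_real_, NA_real_, FALSE, nrow(frame)))
  est <- lme4::fixef(fit)[["x"]]
  se <- sqrt(as.matrix(stats::vcov(fit))["x", "x"])
  boundary <- lme4::isSingular(fit)
  converged <- length(fit@optinfo$conv$lme4) == 0 || boundary
  .fit_result(spec, est, se, converged, nrow(frame),
              extra = list(fitted = stats::fitted(fit), y = frame$y,
                           boundary = boundary))
}
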
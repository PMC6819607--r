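#' Observed type-I error rate
#'
#' The fraction of converged null-predictor fits with a two-sided
#' p-value at or below the nominal level.
#'
#' @param fits a data frame of battery rows (see [run_model_battery()]);
#'   rows with `predictor != "X_NULL"` are dropped.
#' @param level nominal significance level (non-strict comparison).
#' @return The observed error rate, with attribute `n_converged`.
#' @export
type1_error <- function(fits, level = 0.05) {
  fits <- fits[fits$predictor == "X_NULL", , drop = FALSE]
  ok <- fits$converged & !is.na(fits$p)
  if (!any(ok))
    stop("no converged null fits: error rate undefined", call. = FALSE)
  out <- mean(fits$p[ok] <= level)
  attr(out, "n_converged") <- sum(ok)
  out
}

.truth_for <- function(fits, truth) {
  theta_or <- truth$odds_ratio
  theta_rr <- truth$relative_risk
  if (length(theta_or) > 1L || !is.null(names(theta_or))) {
    # per-population truth table: align by the population of each row
    theta_or <- unname(theta_or[as.character(fits$population)])
    theta_rr <- unname(theta_rr[as.character(fits$population)])
  }
  ifelse(fits$family == "binomial_logit", theta_or, theta_rr)
}

#' Confidence-interval coverage of the true risk parameter
#'
#' The fraction of converged `X_predict` fits whose exponentiated 95%
#' interval contains the population parameter: the odds ratio for
#' logit-link fits, the relative risk for log-link fits.
#'
#' @param fits a data frame of battery rows.
#' @param truth a `population_parameters` object (or a data frame of
#'   per-population truths when `fits` carries a `population` column
#'   matched by name).
#' @return Coverage proportion with attribute `n_converged`.
#' @export
coverage_rate <- function(fits, truth) {
  fits <- fits[fits$predictor == "X_predict", , drop = FALSE]
  ok <- fits$converged & !is.na(fits$ci_lo)
  if (!any(ok))
    stop("no converged fits: coverage undefined", call. = FALSE)
  fits <- fits[ok, , drop = FALSE]
  theta <- .truth_for(fits, truth)
  out <- mean(fits$ci_lo <= theta & theta <= fits$ci_hi)
  attr(out, "n_converged") <- nrow(fits)
  out
}

#' Relative bias of the exponentiated risk estimates
#'
#' `100 * (center(theta_hat) - theta) / theta`, computed on the
#' exponentiated scale, where `theta` is the population odds ratio or
#' relative risk matching the fit family.
#'
#' @param fits battery rows (only `X_predict` rows are used).
#' @param truth a `population_parameters` object.
#' @param center `"mean"` or `"median"`.
#' @return Relative bias in percent.
#' @export
relative_bias <- function(fits, truth, center = c("mean", "median")) {
  center <- match.arg(center)
  fits <- fits[fits$predictor == "X_predict" & fits$converged &
                 !is.na(fits$estimate_exp), , drop = FALSE]
  if (nrow(fits) == 0L)
    stop("no converged fits: bias undefined", call. = FALSE)
  theta <- .truth_for(fits, truth)
  stat <- if (center == "mean") mean else stats::median
  100 * (stat(fits$estimate_exp / theta) - 1)
}

#' Reduce replicate fits to the study's summary metrics
#'
#' Produces per-population and pooled (all replicates of all populations
#' together, with equal weight per replicate) summaries of type-I error,
#' coverage, mean and median relative bias, predictive accuracy and the
#' number of converged replicates, one row per model variant.  The
#' accuracy cell is reported only for models satisfying the validity
#' gate: observed error rate at most 0.05 and coverage at least 0.95;
#' the ungated value is kept in `accuracy_all`.
#'
#' @param fits long data frame of battery rows carrying a `population`
#'   column (a population identifier).
#' @param truths named list of `population_parameters`, one per
#'   population id appearing in `fits`.
#' @param gate_error,gate_coverage the accuracy reporting gate.
#'
#' @return A data frame keyed by (`population`, `label`), with the pooled
#'   rows labelled `"pooled"`.
#' @export
summarize_study <- function(fits, truths, gate_error = 0.05,
                            gate_coverage = 0.95) {
  stopifnot("population" %in% names(fits))
  one_cell <- function(rows, truth) {
    err <- tryCatch(type1_error(rows), error = function(e) NA_real_)
    cov <- tryCatch(coverage_rate(rows, truth), error = function(e) NA_real_)
    acc_rows <- rows[rows$predictor == "X_predict" & rows$converged, ,
                     drop = FALSE]
    acc <- if (nrow(acc_rows)) mean(acc_rows$accuracy, na.rm = TRUE)
           else NA_real_
    data.frame(
      error = as.numeric(err), coverage = as.numeric(cov),
      bias_mean = tryCatch(relative_bias(rows, truth, "mean"),
                           error = function(e) NA_real_),
      bias_median = tryCatch(relative_bias(rows, truth, "median"),
                             error = function(e) NA_real_),
      accuracy = if (!is.na(err) && !is.na(cov) && err <= gate_error &&
                     cov >= gate_coverage) acc else NA_real_,
      accuracy_all = acc,
      n_converged = sum(rows$converged & rows$predictor == "X_NULL"),
      n_failed = sum(!rows$converged & rows$predictor == "X_NULL")
    )
  }
  # pooled truth: named per-population lookup vectors; each replicate row
  # is compared with its own population's parameter (aligned after any
  # subsetting inside the metric functions)
  pooled_cell <- function(rows) {
    one_cell(rows, list(
      odds_ratio = vapply(truths, function(t) t$odds_ratio, numeric(1)),
      relative_risk = vapply(truths, function(t) t$relative_risk,
                             numeric(1))))
  }
  out <- list()
  for (lab in unique(fits$label)) {
    frows <- fits[fits$label == lab, , drop = FALSE]
    for (popid in unique(frows$population)) {
      cell <- one_cell(frows[frows$population == popid, , drop = FALSE],
                       truths[[as.character(popid)]])
      out[[length(out) + 1L]] <-
        cbind(data.frame(population = popid, label = lab), cell)
    }
    out[[length(out) + 1L]] <-
      cbind(data.frame(population = "pooled", label = lab),
            pooled_cell(frows))
  }
  do.call(rbind, out)
}
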
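test_that("model_spec enforces its structural invariants", {
  expect_error(model_spec("binomial_logit", clustering = "gee_ar1_chain",
                          variance = "model_based"),
               "sandwich")
  expect_error(model_spec("poisson_log",
                          clustering = "glmm_seed_intercept",
                          variance = "sandwich_classical"),
               "model-based")
  spec <- model_spec("poisson_log", "rds2")
  expect_s3_class(spec, "model_spec")
})

test_that("prepare_regression_data excludes seeds and attaches fields", {
  pop <- small_population(N = 800)
  set.seed(41)
  s <- rds_sample(pop, rds_config(n_seeds = 10, target_n = 200))
  spec_w <- model_spec("binomial_logit", "rds2",
                       "recruiter_outcome_covariate")
  fr <- prepare_regression_data(s, "X_predict", spec_w)
  n_seeds <- sum(is.na(s$recruiter))
  expect_equal(nrow(fr), 200 - n_seeds)
  expect_true(all(fr$wave >= 1))
  # every row carries its recruiter's observed outcome
  expect_equal(fr$recruiter_y,
               s$group[match(fr$cluster_recruiter, s$id)])
  # mean-one weights on the analysis rows
  expect_equal(sum(fr$w), nrow(fr))
  # unweighted spec has no weight column
  fr0 <- prepare_regression_data(s, "X_NULL", model_spec("binomial_logit"))
  expect_null(fr0[["w"]])
  expect_equal(fr0$x, s$X_NULL[!is.na(s$recruiter)])
})

test_that("fit_glm matches an independent Newton-Raphson oracle", {
  set.seed(42)
  n <- 120
  frame <- data.frame(y = rbinom(n, 1, 0.35), x = rnorm(n),
                      w = rds2_weights(sample(1:20, n, TRUE)))
  for (family in c("binomial_logit", "poisson_log")) {
    for (weighted in c(FALSE, TRUE)) {
      spec <- model_spec(family, if (weighted) "rds2" else "none")
      fr <- frame
      if (!weighted) fr$w <- NULL
      fit <- fit_glm(fr, spec)
      orc <- nr_glm_oracle(cbind(1, frame$x), frame$y,
                           if (weighted) frame$w else rep(1, n),
                           sub("_.*", "", family))
      expect_equal(fit$slope, orc$beta[2], tolerance = 1e-8)
      # IRLS (deviance-based stopping) vs Newton-Raphson (step-based):
      # SEs agree far beyond any inferential relevance
      expect_equal(fit$se, orc$se[2], tolerance = 1e-7)
      expect_true(fit$converged)
      # Wald construction
      expect_equal(fit$ci, fit$slope + c(-1, 1) * qnorm(0.975) * fit$se)
      expect_equal(fit$ci_exp, exp(fit$ci))
      expect_equal(fit$p, 2 * pnorm(-abs(fit$slope / fit$se)))
    }
  }
})

test_that("equal weights reproduce the unweighted fit exactly", {
  set.seed(43)
  n <- 150
  frame <- data.frame(y = rbinom(n, 1, 0.3), x = rnorm(n))
  un <- fit_glm(frame, model_spec("binomial_logit"))
  frame$w <- rds2_weights(rep(7, n))   # all equal -> all exactly 1
  wt <- fit_glm(frame, model_spec("binomial_logit", "rds2"))
  expect_equal(wt$slope, un$slope, tolerance = 1e-12)
  expect_equal(wt$se, un$se, tolerance = 1e-12)
})

test_that("binomial and poisson slopes agree in sign on real effects", {
  for (s in 1:5) {
    set.seed(50 + s)
    n <- 200
    g <- rbinom(n, 1, 0.3)
    frame <- data.frame(y = g, x = rnorm(n, mean = 1.5 * g))
    b <- fit_glm(frame, model_spec("binomial_logit"))
    p <- fit_glm(frame, model_spec("poisson_log"))
    expect_gt(b$slope * p$slope, 0)
  }
})

test_that("a low-degree leverage point moves the weighted fit more", {
  # balanced fixture plus one extreme-x G2 observation with degree 1
  set.seed(44)
  n <- 60
  g <- rep(c(1, 0), n / 2)
  x <- rnorm(n, mean = 2 * g)
  d <- rep(10, n)
  base <- data.frame(y = g, x = x)
  base_w <- transform(base, w = rds2_weights(d))
  lev <- rbind(base, data.frame(y = 0, x = 4.5))
  lev_w <- transform(lev, w = rds2_weights(c(d, 1)))
  spec_u <- model_spec("binomial_logit")
  spec_w <- model_spec("binomial_logit", "rds2")
  shift_u <- abs(fit_glm(lev, spec_u)$slope - fit_glm(base, spec_u)$slope)
  shift_w <- abs(fit_glm(lev_w, spec_w)$slope -
                   fit_glm(base_w, spec_w)$slope)
  expect_gt(shift_w, shift_u)
})

test_that("non-convergent or separated fits are flagged, not fatal", {
  # perfect separation: glm diverges, SE blows up
  frame <- data.frame(y = rep(c(0, 1), each = 20),
                      x = c(rnorm(20, -8), rnorm(20, 8)))
  fit <- suppressWarnings(fit_glm(frame, model_spec("binomial_logit")))
  expect_false(fit$converged)
  expect_true(is.na(fit$p))
})

test_that("run_model_battery is complete, keyed and deterministic", {
  pop <- small_population(N = 800)
  set.seed(45)
  s <- rds_sample(pop, rds_config(n_seeds = 6, target_n = 200))
  out <- run_model_battery(s, headline_battery())
  expect_equal(nrow(out), 8)              # 4 specs x 2 predictors
  expect_setequal(unique(out$predictor), c("X_NULL", "X_predict"))
  # accuracy only for the predictive fits
  expect_true(all(is.na(out$accuracy[out$predictor == "X_NULL"])))
  expect_true(all(!is.na(out$accuracy[out$predictor == "X_predict" &
                                        out$converged])))
  set.seed(46)
  a <- run_model_battery(s, headline_battery())
  set.seed(46)
  b <- run_model_battery(s, headline_battery())
  expect_identical(a, b)
})

test_that("prediction accuracy counts thresholded fitted values", {
  fit <- list(fitted = c(0.6, 0.4), y = c(1, 0))
  expect_equal(prediction_accuracy(fit), 100)
  fit2 <- list(fitted = c(0.6, 0.4, 0.7, 0.2), y = c(1, 1, 0, 0))
  expect_equal(prediction_accuracy(fit2), 50)
  # perfect separation fixture scores 100%
  frame <- data.frame(y = rep(c(0, 1), each = 15),
                      x = c(rnorm(15, -3), rnorm(15, 3)))
  fit3 <- suppressWarnings(fit_glm(frame, model_spec("binomial_logit")))
  expect_equal(prediction_accuracy(fit3, frame), 100)
})

test_that("optional seed-intercept GLMM collapses to GLM when seeds are null", {
  skip_if_not_installed("lme4")
  pop <- small_population(N = 1000)
  set.seed(47)
  s <- rds_sample(pop, rds_config(n_seeds = 8, target_n = 300))
  spec <- model_spec("binomial_logit", clustering = "glmm_seed_intercept")
  fr <- prepare_regression_data(s, "X_predict", spec)
  fit <- fit_glmm_seed_intercept(fr, spec)
  glm_fit <- fit_glm(fr, model_spec("binomial_logit"))
  # homophily 1.2 induces little seed-level variance: the GLMM slope
  # should sit near the GLM slope
  expect_lt(abs(fit$slope - glm_fit$slope), 0.3)
  expect_true(is.finite(fit$se))
})
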
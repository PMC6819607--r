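# working correlation matrix for one cluster.  For the chain AR(1)
# structure the correlation between two participants is alpha^|wave_i -
# wave_j|; distinct participants recruited at the same wave of the same
# chain (siblings) receive correlation alpha -- a zero exponent would
# declare them perfectly correlated and make the working covariance
# singular.
.working_cor <- function(corstr, alpha, ni, waves) {
  if (corstr == "exchangeable")
    return((1 - alpha) * diag(ni) + alpha)
  dw <- pmax(abs(outer(waves, waves, "-")), 1)
  R <- alpha^dw
  diag(R) <- 1
  R
}

#' Fit generalized estimating equations to an RDS sample
#'
#' Population-average regression with a working intra-cluster
#' correlation, solved by Fisher scoring.  Three structures are
#' supported, matching the clustering options of [model_spec()]:
#' independence or exchangeable correlation within immediate-recruiter
#' clusters, and first-order autoregressive correlation along each seed's
#' recruitment chain, where the correlation between two participants of
#' the same chain is `alpha^|wave_i - wave_j|` and participants of
#' different chains are uncorrelated.  The working correlation parameter
#' is estimated by the usual moment (Pearson residual) estimator; an
#' estimate outside `[0, 0.95]` triggers a flagged fallback to
#' independence.  Standard errors are cluster-robust sandwich estimates
#' of the flavor named in the spec.
#'
#' @param frame a model frame from [prepare_regression_data()].
#' @param spec a [model_spec()] with a `gee_*` clustering option.
#' @param maxit,tol Fisher scoring controls.
#'
#' @return An `rds_fit`; the working correlation estimate is stored as
#'   `$alpha` and a fallback to independence as `$alpha_fallback`.
#' @export
fit_gee <- function(frame, spec, maxit = 25L, tol = 1e-8) {
  stopifnot(inherits(spec, "model_spec"))
  corstr <- switch(spec$clustering,
                   gee_independence_recruiter = "independence",
                   gee_exchangeable_recruiter = "exchangeable",
                   gee_ar1_chain = "ar1",
                   stop("fit_gee requires a gee_* clustering option",
                        call. = FALSE))
  cluster <- if (corstr == "ar1") frame$cluster_seed
             else frame$cluster_recruiter
  X <- .design_matrix(frame, spec)
  y <- frame$y
  w <- if (is.null(frame[["w"]])) rep(1, length(y)) else frame[["w"]]
  fam <- .fam(spec$family)
  p <- ncol(X)
  n <- length(y)
  idx <- split(seq_len(n), cluster)
  waves <- frame$wave

  # initial values from the independence fit
  init <- withCallingHandlers(
    stats::glm.fit(X, y, weights = w, family = fam),
    warning = function(cnd) {
      if (grepl("non-integer", conditionMessage(cnd)))
        invokeRestart("muffleWarning")
    })
  beta <- init$coefficients
  alpha <- 0
  alpha_fallback <- FALSE
  eff_corstr <- corstr
  converged <- FALSE

  estimate_alpha <- function(e, phi) {
    if (eff_corstr == "independence") return(0)
    num <- 0; npairs <- 0
    for (i in idx) {
      if (length(i) < 2L) next
      ei <- e[i]
      if (eff_corstr == "exchangeable") {
        num <- num + (sum(ei)^2 - sum(ei^2)) / 2
        npairs <- npairs + length(i) * (length(i) - 1) / 2
      } else {
        dw <- abs(outer(waves[i], waves[i], "-"))
        lag1 <- which(dw == 1 & upper.tri(dw), arr.ind = TRUE)
        if (nrow(lag1)) {
          num <- num + sum(ei[lag1[, 1]] * ei[lag1[, 2]])
          npairs <- npairs + nrow(lag1)
        }
      }
    }
    if (npairs <= p) return(0)
    num / ((npairs - p) * phi)
  }

  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- fam$linkinv(eta)
    v <- fam$variance(mu)
    e <- (y - mu) / sqrt(v)
    phi <- sum(w * e^2) / (n - p)
    a <- estimate_alpha(e, phi)
    if (eff_corstr != "independence" && (a < 0 || a >= 0.95)) {
      alpha_fallback <- TRUE
      eff_corstr <- "independence"
      a <- 0
    }
    alpha <- a

    lhs <- matrix(0, p, p)
    rhs <- numeric(p)
    for (i in idx) {
      ni <- length(i)
      D <- v[i] * X[i, , drop = FALSE]
      if (eff_corstr == "independence" || ni == 1L) {
        G <- t(X[i, , drop = FALSE] * w[i])       # D' Vinv
      } else {
        R <- .working_cor(eff_corstr, alpha, ni, waves[i])
        s <- sqrt(v[i] / w[i])
        V <- outer(s, s) * R
        G <- crossprod(D, solve(V))
      }
      lhs <- lhs + G %*% D
      rhs <- rhs + drop(G %*% (y[i] - mu[i]))
    }
    step <- solve(lhs, rhs)
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }

  eta <- drop(X %*% beta)
  mu <- fam$linkinv(eta)
  v <- fam$variance(mu)
  parts <- lapply(idx, function(i) {
    ni <- length(i)
    D <- v[i] * X[i, , drop = FALSE]
    if (eff_corstr == "independence" || ni == 1L) {
      Vinv <- diag(w[i] / v[i], ni)
    } else {
      R <- .working_cor(eff_corstr, alpha, ni, waves[i])
      s <- sqrt(v[i] / w[i])
      Vinv <- solve(outer(s, s) * R)
    }
    list(D = D, Vinv = Vinv, e = y[i] - mu[i])
  })
  V <- .sandwich_core(parts, sub("^sandwich_", "", spec$variance), n = n)
  se <- sqrt(V[2, 2])
  .fit_result(spec, unname(beta[2]), se, converged, n,
              extra = list(fitted = mu, y = y, beta = beta,
                           alpha = alpha, alpha_fallback = alpha_fallback,
                           vcov = V))
}
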
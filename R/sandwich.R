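# Cluster-robust sandwich machinery shared by GLM and GEE fits.
#
# All fits here use canonical links, so the cluster score of a weighted
# GLM is U_c = X_c' W_c (y_c - mu_c) and the information (inverse bread)
# is B = X' diag(w v) X.  For GEE fits the caller supplies the cluster
# derivative D_c and working-covariance inverse Vinv_c and the same
# formulas apply with U_c = D_c' Vinv_c e_c, B_c = D_c' Vinv_c D_c.

# parts: list of clusters, each a list(D, Vinv, e); returns flavored
# covariance matrix of beta-hat
.sandwich_core <- function(parts, flavor = c("classical", "firores",
                                             "firoeeq", "mbn"),
                           n, fg_bound = 0.75) {
  flavor <- match.arg(flavor)
  K <- length(parts)
  if (K < 2L)
    stop("cluster-robust variance undefined with a single cluster",
         call. = FALSE)
  p <- ncol(parts[[1]]$D)
  B <- matrix(0, p, p)
  for (cl in parts) B <- B + crossprod(cl$D, cl$Vinv %*% cl$D)
  Binv <- solve(B)

  score <- function(cl) drop(crossprod(cl$D, cl$Vinv %*% cl$e))
  meat <- matrix(0, p, p)
  if (flavor == "firores") {
    # residual-level bias correction: e_c -> (I - H_cc)^{-1} e_c with
    # H_cc = D_c B^{-1} D_c' Vinv_c
    for (cl in parts) {
      H <- cl$D %*% Binv %*% crossprod(cl$D, cl$Vinv)
      e_adj <- solve(diag(nrow(H)) - H, cl$e)
      U <- drop(crossprod(cl$D, cl$Vinv %*% e_adj))
      meat <- meat + tcrossprod(U)
    }
    return(Binv %*% meat %*% Binv)
  }
  if (flavor == "firoeeq") {
    # estimating-equation correction with the customary bound 0.75 on
    # the per-parameter leverage
    for (cl in parts) {
      Bc <- crossprod(cl$D, cl$Vinv %*% cl$D)
      lev <- pmin(fg_bound, diag(Bc %*% Binv))
      A <- diag(1 / sqrt(1 - lev), p)
      U <- A %*% score(cl)
      meat <- meat + tcrossprod(U)
    }
    return(Binv %*% meat %*% Binv)
  }
  for (cl in parts) meat <- meat + tcrossprod(score(cl))
  V <- Binv %*% meat %*% Binv
  if (flavor == "classical") return(V)
  # mbn: inflate the classical estimator and add a scaled model-based
  # term, guarding against few clusters
  cf <- if (n > p && K > 1L) ((n - 1) / (n - p)) * (K / (K - 1)) else 1
  delta <- min(0.5, p / max(K - p, 1))
  xi <- max(1, cf * sum(diag(Binv %*% meat)) / p)
  cf * V + delta * xi * Binv
}

# independence-working parts for a weighted GLM
.glm_parts <- function(X, y, w, mu, v, cluster) {
  idx <- split(seq_along(y), cluster)
  lapply(idx, function(i) {
    list(D = v[i] * X[i, , drop = FALSE],
         Vinv = diag(w[i] / v[i], length(i)),
         e = y[i] - mu[i])
  })
}

.sandwich_glm <- function(X, y, w, mu, fam, cluster, flavor) {
  v <- fam$variance(mu)
  .sandwich_core(.glm_parts(X, y, w, mu, v, cluster), flavor,
                 n = length(y))
}

#' Cluster-robust sandwich variance of a fitted model
#'
#' Replaces the standard error of an [fit_glm()] result with a
#' cluster-robust sandwich estimate.  Flavors: `classical`
#' (Huber-White), `firores` (residual-level small-sample correction,
#' multiplying cluster residuals by the inverse of `I - H_cc`),
#' `firoeeq` (estimating-equation correction with the per-parameter
#' leverage bounded at 0.75) and `mbn` (Morel-Bokossa-Neerchal
#' inflation, which is never smaller than the classical estimator).
#'
#' @param fit an `rds_fit` from [fit_glm()].
#' @param frame the model frame used to produce `fit`.
#' @param cluster `"observations"` (each row its own cluster),
#'   `"recruiter"` or `"seed"`.
#' @param flavor one of `"classical"`, `"firores"`, `"firoeeq"`, `"mbn"`.
#'
#' @return A new `rds_fit` with the robust standard error and the
#'   corresponding confidence limits and p-value.
#' @export
sandwich_variance <- function(fit, frame,
                              cluster = c("observations", "recruiter",
                                          "seed"),
                              flavor = c("classical", "firores",
                                         "firoeeq", "mbn")) {
  cluster <- match.arg(cluster)
  flavor <- match.arg(flavor)
  if (is.null(fit$X))
    stop("fit does not carry its design matrix; refit with fit_glm",
         call. = FALSE)
  cl <- switch(cluster,
               observations = seq_len(fit$n),
               recruiter = frame$cluster_recruiter,
               seed = frame$cluster_seed)
  fam <- .fam(fit$spec$family)
  V <- .sandwich_glm(fit$X, fit$y, fit$w, fit$fitted, fam, cl, flavor)
  out <- .fit_result(fit$spec, fit$slope, sqrt(V[2, 2]), fit$converged,
                     fit$n,
                     extra = list(fitted = fit$fitted, y = fit$y,
                                  vcov = V, cluster = cluster,
                                  flavor = flavor))
  out
}
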
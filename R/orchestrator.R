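#' Configure a simulation study
#'
#' A single declarative configuration for the primary (prevalence by
#' homophily grid) and secondary (degree-outcome correlation) Monte-Carlo
#' experiments.  Presets: `smoke` (5 replicates, for end-to-end checks),
#' `desk` (250 replicates, reproduces all reported proportions within
#' Monte-Carlo tolerance), `full` (1000 replicates, the reference scale).
#'
#' @param pis prevalence grid.
#' @param hxs homophily grid.
#' @param N population size.
#' @param sampler an [rds_config()].
#' @param battery list of [model_spec()]s.
#' @param seed root seed; per-population and per-replicate streams are
#'   derived from it and recorded in the manifest.
#' @param preset `"smoke"`, `"desk"` or `"full"`.
#' @param n_replicates overrides the preset replicate count.
#' @param spec degree distribution.
#' @param out_dir optional output directory for CSV tables and the JSON
#'   manifest.
#'
#' @return An object of class `study_config`.
#' @export
study_config <- function(pis = c(0.10, 0.30, 0.50),
                         hxs = c(1.0, 1.1, 1.25, 1.5),
                         N = 10000,
                         sampler = rds_config(),
                         battery = headline_battery(),
                         seed = 1L,
                         preset = c("desk", "smoke", "full"),
                         n_replicates = NULL,
                         spec = default_degree_spec(),
                         out_dir = NULL) {
  preset <- match.arg(preset)
  reps <- if (!is.null(n_replicates)) as.integer(n_replicates)
          else switch(preset, smoke = 5L, desk = 250L, full = 1000L)
  if (reps < 1L) stop("need at least one replicate", call. = FALSE)
  structure(list(pis = pis, hxs = hxs, N = as.integer(N),
                 sampler = sampler, battery = battery,
                 seed = as.integer(seed), preset = preset,
                 n_replicates = reps, spec = spec, out_dir = out_dir),
            class = "study_config")
}

.derive_seeds <- function(root, n) {
  set.seed(root)
  sample.int(.Machine$integer.max - 1L, n)
}

.prevalence_rows <- function(s, popid, r) {
  ests <- list(
    naive = naive_prevalence(s),
    rds1 = tryCatch(rds1_prevalence(s), error = function(e) NULL),
    rds2 = rds2_prevalence(s),
    svy_unweighted = prevalence_interval(s, "naive", "design_robust")
  )
  do.call(rbind, lapply(names(ests), function(nm) {
    e <- ests[[nm]]
    if (is.null(e)) return(NULL)
    data.frame(population = popid, replicate = r, estimator = nm,
               point = e$point, se = e$se, ci_lo = e$ci[1],
               ci_hi = e$ci[2], method = e$method,
               stringsAsFactors = FALSE)
  }))
}

.run_one_population <- function(pop, popid, config, rep_seeds,
                                predictors = c("X_NULL", "X_predict"),
                                prevalence = TRUE) {
  fits <- vector("list", config$n_replicates)
  prev <- vector("list", config$n_replicates)
  stats_m <- matrix(NA_real_, config$n_replicates, 3,
                    dimnames = list(NULL, c("degree", "waves",
                                            "recruits_per_seed")))
  for (r in seq_len(config$n_replicates)) {
    set.seed(rep_seeds[r])
    s <- rds_sample(pop, config$sampler)
    f <- run_model_battery(s, config$battery, predictors = predictors)
    f$population <- popid; f$replicate <- r
    fits[[r]] <- f
    stats_m[r, ] <- c(mean(s$degree), attr(s, "n_waves"),
                      attr(s, "recruits_per_seed"))
    if (prevalence) prev[[r]] <- .prevalence_rows(s, popid, r)
  }
  list(fits = do.call(rbind, fits),
       prevalence = if (prevalence) do.call(rbind, prev),
       sample_stats = colMeans(stats_m, na.rm = TRUE))
}

.write_study <- function(bundle, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in intersect(c("table1", "table2", "table3", "table4"),
                       names(bundle)))
    utils::write.csv(bundle[[nm]],
                     file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  utils::write.csv(bundle$fits, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$prevalence))
    utils::write.csv(bundle$prevalence,
                     file.path(out_dir, "prevalence.csv"),
                     row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rdsregsim")),
    seed = config$seed, preset = config$preset,
    n_replicates = config$n_replicates, N = config$N,
    pis = config$pis, hxs = config$hxs,
    pop_seeds = bundle$pop_seeds,
    n_failed_fits = sum(!bundle$fits$converged),
    models = vapply(config$battery, function(s) s$label, character(1)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the primary simulation study
#'
#' Builds one population for every (prevalence, homophily) cell of the
#' grid, computes its full-population regression parameters, draws the
#' configured number of RDS replicates from each, fits the model battery
#' twice per replicate (null and predictive), estimates prevalence per
#' replicate, and reduces everything to the study's summary tables.  The
#' whole run is deterministic given the root seed.
#'
#' @param config a [study_config()].
#' @return A list of class `rds_study` with elements `table1`
#'   (population and mean sample characteristics), `table2` (per
#'   population and pooled model performance), `table3` (prevalence
#'   estimator summaries), `fits` and `prevalence` (replicate-level long
#'   tables), `truths`, and `pop_seeds`.  Tables are also written as CSV
#'   when the config names an `out_dir`.
#' @export
run_primary_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  grid <- expand.grid(pi = config$pis, hx = config$hxs,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$pi, grid$hx), , drop = FALSE]
  n_pop <- nrow(grid)
  pop_seeds <- .derive_seeds(config$seed, 2L * n_pop)
  build_seeds <- pop_seeds[seq_len(n_pop)]
  stream_seeds <- pop_seeds[n_pop + seq_len(n_pop)]

  truths <- list(); all_fits <- list(); all_prev <- list()
  t1 <- vector("list", n_pop)
  for (i in seq_len(n_pop)) {
    popid <- sprintf("pi%02d_hx%.2f", round(100 * grid$pi[i]), grid$hx[i])
    set.seed(build_seeds[i])
    pop <- build_population(grid$pi[i], grid$hx[i], N = config$N,
                            spec = config$spec)
    truth <- population_parameters(pop)
    truths[[popid]] <- truth
    rep_seeds <- .derive_seeds(stream_seeds[i], config$n_replicates)
    res <- .run_one_population(pop, popid, config, rep_seeds)
    all_fits[[popid]] <- res$fits
    all_prev[[popid]] <- res$prevalence
    t1[[i]] <- data.frame(
      population = popid, prevalence = grid$pi[i], homophily = grid$hx[i],
      odds_ratio = truth$odds_ratio, relative_risk = truth$relative_risk,
      hx_realized = pop$hx_realized, omega = pop$omega_realized,
      mean_sample_degree = res$sample_stats[["degree"]],
      mean_waves = res$sample_stats[["waves"]],
      mean_recruits_per_seed = res$sample_stats[["recruits_per_seed"]])
    rm(pop)
  }
  fits <- do.call(rbind, all_fits)
  prevalence <- do.call(rbind, all_prev)
  table1 <- do.call(rbind, t1)
  table2 <- summarize_study(fits, truths)
  # prevalence summary: mean and sd of the point estimates plus coverage
  # of the realized population prevalence
  prevalence$truth <- grid$pi[match(prevalence$population,
                                    table1$population)]
  agg <- function(v, f) stats::aggregate(
    v, by = list(population = prevalence$population,
                 estimator = prevalence$estimator), FUN = f)
  m <- agg(prevalence$point, mean)
  s <- agg(prevalence$point, stats::sd)
  cov <- agg(prevalence$ci_lo <= prevalence$truth &
               prevalence$truth <= prevalence$ci_hi, mean)
  table3 <- data.frame(population = m$population, estimator = m$estimator,
                       mean_point = m$x, sd_point = s$x, coverage = cov$x)
  bundle <- structure(
    list(table1 = table1, table2 = table2, table3 = table3,
         fits = fits, prevalence = prevalence, truths = truths,
         pop_seeds = build_seeds, config = config),
    class = "rds_study")
  if (!is.null(config$out_dir)) .write_study(bundle, config$out_dir, config)
  bundle
}

#' Run the secondary (correlated degree-outcome) study
#'
#' Builds the eight correlated populations (four assignment modes crossed
#' with homophily 1.25 and 1.5, prevalence fixed at 10%), draws the
#' configured replicates and evaluates the type-I error of the battery
#' (null predictor only).
#'
#' @param config a [study_config()]; its `hxs` field is interpreted as
#'   the secondary homophily grid (default `c(1.25, 1.5)`).
#' @param modes the degree-outcome assignment modes to include.
#' @return A list of class `rds_study` with `table4` (per population:
#'   realized correlation `rho` and error rate per model) and `fits`.
#' @export
run_secondary_study <- function(config = study_config(hxs = c(1.25, 1.5)),
                                modes = c("extreme_neg", "extreme_pos",
                                          "moderate_neg", "moderate_pos")) {
  stopifnot(inherits(config, "study_config"))
  hxs <- config$hxs
  grid <- expand.grid(mode = modes, hx = hxs, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  n_pop <- nrow(grid)
  pop_seeds <- .derive_seeds(config$seed + 1L, 2L * n_pop)

  all_fits <- list(); t4 <- vector("list", n_pop)
  for (i in seq_len(n_pop)) {
    popid <- sprintf("%s_hx%.2f", grid$mode[i], grid$hx[i])
    set.seed(pop_seeds[i])
    pop <- build_correlated_population(grid$mode[i], grid$hx[i],
                                       N = config$N, spec = config$spec)
    rep_seeds <- .derive_seeds(pop_seeds[n_pop + i], config$n_replicates)
    res <- .run_one_population(pop, popid, config, rep_seeds,
                               predictors = "X_NULL", prevalence = FALSE)
    all_fits[[popid]] <- res$fits
    errors <- vapply(config$battery, function(spec) {
      rows <- res$fits[res$fits$label == spec$label, , drop = FALSE]
      tryCatch(as.numeric(type1_error(rows)), error = function(e) NA_real_)
    }, numeric(1))
    t4[[i]] <- cbind(
      data.frame(population = popid, mode = grid$mode[i], hx = grid$hx[i],
                 rho = pop$rho, hx_realized = pop$hx_realized),
      as.data.frame(as.list(errors)))
    rm(pop)
  }
  bundle <- structure(
    list(table4 = do.call(rbind, t4), fits = do.call(rbind, all_fits),
         pop_seeds = pop_seeds[seq_len(n_pop)], config = config),
    class = "rds_study")
  if (!is.null(config$out_dir)) .write_study(bundle, config$out_dir, config)
  bundle
}

#' @export
print.rds_study <- function(x, ...) {
  cat("RDS simulation study bundle\n")
  for (nm in intersect(c("table1", "table2", "table3", "table4"), names(x)))
    cat(sprintf("  %s: %d rows\n", nm, nrow(x[[nm]])))
  cat(sprintf("  fits: %d rows (%d non-converged)\n",
              nrow(x$fits), sum(!x$fits$converged)))
  invisible(x)
}
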
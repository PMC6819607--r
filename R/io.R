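#' Write a networked population to plain-text files
#'
#' Writes `nodes.csv` (id, degree, group, X_predict, X_NULL),
#' `edges.csv` (u, v; 1-based ids) and `meta.json` (declared and realized
#' population parameters) into `dir`.
#'
#' @param pop a `networked_population`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "networked_population"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    data.frame(id = seq_len(pop$N), degree = pop$degree, group = pop$group,
               X_predict = pop$X_predict, X_NULL = pop$X_NULL),
    file.path(dir, "nodes.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(pop$edges),
                   file.path(dir, "edges.csv"), row.names = FALSE)
  meta <- list(N = pop$N, pi = pop$pi, hx = pop$hx,
               prevalence_realized = pop$prevalence_realized,
               hx_realized = pop$hx_realized,
               omega_realized = pop$omega_realized,
               t_ii = pop$t_ii, t_ij = pop$t_ij,
               mode = pop$mode, rho = pop$rho,
               hx_clipped = pop$hx_clipped)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a networked population written by [write_population()]
#'
#' @param dir directory containing `nodes.csv`, `edges.csv`, `meta.json`.
#' @return A `networked_population`.
#' @export
read_population <- function(dir) {
  nodes <- utils::read.csv(file.path(dir, "nodes.csv"))
  edges <- as.matrix(utils::read.csv(file.path(dir, "edges.csv")))
  storage.mode(edges) <- "integer"
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  extra <- list()
  if (!is.null(meta$mode))
    extra <- list(mode = meta$mode, rho = meta$rho,
                  hx_clipped = isTRUE(meta$hx_clipped))
  .new_population(nrow(nodes), nodes$degree, nodes$group, nodes$X_predict,
                  nodes$X_NULL, edges, meta$pi, meta$hx, extra = extra)
}

#' Write an RDS sample to CSV
#'
#' Flat participant table with the sample-level metadata as a JSON
#' sidecar.
#'
#' @param sample an `rds_sample`.
#' @param file output CSV path; the sidecar replaces the extension with
#'   `.json`.
#' @return `file`, invisibly.
#' @export
write_sample <- function(sample, file) {
  utils::write.csv(as.data.frame(sample), file, row.names = FALSE)
  meta <- list(n_waves = attr(sample, "n_waves"),
               n_seeds = attr(sample, "n_seeds"),
               n_reseeds = attr(sample, "n_reseeds"),
               productive_seeds = attr(sample, "productive_seeds"),
               recruits_per_seed = attr(sample, "recruits_per_seed"),
               population = attr(sample, "population"))
  jsonlite::write_json(meta, sub("\\.[^.]*$", ".json", file),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read an RDS sample written by [write_sample()]
#'
#' @param file CSV path from [write_sample()].
#' @return An `rds_sample`.
#' @export
read_sample <- function(file) {
  out <- utils::read.csv(file)
  meta <- jsonlite::read_json(sub("\\.[^.]*$", ".json", file),
                              simplifyVector = TRUE)
  for (a in c("n_waves", "n_seeds", "n_reseeds", "productive_seeds",
              "recruits_per_seed"))
    attr(out, a) <- meta[[a]]
  attr(out, "population") <- meta$population
  class(out) <- c("rds_sample", "data.frame")
  out
}
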
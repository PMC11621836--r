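#' Write a run archive
#'
#' Persists a finished run as a directory of plain-text files: the
#' configuration (`params.yaml`), the per-step series, final per-individual
#' and per-community tables, the end-of-run summary tables, and a manifest
#' recording the seed, stop reason and event counters.
#'
#' @param run A `culthitch_run`.
#' @param dir Output directory (created if absent).
#' @param force Overwrite an existing archive (default `FALSE`: refuse).
#' @return `dir`, invisibly.
#' @export
write_run_archive <- function(run, dir, force = FALSE) {
  manifest_path <- file.path(dir, "manifest.yaml")
  if (file.exists(manifest_path) && !force)
    stop("archive already exists at '", dir, "'; use force = TRUE to overwrite",
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sim_config(run$params, file.path(dir, "params.yaml"))
  utils::write.csv(run$series, file.path(dir, "series.csv"),
                   row.names = FALSE)
  utils::write.csv(individuals(run$world),
                   file.path(dir, "individuals.csv"), row.names = FALSE)
  utils::write.csv(communities(run$world),
                   file.path(dir, "communities.csv"), row.names = FALSE)
  sm <- run_summary(run)
  utils::write.csv(sm$type_counts, file.path(dir, "type_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(sm$proportions, file.path(dir, "proportions.csv"),
                   row.names = FALSE)
  utils::write.csv(sm$community_proportions,
                   file.path(dir, "community_proportions.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(
    seed = run$seed,
    stop_reason = run$stop_reason,
    converged = run$converged,
    steps = nrow(run$series),
    growth_rate_A = unname(sm$growth_rates[["A"]]),
    growth_rate_B = unname(sm$growth_rates[["B"]]),
    counters = as.list(run$counters)
  ), manifest_path)
  invisible(dir)
}

#' Read a run archive
#'
#' @param dir Directory written by [write_run_archive()].
#' @return A list with `params`, `manifest`, and tibbles `series`,
#'   `individuals`, `communities`, `type_counts`, `proportions`,
#'   `community_proportions`.
#' @export
read_run_archive <- function(dir) {
  rd <- function(f) tibble::as_tibble(
    utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE))
  list(
    params = read_sim_config(file.path(dir, "params.yaml")),
    manifest = yaml::read_yaml(file.path(dir, "manifest.yaml")),
    series = rd("series.csv"),
    individuals = rd("individuals.csv"),
    communities = rd("communities.csv"),
    type_counts = rd("type_counts.csv"),
    proportions = rd("proportions.csv"),
    community_proportions = rd("community_proportions.csv")
  )
}
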
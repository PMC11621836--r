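#' Plot the demographic trajectory of a run
#'
#' Population of each community lineage over the main phase, on a log scale
#' (so the effective growth rates appear as slopes).
#'
#' @param object A `culthitch_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.culthitch_run <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$population,
                                  colour = .data$lineage)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time step", y = "living individuals",
                  colour = "lineage",
                  title = "Population by community lineage")
}

#' Plot community type counts by lineage
#'
#' @param object A `culthitch_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.culthitch_summary <- function(object, ...) {
  ggplot2::ggplot(object$type_counts,
                  ggplot2::aes(x = .data$lineage, y = .data$n,
                               fill = .data$type)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "descent lineage", y = "communities",
                  fill = "community type",
                  title = "Final community types by lineage")
}

#' Box-and-whisker view of sweep trait proportions
#'
#' Distribution, across replicates, of the 1-variant proportion per trait
#' and community-type group, coloured by sex bias — the standard way of
#' comparing transmission pathways across scenarios.
#'
#' @param sweep_tbl Output of [run_sweep()].
#' @return A ggplot object.
#' @export
plot_trait_proportions <- function(sweep_tbl) {
  ggplot2::ggplot(sweep_tbl,
                  ggplot2::aes(x = .data$trait, y = .data$proportion,
                               colour = factor(.data$p_bias))) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_grid(ggplot2::vars(.data$group),
                        ggplot2::vars(.data$beta, .data$f),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "neutral trait", y = "proportion with 1-variant",
                  colour = "p_bias")
}

#' Histogram of per-community 1-variant proportions
#'
#' The between-community cultural-diversity view: distribution of the
#' per-community proportion of analyzed individuals carrying the 1-variant,
#' split by community-type group.
#'
#' @param world A `culthitch_world` (typically a finished run's world).
#' @param p_bias Sex bias governing the analyzed set; defaults to the
#'   world's parameter.
#' @return A ggplot object.
#' @export
plot_community_proportions <- function(world, p_bias = world$params$p_bias) {
  d <- community_neutral_proportions(world, p_bias)
  d$group <- ifelse(d$type == "A", "A", "BC")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$proportion)) +
    ggplot2::geom_histogram(bins = 20, boundary = 0) +
    ggplot2::facet_grid(ggplot2::vars(.data$group),
                        ggplot2::vars(.data$trait)) +
    ggplot2::labs(x = "per-community proportion with 1-variant",
                  y = "communities")
}
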
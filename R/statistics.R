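#' Classify a community by its adaptive variants
#'
#' Type `"A"` when all three adaptive variants are 0 (the incumbent
#' technology), `"B"` when all are 1 (the full novel technology), `"C"`
#' otherwise (partial adoption).
#'
#' @param a A length-3 0/1 vector, or a matrix with 3 columns (one row per
#'   community).
#' @return A character vector of types.
#' @export
#' @examples
#' classify_community(c(0, 0, 0))
#' classify_community(rbind(c(1, 1, 1), c(1, 0, 0)))
classify_community <- function(a) {
  if (is.matrix(a)) classify_community_matrix(a)
  else classify_community_matrix(matrix(a, nrow = 1))
}

classify_community_matrix <- function(a) {
  s <- rowSums(a)
  ifelse(s == 0, "A", ifelse(s == ncol(a), "B", "C"))
}

#' Community counts by lineage and type
#'
#' Cross-classifies the extant communities by descent lineage (from the
#' initial incumbent or migrant communities) and current type.
#'
#' @param world A `culthitch_world`.
#' @return A tibble with columns `lineage` (`"A"`/`"B"`), `type`
#'   (`"A"`/`"B"`/`"C"`) and `n`, complete over all six cells.
#' @export
lineage_type_counts <- function(world) {
  active <- which(world$c_active[seq_len(world$n_com)])
  type <- classify_community(world$c_a[active, , drop = FALSE])
  lineage <- c("A", "B")[world$c_lineage[active]]
  tibble::tibble(
    lineage = factor(lineage, levels = c("A", "B")),
    type = factor(type, levels = c("A", "B", "C"))
  ) |>
    dplyr::count(.data$lineage, .data$type, .drop = FALSE) |>
    dplyr::mutate(lineage = as.character(.data$lineage),
                  type = as.character(.data$type))
}

analyzed_set <- function(world, p_bias) {
  liv <- living(world)
  if (p_bias == 0) liv[!world$i_female[liv]]
  else if (p_bias == 1) liv[world$i_female[liv]]
  else liv
}

#' Neutral 1-variant proportions by community-type group
#'
#' The hitchhiking statistic: for each neutral trait, the fraction of
#' analyzed individuals carrying the 1-variant, pooled over type A
#' communities and, separately, over type B and C communities (the
#' communities that adopted the novel technology to some degree). Under a
#' fully sex-biased transmission regime only the biased-toward sex is
#' analyzed: males when `p_bias = 0`, females when `p_bias = 1`, everyone
#' otherwise.
#'
#' @param world A `culthitch_world`.
#' @param p_bias Sex bias governing the analyzed set; defaults to the
#'   world's parameter.
#' @return A tibble with columns `trait` (`"c1"`, ...), `group` (`"A"` or
#'   `"BC"`), `n_analyzed` and `proportion` (`NA` when the group has no
#'   analyzed individuals).
#' @export
neutral_proportions <- function(world, p_bias = world$params$p_bias) {
  ids <- analyzed_set(world, p_bias)
  type <- classify_community(world$c_a[world$i_com[ids], , drop = FALSE])
  group <- ifelse(type == "A", "A", "BC")
  z <- world$params$z
  out <- lapply(c("A", "BC"), function(g) {
    sel <- ids[group == g]
    tibble::tibble(
      trait = paste0("c", seq_len(z)),
      group = g,
      n_analyzed = length(sel),
      proportion = if (length(sel))
        colMeans(world$m_neutral[sel, , drop = FALSE]) else rep(NA_real_, z)
    )
  })
  dplyr::bind_rows(out)
}

#' Per-community neutral 1-variant proportions
#'
#' The between-community diversity view: for every extant community and
#' every neutral trait, the fraction of analyzed members carrying the
#' 1-variant.
#'
#' @inheritParams neutral_proportions
#' @return A tibble with columns `community`, `type`, `lineage`, `trait`,
#'   `n_analyzed`, `proportion`.
#' @export
community_neutral_proportions <- function(world,
                                          p_bias = world$params$p_bias) {
  ids <- analyzed_set(world, p_bias)
  active <- which(world$c_active[seq_len(world$n_com)])
  type <- classify_community(world$c_a[active, , drop = FALSE])
  lineage <- c("A", "B")[world$c_lineage[active]]
  z <- world$params$z
  com <- world$i_com[ids]
  cnt <- tabulate(com, nbins = world$n_com)
  ones <- rowsum(world$m_neutral[ids, , drop = FALSE], group = com,
                 reorder = FALSE)
  prop <- matrix(NA_real_, length(active), z)
  rows <- match(as.integer(rownames(ones)), active)
  keep <- !is.na(rows)
  prop[rows[keep], ] <- ones[keep, , drop = FALSE] / cnt[active[rows[keep]]]
  tibble::tibble(
    community = rep(active, each = z),
    type = rep(type, each = z),
    lineage = rep(lineage, each = z),
    trait = rep(paste0("c", seq_len(z)), times = length(active)),
    n_analyzed = rep(cnt[active], each = z),
    proportion = as.vector(t(prop))
  )
}

#' Effective per-step growth rate
#'
#' Least-squares slope of log population against time. The default window
#' drops the final 10% of the series, where the grid-full stopping rule
#' distorts growth.
#'
#' @param series A data frame with columns `t` and `population`.
#' @param drop_tail Fraction of trailing steps to exclude (default 0.1).
#' @return The per-step exponential growth rate (slope of the log-linear
#'   fit).
#' @export
#' @examples
#' s <- data.frame(t = 0:49, population = 100 * exp(0.01 * (0:49)))
#' growth_rate(s)  # ~0.01
growth_rate <- function(series, drop_tail = 0.1) {
  stopifnot(is.data.frame(series), all(c("t", "population") %in% names(series)))
  n <- nrow(series)
  if (n < 10) stop("need at least 10 points to estimate a growth rate",
                   call. = FALSE)
  keep <- seq_len(max(10L, floor(n * (1 - drop_tail))))
  s <- series[keep, ]
  if (any(s$population <= 0))
    stop("non-positive population in the fitting window", call. = FALSE)
  unname(stats::coef(stats::lm(log(population) ~ t, data = s))[2])
}

lineage_growth_rates <- function(run, drop_tail = 0.1) {
  s <- run$series
  est <- function(pop) {
    ok <- pop > 0
    if (sum(ok) < 10) return(NA_real_)
    growth_rate(data.frame(t = s$t[ok], population = pop[ok]),
                drop_tail = drop_tail)
  }
  c(A = est(s$pop_lineage_A), B = est(s$pop_lineage_B))
}

#' Summarize a finished run
#'
#' Collects the end-of-run statistics: community counts by lineage and
#' type, pooled and per-community neutral 1-variant proportions by
#' community-type group, and the per-lineage effective growth rates fitted
#' to the main-phase series.
#'
#' @param run A `culthitch_run`.
#' @return A `culthitch_summary`: list with elements `type_counts`,
#'   `proportions`, `community_proportions`, `growth_rates` and `glance`.
#' @export
run_summary <- function(run) {
  out <- list(
    type_counts = lineage_type_counts(run$world),
    proportions = neutral_proportions(run$world),
    community_proportions = community_neutral_proportions(run$world),
    growth_rates = lineage_growth_rates(run),
    glance = glance(run)
  )
  class(out) <- "culthitch_summary"
  out
}

#' @export
print.culthitch_summary <- function(x, ...) {
  cat("<culthitch_summary>\n")
  cat(sprintf("  growth rates: A %.4f, B %.4f\n",
              x$growth_rates[["A"]], x$growth_rates[["B"]]))
  print(tidyr::pivot_wider(x$type_counts, names_from = "type",
                           values_from = "n"))
  invisible(x)
}

#' The full experimental parameter grid
#'
#' All 36 swept combinations: adoption strength `beta` in {-10, 0}, common
#' reproductive bonus `f` in {0, 0.005, 0.015} (applied to all three
#' adaptive traits), sex bias `p_bias` in {0, 0.5, 1} and residence rule
#' `p_location` in {0, 0.5}. The five neutral-trait transmission pathways
#' are all tracked within each run.
#'
#' @return A tibble with columns `beta`, `f`, `p_bias`, `p_location`.
#' @export
default_sweep_grid <- function() {
  tidyr::expand_grid(beta = c(-10, 0), f = c(0, 0.005, 0.015),
                     p_bias = c(0, 0.5, 1), p_location = c(0, 0.5))
}

derive_seed <- function(base_seed, combo, rep) {
  as.integer((as.double(base_seed) + 999983 * combo + 7919 * rep) %%
               2147483629) + 1L
}

#' Run a replicated parameter sweep
#'
#' Executes every grid row for `n_reps` replicates with reproducible,
#' per-combination derived seeds (so results are invariant to execution
#' order and sweeps can be reproduced piecewise), and returns a tidy table
#' with one row per run, trait and community-type group.
#'
#' @param grid A tibble of parameter combinations with columns `beta`, `f`,
#'   `p_bias`, `p_location` (see [default_sweep_grid()]).
#' @param n_reps Replicates per combination.
#' @param base_seed Root seed for the derived per-run seeds.
#' @param base_params Template `culthitch_params` providing every non-swept
#'   parameter; swept fields are overwritten row by row.
#' @return A tibble: grid columns, `rep`, `seed`, `stop_reason`, `steps`,
#'   `pct_lineage_A`, `growth_rate_A`, `growth_rate_B`, community-type
#'   counts, and the per-trait columns `trait`, `group`, `n_analyzed`,
#'   `proportion`.
#' @export
run_sweep <- function(grid = default_sweep_grid(), n_reps = 1,
                      base_seed = 1, base_params = sim_params()) {
  rows <- vector("list", nrow(grid) * n_reps)
  k <- 0L
  for (ci in seq_len(nrow(grid))) {
    g <- grid[ci, ]
    params <- base_params
    params$beta <- g$beta
    params$f1 <- params$f2 <- params$f3 <- g$f
    params$p_bias <- g$p_bias
    params$p_location <- g$p_location
    for (rep_i in seq_len(n_reps)) {
      seed <- derive_seed(base_seed, ci, rep_i)
      run <- run_model_retry(params, seed = seed)
      sm <- run_summary(run)
      gl <- sm$glance
      tc <- tidyr::pivot_wider(sm$type_counts, names_from = "type",
                               values_from = "n", names_prefix = "n_type_")
      tc <- dplyr::summarise(tc, dplyr::across(dplyr::starts_with("n_type_"),
                                               sum))
      k <- k + 1L
      rows[[k]] <- dplyr::bind_cols(
        tibble::tibble(beta = g$beta, f = g$f, p_bias = g$p_bias,
                       p_location = g$p_location, rep = rep_i, seed = seed,
                       stop_reason = gl$stop_reason, steps = gl$steps,
                       pct_lineage_A = gl$pct_lineage_A,
                       growth_rate_A = gl$growth_rate_A,
                       growth_rate_B = gl$growth_rate_B),
        tc[rep(1, nrow(sm$proportions)), ],
        sm$proportions
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Median and interquartile range of sweep proportions
#'
#' Condenses a replicated sweep into the box-and-whisker quantities: per
#' parameter combination, trait and community-type group, the median and
#' quartiles of the 1-variant proportion across replicates.
#'
#' @param sweep_tbl Output of [run_sweep()].
#' @return A tibble with `median`, `q25`, `q75` and `n_reps` per
#'   combination, trait and group.
#' @export
summarize_sweep <- function(sweep_tbl) {
  sweep_tbl |>
    dplyr::group_by(.data$beta, .data$f, .data$p_bias, .data$p_location,
                    .data$trait, .data$group) |>
    dplyr::summarise(
      median = stats::median(.data$proportion, na.rm = TRUE),
      q25 = stats::quantile(.data$proportion, 0.25, na.rm = TRUE),
      q75 = stats::quantile(.data$proportion, 0.75, na.rm = TRUE),
      n_reps = dplyr::n(), .groups = "drop")
}
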
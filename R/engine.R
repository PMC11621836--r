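#' Advance the world by one time step
#'
#' Runs the fixed phase order: (1) aging and mortality; (2) marriage-pool
#' formation, random exogamous pairing and settlement (with postmarital
#' migration); (3) resocialization of this step's migrants, in uniformly
#' random order so an already-resocialized migrant can serve as a role model
#' with its updated variant; (4) community-level adoption of adaptive
#' traits; (5) reproduction with vertical transmission; (6) fission checks.
#' The clock is then incremented and the per-step series recorded.
#'
#' @param world A `culthitch_world` (mutated in place).
#' @return The world, invisibly.
#' @export
step_world <- function(world) {
  if (!is.na(world$stopped)) return(invisible(world))
  step_age_and_mortality(world)
  world$resoc_queue <- integer(0)
  pool <- form_marriage_pool(world)
  if (length(pool) > 1L)
    settle_pairs(world, match_pairs(world, pool))
  q <- world$resoc_queue
  if (length(q) > 1L) q <- q[sample.int(length(q))]
  if (length(q)) {
    # membership is static during the resocialization phase: snapshot the
    # community member lists once for all migrants
    liv <- living(world)
    world$.resoc_cache <- split(liv, world$i_com[liv])
    resocialize_batch(world, q)
    world$.resoc_cache <- NULL
  }
  adoption_step(world)
  reproduce(world)
  fission_check(world)
  retire_empty_communities(world)
  if (is.na(world$stopped) && !any(!world$occupied))
    world$stopped <- "grid_full"
  world$t <- world$t + 1L
  record_series(world)
  invisible(world)
}

# A community is its living members: one whose size reaches zero is
# retired from the landscape (its grid cell is freed and it no longer
# appears in community counts).
retire_empty_communities <- function(world) {
  act <- which(world$c_active[seq_len(world$n_com)])
  dead <- act[community_sizes(world)[act] == 0L]
  if (length(dead)) {
    world$c_active[dead] <- FALSE
    world$occupied[cell_index(world, world$c_x[dead], world$c_y[dead])] <- FALSE
  }
  invisible(world)
}

record_series <- function(world) {
  liv <- living(world)
  lin_i <- world$c_lineage[world$i_com[liv]]
  active <- which(world$c_active[seq_len(world$n_com)])
  type <- classify_community(world$c_a[active, , drop = FALSE])
  lin_c <- c("A", "B")[world$c_lineage[active]]
  cnt <- table(factor(lin_c, levels = c("A", "B")),
               factor(type, levels = c("A", "B", "C")))
  world$series[[length(world$series) + 1L]] <- c(
    t = world$t,
    pop_lineage_A = sum(lin_i == 1L), pop_lineage_B = sum(lin_i == 2L),
    com_A_A = cnt["A", "A"], com_A_B = cnt["A", "B"], com_A_C = cnt["A", "C"],
    com_B_A = cnt["B", "A"], com_B_B = cnt["B", "B"], com_B_C = cnt["B", "C"]
  )
  invisible(world)
}

series_tibble <- function(world) {
  if (!length(world$series)) {
    return(tibble::tibble(t = integer(0), pop_lineage_A = integer(0),
                          pop_lineage_B = integer(0)))
  }
  tibble::as_tibble(as.data.frame(do.call(rbind, world$series)))
}

#' Demographic burn-in
#'
#' Equilibrates the age and family structure before the experiment proper:
#' for `burn_in_steps` iterations only aging/mortality, the standard
#' exogamous marriage routine, reproduction without cultural copying, and
#' fission with immediate removal of the daughter community that would
#' occupy a new cell (keeping the community count at its initial value) are
#' run. Resocialization and adoption are entirely disabled, and newborns
#' copy nothing from their parents, so the marriage-driven relocations of
#' the burn-in are culturally void: at the end every individual's neutral
#' and carried adaptive variants are (re)set to their community lineage's
#' founding values, the clock is reset to 0 and the event counters cleared.
#' (Restricting burn-in pairing to within-community partners, so that
#' nobody relocates at all, cannot sustain the population: a 70-person
#' marriage market leaves too many fertile adults unmatched.)
#'
#' @param world A freshly initialized `culthitch_world` (mutated in place).
#' @return The world, invisibly.
#' @export
run_burn_in <- function(world) {
  for (s in seq_len(world$params$burn_in_steps)) {
    step_age_and_mortality(world)
    world$resoc_queue <- integer(0)
    pool <- form_marriage_pool(world)
    if (length(pool) > 1L)
      settle_pairs(world, match_pairs(world, pool))
    reproduce(world, transmit = FALSE)
    fission_check(world, burn_in = TRUE)
    sizes <- community_sizes(world)
    if (any(sizes[world$c_active[seq_len(world$n_com)]] == 0L))
      stop(structure(class = c("culthitch_burnin_extinction", "error",
                               "condition"),
                     list(message = sprintf(
                       "community extinction during burn-in at step %d (sizes: %s)",
                       s, paste(sizes, collapse = ", ")),
                       call = NULL)))
    world$t <- world$t + 1L
  }
  reset_variants_to_lineage(world)
  world$t <- 0L
  world$counters[] <- 0
  world$resoc_queue <- integer(0)
  world$series <- list()
  invisible(world)
}

#' Run a full simulation
#'
#' Seeds the RNG, initializes the world, runs the demographic burn-in, then
#' iterates [step_world()] until the grid is full or the safety cap
#' `max_steps` is reached. Identical `(params, seed)` give bitwise-identical
#' results.
#'
#' @param params A valid `culthitch_params`.
#' @param seed Integer RNG seed; defaults to `params$seed`, else 1.
#' @return A `culthitch_run` object: a list with elements `params`, `seed`,
#'   `series` (per-step tibble of lineage populations and community
#'   type-by-lineage counts), `world` (final state), `stop_reason`,
#'   `converged` and `counters`.
#' @export
#' @examples
#' p <- sim_params(grid_width = 3, grid_height = 3, n_incumbent = 2,
#'                 n_migrant = 1, initial_community_size = 30,
#'                 burn_in_steps = 20, n_fission = 40, max_steps = 200)
#' r <- run_model(p, seed = 1)
#' glance(r)
run_model <- function(params, seed = NULL) {
  if (is.null(seed)) seed <- params$seed
  if (is.null(seed)) seed <- 1L
  set.seed(seed)
  world <- init_world(params)
  run_burn_in(world)
  while (is.na(world$stopped) && world$t < params$max_steps)
    step_world(world)
  if (is.na(world$stopped)) world$stopped <- "max_steps"
  res <- list(
    params = params,
    seed = as.integer(seed),
    series = series_tibble(world),
    world = world,
    stop_reason = world$stopped,
    converged = identical(world$stopped, "grid_full"),
    counters = world$counters
  )
  class(res) <- "culthitch_run"
  res
}

#' Run a simulation, retrying seeds lost to burn-in extinction
#'
#' A founding community occasionally dies out during the demographic
#' burn-in (a patrilocal community that runs short of males exports its
#' daughters and can spiral to extinction); [run_model()] then aborts with
#' a `culthitch_burnin_extinction` condition, since the experiment requires
#' all initial communities to survive the burn-in. This wrapper retries
#' with deterministically salted seeds until a run clears the burn-in, so
#' replicated experiments remain reproducible functions of the seed.
#'
#' @param params A valid `culthitch_params`.
#' @param seed Base seed for the first attempt.
#' @param max_attempts Attempts before giving up.
#' @return A `culthitch_run`, with an extra element `attempts`.
#' @export
run_model_retry <- function(params, seed, max_attempts = 25L) {
  for (k in seq_len(max_attempts)) {
    sk <- as.integer((as.double(seed) + 31607 * (k - 1)) %% 2147483629)
    res <- tryCatch(run_model(params, seed = sk),
                    culthitch_burnin_extinction = function(e) NULL)
    if (!is.null(res)) {
      res$attempts <- k
      return(res)
    }
  }
  stop("no burn-in survived in ", max_attempts, " attempts", call. = FALSE)
}

#' @export
print.culthitch_run <- function(x, ...) {
  cat(sprintf(
    "<culthitch_run> seed %d; %d steps; stop: %s; %d communities, %d living\n",
    x$seed, nrow(x$series), x$stop_reason,
    sum(x$world$c_active[seq_len(x$world$n_com)]), length(living(x$world))))
  invisible(x)
}

#' Tidy the per-step series of a run
#'
#' @param x A `culthitch_run`.
#' @param ... Unused.
#' @return A long tibble with columns `t`, `lineage`, `population`,
#'   `communities_A`, `communities_B`, `communities_C`.
#' @export
tidy.culthitch_run <- function(x, ...) {
  s <- x$series
  dplyr::bind_rows(
    tibble::tibble(t = s$t, lineage = "A", population = s$pop_lineage_A,
                   communities_A = s$com_A_A, communities_B = s$com_A_B,
                   communities_C = s$com_A_C),
    tibble::tibble(t = s$t, lineage = "B", population = s$pop_lineage_B,
                   communities_A = s$com_B_A, communities_B = s$com_B_B,
                   communities_C = s$com_B_C)
  ) |> dplyr::arrange(.data$t, .data$lineage)
}

#' One-row summary of a run
#'
#' @param x A `culthitch_run`.
#' @param ... Unused.
#' @return A one-row tibble: seed, elapsed steps, stop reason, final
#'   population and community counts, estimated per-step growth rate per
#'   lineage, and the main event counters.
#' @export
glance.culthitch_run <- function(x, ...) {
  w <- x$world
  active <- which(w$c_active[seq_len(w$n_com)])
  gr <- lineage_growth_rates(x)
  tibble::tibble(
    seed = x$seed,
    steps = nrow(x$series),
    stop_reason = x$stop_reason,
    converged = x$converged,
    population = length(living(w)),
    n_communities = length(active),
    pct_lineage_A = 100 * mean(w$c_lineage[active] == 1L),
    growth_rate_A = gr[["A"]],
    growth_rate_B = gr[["B"]],
    births = unname(x$counters["births"]),
    deaths = unname(x$counters["deaths"]),
    marriages = unname(x$counters["marriages"]),
    migrations = unname(x$counters["migrations"]),
    adoptions = unname(x$counters["adoptions"]),
    fissions = unname(x$counters["fissions"])
  )
}
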
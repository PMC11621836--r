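#' Default age-specific mortality schedule
#'
#' Piecewise-constant annual death probabilities loosely calibrated to
#' ethnographic hunter-gatherer mortality: 0.15 for ages 0--5, 0.01 for
#' 6--40, 0.02 for 41--65, 0.05 for 66--85 and 1 above 85.
#'
#' @return A tibble with columns `age_min` (lower band edge, inclusive) and
#'   `p` (annual death probability in that band).
#' @export
#' @examples
#' default_death_schedule()
default_death_schedule <- function() {
  tibble::tibble(
    age_min = c(0L, 6L, 41L, 66L, 86L),
    p = c(0.15, 0.01, 0.02, 0.05, 1.0)
  )
}

#' Default neutral-trait transmission pathways
#'
#' The canonical five-trait set: one trait with no postmarital learning,
#' two horizontal traits (learning from peers within 20 years of age) and
#' two oblique traits (learning from individuals at least 20 years older),
#' at postmarital learning probabilities 0, 0.9, 1, 0.9 and 1.
#'
#' @return A tibble with columns `trait_id`, `name`, `p_transmit`, `pathway`.
#' @export
#' @examples
#' default_traits()
default_traits <- function() {
  tibble::tibble(
    trait_id = 1:5,
    name = paste0("c", 1:5),
    p_transmit = c(0, 0.9, 1, 0.9, 1),
    pathway = c("none", "horizontal", "horizontal", "oblique", "oblique")
  )
}

#' Trait set with no postmarital learning
#'
#' Convenience constructor for scenarios where neutral traits are only ever
#' transmitted vertically at birth (`p_transmit = 0` for every trait).
#'
#' @param z Number of neutral traits.
#' @return A tibble like [default_traits()].
#' @export
traits_vertical_only <- function(z = 5L) {
  tibble::tibble(
    trait_id = seq_len(z),
    name = paste0("c", seq_len(z)),
    p_transmit = 0,
    pathway = "none"
  )
}

#' Simulation parameters
#'
#' Bundles every knob of the simulator: the grid, the initial communities,
#' the demographic constants, the adoption strength and the neutral-trait
#' transmission setup. Defaults are the study conditions: a 10x10 grid
#' seeded with eight incumbent communities (adaptive variants all 0) and two
#' migrant communities (all 1) of 70 individuals each, baseline per-pair
#' reproduction probability `b = 0.3224`, fission threshold 100 and a
#' 500-step demographic burn-in.
#'
#' @param grid_width,grid_height Grid dimensions (cells are addresses only;
#'   no spatial interaction).
#' @param n_incumbent Number of initial incumbent (type A) communities.
#' @param n_migrant Number of initial migrant (type B) communities.
#' @param initial_community_size Individuals per initial community.
#' @param burn_in_steps Steps of the demographic burn-in phase.
#' @param b Baseline reproduction probability per married pair per step.
#' @param f1,f2,f3 Reproductive bonus conferred by each adaptive variant in
#'   its novel (1) state; added to `b` for pairs residing in a community
#'   carrying that variant.
#' @param beta Adoption-strength exponent of the frequency-dependent
#'   community-level adoption rule; `beta = 0` gives adoption probability
#'   `k/n`, large negative values suppress adoption.
#' @param p_bias Probability that any social-learning event (vertical or
#'   postmarital) copies from a female; 0 and 1 give strictly patrilineal
#'   and matrilineal transmission.
#' @param p_location Probability a new couple resides in the female
#'   partner's community (0 = patrilocality, 0.5 = bilocality,
#'   1 = matrilocality).
#' @param death_schedule Mortality schedule, see [default_death_schedule()].
#' @param reproduction_age_min,reproduction_age_max Fertile age window
#'   (inclusive) for both partners.
#' @param marriage_age_min Minimum age to enter the marriage pool
#'   (inclusive; see `marriage_age_strict`).
#' @param marriage_age_strict If `TRUE`, pool entry requires age strictly
#'   greater than `marriage_age_min`. Default `FALSE`, aligning the marriage
#'   threshold with the inclusive fertile window.
#' @param generation_gap Age difference (years) separating generations for
#'   horizontal (< gap) versus oblique (>= gap) transmission.
#' @param n_fission Community size at which fission is triggered.
#' @param z Number of neutral traits; must equal `nrow(trait_configs)`.
#' @param trait_configs Neutral-trait pathway table, see [default_traits()].
#' @param max_steps Safety cap on main-phase steps.
#' @param seed Default RNG seed used by [run_model()] when none is given.
#' @return An object of class `culthitch_params` (a named list).
#' @export
#' @examples
#' p <- sim_params(beta = -10, f1 = 0.015, f2 = 0.015, f3 = 0.015)
#' validate_params(p)
sim_params <- function(grid_width = 10L, grid_height = 10L,
                       n_incumbent = 8L, n_migrant = 2L,
                       initial_community_size = 70L,
                       burn_in_steps = 500L,
                       b = 0.3224, f1 = 0, f2 = 0, f3 = 0,
                       beta = 0, p_bias = 0.5, p_location = 0,
                       death_schedule = default_death_schedule(),
                       reproduction_age_min = 18L, reproduction_age_max = 45L,
                       marriage_age_min = 18L, marriage_age_strict = FALSE,
                       generation_gap = 20L,
                       n_fission = 100L, z = NULL,
                       trait_configs = default_traits(),
                       max_steps = 5000L, seed = NULL) {
  if (is.null(z)) z <- nrow(trait_configs)
  p <- list(
    grid_width = as.integer(grid_width), grid_height = as.integer(grid_height),
    n_incumbent = as.integer(n_incumbent), n_migrant = as.integer(n_migrant),
    initial_community_size = as.integer(initial_community_size),
    burn_in_steps = as.integer(burn_in_steps),
    b = as.numeric(b), f1 = as.numeric(f1), f2 = as.numeric(f2),
    f3 = as.numeric(f3), beta = as.numeric(beta),
    p_bias = as.numeric(p_bias), p_location = as.numeric(p_location),
    death_schedule = tibble::tibble(
      age_min = as.integer(death_schedule$age_min),
      p = as.numeric(death_schedule$p)),
    reproduction_age_min = as.integer(reproduction_age_min),
    reproduction_age_max = as.integer(reproduction_age_max),
    marriage_age_min = as.integer(marriage_age_min),
    marriage_age_strict = isTRUE(marriage_age_strict),
    generation_gap = as.integer(generation_gap),
    n_fission = as.integer(n_fission), z = as.integer(z),
    trait_configs = trait_configs,
    max_steps = as.integer(max_steps),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(p) <- "culthitch_params"
  p
}

#' Validate simulation parameters
#'
#' Reporting operation: checks every invariant of a parameter set and
#' returns the violations rather than erroring, so callers (including the
#' command-line interface) can present all problems at once.
#'
#' @param params A `culthitch_params` object.
#' @return A character vector of violation messages, each naming the
#'   offending field; empty when the parameters are valid.
#' @export
validate_params <- function(params) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  chk_prob <- function(name) {
    x <- params[[name]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      add(sprintf("%s must be a probability in [0, 1]", name))
  }
  for (nm in c("b", "f1", "f2", "f3", "p_bias", "p_location")) chk_prob(nm)
  if (!is.numeric(params$beta) || length(params$beta) != 1 || is.na(params$beta))
    add("beta must be a single real number")
  pos_int <- function(name, min = 1L) {
    x <- params[[name]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min)
      add(sprintf("%s must be an integer >= %d", name, min))
  }
  pos_int("grid_width"); pos_int("grid_height")
  pos_int("n_incumbent", 0L); pos_int("n_migrant", 0L)
  pos_int("initial_community_size"); pos_int("burn_in_steps", 0L)
  pos_int("max_steps")
  if (params$n_incumbent + params$n_migrant < 1L)
    add("n_incumbent + n_migrant must be at least 1")
  if (params$n_incumbent + params$n_migrant >
      params$grid_width * params$grid_height)
    add("n_incumbent + n_migrant exceeds grid capacity (grid_width x grid_height)")
  if (params$n_fission <= params$initial_community_size)
    add("n_fission must exceed initial_community_size")
  sched <- params$death_schedule
  if (!is.data.frame(sched) || !all(c("age_min", "p") %in% names(sched)) ||
      nrow(sched) < 1 || is.unsorted(sched$age_min, strictly = TRUE) ||
      sched$age_min[1] != 0 || any(sched$p < 0 | sched$p > 1))
    add("death_schedule must map increasing age bands starting at 0 to probabilities")
  tc <- params$trait_configs
  if (!is.data.frame(tc) ||
      !all(c("trait_id", "p_transmit", "pathway") %in% names(tc))) {
    add("trait_configs must have columns trait_id, p_transmit, pathway")
  } else {
    if (nrow(tc) != params$z)
      add("z must equal the number of rows of trait_configs")
    if (any(tc$p_transmit < 0 | tc$p_transmit > 1))
      add("trait_configs: p_transmit must be in [0, 1]")
    if (!all(tc$pathway %in% c("none", "horizontal", "oblique")))
      add("trait_configs: pathway must be none, horizontal or oblique")
    bad <- (tc$pathway == "none") != (tc$p_transmit == 0)
    if (any(bad, na.rm = TRUE))
      add("trait_configs: pathway is 'none' iff p_transmit is 0")
  }
  if (params$reproduction_age_min > params$reproduction_age_max)
    add("reproduction_age_min must not exceed reproduction_age_max")
  if (params$generation_gap < 1)
    add("generation_gap must be a positive number of years")
  v
}

#' @export
print.culthitch_params <- function(x, ...) {
  cat("<culthitch_params>\n")
  cat(sprintf("  grid %dx%d; %d incumbent + %d migrant communities of %d\n",
              x$grid_width, x$grid_height, x$n_incumbent, x$n_migrant,
              x$initial_community_size))
  cat(sprintf("  b = %.4f, f = (%g, %g, %g), beta = %g\n",
              x$b, x$f1, x$f2, x$f3, x$beta))
  cat(sprintf("  p_bias = %g, p_location = %g, n_fission = %d, z = %d\n",
              x$p_bias, x$p_location, x$n_fission, x$z))
  cat(sprintf("  burn-in %d steps, max %d steps\n",
              x$burn_in_steps, x$max_steps))
  invisible(x)
}

# Flat serialization used by write_sim_config/read_sim_config: trait table
# and death schedule become parallel lists so the YAML stays key -> value.
params_to_list <- function(params) {
  list(
    grid_width = params$grid_width, grid_height = params$grid_height,
    n_incumbent = params$n_incumbent, n_migrant = params$n_migrant,
    initial_community_size = params$initial_community_size,
    burn_in_steps = params$burn_in_steps,
    b = params$b, f1 = params$f1, f2 = params$f2, f3 = params$f3,
    beta = params$beta, p_bias = params$p_bias, p_location = params$p_location,
    death_age_min = params$death_schedule$age_min,
    death_p = params$death_schedule$p,
    reproduction_age_min = params$reproduction_age_min,
    reproduction_age_max = params$reproduction_age_max,
    marriage_age_min = params$marriage_age_min,
    marriage_age_strict = params$marriage_age_strict,
    generation_gap = params$generation_gap,
    n_fission = params$n_fission, z = params$z,
    trait_p_transmit = params$trait_configs$p_transmit,
    trait_pathway = params$trait_configs$pathway,
    max_steps = params$max_steps,
    seed = params$seed
  )
}

#' Write a simulation configuration file
#'
#' Serializes a parameter set to a flat YAML file that maps one-to-one onto
#' [sim_params()]; [read_sim_config()] round-trips it exactly.
#'
#' @param params A `culthitch_params` object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(params, path) {
  yaml::write_yaml(params_to_list(params), path)
  invisible(path)
}

#' Read a simulation configuration file
#'
#' @param path Path to a YAML file written by [write_sim_config()] (or by
#'   hand; missing keys fall back to the defaults of [sim_params()]).
#' @return A `culthitch_params` object.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- sim_params()
  get <- function(name, fallback) if (!is.null(cfg[[name]])) cfg[[name]] else fallback
  sched <- if (!is.null(cfg$death_age_min)) {
    tibble::tibble(age_min = as.integer(unlist(cfg$death_age_min)),
                   p = as.numeric(unlist(cfg$death_p)))
  } else defaults$death_schedule
  traits <- if (!is.null(cfg$trait_p_transmit)) {
    pt <- as.numeric(unlist(cfg$trait_p_transmit))
    tibble::tibble(trait_id = seq_along(pt), name = paste0("c", seq_along(pt)),
                   p_transmit = pt,
                   pathway = as.character(unlist(cfg$trait_pathway)))
  } else defaults$trait_configs
  sim_params(
    grid_width = get("grid_width", defaults$grid_width),
    grid_height = get("grid_height", defaults$grid_height),
    n_incumbent = get("n_incumbent", defaults$n_incumbent),
    n_migrant = get("n_migrant", defaults$n_migrant),
    initial_community_size = get("initial_community_size",
                                 defaults$initial_community_size),
    burn_in_steps = get("burn_in_steps", defaults$burn_in_steps),
    b = get("b", defaults$b),
    f1 = get("f1", defaults$f1), f2 = get("f2", defaults$f2),
    f3 = get("f3", defaults$f3),
    beta = get("beta", defaults$beta),
    p_bias = get("p_bias", defaults$p_bias),
    p_location = get("p_location", defaults$p_location),
    death_schedule = sched,
    reproduction_age_min = get("reproduction_age_min",
                               defaults$reproduction_age_min),
    reproduction_age_max = get("reproduction_age_max",
                               defaults$reproduction_age_max),
    marriage_age_min = get("marriage_age_min", defaults$marriage_age_min),
    marriage_age_strict = get("marriage_age_strict",
                              defaults$marriage_age_strict),
    generation_gap = get("generation_gap", defaults$generation_gap),
    n_fission = get("n_fission", defaults$n_fission),
    trait_configs = traits,
    max_steps = get("max_steps", defaults$max_steps),
    seed = cfg$seed
  )
}
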
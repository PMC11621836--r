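# Hand-built miniature worlds shared by the test-suite and demos. These are
# constructed directly (no RNG), so their state is fully enumerable.

#' Append one individual to a world
#'
#' Low-level constructor used to hand-build miniature worlds for tests and
#' demos; bypasses demography entirely.
#'
#' @param world A `culthitch_world`.
#' @param female Logical sex flag.
#' @param age Age in years.
#' @param community Community id of residence.
#' @param natal Natal community id (defaults to `community`).
#' @param neutral Length-`z` 0/1 vector; defaults to the community
#'   lineage's founding value.
#' @param carried Length-3 0/1 vector; defaults to the community's current
#'   adaptive vector.
#' @param spouse Optional spouse id (the link is made symmetric).
#' @param family Family id; defaults to a fresh singleton family.
#' @param migrated_at Optional migration step.
#' @return The new individual's id.
#' @export
add_individual <- function(world, female, age, community,
                           natal = community, neutral = NULL, carried = NULL,
                           spouse = NA_integer_, family = NULL,
                           migrated_at = NA_integer_) {
  ensure_ind_capacity(world, 1L)
  id <- world$n_ind + 1L
  world$n_ind <- id
  world$i_female[id] <- female
  world$i_age[id] <- as.integer(age)
  world$i_alive[id] <- TRUE
  world$i_com[id] <- community
  world$i_natal[id] <- natal
  world$i_mig_at[id] <- migrated_at
  if (is.null(family)) {
    family <- world$next_family
    world$next_family <- family + 1L
  }
  world$i_family[id] <- family
  if (is.null(neutral))
    neutral <- rep(if (world$c_lineage[natal] == 1L) 0L else 1L,
                   world$params$z)
  world$m_neutral[id, ] <- as.integer(neutral)
  if (is.null(carried)) carried <- world$c_a[community, ]
  world$m_carried[id, ] <- as.integer(carried)
  if (!is.na(spouse)) {
    world$i_spouse[id] <- spouse
    world$i_spouse[spouse] <- id
    world$i_married[c(id, spouse)] <- TRUE
  }
  id
}

empty_fixture_world <- function(params) new_world_env(params)

#' Deterministic fixture worlds
#'
#' A small catalogue of hand-built worlds with fully enumerable state:
#'
#' * `"two_communities"`: one incumbent (A) and one migrant (B) community of
#'   6 members each with fixed ages and alternating sexes; neutral variants
#'   split 0/1 by community.
#' * `"lonely_migrant"`: a female migrant from the B community living alone
#'   in an A community, resocialization pending — every postmarital learning
#'   attempt finds no candidate.
#' * `"fission_ready"`: one community of exactly `n_fission = 100` members
#'   organized into 25 four-member families (married parents plus two
#'   children), on a grid with empty cells.
#'
#' @param name Fixture name.
#' @param ... Overrides passed to [sim_params()] (e.g. `p_bias`).
#' @return A `culthitch_world`.
#' @export
#' @examples
#' w <- make_fixture("two_communities")
#' communities(w)
make_fixture <- function(name, ...) {
  catalogue <- c("two_communities", "lonely_migrant", "fission_ready")
  if (!name %in% catalogue)
    stop("unknown fixture '", name, "'; available: ",
         paste(catalogue, collapse = ", "), call. = FALSE)
  switch(name,
    two_communities = fixture_two_communities(...),
    lonely_migrant = fixture_lonely_migrant(...),
    fission_ready = fixture_fission_ready(...)
  )
}

fixture_two_communities <- function(...) {
  params <- sim_params(grid_width = 5, grid_height = 5, n_incumbent = 1,
                       n_migrant = 1, initial_community_size = 6,
                       burn_in_steps = 0, n_fission = 50, ...)
  w <- empty_fixture_world(params)
  ca <- add_community(w, 1L, 1L, 1L, c(0L, 0L, 0L))
  cb <- add_community(w, 2L, 1L, 2L, c(1L, 1L, 1L))
  ages <- c(5L, 25L, 30L, 45L, 50L, 70L)
  for (j in seq_along(ages)) {
    add_individual(w, female = j %% 2L == 1L, age = ages[j], community = ca)
    add_individual(w, female = j %% 2L == 0L, age = ages[j], community = cb)
  }
  w
}

fixture_lonely_migrant <- function(...) {
  params <- sim_params(grid_width = 5, grid_height = 5, n_incumbent = 1,
                       n_migrant = 1, initial_community_size = 6,
                       burn_in_steps = 0, n_fission = 50, ...)
  w <- empty_fixture_world(params)
  ca <- add_community(w, 1L, 1L, 1L, c(0L, 0L, 0L))
  cb <- add_community(w, 2L, 1L, 2L, c(1L, 1L, 1L))
  # origin community keeps two residents; the migrant is alone at the
  # destination, so no role model of any sex or pathway exists
  add_individual(w, female = TRUE, age = 50L, community = cb)
  add_individual(w, female = FALSE, age = 52L, community = cb)
  mig <- add_individual(w, female = TRUE, age = 25L, community = ca,
                        natal = cb, carried = c(1L, 1L, 1L),
                        migrated_at = 0L)
  w$i_married[mig] <- TRUE
  w$resoc_queue <- mig
  w
}

fixture_fission_ready <- function(...) {
  params <- sim_params(grid_width = 10, grid_height = 10, n_incumbent = 1,
                       n_migrant = 0, initial_community_size = 99,
                       burn_in_steps = 0, n_fission = 100, ...)
  w <- empty_fixture_world(params)
  ca <- add_community(w, 5L, 5L, 1L, c(0L, 0L, 0L))
  for (fam in 1:25) {
    fid <- w$next_family
    w$next_family <- fid + 1L
    mother <- add_individual(w, TRUE, 40L, ca, family = fid)
    add_individual(w, FALSE, 42L, ca, family = fid, spouse = mother)
    add_individual(w, fam %% 2L == 0L, 10L, ca, family = fid)
    add_individual(w, fam %% 2L == 1L, 12L, ca, family = fid)
  }
  w
}
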
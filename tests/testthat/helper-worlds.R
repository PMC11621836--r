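# Builders for miniature worlds used across the suite. Everything is
# constructed in code; nothing is read from disk.

# A small world suitable for fast end-to-end runs: 3x3 grid, 2 A + 1 B
# communities of 30, short burn-in, low fission threshold.
small_run_params <- function(...) {
  args <- list(grid_width = 3, grid_height = 3, n_incumbent = 2,
               n_migrant = 1, initial_community_size = 30,
               burn_in_steps = 30, n_fission = 60, max_steps = 400)
  do.call(sim_params, utils::modifyList(args, list(...)))
}

# Two communities (A and B) with nf females + nm males each, all of the
# given ages, plus full control over parameters.
two_community_world <- function(ages_a = c(25L, 30L), ages_b = c(25L, 30L),
                                sexes_a = NULL, sexes_b = NULL, ...) {
  params <- sim_params(grid_width = 4, grid_height = 4, n_incumbent = 1,
                       n_migrant = 1, initial_community_size = 2,
                       burn_in_steps = 0, n_fission = 1000, ...)
  w <- culthitch:::new_world_env(params)
  ca <- culthitch:::add_community(w, 1L, 1L, 1L, c(0L, 0L, 0L))
  cb <- culthitch:::add_community(w, 2L, 1L, 2L, c(1L, 1L, 1L))
  if (is.null(sexes_a)) sexes_a <- rep(c(TRUE, FALSE), length.out = length(ages_a))
  if (is.null(sexes_b)) sexes_b <- rep(c(TRUE, FALSE), length.out = length(ages_b))
  for (j in seq_along(ages_a))
    add_individual(w, female = sexes_a[j], age = ages_a[j], community = ca)
  for (j in seq_along(ages_b))
    add_individual(w, female = sexes_b[j], age = ages_b[j], community = cb)
  w
}

# A single community of n members with a given adaptive vector, k of whom
# carry the complementary adaptive vector (as frozen migrant variants).
discordance_world <- function(n, k, a = c(0L, 0L, 0L), ...) {
  params <- sim_params(grid_width = 12, grid_height = 12, n_incumbent = 1,
                       n_migrant = 0, initial_community_size = 2,
                       burn_in_steps = 0, n_fission = 10 * n, ...)
  w <- culthitch:::new_world_env(params)
  cid <- culthitch:::add_community(w, 1L, 1L, 1L, a)
  for (j in seq_len(n)) {
    carried <- if (j <= k) 1L - a else a
    add_individual(w, female = j %% 2 == 0, age = 30L, community = cid,
                   carried = carried)
  }
  w
}
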
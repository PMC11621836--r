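test_that("death probabilities follow the piecewise mortality schedule", {
  expect_equal(death_probability(3), 0.15)
  expect_equal(death_probability(5), 0.15)
  expect_equal(death_probability(6), 0.01)
  expect_equal(death_probability(40), 0.01)
  expect_equal(death_probability(41), 0.02)
  expect_equal(death_probability(50), 0.02)
  expect_equal(death_probability(65), 0.02)
  expect_equal(death_probability(66), 0.05)
  expect_equal(death_probability(85), 0.05)
  expect_equal(death_probability(86), 1.0)
  expect_equal(death_probability(90), 1.0)
  expect_error(death_probability(-1), "non-negative")
})

test_that("aging increments everyone and the over-85 die with certainty", {
  w <- two_community_world(ages_a = c(85L, 30L), ages_b = c(85L, 30L))
  set.seed(1)
  step_age_and_mortality(w)
  expect_equal(w$i_age[1:4], c(86L, 31L, 86L, 31L))
  # the 85-year-olds aged to 86 and must be dead with certainty
  expect_false(w$i_alive[1])
  expect_false(w$i_alive[3])
})

test_that("a surviving spouse is widowed and never re-enters the pool", {
  w <- two_community_world(ages_a = c(85L, 30L), ages_b = c(30L, 40L))
  # marry the 85-year-old (id 1, community A) to id 3 (community B)
  w$i_spouse[1] <- 3L; w$i_spouse[3] <- 1L
  w$i_married[c(1L, 3L)] <- TRUE
  set.seed(1)
  step_age_and_mortality(w)
  expect_false(w$i_alive[1])
  expect_true(w$i_alive[3])
  expect_true(is.na(w$i_spouse[3]))
  expect_true(w$i_married[3])
  expect_false(3L %in% form_marriage_pool(w))
})

test_that("an empty world passes through mortality unchanged", {
  w <- two_community_world()
  w$i_alive[1:4] <- FALSE
  before <- world_state(w)
  step_age_and_mortality(w)
  expect_identical(world_state(w), before)
})

test_that("the marriage pool takes never-married adults at the threshold", {
  w <- two_community_world(ages_a = c(17L, 18L), ages_b = c(30L, 30L))
  pool <- form_marriage_pool(w)
  expect_setequal(pool, c(2L, 3L, 4L))

  # strict reading excludes the 18-year-old
  ws <- two_community_world(ages_a = c(17L, 18L), ages_b = c(30L, 30L),
                            marriage_age_strict = TRUE)
  expect_setequal(form_marriage_pool(ws), c(3L, 4L))
})

test_that("pairs require opposite sex and different communities", {
  # one female + one male, same community: no pair
  w <- two_community_world(ages_a = c(30L, 30L), ages_b = integer(0),
                           sexes_a = c(TRUE, FALSE))
  set.seed(1)
  expect_equal(nrow(match_pairs(w, form_marriage_pool(w))), 0)
  # across communities: exactly the one feasible pair
  w <- two_community_world(ages_a = 30L, ages_b = 30L,
                           sexes_a = TRUE, sexes_b = FALSE)
  set.seed(1)
  pr <- match_pairs(w, form_marriage_pool(w))
  expect_equal(pr, tibble::tibble(female = 1L, male = 2L))
})

test_that("matching picks uniformly among eligible males", {
  # two males in X, one female in Y: each male chosen about half the time
  w <- two_community_world(ages_a = c(30L, 35L), ages_b = 30L,
                           sexes_a = c(FALSE, FALSE), sexes_b = TRUE)
  pool <- form_marriage_pool(w)
  set.seed(99)
  n <- 4000
  picks <- vapply(seq_len(n), function(i) match_pairs(w, pool)$male, integer(1))
  frac <- mean(picks == 1L)
  expect_true(abs(frac - 0.5) < 3 * sqrt(0.25 / n))
})

test_that("residence follows p_location and movers freeze carried variants", {
  mk <- function(p_location) {
    w <- two_community_world(ages_a = 30L, ages_b = 30L,
                             sexes_a = TRUE, sexes_b = FALSE,
                             p_location = p_location)
    w
  }
  # patrilocality: female moves to male's community (B), carries A's vector
  set.seed(1)
  w <- mk(0)
  mover <- settle_pair(w, 1L, 2L)
  expect_equal(w$i_com[1], 2L)
  expect_equal(w$i_spouse[1], 2L)
  expect_equal(w$i_spouse[2], 1L)
  expect_true(all(w$i_married[1:2]))
  expect_equal(unname(w$m_carried[1, ]), c(0L, 0L, 0L))
  expect_equal(w$i_mig_at[1], w$t)
  expect_equal(w$resoc_queue, 1L)
  # matrilocality limit: male moves
  set.seed(1)
  w <- mk(1)
  settle_pair(w, 1L, 2L)
  expect_equal(w$i_com[2], 1L)
  expect_equal(unname(w$m_carried[2, ]), c(1L, 1L, 1L))
})

test_that("bilocal residence is a fair coin within binomial noise", {
  n <- 5000
  set.seed(7)
  female_side <- logical(n)
  for (i in seq_len(n)) {
    w <- two_community_world(ages_a = 30L, ages_b = 30L,
                             sexes_a = TRUE, sexes_b = FALSE,
                             p_location = 0.5)
    settle_pair(w, 1L, 2L)
    female_side[i] <- w$i_com[2] == 1L
  }
  expect_true(abs(mean(female_side) - 0.5) < 3 * sqrt(0.25 / n))
})

test_that("reproduction probability is b plus the community's bonuses", {
  trials <- 3000
  birth_freq <- function(ages, f, a) {
    w <- two_community_world(ages_a = ages, ages_b = integer(0),
                             sexes_a = c(TRUE, FALSE),
                             b = 0.3224, f1 = f, f2 = f, f3 = f)
    w$c_a[1, ] <- a
    w$i_spouse[1] <- 2L; w$i_spouse[2] <- 1L; w$i_married[1:2] <- TRUE
    n0 <- 0
    for (i in seq_len(trials)) {
      w$n_ind <- 2L  # discard newborns between trials
      n0 <- n0 + length(reproduce(w))
    }
    n0 / trials
  }
  set.seed(21)
  f0 <- birth_freq(c(30L, 30L), 0.015, c(0L, 0L, 0L))
  expect_true(abs(f0 - 0.3224) < 3 * sqrt(0.3224 * 0.6776 / trials))
  f3 <- birth_freq(c(30L, 30L), 0.015, c(1L, 1L, 1L))
  expect_true(abs(f3 - 0.3674) < 3 * sqrt(0.3674 * 0.6326 / trials))
  # one partner outside the fertile window: no attempt at all
  expect_equal(birth_freq(c(30L, 46L), 0.015, c(1L, 1L, 1L)), 0)
})

test_that("newborns inherit residence, family and the community a-vector", {
  w <- two_community_world(ages_a = c(30L, 30L), ages_b = integer(0),
                           sexes_a = c(TRUE, FALSE), b = 1)
  w$i_spouse[1] <- 2L; w$i_spouse[2] <- 1L; w$i_married[1:2] <- TRUE
  w$i_family[1:2] <- 77L
  w$c_a[1, ] <- c(1L, 0L, 0L)
  set.seed(3)
  ids <- reproduce(w)
  expect_length(ids, 1)
  expect_equal(w$i_com[ids], 1L)
  expect_equal(w$i_natal[ids], 1L)
  expect_equal(w$i_family[ids], 77L)
  expect_equal(w$i_age[ids], 0L)
  expect_equal(unname(w$m_carried[ids, ]), c(1L, 0L, 0L))
})

test_that("fission balances families, never splitting one", {
  set.seed(31)
  w <- make_fixture("fission_ready")
  # bring it to exactly the threshold with one more family
  fid <- w$next_family; w$next_family <- fid + 1L
  m <- add_individual(w, TRUE, 40L, 1L, family = fid)
  add_individual(w, FALSE, 42L, 1L, family = fid, spouse = m)
  add_individual(w, TRUE, 10L, 1L, family = fid)
  add_individual(w, FALSE, 12L, 1L, family = fid)
  # 26 families of 4 = 104 members >= 100
  fam_before <- split(seq_len(w$n_ind), w$i_family[seq_len(w$n_ind)])
  fission_check(w)
  com <- communities(w)
  expect_equal(nrow(com), 2)
  expect_true(abs(diff(com$size)) <= 4)
  expect_equal(sum(com$size), 104)
  # families intact: all members of each family share a community
  for (fam in fam_before)
    expect_length(unique(w$i_com[fam]), 1)
  # daughters inherit the adaptive vector and lineage
  expect_equal(com$lineage, c("A", "A"))
  expect_true(all(as.matrix(com[, c("a1", "a2", "a3")]) == 0))
  # the larger daughter keeps the original cell
  orig <- com[com$x == 5 & com$y == 5, ]
  expect_gte(orig$size, max(com$size[com$id != orig$id]))
})

test_that("below-threshold communities never fission", {
  set.seed(1)
  w <- make_fixture("fission_ready")  # 100 members at threshold 100... minus 0
  w2 <- world_clone(w)
  w2$params$n_fission <- 101L
  fission_check(w2)
  expect_equal(nrow(communities(w2)), 1)
})

test_that("fission with a full grid stops the world and leaves it intact", {
  set.seed(8)
  w <- make_fixture("fission_ready")
  w$params$grid_width <- 1L
  w$params$grid_height <- 1L
  w$occupied <- TRUE  # single cell, already occupied by the community
  fission_check(w)
  expect_equal(w$stopped, "grid_full")
  expect_equal(nrow(communities(w)), 1)
  expect_equal(sum(community_sizes(w)), 100)
})

test_that("one step conserves individuals: before + births - deaths", {
  set.seed(13)
  w <- init_world(small_run_params())
  for (i in 1:10) {
    before <- length(living(w))
    b0 <- w$counters["births"]; d0 <- w$counters["deaths"]
    step_world(w)
    expect_equal(length(living(w)),
                 before + unname(w$counters["births"] - b0) -
                   unname(w$counters["deaths"] - d0))
  }
})
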
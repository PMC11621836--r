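test_that("a world with no eligible singles and no adoption only ages", {
  set.seed(20)
  w <- two_community_world(ages_a = c(10L, 12L), ages_b = c(9L, 14L),
                           beta = -10)
  a_before <- w$c_a[1:2, ]
  step_world(w)
  expect_equal(unname(w$counters["marriages"]), 0)
  expect_equal(unname(w$counters["migrations"]), 0)
  expect_equal(unname(w$counters["adoptions"]), 0)
  expect_equal(unname(w$counters["births"]), 0)
  expect_equal(w$c_a[1:2, ], a_before)
  expect_equal(w$t, 1L)
  expect_true(all(w$i_age[1:4] == c(11L, 13L, 10L, 15L)))
})

test_that("one cross-community pair under patrilocality moves one female", {
  set.seed(30)
  ok <- FALSE
  for (attempt in 1:5) {
    w <- two_community_world(ages_a = 25L, ages_b = 25L,
                             sexes_a = TRUE, sexes_b = FALSE,
                             p_location = 0, beta = -10)
    step_world(w)
    if (w$i_alive[1] && w$i_alive[2]) { ok <- TRUE; break }
  }
  expect_true(ok)
  expect_equal(unname(w$counters["marriages"]), 1)
  expect_equal(unname(w$counters["migrations"]), 1)
  expect_equal(w$i_com[1], 2L)   # the female joined the male's community
  expect_equal(w$i_mig_at[1], 0L)
})

test_that("a community crossing the fission threshold splits within the step", {
  set.seed(3)
  w <- make_fixture("fission_ready")
  w$params$burn_in_steps <- 0L
  # add one family to cross the threshold after births are impossible
  fid <- w$next_family; w$next_family <- fid + 1L
  m <- add_individual(w, TRUE, 30L, 1L, family = fid)
  add_individual(w, FALSE, 30L, 1L, family = fid, spouse = m)
  add_individual(w, TRUE, 5L, 1L, family = fid)
  add_individual(w, FALSE, 6L, 1L, family = fid)
  step_world(w)
  expect_equal(nrow(communities(w)), 2)
})

test_that("burn-in keeps the initial community count and resets culture", {
  set.seed(44)
  p <- small_run_params(burn_in_steps = 120)
  w <- init_world(p)
  run_burn_in(w)
  com <- communities(w)
  expect_equal(nrow(com), 3)
  expect_equal(w$t, 0L)
  expect_true(all(w$counters == 0))
  ind <- individuals(w)
  lin <- com$lineage[match(ind$community, com$id)]
  for (tr in paste0("c", 1:5))
    expect_true(all(ind[[tr]] == ifelse(lin == "A", 0, 1)))
  expect_true(all(ind$a1 == ifelse(lin == "A", 0, 1)))
})

test_that("a zero-length burn-in only re-asserts the lineage variants", {
  set.seed(4)
  w <- init_world(small_run_params(burn_in_steps = 0))
  before <- world_state(w)
  run_burn_in(w)
  after <- world_state(w)
  expect_identical(after, before)  # fresh worlds already carry lineage values
})

test_that("the age structure is stationary after burn-in", {
  set.seed(51)
  p <- sim_params(grid_width = 5, grid_height = 5, n_incumbent = 3,
                  n_migrant = 1, initial_community_size = 70,
                  burn_in_steps = 500, trait_configs = traits_vertical_only(5))
  w <- init_world(p)
  run_burn_in(w)
  # run two disjoint 100-step windows of the same restricted dynamics and
  # compare mean ages
  mean_age_window <- function() {
    m <- numeric(100)
    for (i in 1:100) {
      step_age_and_mortality(w)
      pool <- form_marriage_pool(w)
      if (length(pool) > 1) {
        pr <- match_pairs(w, pool)
        for (j in seq_len(nrow(pr))) settle_pair(w, pr$female[j], pr$male[j])
      }
      reproduce(w, transmit = FALSE)
      fission_check(w, burn_in = TRUE)
      liv <- living(w)
      m[i] <- mean(w$i_age[liv])
    }
    mean(m)
  }
  m1 <- mean_age_window()
  m2 <- mean_age_window()
  expect_lt(abs(m1 - m2), 2)
})

test_that("a tiny grid saturates at the first fission attempt", {
  set.seed(61)
  p <- sim_params(grid_width = 2, grid_height = 1, n_incumbent = 1,
                  n_migrant = 1, initial_community_size = 30,
                  burn_in_steps = 10, n_fission = 40, max_steps = 300)
  r <- run_model(p, seed = 5)
  expect_equal(r$stop_reason, "grid_full")
  expect_equal(nrow(communities(r$world)), 2)
})

test_that("the safety cap flags a non-converged run", {
  set.seed(1)
  p <- small_run_params(max_steps = 5)
  r <- run_model(p, seed = 3)
  expect_equal(r$stop_reason, "max_steps")
  expect_false(r$converged)
  expect_equal(nrow(r$series), 5)
})

test_that("identical parameters and seed replay bitwise-identically", {
  p <- small_run_params(p_location = 0.5, beta = 0)
  r1 <- run_model(p, seed = 17)
  r2 <- run_model(p, seed = 17)
  expect_identical(r1$series, r2$series)
  expect_identical(world_state(r1$world), world_state(r2$world))
  expect_identical(r1$counters, r2$counters)
  r3 <- run_model(p, seed = 18)
  expect_false(identical(r1$series, r3$series))
})

test_that("without adoption no community ever changes its adaptive vector", {
  set.seed(70)
  p <- small_run_params(beta = -10, f1 = 0.015, f2 = 0.015, f3 = 0.015,
                        p_location = 0.5)
  w <- init_world(p)
  run_burn_in(w)
  a0 <- w$c_a[seq_len(w$n_com), , drop = FALSE]
  lin0 <- w$c_lineage[seq_len(w$n_com)]
  repeat {
    step_world(w)
    m <- w$n_com
    # original communities unchanged; daughters carry their lineage value
    expect_identical(w$c_a[seq_len(nrow(a0)), , drop = FALSE], a0)
    expect_true(all(w$c_a[seq_len(m), 1] == ifelse(
      w$c_lineage[seq_len(m)] == 1L, 0L, 1L)))
    if (!is.na(w$stopped) || w$t > 150) break
  }
  tc <- lineage_type_counts(w)
  expect_equal(sum(tc$n[tc$type == "C"]), 0)
})

test_that("tidy and glance summarize a run", {
  set.seed(2)
  r <- run_model(small_run_params(), seed = 9)
  td <- tidy(r)
  expect_setequal(unique(td$lineage), c("A", "B"))
  expect_equal(nrow(td), 2 * nrow(r$series))
  gl <- glance(r)
  expect_equal(gl$seed, 9L)
  expect_equal(gl$population, length(culthitch:::living(r$world)))
  expect_true(gl$pct_lineage_A >= 0 && gl$pct_lineage_A <= 100)
})

test_that("run archives round-trip and replays write identical files", {
  p <- small_run_params()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_model(p, seed = 21)
  r2 <- run_model(p, seed = 21)
  write_run_archive(r1, d1)
  write_run_archive(r2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  expect_error(write_run_archive(r1, d1), "force")
  arc <- read_run_archive(d1)
  expect_equal(arc$manifest$seed, 21L)
  expect_equal(arc$params, p)
  expect_equal(nrow(arc$series), nrow(r1$series))
})
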
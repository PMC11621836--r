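# World state lives in an environment: a forward simulation mutates tens of
# thousands of individual records per step, so the hot state is kept as flat
# parallel vectors (individuals) and matrices (trait variants) updated in
# place. Tidy views are provided by individuals()/communities().

# Founding populations are young (uniform ages on [0, INIT_AGE_MAX]):
# marriages are random in age and remarriage is impossible, so seeding
# communities with elderly members would lock fertile founders into
# infertile pairs for life and push 70-person communities to extinction
# before the burn-in can equilibrate. A young colonizing cohort instead
# grows into the stationary age pyramid during the burn-in (surplus is
# culled by the burn-in fission rule).
INIT_AGE_MAX <- 30L

new_world_env <- function(params) {
  w <- new.env(parent = emptyenv())
  w$params <- params
  cap <- 4L * max(1L, (params$n_incumbent + params$n_migrant) *
                    params$initial_community_size)
  w$n_ind <- 0L
  w$i_female <- logical(cap)
  w$i_age <- integer(cap)
  w$i_alive <- logical(cap)
  w$i_com <- rep(NA_integer_, cap)
  w$i_natal <- rep(NA_integer_, cap)
  w$i_spouse <- rep(NA_integer_, cap)
  w$i_married <- logical(cap)
  w$i_family <- rep(NA_integer_, cap)
  w$i_mig_at <- rep(NA_integer_, cap)
  z <- params$z
  w$m_neutral <- matrix(0L, cap, z)
  w$m_carried <- matrix(0L, cap, 3L)
  w$m_src <- matrix(0L, cap, z)      # id copied from (0 = founding assignment)
  w$m_fail <- matrix(FALSE, cap, z)  # postmarital learning failed: no candidate
  ccap <- max(16L, params$grid_width * params$grid_height)
  w$n_com <- 0L
  w$c_x <- integer(ccap)
  w$c_y <- integer(ccap)
  w$c_active <- logical(ccap)
  w$c_lineage <- integer(ccap)  # 1 = A-descended, 2 = B-descended
  w$c_a <- matrix(0L, ccap, 3L)
  w$occupied <- logical(params$grid_width * params$grid_height)
  w$t <- 0L
  w$stopped <- NA_character_
  w$next_family <- 1L
  w$resoc_queue <- integer(0)
  w$counters <- c(births = 0, deaths = 0, marriages = 0, migrations = 0,
                  resoc_attempted = 0, resoc_succeeded = 0, resoc_failed = 0,
                  adoptions = 0, fissions = 0, burnin_removed = 0)
  w$series <- list()
  class(w) <- "culthitch_world"
  w
}

ensure_ind_capacity <- function(world, extra) {
  cap <- length(world$i_age)
  need <- world$n_ind + extra
  if (need <= cap) return(invisible(world))
  newcap <- max(2L * cap, need)
  grow <- function(x, fill) c(x, rep(fill, newcap - cap))
  world$i_female <- grow(world$i_female, FALSE)
  world$i_age <- grow(world$i_age, 0L)
  world$i_alive <- grow(world$i_alive, FALSE)
  world$i_com <- grow(world$i_com, NA_integer_)
  world$i_natal <- grow(world$i_natal, NA_integer_)
  world$i_spouse <- grow(world$i_spouse, NA_integer_)
  world$i_married <- grow(world$i_married, FALSE)
  world$i_family <- grow(world$i_family, NA_integer_)
  world$i_mig_at <- grow(world$i_mig_at, NA_integer_)
  growm <- function(m, fill) rbind(m, matrix(fill, newcap - cap, ncol(m)))
  world$m_neutral <- growm(world$m_neutral, 0L)
  world$m_carried <- growm(world$m_carried, 0L)
  world$m_src <- growm(world$m_src, 0L)
  world$m_fail <- growm(world$m_fail, FALSE)
  invisible(world)
}

add_community <- function(world, x, y, lineage, a) {
  if (world$n_com >= length(world$c_x)) {
    grow <- length(world$c_x)
    world$c_x <- c(world$c_x, integer(grow))
    world$c_y <- c(world$c_y, integer(grow))
    world$c_active <- c(world$c_active, logical(grow))
    world$c_lineage <- c(world$c_lineage, integer(grow))
    world$c_a <- rbind(world$c_a, matrix(0L, grow, 3L))
  }
  id <- world$n_com + 1L
  world$n_com <- id
  world$c_x[id] <- x
  world$c_y[id] <- y
  world$c_active[id] <- TRUE
  world$c_lineage[id] <- lineage
  world$c_a[id, ] <- as.integer(a)
  world$occupied[cell_index(world, x, y)] <- TRUE
  id
}

cell_index <- function(world, x, y) (y - 1L) * world$params$grid_width + x

cell_xy <- function(world, idx) {
  x <- ((idx - 1L) %% world$params$grid_width) + 1L
  y <- ((idx - 1L) %/% world$params$grid_width) + 1L
  cbind(x = x, y = y)
}

empty_cells <- function(world) which(!world$occupied)

living <- function(world) which(world$i_alive[seq_len(world$n_ind)])

#' Sizes of all communities
#'
#' @param world A `culthitch_world`.
#' @return Integer vector of living-member counts, indexed by community id
#'   (removed communities count 0).
#' @export
community_sizes <- function(world) {
  liv <- living(world)
  tabulate(world$i_com[liv], nbins = world$n_com)
}

#' Initialize a simulation world
#'
#' Creates the grid, places the incumbent (lineage A, adaptive variants
#' `(0,0,0)`, neutral variants all 0) and migrant (lineage B, all 1)
#' communities on distinct uniformly random empty cells, and populates each
#' with `initial_community_size` individuals of random sex (50:50) and
#' uniform random age on `[0, 30]` (a young founding cohort; the burn-in
#' grows it into the stationary age pyramid). All individuals start
#' unmarried, each in a singleton family.
#'
#' @param params A valid `culthitch_params` object.
#' @return A `culthitch_world` environment.
#' @export
#' @examples
#' set.seed(1)
#' w <- init_world(sim_params(n_incumbent = 2, n_migrant = 1,
#'                            initial_community_size = 10))
#' communities(w)
init_world <- function(params) {
  viol <- validate_params(params)
  if (length(viol))
    stop("configuration error:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  world <- new_world_env(params)
  ncom <- params$n_incumbent + params$n_migrant
  cells <- sample(length(world$occupied), ncom)
  xy <- cell_xy(world, cells)
  for (j in seq_len(ncom)) {
    lineage <- if (j <= params$n_incumbent) 1L else 2L
    a <- if (lineage == 1L) c(0L, 0L, 0L) else c(1L, 1L, 1L)
    cid <- add_community(world, xy[j, "x"], xy[j, "y"], lineage, a)
    seed_community_members(world, cid, params$initial_community_size)
  }
  world
}

seed_community_members <- function(world, cid, n) {
  ensure_ind_capacity(world, n)
  ids <- world$n_ind + seq_len(n)
  world$n_ind <- world$n_ind + n
  world$i_female[ids] <- stats::runif(n) < 0.5
  world$i_age[ids] <- sample.int(INIT_AGE_MAX + 1L, n, replace = TRUE) - 1L
  world$i_alive[ids] <- TRUE
  world$i_com[ids] <- cid
  world$i_natal[ids] <- cid
  world$i_family[ids] <- world$next_family - 1L + seq_len(n)
  world$next_family <- world$next_family + n
  variant <- if (world$c_lineage[cid] == 1L) 0L else 1L
  world$m_neutral[ids, ] <- variant
  world$m_carried[ids, ] <- rep(world$c_a[cid, ], each = n)
  invisible(ids)
}

# Reset every individual's neutral and carried variants to the founding
# values of their community's lineage (all-0 for A, all-1 for B). Used at
# initialization-time bookkeeping after the burn-in.
reset_variants_to_lineage <- function(world) {
  liv <- living(world)
  lin <- world$c_lineage[world$i_com[liv]]
  world$m_neutral[liv, ] <- rep(ifelse(lin == 1L, 0L, 1L),
                                times = world$params$z)
  world$m_carried[liv, ] <- world$c_a[world$i_com[liv], , drop = FALSE]
  world$m_src[liv, ] <- 0L
  world$m_fail[liv, ] <- FALSE
  invisible(world)
}

#' Individuals as a tibble
#'
#' Tidy view of the individual registry (living and, optionally, dead).
#'
#' @param world A `culthitch_world`.
#' @param alive_only Keep only living individuals (default `TRUE`).
#' @return A tibble with one row per individual: id, sex, age, community,
#'   natal community, spouse, marriage state, family, migration step, the
#'   neutral-variant columns `c1..cz` and carried adaptive columns `a1..a3`.
#' @export
individuals <- function(world, alive_only = TRUE) {
  n <- world$n_ind
  idx <- if (alive_only) living(world) else seq_len(n)
  out <- tibble::tibble(
    id = idx,
    sex = ifelse(world$i_female[idx], "female", "male"),
    age = world$i_age[idx],
    alive = world$i_alive[idx],
    community = world$i_com[idx],
    natal_community = world$i_natal[idx],
    spouse = world$i_spouse[idx],
    ever_married = world$i_married[idx],
    family = world$i_family[idx],
    migrated_at = world$i_mig_at[idx]
  )
  nz <- world$params$z
  neut <- world$m_neutral[idx, , drop = FALSE]
  colnames(neut) <- paste0("c", seq_len(nz))
  car <- world$m_carried[idx, , drop = FALSE]
  colnames(car) <- paste0("a", 1:3)
  dplyr::bind_cols(out, tibble::as_tibble(neut), tibble::as_tibble(car))
}

#' Communities as a tibble
#'
#' @param world A `culthitch_world`.
#' @param active_only Keep only extant communities (default `TRUE`).
#' @return A tibble with one row per community: id, grid location, lineage
#'   (`"A"`/`"B"` by descent from the initial incumbent or migrant
#'   communities), adaptive-variant columns `a1..a3`, living size and
#'   community type (`"A"`, `"B"` or `"C"`).
#' @export
communities <- function(world, active_only = TRUE) {
  idx <- seq_len(world$n_com)
  if (active_only) idx <- idx[world$c_active[idx]]
  a <- world$c_a[idx, , drop = FALSE]
  colnames(a) <- paste0("a", 1:3)
  sizes <- community_sizes(world)
  tibble::tibble(
    id = idx,
    x = world$c_x[idx],
    y = world$c_y[idx],
    lineage = c("A", "B")[world$c_lineage[idx]],
    size = sizes[idx]
  ) |>
    dplyr::bind_cols(tibble::as_tibble(a)) |>
    dplyr::mutate(type = classify_community_matrix(a))
}

#' Snapshot of the full world state
#'
#' Returns a plain list of the substantive state (individual registry,
#' communities, clock, counters), trimmed to the used capacity, suitable for
#' `identical()` comparisons in determinism checks.
#'
#' @param world A `culthitch_world`.
#' @return A named list.
#' @export
world_state <- function(world) {
  n <- world$n_ind
  m <- world$n_com
  list(
    t = world$t, stopped = world$stopped, n_ind = n, n_com = m,
    female = world$i_female[seq_len(n)], age = world$i_age[seq_len(n)],
    alive = world$i_alive[seq_len(n)], com = world$i_com[seq_len(n)],
    natal = world$i_natal[seq_len(n)], spouse = world$i_spouse[seq_len(n)],
    married = world$i_married[seq_len(n)], family = world$i_family[seq_len(n)],
    mig_at = world$i_mig_at[seq_len(n)],
    neutral = world$m_neutral[seq_len(n), , drop = FALSE],
    carried = world$m_carried[seq_len(n), , drop = FALSE],
    c_x = world$c_x[seq_len(m)], c_y = world$c_y[seq_len(m)],
    c_active = world$c_active[seq_len(m)],
    c_lineage = world$c_lineage[seq_len(m)],
    c_a = world$c_a[seq_len(m), , drop = FALSE],
    counters = world$counters
  )
}

#' Deep-copy a world
#'
#' Worlds are environments and mutate in place; `world_clone()` gives an
#' independent copy (useful for before/after comparisons).
#'
#' @param world A `culthitch_world`.
#' @return A new, independent `culthitch_world`.
#' @export
world_clone <- function(world) {
  w2 <- new.env(parent = emptyenv())
  for (nm in ls(world, all.names = TRUE))
    assign(nm, get(nm, envir = world), envir = w2)
  class(w2) <- "culthitch_world"
  w2
}

#' @export
print.culthitch_world <- function(x, ...) {
  sizes <- community_sizes(x)
  cat(sprintf(
    "<culthitch_world> t = %d; %d living individuals in %d communities%s\n",
    x$t, length(living(x)), sum(x$c_active[seq_len(x$n_com)]),
    if (!is.na(x$stopped)) paste0(" [stopped: ", x$stopped, "]") else ""))
  invisible(x)
}

# Internal consistency check used by property tests: every living individual
# belongs to exactly one active community, spouse links are symmetric.
check_world_invariants <- function(world) {
  liv <- living(world)
  com <- world$i_com[liv]
  stopifnot(!anyNA(com), all(world$c_active[com]))
  stopifnot(sum(community_sizes(world)) == length(liv))
  sp <- world$i_spouse[liv]
  has <- !is.na(sp)
  stopifnot(all(world$i_spouse[sp[has]] == liv[has]))
  stopifnot(all(world$i_married[liv][has]))
  invisible(TRUE)
}
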
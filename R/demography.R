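#' Age-specific death probability
#'
#' Piecewise-constant lookup in a mortality schedule; bands are inclusive of
#' both printed endpoints (e.g. the default schedule gives 0.15 for ages 0
#' through 5 and 0.02 for 41 through 65).
#'
#' @param age Integer age(s) in years, `>= 0`.
#' @param schedule Mortality schedule, see [default_death_schedule()].
#' @return Numeric vector of annual death probabilities.
#' @export
#' @examples
#' death_probability(c(3, 50, 90))
death_probability <- function(age, schedule = default_death_schedule()) {
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  schedule$p[findInterval(age, schedule$age_min)]
}

#' Age everyone one year and apply mortality
#'
#' Every living individual's age is incremented, then each dies
#' independently with the death probability at the new age. A decedent's
#' surviving spouse is widowed: the spouse link is cleared but
#' `ever_married` remains set, so widows and widowers never re-enter the
#' marriage pool. Dead individuals leave their community's member set but
#' stay in the registry for statistics.
#'
#' @param world A `culthitch_world` (mutated in place).
#' @return The world, invisibly.
#' @export
step_age_and_mortality <- function(world) {
  liv <- living(world)
  if (!length(liv)) return(invisible(world))
  age <- world$i_age[liv] + 1L
  world$i_age[liv] <- age
  p <- death_probability(age, world$params$death_schedule)
  dies <- stats::runif(length(liv)) < p
  dead <- liv[dies]
  if (length(dead)) {
    world$i_alive[dead] <- FALSE
    world$i_com[dead] <- NA_integer_
    sp <- world$i_spouse[dead]
    sp <- sp[!is.na(sp)]
    widowed <- sp[world$i_alive[sp]]
    world$i_spouse[widowed] <- NA_integer_
    world$i_spouse[dead] <- NA_integer_
    world$counters["deaths"] <- world$counters["deaths"] + length(dead)
  }
  invisible(world)
}

#' Marriage pool
#'
#' All living, never-married individuals at or above the marriage age
#' (strictly above when `marriage_age_strict` is set). Widowed individuals
#' are excluded for life.
#'
#' @param world A `culthitch_world`.
#' @return Integer vector of individual ids.
#' @export
form_marriage_pool <- function(world) {
  n <- world$n_ind
  idx <- seq_len(n)
  amin <- world$params$marriage_age_min
  old_enough <- if (world$params$marriage_age_strict)
    world$i_age[idx] > amin else world$i_age[idx] >= amin
  idx[world$i_alive[idx] & !world$i_married[idx] & old_enough]
}

#' Random exogamous pair matching
#'
#' Forms marriage pairs from the pool: females are shuffled uniformly and
#' each, in order, picks a uniformly random not-yet-matched male from a
#' different current community (or, during the demographic burn-in, from
#' the same community). Individuals left unmatched simply wait for the next
#' step.
#'
#' @param world A `culthitch_world`.
#' @param pool Integer ids from [form_marriage_pool()].
#' @param within_community If `TRUE`, require partners from the *same*
#'   community instead (burn-in pairing mode).
#' @return A tibble with columns `female`, `male` (ids), one row per pair.
#' @export
match_pairs <- function(world, pool, within_community = FALSE) {
  fem <- pool[world$i_female[pool]]
  mal <- pool[!world$i_female[pool]]
  empty <- tibble::tibble(female = integer(0), male = integer(0))
  if (!length(fem) || !length(mal)) return(empty)
  fem <- fem[sample.int(length(fem))]
  mcom <- world$i_com[mal]
  avail <- rep(TRUE, length(mal))
  rf <- integer(length(fem)); rm_ <- integer(length(fem)); k <- 0L
  for (fi in fem) {
    fcom <- world$i_com[fi]
    ok <- if (within_community) avail & mcom == fcom else avail & mcom != fcom
    w <- which(ok)
    if (length(w)) {
      j <- if (length(w) == 1L) w else w[sample.int(length(w), 1L)]
      avail[j] <- FALSE
      k <- k + 1L
      rf[k] <- fi; rm_[k] <- mal[j]
    }
  }
  if (!k) return(empty)
  tibble::tibble(female = rf[seq_len(k)], male = rm_[seq_len(k)])
}

#' Marry a pair and settle its residence
#'
#' Sets the symmetric spouse links and `ever_married` flags, merges the
#' couple into a fresh family, and draws the postmarital residence: with
#' probability `p_location` the couple lives in the female's community (the
#' male relocates), otherwise in the male's (the female relocates). The
#' mover leaves the old member set, joins the new community, records the
#' migration step and freezes their carried adaptive vector to the origin
#' community's current variants at departure, and is enqueued for
#' postmarital resocialization this step. When both partners already share a
#' community (burn-in pairing) nobody moves.
#'
#' @param world A `culthitch_world` (mutated in place).
#' @param female_id,male_id Ids of the partners.
#' @return The id of the partner who relocated, or `NA` if none did.
#' @export
settle_pair <- function(world, female_id, male_id) {
  movers <- settle_pairs(world, tibble::tibble(female = female_id,
                                               male = male_id))
  invisible(if (length(movers)) movers else NA_integer_)
}

# Batched settlement: one pass over all of a step's pairs, writing each
# state vector once (per-pair writes into an environment-bound vector
# would duplicate the whole vector at every call).
settle_pairs <- function(world, pairs) {
  np <- nrow(pairs)
  if (!np) return(invisible(integer(0)))
  f <- pairs$female
  m <- pairs$male
  sp <- world$i_spouse; sp[f] <- m; sp[m] <- f; world$i_spouse <- sp
  mar <- world$i_married; mar[f] <- TRUE; mar[m] <- TRUE
  world$i_married <- mar
  fams <- world$next_family + seq_len(np) - 1L
  world$next_family <- world$next_family + np
  ifam <- world$i_family; ifam[f] <- fams; ifam[m] <- fams
  world$i_family <- ifam
  world$counters["marriages"] <- world$counters["marriages"] + np
  fcom <- world$i_com[f]
  mcom <- world$i_com[m]
  cross <- which(fcom != mcom)
  if (!length(cross)) return(invisible(integer(0)))
  to_female <- stats::runif(length(cross)) < world$params$p_location
  mover <- ifelse(to_female, m[cross], f[cross])
  dest <- ifelse(to_female, fcom[cross], mcom[cross])
  origin <- ifelse(to_female, mcom[cross], fcom[cross])
  icom <- world$i_com; icom[mover] <- dest; world$i_com <- icom
  imig <- world$i_mig_at; imig[mover] <- world$t; world$i_mig_at <- imig
  mc <- world$m_carried
  mc[mover, ] <- world$c_a[origin, , drop = FALSE]
  world$m_carried <- mc
  world$resoc_queue <- c(world$resoc_queue, mover)
  world$counters["migrations"] <- world$counters["migrations"] + length(mover)
  invisible(mover)
}

#' Reproduction step
#'
#' Every married pair with both partners alive and both ages inside the
#' fertile window produces one offspring with probability
#' `b + f1*[a1 = 1] + f2*[a2 = 1] + f3*[a3 = 1]`, where `a` is the adaptive
#' vector of the couple's community of residence. Newborns get random sex,
#' age 0, the couple's community and family, the community's current
#' adaptive vector as their carried variants, and neutral variants by
#' vertical transmission (each trait independently from the mother with
#' probability `p_bias`, else the father).
#'
#' @param world A `culthitch_world` (mutated in place).
#' @param transmit If `FALSE` (burn-in), newborn neutral variants are left
#'   as placeholders instead of being copied from the parents.
#' @return Integer ids of the newborns, invisibly.
#' @export
reproduce <- function(world, transmit = TRUE) {
  n <- world$n_ind
  idx <- seq_len(n)
  p <- world$params
  amin <- p$reproduction_age_min; amax <- p$reproduction_age_max
  cand <- idx[world$i_alive[idx] & !is.na(world$i_spouse[idx]) &
                world$i_female[idx] &
                world$i_age[idx] >= amin & world$i_age[idx] <= amax]
  if (!length(cand)) return(invisible(integer(0)))
  sp <- world$i_spouse[cand]
  ok <- world$i_alive[sp] & world$i_age[sp] >= amin & world$i_age[sp] <= amax
  mothers <- cand[ok]
  if (!length(mothers)) return(invisible(integer(0)))
  fathers <- world$i_spouse[mothers]
  com <- world$i_com[mothers]
  a <- world$c_a[com, , drop = FALSE]
  prob <- p$b + a[, 1] * p$f1 + a[, 2] * p$f2 + a[, 3] * p$f3
  births <- stats::runif(length(mothers)) < prob
  mothers <- mothers[births]
  if (!length(mothers)) return(invisible(integer(0)))
  fathers <- fathers[births]
  com <- com[births]
  nb <- length(mothers)
  ensure_ind_capacity(world, nb)
  ids <- world$n_ind + seq_len(nb)
  world$n_ind <- world$n_ind + nb
  world$i_female[ids] <- stats::runif(nb) < 0.5
  world$i_age[ids] <- 0L
  world$i_alive[ids] <- TRUE
  world$i_com[ids] <- com
  world$i_natal[ids] <- com
  world$i_family[ids] <- world$i_family[mothers]
  world$m_carried[ids, ] <- world$c_a[com, , drop = FALSE]
  z <- p$z
  if (transmit) {
    from_mother <- matrix(stats::runif(nb * z) < p$p_bias, nb, z)
    mv <- world$m_neutral[mothers, , drop = FALSE]
    fv <- world$m_neutral[fathers, , drop = FALSE]
    world$m_neutral[ids, ] <- ifelse(from_mother, mv, fv)
    world$m_src[ids, ] <- ifelse(from_mother,
                                 matrix(mothers, nb, z),
                                 matrix(fathers, nb, z))
  } else {
    world$m_neutral[ids, ] <- 0L
    world$m_src[ids, ] <- 0L
  }
  world$counters["births"] <- world$counters["births"] + nb
  invisible(ids)
}

#' Community fission
#'
#' Each community whose living size has reached `n_fission` splits: its
#' families are shuffled and assigned greedily, each to the currently
#' smaller daughter, so the daughters end up of similar size without ever
#' splitting a family. The larger daughter keeps the parent's grid cell; the
#' other moves to a uniformly random empty cell (inheriting the parent's
#' adaptive vector and lineage). If no empty cell exists the world stops
#' with reason `"grid_full"` and the community stays intact. Communities
#' crossing the threshold in the same step are processed in random order.
#'
#' @param world A `culthitch_world` (mutated in place).
#' @param burn_in During burn-in, the daughter that would take a new cell is
#'   instead removed from the system, keeping the community count constant.
#' @return The world, invisibly.
#' @export
fission_check <- function(world, burn_in = FALSE) {
  sizes <- community_sizes(world)
  big <- which(world$c_active[seq_len(world$n_com)] &
                 sizes >= world$params$n_fission)
  if (!length(big)) return(invisible(world))
  if (length(big) > 1L) big <- big[sample.int(length(big))]
  for (cid in big) {
    if (!is.na(world$stopped)) break
    fission_one(world, cid, burn_in = burn_in)
  }
  invisible(world)
}

fission_one <- function(world, cid, burn_in = FALSE) {
  liv <- living(world)
  members <- liv[world$i_com[liv] == cid]
  fams <- world$i_family[members]
  uf <- unique(fams)
  if (length(uf) < 2L) return(invisible(world))  # cannot split a single family
  uf <- uf[sample.int(length(uf))]
  fam_sizes <- tabulate(match(fams, uf), nbins = length(uf))
  keep_size <- 0L; move_size <- 0L
  to_move <- logical(length(uf))
  for (j in seq_along(uf)) {
    if (move_size < keep_size) {
      to_move[j] <- TRUE; move_size <- move_size + fam_sizes[j]
    } else {
      keep_size <- keep_size + fam_sizes[j]
    }
  }
  # larger daughter keeps the original cell
  if (move_size > keep_size) to_move <- !to_move
  movers <- members[fams %in% uf[to_move]]
  if (burn_in) {
    world$i_alive[movers] <- FALSE
    world$i_com[movers] <- NA_integer_
    sp <- world$i_spouse[movers]
    widowed <- setdiff(sp[!is.na(sp)], movers)
    world$i_spouse[widowed] <- NA_integer_
    world$i_spouse[movers] <- NA_integer_
    world$counters["burnin_removed"] <-
      world$counters["burnin_removed"] + length(movers)
    world$counters["fissions"] <- world$counters["fissions"] + 1
    return(invisible(world))
  }
  free <- empty_cells(world)
  if (!length(free)) {
    world$stopped <- "grid_full"
    return(invisible(world))
  }
  cell <- if (length(free) == 1L) free else free[sample.int(length(free), 1L)]
  xy <- cell_xy(world, cell)
  new_cid <- add_community(world, xy[1, "x"], xy[1, "y"],
                           world$c_lineage[cid], world$c_a[cid, ])
  world$i_com[movers] <- new_cid
  world$counters["fissions"] <- world$counters["fissions"] + 1
  invisible(world)
}
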
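#' Vertical transmission of neutral variants
#'
#' At birth, the child copies each trait independently from the mother with
#' probability `p_bias`, otherwise from the father. `p_bias = 1` and
#' `p_bias = 0` give strictly matrilineal and patrilineal inheritance.
#'
#' @param mother_variants,father_variants Integer 0/1 vectors of equal
#'   length `z`.
#' @param p_bias Probability of copying the mother, per trait.
#' @return Integer 0/1 vector of the child's variants.
#' @export
#' @examples
#' vertical_transmit(c(1, 1, 1), c(0, 0, 0), p_bias = 1)
vertical_transmit <- function(mother_variants, father_variants, p_bias) {
  stopifnot(length(mother_variants) == length(father_variants))
  from_mother <- stats::runif(length(mother_variants)) < p_bias
  as.integer(ifelse(from_mother, mother_variants, father_variants))
}

#' Eligible role models for postmarital learning
#'
#' Living members of a community, excluding the learner, that satisfy the
#' pathway's age rule relative to the learner — horizontal: absolute age
#' difference below `generation_gap` (20 years by default); oblique: at
#' least `generation_gap` years older — and an optional sex filter.
#'
#' @param world A `culthitch_world`.
#' @param learner_id The learning individual's id.
#' @param pathway `"horizontal"` or `"oblique"`.
#' @param sex `"any"`, `"female"` or `"male"`.
#' @param community_id Community searched; defaults to the learner's current
#'   residence.
#' @return Integer vector of candidate ids (possibly empty).
#' @export
eligible_role_models <- function(world, learner_id,
                                 pathway = c("horizontal", "oblique"),
                                 sex = c("any", "female", "male"),
                                 community_id = world$i_com[learner_id]) {
  pathway <- match.arg(pathway)
  sex <- match.arg(sex)
  liv <- living(world)
  cand <- liv[world$i_com[liv] == community_id & liv != learner_id]
  if (!length(cand)) return(integer(0))
  gap <- world$params$generation_gap
  dage <- world$i_age[cand] - world$i_age[learner_id]
  keep <- if (pathway == "horizontal") abs(dage) < gap else dage >= gap
  cand <- cand[keep]
  if (sex == "female") cand <- cand[world$i_female[cand]]
  if (sex == "male") cand <- cand[!world$i_female[cand]]
  cand
}

#' Postmarital resocialization of a migrant
#'
#' For each neutral trait with a postmarital pathway, independently: with
#' probability `p_transmit` the migrant attempts to learn — a role-model sex
#' is drawn (female with probability `p_bias`), the eligible candidates for
#' the trait's pathway and that sex are collected in the destination
#' community, one is picked uniformly and its current variant copied. If the
#' candidate set is empty the migrant retains the variant acquired in the
#' community of origin (a no-candidate event, recorded per trait). Traits
#' without a postmarital pathway are never updated. Resocialization happens
#' exactly once per migration, and — since remarriage is impossible — at
#' most once per lifetime.
#'
#' @param world A `culthitch_world` (mutated in place).
#' @param migrant_id Id of an individual who relocated this step.
#' @return The world, invisibly.
#' @export
resocialize <- function(world, migrant_id) {
  resocialize_batch(world, migrant_id)
}

# All of a step's migrants in one pass: the trait-variant matrices are
# pulled into locals and written back once (per-event writes into
# environment-bound matrices would duplicate the whole matrix each time).
resocialize_batch <- function(world, ids) {
  tc <- world$params$trait_configs
  pathway <- tc$pathway
  p_transmit <- tc$p_transmit
  active <- which(pathway != "none")
  if (!length(active) || !length(ids)) return(invisible(world))
  p_bias <- world$params$p_bias
  gap <- world$params$generation_gap
  cache <- world$.resoc_cache
  neutral <- world$m_neutral
  src <- world$m_src
  fail <- world$m_fail
  cnt <- world$counters
  for (mid in ids) {
    # one membership snapshot serves all traits (nobody relocates during
    # the resocialization phase)
    cid <- world$i_com[mid]
    if (!is.null(cache)) {
      mem <- cache[[as.character(cid)]]
      mem <- mem[mem != mid]
    } else {
      idx <- seq_len(world$n_ind)
      mem <- idx[world$i_alive[idx] & !is.na(world$i_com[idx]) &
                   world$i_com[idx] == cid & idx != mid]
    }
    dage <- world$i_age[mem] - world$i_age[mid]
    fem <- world$i_female[mem]
    horizontal_ok <- abs(dage) < gap
    oblique_ok <- dage >= gap
    for (i in active) {
      if (stats::runif(1) >= p_transmit[i]) next
      cnt["resoc_attempted"] <- cnt["resoc_attempted"] + 1
      want_female <- stats::runif(1) < p_bias
      sel <- if (pathway[i] == "horizontal") horizontal_ok else oblique_ok
      cand <- mem[sel & (fem == want_female)]
      if (!length(cand)) {
        fail[mid, i] <- TRUE
        cnt["resoc_failed"] <- cnt["resoc_failed"] + 1
        next
      }
      model <- if (length(cand) == 1L) cand else
        cand[sample.int(length(cand), 1L)]
      neutral[mid, i] <- neutral[model, i]
      src[mid, i] <- model
      cnt["resoc_succeeded"] <- cnt["resoc_succeeded"] + 1
    }
  }
  world$m_neutral <- neutral
  world$m_src <- src
  world$m_fail <- fail
  world$counters <- cnt
  invisible(world)
}

#' Audit retention of out-of-lineage variants
#'
#' For one trait, finds every living individual (optionally restricted by
#' sex) whose variant differs from their community lineage's founding value
#' and traces its provenance through the recorded copy chain (parent at
#' birth, role model at resocialization). A deviation is *accounted* when
#' the chain terminates in a no-candidate resocialization event (the variant
#' was retained for lack of a role model) or in a copy taken from a migrant
#' before that migrant's own resocialization.
#'
#' @param world A `culthitch_world`.
#' @param trait Trait index (column of the neutral-variant matrix).
#' @param sex `"any"`, `"female"` or `"male"`: restrict the audited set.
#' @return A tibble with one row per deviant individual: `id`, `community`,
#'   `lineage`, `variant`, `accounted`, `reason`.
#' @export
audit_retention <- function(world, trait, sex = "any") {
  liv <- living(world)
  if (sex == "female") liv <- liv[world$i_female[liv]]
  if (sex == "male") liv <- liv[!world$i_female[liv]]
  lin <- world$c_lineage[world$i_com[liv]]
  expected <- ifelse(lin == 1L, 0L, 1L)
  dev <- liv[world$m_neutral[liv, trait] != expected]
  if (!length(dev)) {
    return(tibble::tibble(id = integer(0), community = integer(0),
                          lineage = character(0), variant = integer(0),
                          accounted = logical(0), reason = character(0)))
  }
  trace_one <- function(id) {
    val <- world$m_neutral[id, trait]
    seen <- integer(0)
    while (TRUE) {
      if (id %in% seen) return("cycle")
      seen <- c(seen, id)
      if (world$m_fail[id, trait]) return("no_candidate_retention")
      src <- world$m_src[id, trait]
      if (src == 0L) return("founding_assignment")
      if (world$m_neutral[src, trait] != val) return("copied_before_resocialization")
      id <- src
    }
  }
  reasons <- vapply(dev, trace_one, character(1))
  tibble::tibble(
    id = dev,
    community = world$i_com[dev],
    lineage = c("A", "B")[world$c_lineage[world$i_com[dev]]],
    variant = world$m_neutral[dev, trait],
    accounted = reasons %in% c("no_candidate_retention",
                               "copied_before_resocialization"),
    reason = reasons
  )
}
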
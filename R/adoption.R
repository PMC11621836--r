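#' Frequency-dependent community adoption probability
#'
#' Probability that a community of `n` living residents flips an adaptive
#' trait, given `k` residents carrying the discordant variant:
#' `p = k^(1-beta) / (k^(1-beta) + (n-k)^(1-beta))`.
#' At `beta = 0` this is exactly `k/n`; large negative `beta` suppresses
#' adoption almost entirely. The degenerate cases `k = 0` and `k = n` return
#' exactly 0 and 1 before any exponentiation, and the interior is evaluated
#' in log space so strongly negative `beta` neither overflows nor loses
#' precision.
#'
#' @param k Number of discordant residents, `0 <= k <= n` (vectorized).
#' @param n Community size including migrants, `>= 1`.
#' @param beta Adoption-strength exponent (any real).
#' @return Adoption probability (or probabilities) in `[0, 1]`.
#' @export
#' @examples
#' adoption_probability(1, 100, 0)     # 0.01
#' adoption_probability(1, 100, -10)   # ~1.1e-22
adoption_probability <- function(k, n, beta) {
  if (any(n < 1) || any(k < 0) || any(k > n))
    stop("require n >= 1 and 0 <= k <= n", call. = FALSE)
  if (length(n) == 1L && length(k) > 1L) n <- rep(n, length(k))
  if (length(k) == 1L && length(n) > 1L) k <- rep(k, length(n))
  p <- numeric(length(k))
  p[k == n] <- 1
  interior <- k > 0 & k < n
  if (any(interior)) {
    ki <- k[interior]; ni <- n[interior]
    if (beta == 0) {
      p[interior] <- ki / ni
    } else {
      # p = 1 / (1 + ((n-k)/k)^(1-beta)), computed via logs
      p[interior] <- 1 / (1 + exp((1 - beta) * (log(ni - ki) - log(ki))))
    }
  }
  p
}

#' Count residents discordant with the community's adaptive variant
#'
#' For one adaptive trait, the number of living members whose *carried*
#' variant — frozen at birth or at their last migration — differs from the
#' community's currently adopted variant. Discordance is cumulative over all
#' surviving carriers, not just the current step's arrivals, and a community
#' flip turns its natal members into the discordant class.
#'
#' @param world A `culthitch_world`.
#' @param community_id Community id.
#' @param trait_index Adaptive trait index in `1:3`.
#' @return Integer count.
#' @export
count_discordant <- function(world, community_id, trait_index) {
  stopifnot(trait_index %in% 1:3)
  liv <- living(world)
  members <- liv[world$i_com[liv] == community_id]
  sum(world$m_carried[members, trait_index] !=
        world$c_a[community_id, trait_index])
}

#' Community-level adoption step
#'
#' For every community and every adaptive trait independently, flips the
#' community's variant to its complement with probability
#' [adoption_probability()] evaluated at the discordant count `k` and the
#' living size `n` taken at the start of the adoption phase (flips within
#' one step never feed back into the same step's probabilities).
#'
#' @param world A `culthitch_world` (mutated in place).
#' @return The world, invisibly.
#' @export
adoption_step <- function(world) {
  active <- which(world$c_active[seq_len(world$n_com)])
  if (!length(active)) return(invisible(world))
  liv <- living(world)
  com <- world$i_com[liv]
  sizes <- tabulate(com, nbins = world$n_com)
  # per-community counts of carried 1-variants, all three traits at once
  ones <- rowsum(world$m_carried[liv, , drop = FALSE], group = com,
                 reorder = FALSE)
  cids <- as.integer(rownames(ones))
  beta <- world$params$beta
  for (j in seq_along(cids)) {
    cid <- cids[j]
    n <- sizes[cid]
    if (n == 0L) next
    a <- world$c_a[cid, ]
    k <- ifelse(a == 1L, n - ones[j, ], ones[j, ])
    pr <- adoption_probability(k, n, beta)
    flip <- stats::runif(3) < pr
    if (any(flip)) {
      world$c_a[cid, flip] <- 1L - a[flip]
      world$counters["adoptions"] <- world$counters["adoptions"] + sum(flip)
    }
  }
  invisible(world)
}
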
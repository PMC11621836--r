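---
title: "Simulating cultural hitchhiking under intergroup exogamy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cultural hitchhiking under intergroup exogamy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

When a migrant population carrying a beneficial technology (say, farming)
expands into a region held by incumbent groups, selectively *neutral* traits
(pottery styles, ornaments) that happen to ride along with the technology can
spread with it — *cultural hitchhiking*. Whether the statistical association
between adaptive and neutral variants survives depends on how people move
between groups and whom they learn from after moving. `culthitch` is a
forward-time, individual-based meta-population simulator built to explore
exactly that: it couples an age-structured demography with intergroup
exogamy, postmarital residence rules, sex-biased social learning along
vertical/horizontal/oblique pathways, and a frequency-dependent,
community-level adoption rule for the adaptive traits.

## The model

**Individuals** have a sex, an age, a length-`z` vector of neutral variants
`c_i ∈ {0,1}`, and the adaptive variants they carried from their community of
origin. **Communities** sit on distinct cells of a (default 10×10) grid and
carry three community-level adaptive variants `a_i ∈ {0,1}` plus a lineage
label recording whether they descend from the initial incumbent (A) or
migrant (B) communities. Each time step runs, in order:

1. **Aging and mortality.** Ages increment; death strikes with a
   piecewise-constant probability (0.15 up to age 5, 0.01 to 40, 0.02 to 65,
   0.05 to 85, certain above 85). Widows and widowers never remarry.
2. **Marriage and migration.** All never-married adults (age ≥ 18) enter a
   common pool; random opposite-sex pairs form across community boundaries.
   With probability `p_location` the couple settles in the female partner's
   community (`0` = patrilocality, `0.5` = bilocality); the relocating
   partner freezes the origin community's current `a`-vector as their
   carried variants.
3. **Resocialization.** Each migrant, per trait with a postmarital pathway,
   attempts learning with probability `p_transmit`: a role-model sex is
   drawn (female with probability `p_bias`), candidates are community
   members within 20 years of age (horizontal) or at least 20 years older
   (oblique), and one is copied uniformly. With no candidate, the natal
   variant is retained (logged — these events explain the rare departures
   from complete homogenization).
4. **Adoption of adaptive traits.** Every community flips each `a_i`
   independently with probability
   `p = k^(1-β) / (k^(1-β) + (n-k)^(1-β))`,
   where `n` is the community's living size and `k` the number of residents
   whose frozen carried variant disagrees with the current `a_i`. At `β = 0`
   this is the discordant fraction `k/n`; at `β = -10` it is ~10⁻²² for a
   lone migrant in a community of 100.
5. **Reproduction.** Each married pair with both partners aged 18–45
   produces a child with probability `b + Σ f_i·[a_i = 1]` evaluated on the
   residence community (`b = 0.3224`). Children copy each neutral trait from
   the mother with probability `p_bias`, else the father.
6. **Fission.** A community reaching `n_fission = 100` splits by whole
   families (randomized greedy balancing); the larger daughter keeps the
   cell, the other takes a random empty cell. A full grid stops the run.

The default experiment initializes eight incumbent communities (all
variants 0) and two migrant communities (all variants 1) of 70 people each,
runs a 500-step demographic burn-in, and then simulates until the grid
fills. `run_sweep()` executes the 36-combination grid (β ∈ {−10, 0},
f ∈ {0, 0.005, 0.015}, `p_bias` ∈ {0, 0.5, 1}, `p_location` ∈ {0, 0.5}).

```{r}
library(culthitch)
params <- sim_params(beta = -10, f1 = 0.015, f2 = 0.015, f3 = 0.015,
                     p_bias = 1, p_location = 0)
run <- run_model(params, seed = 1)
glance(run)
neutral_proportions(run$world)
autoplot(run)
```

## Summary statistics

* `lineage_type_counts()` cross-classifies communities by descent lineage
  and current type (A: `a = (0,0,0)`; B: all ones; C: partial adoption).
* `neutral_proportions()` is the hitchhiking statistic: the fraction of
  analyzed individuals carrying `c_i = 1`, pooled over type-A communities
  and over type-B/C communities. Under a fully sex-biased regime only the
  biased-toward sex is analyzed (males for `p_bias = 0`, females for
  `p_bias = 1`): variants of the other sex can never cross community
  boundaries and would dilute the signal. Pooling over individuals is the
  primary reading; `community_neutral_proportions()` also emits the
  per-community distribution so the per-community-averaged reading stays
  recoverable.
* `growth_rate()` fits log population against time by least squares,
  dropping the final 10% of steps where the grid-full stopping rule bends
  the trajectory. With the default mortality schedule and `b = 0.3224` the
  baseline (f = 0) per-step rate is ≈ 0.008 and rises to ≈ 0.015 when all
  three bonuses are 0.015 — reproduced by the acceptance suite.

## Design choices in the open corners

The model description leaves several corners unspecified; these are the
package's choices and the reasons.

**Initial ages.** Only "chosen at random" is specified. Uniform ages over
the whole lifespan are demographically fatal here: marriages are random in
age and remarriage is impossible, so fertile founders wed elderly partners
and are lost to reproduction for life — measured on this implementation, a
uniform-[0, 85] start collapses the metapopulation from 700 to ~100 within
150 steps. We instead found communities with a young cohort (uniform on
[0, 30]), whose initial marriages are fertile-by-fertile; the burn-in then
grows the stationary age pyramid. After the burn-in, mean age is stationary
(two disjoint 100-step windows differ by < 2 years).

**Burn-in pairing.** The burn-in requires reproduction (fissions occur)
while forbidding cultural transmission. Restricting pairing to
within-community partners — so that nobody relocates — cannot sustain the
population: in a 70-person marriage market ~40% of fertile-age females
remain unmatched whenever the singles of a community happen to be same-sex,
and communities die. The burn-in therefore uses the identical exogamous
marriage routine as the main phase. Its relocations are culturally void:
transmission and adoption are off, newborns copy nothing, and every
individual's variants are re-asserted from the community lineage at burn-in
end. This is also the only reading under which `b = 0.3224` is calibrated
against the same marriage machinery that produces the reported growth
rates.

**Pair matching.** "Random pairs" is implemented as: shuffle the females
uniformly; each female in turn picks a uniformly random eligible male
(opposite community, unmatched). Unmatched individuals simply wait for the
next step.

**Families.** A family is a married pair (or its surviving widow/er) plus
their co-resident never-married offspring; marrying founds a new family.
Because migration happens only at marriage, families are always
co-resident, so fission by families never splits a household.

**Discordance accounting (`k`).** `k` counts *all* living residents whose
frozen carried vector disagrees with the community's current variant — not
just the step's arrivals — matching the formula's `n` being the full
community size "including the migrants". Carried vectors are frozen at
birth or at migration and are *not* rebaselined when a community flips, so
a flip turns the natal majority into the discordant class and back-flips
are possible; the alternative reading is isolated behind one function.

**Degenerate adoption.** The adoption rule is evaluated in log space with
`k = 0 → 0` and `k = n → 1` fixed exactly before exponentiation (avoiding
`0^(1-β)` and overflow at `β = -10`; interior values match a 40-digit
reference to 12 significant digits). The `k = n` case has a real
consequence: a near-extinct community whose surviving members are all
discordant-carrying migrants adopts their variants with certainty even at
`β = -10` — total cultural replacement of a dying community. This touches a
minority of runs (the affected communities hold a handful of people) and is
the one mechanism by which a community can change type without "adoption"
in the ordinary sense. Relatedly, a community whose size reaches zero is
retired from the grid and its cell freed. Two monotonicity caveats follow
from the formula itself: the flip probability is nondecreasing in `k` only
while `1 - β ≥ 0`, and nondecreasing in `β` only while the discordant class
is the minority (`k ≤ n/2`).

**Marriage age.** "Older than 18" is read inclusively (age ≥ 18) so the
marriage and fertility windows coincide; `marriage_age_strict = TRUE`
switches to the strict reading.

**Within-step orderings.** Mortality uses the age after incrementing.
Same-step migrants resocialize in uniformly random order, so an
already-resocialized migrant can serve as a role model with its updated
variant — and a migrant can also copy from a fellow migrant who has *not*
yet resocialized, which the retention audit (`audit_retention()`) treats as
its own provenance class. Communities crossing the fission threshold in the
same step are processed in random order.

**Burn-in extinction.** Occasionally a founding community spirals to
extinction during the burn-in (a patrilocal community short of males
exports all its daughters); the experiment requires all ten founders to
survive, so the run aborts with a classed condition and
`run_model_retry()` deterministically salts the seed and tries again.

## What the generator emulates — and what it does not

The simulator reproduces the experiment's study conditions: its defaults
*are* the fixed demographic constants (mortality schedule, `b = 0.3224`,
`n_fission = 100`, 8 + 2 communities of 70 on a 10×10 grid, 500-step
burn-in) and the swept ranges. It does not model carrying-capacity
regulation (dynamics after the expansion phase are out of scope), spatially
structured interaction (cells are addresses), divorce or remarriage,
payoff-biased adoption, or conformity among role models — uniform choice
only. Passing tests therefore speak to the expansion phase of a
colonization scenario, not to saturated landscapes.

## Problem sizes used by the tests

Unit and property tests run on hand-built micro-worlds (2–3 communities,
enumerable members) and on a reduced landscape (3×3 grid, communities of
30, fission at 60) where a full run takes seconds. The acceptance suite
runs the full-scale experiment: growth rates average 5 replicate runs,
the lineage-ratio check averages 20 replicate runs (the published
experiment used 125 repetitions per combination; 20 suffices for a mean
within a few percentage points), and the invariant checks use two
full-scale runs with a-priori seeds. Stochastic assertions use 3-sigma
binomial bands around analytically known frequencies.
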
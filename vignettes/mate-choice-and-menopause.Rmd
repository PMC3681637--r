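---
title: "Mate choice, mutation accumulation, and the origin of menopause: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mate choice, mutation accumulation, and the origin of menopause: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Classic one-sex mutation-accumulation theory predicts a "death barrier":
deleterious mutations whose effects begin after the last age of female
reproduction feel no purifying selection, accumulate to fixation, and
collapse survival just beyond the reproductive span.  Humans show no such
barrier — women routinely live decades past menopause — and, conversely,
menopause itself (fertility declining while survival stays high) is the
puzzle: why did selection not maintain late female fertility?

`matesim` implements a stochastic, individual-based, two-sex answer to
both questions.  Mating pairs form through an age-indexed preference
matrix, so *who mates with whom* determines which mutations are exposed to
selection.  Extended male mating keeps late-acting mortality mutations
rare in both sexes (no death barrier); male preference for young females
removes selection from late-acting, female-specific fertility mutations,
which then accumulate by recurrent mutation and drift — menopause
originates without any intrinsic female decline and without inclusive
fitness or grandmother effects.

## The model

A population holds exactly `N` males and `N` females in 18 age classes,
each class representing five years.  Each period:

1. **Survival.** Every individual survives with probability
   `S_sex(x) * prod over expressed mortality loci (1 - e)^(allele count)`
   where `S_sex(x)` is the intrinsic survival table at its age class `x`.
   Survivors advance one class; class-18 individuals always die.
2. **Replacement births.** Deaths are counted per sex, and exactly that
   many newborns are created per sex, so the census never changes.  Each
   birth repeats: draw a father uniformly from the surviving males and a
   mother uniformly from the surviving females, accept the pair with
   probability `M[i, j]` for their age classes, then let the birth occur
   with probability `F_m(father) * F_f(mother)` — the product of the
   parents' effective fertilities (both parents must be fertile).  A
   rejected draw is simply repeated; parents are sampled with
   replacement, so one individual can parent several newborns per period.
3. **Inheritance and mutation.** Newborns enter class 1 with a genotype
   built by Mendelian transmission (homozygous parents transmit the
   mutant allele always, heterozygotes with probability 1/2, loci
   unlinked) followed by mutation: each wild-type allele copy flips to
   the mutant state with its locus rate `mu`.  There is no back
   mutation.

Each locus is deleterious, non-pleiotropic, and age-gated: it affects
either survival or fertility, in both sexes or one, and only from its
onset class onward.  Effects are multiplicative and codominant by
default — each expressed allele scales the affected probability by
`1 - e`; a dominance coefficient `h` (heterozygote factor `1 - h*e`) is
exposed for sensitivity analyses.

Runs begin with founders assigned uniformly to age classes, wild type at
every locus (unless a locus is given a nonzero initial frequency for
drift experiments), followed by a mutation-free burn-in that lets the age
distribution relax to its quasi-stationary shape.

## Parameters and defaults

| Parameter | Meaning | Default | Rationale |
|---|---|---|---|
| `N` | individuals per sex | 1000 | headline population size of the reference experiments |
| `mu` | mutation rate per allele copy per newborn | 0.005 | headline value of the preference-shift experiment |
| `e` | per-allele reduction of the affected probability | 0.025 | headline value; the fertility effect of a homozygote is `(1-e)^2` |
| `h` | dominance (heterozygote factor `1-h*e`) | 1 | codominant per-copy action, the simplest form consistent with load depending on allele count |
| onset classes | first expressed age class | 6–10 | spans ages ~25–50, bracketing the human menopausal transition |
| `A, B, C` | Gompertz–Makeham hazard: survival `exp(-(A + B e^(Cx)))` | 0.01, 1e-4, 0.5 | per-period survival > 0.9 through class ~10, declining thereafter; class 18 truncated to 0 |
| fertility plateau | intrinsic fertility when fertile | 0.9 | high but non-certain fertility; classes 1–3 are juvenile (fertility 0) |
| young window | YP/YF female (and YP male) mating classes | 4–7 | ages ~15–35; chosen so that loci with onset 7 sit at the window edge (partial selection) and onset 8+ escape entirely |
| `adult_min` | first mating class under AP/YF males | 3 | mating allowed at all classes after the second |
| `burn_in` | mutation-free periods before recording | 200 | several mean lifespans (~13 periods each); age-class fractions are stationary to within binomial noise afterwards |

Two intrinsic fertility schedules ship with the package:
`"prolonged"` (plateau to class 17 in both sexes — the ancestral state for
the menopause-origin experiments) and `"declining_female"` (female
fertility ends at class 9 — the fixed female decline premise of the
mortality-only experiments, with male fertility still prolonged).

The `mu` convention is per allele copy; `mu_convention = "per_diploid"`
re-reads the same number as a per-locus rate (internally `mu/2` per copy)
so both conventions found in the literature can be compared.

## What the simulator emulates — and what it does not

The simulator *is* the study system: all quantitative claims are about
this model population, not directly about humans.  It emulates constant
census size with immediate replacement, discrete 5-year age classes,
uniform random encounter within the preference matrix, and unlinked
autosomal diploid loci with one-way mutation.  It does not emulate
density dependence, environmental stochasticity, linkage or epistasis,
pair-bond persistence, heritable mate preference, or inclusive-fitness
transfers.  Passing tests therefore demonstrate the internal logic of the
mate-choice mechanism, not its sufficiency in real human demography.

## Numerical and design choices

* **Mating age.** Survival is resolved before births, so parents are
  drawn from survivors at their advanced age class.  A locus with onset
  class `x` consequently affects mating from class `x + ...` survival
  transitions at `x` onward: under a young window ending at class 7, an
  onset-7 locus touches only the 7→8 transition and is effectively
  neutral, while onset 6 remains under partial selection.  This single
  timing convention, applied consistently, reproduces the qualitative
  split of the reference results (onset-6 polymorphic, onset-7+ fixing
  under restricted mating).
* **Joint vs sequential acceptance.** Pair acceptance (`M[i,j]`) and the
  fertility Bernoulli are drawn sequentially; for independent draws this
  is distributionally identical to a single joint draw.
* **Per-sex replacement.** Each sex's deaths are replaced by newborns of
  that sex, keeping the per-sex census exact (a random-sex top-up would
  let the sex ratio wander).
* **Degenerate configurations.** If no birth is accepted after
  `max_attempts` (default 1e6) draws in a period, the run stops with a
  "no fertile pairs" error rather than spinning silently; a sex with no
  survivors likewise errors.
* **Determinism.** Every stochastic draw — survival, pair rejection,
  fertility, segregation, mutation — flows through R's RNG, so a seed
  fully determines a run, whether stepped manually or via `run_sim()`.
* **End-state curves.** Realized survivorship/fertility by age class are
  averaged over the final 50 periods (configurable) to smooth the small
  per-class counts at late ages.
* **Early stopping.** With all mutation rates zero, frequencies 0 and 1
  are absorbing; `stop_when_fixed = TRUE` ends such runs at absorption
  (used by the drift-oracle tests).

## Problem sizes used in the shipped analyses

The package's own reproduction runs use `N = 1000` per sex with 10
replicates: 10000 recorded periods in the test suite and 15000 in the
acceptance script (the reference equilibria were originally quoted at
50000 periods and 100 replicates; at `mu = 0.005` the recurrent-mutation
input reaches fixation well before 15000 periods for unselected loci, and
balance loci equilibrate within a few thousand periods).  Shift
experiments use 20 replicates of 3500 periods with the shift at period
1000.  Replicate `r` of an experiment uses seed `seed_base + r`, so any
replicate can be regenerated in isolation.

## Known limitations

* Equilibrium frequencies at mutation–selection balance depend strongly
  on the intrinsic tables and on `(mu, e)`; the original study's exact
  intrinsic tables and multi-locus rates were published only as
  supplementary files, so this package documents its own defaults (above)
  and treats the printed equilibrium values as order-of-magnitude
  anchors: the qualitative contrasts (fixation vs balance, female vs
  male, onset ordering, shift dynamics) are the reproducible content.
* Frequencies are recorded per sex; for sex-indifferent loci the two
  trajectories differ only by sampling noise, and tests use the female
  population as the reference, as the source tables do.
* With 18 fixed classes, scenarios needing other life-cycle lengths are
  emulated by zeroing survival beyond an effective last class (see
  `make_fixture("toy_tables")`).
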
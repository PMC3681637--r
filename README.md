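# matesim

Individual-based, two-sex simulation of mutation accumulation under mate
choice — the demographic-genetic machinery behind the evolutionary origin
of menopause.

## The problem

One-sex mutation-accumulation theory predicts that mutations whose
deleterious effects begin after the last female reproductive age escape
selection, accumulate, and produce a "death barrier" — survival collapsing
right after the reproductive span.  Human populations show no death
barrier, and the actual puzzle is the mirror image: menopause, a decline
of female *fertility* while survival stays high.  Two-sex models resolve
both once mating is age-structured: males who keep mating at older ages
keep late-acting mortality mutations under selection, and males who
prefer *young* females remove selection from late-acting, female-specific
fertility mutations — which then accumulate by recurrent mutation and
drift until female fertility ends while survival continues.

`matesim` is for population geneticists and evolutionary demographers who
want to simulate and dissect these dynamics: which preference structures
produce death barriers, menopause, or neither, and how equilibrium allele
frequencies respond to mutation rate, selection strength, age of onset,
and population size.

## The model

A constant population of N males and N females lives in 18 five-year age
classes.  Per period, each individual survives with probability

    S_sex(x) * Π_ℓ (1 − e_ℓ)^{c_ℓ}      (expressed mortality loci ℓ)

where `S_sex(x)` is the intrinsic (Gompertz–Makeham) survival at age
class `x`, `c_ℓ` the mutant-allele count, and a locus is expressed once
`x ≥ onset_ℓ` in a sex within its scope.  Survivors advance one class;
class 18 always dies.  Deaths are replaced per sex: each birth draws a
father and a mother uniformly from survivors, accepts the pair with
probability `M[i, j]` (the mating-preference matrix over male age `i`,
female age `j`), and yields a newborn with probability
`F_m(father) · F_f(mother)` — the parents' effective fertilities,
intrinsic fertility times the fertility-locus load.  Newborns inherit by
Mendelian rules at unlinked loci, and each wild-type allele copy mutates
with probability μ (no back mutation).

Built-in preference matrices: **AP** (all adult pairs, age-indifferent),
**YP** (both sexes restricted to young classes 4–7), **YF** (males any
adult age, females young only).  Recurrent mutation (μ per copy) against
multiplicative selection (e per allele) gives mutation–selection balance
at loci the matrix exposes to selection, and fixation at loci it hides.

## Worked example

A single female-specific infertility locus with onset in age class 8,
under male preference for young females (YF) — the menopause mechanism in
miniature:

```r
library(matesim)

cfg <- sim_config(
  N = 200,
  loci = locus_set(effect = "fertility", scope = "female", onset = 8,
                   e = 0.025, mu = 0.005),
  tables = default_life_tables("prolonged"),
  matrix = mating_matrix("YF"),
  n_periods = 2000, burn_in = 200)

run_sim(cfg, seed = 42)
#> Two-sex simulation result: 2000 periods, N = 200 per sex, seed 42
#> Final mutant-allele frequencies:
#>             male female
#> L1_fert_f8 0.785 0.8275

run_replicates(cfg, n_reps = 5, seed_base = 42)
#> Replicate summary: 5 replicates, N = 200 per sex, 2000 periods
#> Female mutant-allele frequencies (mean over replicates, SE):
#>  locus    effect  scope onset    sex mean_freq    se
#>      1 fertility female     8 female     0.781 0.106
```

The locus onset (class 8) lies beyond the female mating window (classes
4–7), so no mating female ever expresses it: selection is blind to the
allele and recurrent mutation has driven it to ~0.78 after 2000 periods
(10000 simulated years), on its way to fixation — menopause evolving in
real time.  Under `mating_matrix("AP")` the same locus is held near
mutation–selection balance instead.  `plot(res, "trajectory")` and
`plot(res, "curves")` show the frequency paths and the end-state
survivorship/fertility curves.

Pre-registered experiment wrappers reproduce the full scenarios:
`scenario_mortality_only("AP"|"YP")` (death barrier),
`scenario_fertility_mortality("AP"|"YF")` (menopause origin, 15 loci),
and `scenario_matrix_shift()` (single-locus AP→YF preference shift).  A
thin command-line front end is in `inst/cli/matesim.R`.

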
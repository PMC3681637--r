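#' Standard locus sets for the reference experiments
#'
#' `mortality_loci()` gives five sex-indifferent mortality loci with onset
#' classes 6-10 (roughly ages 25-50).  `fertility_mortality_loci()` gives
#' the fifteen-locus set used with prolonged intrinsic fertility: the same
#' five mortality loci plus five male-only and five female-only fertility
#' loci at matched onsets.
#'
#' @param e selection strength per allele (default 0.025).
#' @param mu mutation rate (default 0.005).
#' @return A [locus_set()].
#' @export
mortality_loci <- function(e = 0.025, mu = 0.005) {
  locus_set(effect = "mortality", scope = "both", onset = 6:10,
            e = e, mu = mu)
}

#' @rdname mortality_loci
#' @export
fertility_mortality_loci <- function(e = 0.025, mu = 0.005) {
  c(locus_set("mortality", "both", 6:10, e = e, mu = mu),
    locus_set("fertility", "male", 6:10, e = e, mu = mu),
    locus_set("fertility", "female", 6:10, e = e, mu = mu))
}

#' Mortality-only experiment (age-indifferent vs young-pairs preference)
#'
#' Five sex-indifferent mortality loci (onsets 6-10) evolve under either
#' the age-indifferent (`"AP"`) or young-pairs (`"YP"`) mating matrix, with
#' a fixed intrinsic decline in late female fertility
#' (`default_life_tables("declining_female")`).  Under AP, late-acting
#' mortality mutations stay rare at mutation-selection balance; under YP,
#' loci whose onset falls beyond the mating window escape selection and
#' drift to fixation under recurrent mutation — the one-sex "death
#' barrier".
#'
#' @param model `"AP"` or `"YP"`.
#' @param N per-sex population size (default 1000).
#' @param n_periods recorded periods (default 10000).
#' @param n_reps replicates (default 10).
#' @param e,mu selection strength and mutation rate (defaults 0.025,
#'   0.005).
#' @param seed base seed for replicates.
#' @param burn_in mutation-free burn-in periods (default 200).
#' @return A [run_replicates()] object (`sim_replicates`), with the
#'   scenario name in attribute `"scenario"`.
#' @export
scenario_mortality_only <- function(model = c("AP", "YP"), N = 1000,
                                    n_periods = 10000, n_reps = 10,
                                    e = 0.025, mu = 0.005, seed = 1,
                                    burn_in = 200) {
  model <- match.arg(model)
  cfg <- sim_config(N = N, loci = mortality_loci(e = e, mu = mu),
                    tables = default_life_tables("declining_female"),
                    matrix = mating_matrix(model),
                    n_periods = n_periods, burn_in = burn_in, seed = seed)
  out <- run_replicates(cfg, n_reps = n_reps, seed_base = seed)
  attr(out, "scenario") <- paste0("mortality_only_", model)
  out
}

#' Fertility-and-mortality experiment (menopause origin)
#'
#' Fifteen loci — five sex-indifferent mortality, five male-only
#' fertility, five female-only fertility, onsets 6-10 each — evolve from a
#' prolonged-fertility ancestral state under either the age-indifferent
#' (`"AP"`) matrix or male preference for young females (`"YF"`).  Under
#' YF, female-specific fertility mutations with onset beyond the female
#' mating window become nearly neutral and accumulate to fixation, so
#' female fertility declines while female survival stays high (menopause);
#' male fertility loci remain under purifying selection at all onsets.
#'
#' @inheritParams scenario_mortality_only
#' @param model `"AP"` or `"YF"`.
#' @return A `sim_replicates` object with attribute `"scenario"`.
#' @export
scenario_fertility_mortality <- function(model = c("AP", "YF"), N = 1000,
                                         n_periods = 10000, n_reps = 10,
                                         e = 0.025, mu = 0.005, seed = 1,
                                         burn_in = 200) {
  model <- match.arg(model)
  cfg <- sim_config(N = N,
                    loci = fertility_mortality_loci(e = e, mu = mu),
                    tables = default_life_tables("prolonged"),
                    matrix = mating_matrix(model),
                    n_periods = n_periods, burn_in = burn_in, seed = seed)
  out <- run_replicates(cfg, n_reps = n_reps, seed_base = seed)
  attr(out, "scenario") <- paste0("fertility_mortality_", model)
  out
}

#' Preference-shift experiment (single-locus fixation dynamics)
#'
#' A single female-only fertility locus evolves under the age-indifferent
#' matrix until `shift_period`, when male preference shifts to young
#' females (AP to YF).  Before the shift the locus sits at
#' mutation-selection balance (equilibrium frequency decreasing in `e`,
#' increasing in `mu`); after the shift selection is relaxed and recurrent
#' mutation plus drift carry the allele toward fixation, faster for larger
#' `mu` and nearly independently of `N`.
#'
#' @inheritParams scenario_mortality_only
#' @param onset age class of onset for the locus (default 6).
#' @param shift_period period at which the matrix shifts (default 1000).
#' @param n_periods total recorded periods (default 5000).
#' @param n_reps replicates (default 20).
#' @return A `sim_replicates` object; `mean_trajectory[, 1, "female"]` is
#'   the across-replicate mean female mutant frequency per period.
#' @export
scenario_matrix_shift <- function(N = 1000, mu = 0.005, e = 0.025,
                                  onset = 6, shift_period = 1000,
                                  n_periods = 5000, n_reps = 20,
                                  seed = 1, burn_in = 200) {
  if (shift_period >= n_periods)
    stop("shift_period must be < n_periods", call. = FALSE)
  cfg <- sim_config(
    N = N,
    loci = locus_set("fertility", "female", onset, e = e, mu = mu),
    tables = default_life_tables("prolonged"),
    matrix = mating_matrix("AP"),
    n_periods = n_periods, burn_in = burn_in, seed = seed,
    shift = list(period = shift_period, matrix = mating_matrix("YF"))
  )
  out <- run_replicates(cfg, n_reps = n_reps, seed_base = seed)
  attr(out, "scenario") <- "matrix_shift"
  out
}
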
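#' Simulation configuration
#'
#' Bundles everything one run needs: per-sex population size `N`, the
#' [locus_set()], intrinsic [life_tables()], the [mating_matrix()], run
#' length, burn-in, seed, and an optional mid-run preference shift.
#'
#' The population holds exactly `N` males and `N` females at every period
#' boundary; each period (one 5-year age class) resolves survival for every
#' individual, then replaces the period's deaths, per sex, with newborns in
#' age class 1.
#'
#' @param N per-sex population size (`>= 2`).
#' @param loci a [locus_set()].
#' @param tables a [life_tables()] object
#'   (default `default_life_tables("prolonged")`).
#' @param matrix a [mating_matrix()] (default `"AP"`).
#' @param n_periods number of recorded periods after burn-in (`>= 1`).
#' @param burn_in mutation-free periods run first so the age distribution
#'   reaches approximate stationarity (default 200).
#' @param seed default RNG seed used by [run_sim()] when none is given.
#' @param shift optional `list(period =, matrix =)`: from period
#'   `shift$period` on (1-based), `shift$matrix` replaces `matrix`.
#' @param mu_convention `"per_copy"` (each of a newborn's two allele copies
#'   mutates with probability `mu`) or `"per_diploid"` (`mu` is the rate
#'   per diploid locus per newborn; the per-copy rate used is `mu / 2`).
#' @param max_attempts birth-loop rejection cap per period
#'   (default 1e6).
#' @param curve_periods number of final periods over which end-state
#'   survivorship/fertility curves are averaged (default 50).
#' @return A list of class `"sim_config"`.
#' @seealso [run_sim()], [run_replicates()]
#' @export
sim_config <- function(N, loci, tables = default_life_tables("prolonged"),
                       matrix = mating_matrix("AP"), n_periods,
                       burn_in = 200L, seed = 1L, shift = NULL,
                       mu_convention = c("per_copy", "per_diploid"),
                       max_attempts = 1e6, curve_periods = 50L) {
  mu_convention <- match.arg(mu_convention)
  N <- as.integer(N)
  n_periods <- as.integer(n_periods)
  burn_in <- as.integer(burn_in)
  if (N < 2L) stop("N must be >= 2", call. = FALSE)
  if (n_periods < 1L) stop("n_periods must be >= 1", call. = FALSE)
  if (burn_in < 0L) stop("burn_in must be >= 0", call. = FALSE)
  stopifnot(inherits(loci, "locus_set"), inherits(tables, "life_tables"),
            inherits(matrix, "mating_matrix"))
  if (!is.null(shift)) {
    if (!is.list(shift) || is.null(shift$period) || is.null(shift$matrix))
      stop("shift must be list(period =, matrix =)", call. = FALSE)
    shift$period <- as.integer(shift$period)
    stopifnot(inherits(shift$matrix, "mating_matrix"))
    if (shift$period < 1L || shift$period > n_periods)
      stop("shift$period must lie in 1..n_periods", call. = FALSE)
  }
  structure(list(N = N, loci = loci, tables = tables, matrix = matrix,
                 n_periods = n_periods, burn_in = burn_in,
                 seed = as.integer(seed), shift = shift,
                 mu_convention = mu_convention,
                 max_attempts = max_attempts,
                 curve_periods = as.integer(curve_periods)),
            class = "sim_config")
}

# Flattened parameters handed to the C++ engine (matrix chosen per period).
sim_params <- function(config) {
  cd <- loci_codes(config$loci)
  if (config$mu_convention == "per_diploid") cd$mu <- cd$mu / 2
  list(
    surv_m = config$tables$survival[, "male"],
    surv_f = config$tables$survival[, "female"],
    fert_m = config$tables$fertility[, "male"],
    fert_f = config$tables$fertility[, "female"],
    onset = cd$onset, e = cd$e, mu = cd$mu, effect = cd$effect,
    scope = cd$scope, h = cd$h, max_attempts = config$max_attempts
  )
}

#' Mating matrix in force at a given period
#'
#' Before the configured shift period the base matrix applies; from the
#' shift period on, the shift matrix.
#'
#' @param config a [sim_config()].
#' @param period 1-based period index.
#' @return A [mating_matrix()].
#' @export
matrix_in_force <- function(config, period) {
  if (!is.null(config$shift) && period >= config$shift$period)
    config$shift$matrix
  else config$matrix
}

#' Initialise a population
#'
#' `N` males and `N` females with age classes drawn uniformly from 1..18.
#' Founders are wild type at every locus unless a locus has `init_freq > 0`,
#' in which case each founder's mutant-allele count at that locus is drawn
#' Binomial(2, `init_freq`).
#'
#' Uses the current RNG state; call `set.seed()` first for reproducibility
#' (as [run_sim()] does).
#'
#' @param config a [sim_config()].
#' @return A list of class `"population"`: `males` and `females`, each with
#'   integer `age` (length N) and integer `geno` (N x L), plus `period = 0`.
#' @export
init_population <- function(config) {
  N <- config$N
  L <- nrow(config$loci)
  p0 <- config$loci$init_freq
  draw_sex <- function() {
    age <- sample.int(18L, N, replace = TRUE)
    geno <- matrix(0L, N, L)
    for (l in seq_len(L)) {
      if (p0[l] > 0) geno[, l] <- stats::rbinom(N, 2L, p0[l])
    }
    list(age = age, geno = geno)
  }
  males <- draw_sex()
  females <- draw_sex()
  structure(list(males = males, females = females, period = 0L),
            class = "population")
}

#' Advance a population by one period
#'
#' Resolves survival for every individual (intrinsic survival times
#' mutation load; class 18 always dies), advances survivors one age class,
#' then replaces each sex's deaths with newborns in class 1 produced by the
#' birth loop ([simulate_birth()] semantics), Mendelian transmission, and
#' mutation.  Per-sex census is exactly restored.
#'
#' @param pop a population from [init_population()] or a previous step.
#' @param config a [sim_config()].
#' @param mutation_on logical; `FALSE` during burn-in.
#' @param matrix optional [mating_matrix()] overriding the configured one.
#' @return The advanced population; attributes `deaths` (per-sex counts)
#'   and `attempts` (birth-loop draws used) report the period's bookkeeping.
#' @export
step_population <- function(pop, config, mutation_on = TRUE, matrix = NULL) {
  par <- sim_params(config)
  if (is.null(matrix)) matrix <- matrix_in_force(config, pop$period + 1L)
  step_population_(pop, par, unclass(matrix), mutation_on)
}

step_population_ <- function(pop, par, M, mutation_on) {
  st <- cpp_step(pop$males$age, pop$males$geno,
                 pop$females$age, pop$females$geno,
                 par$surv_m, par$surv_f, par$fert_m, par$fert_f,
                 M, par$onset, par$e, par$mu, par$effect, par$scope, par$h,
                 mutation_on, par$max_attempts)
  out <- structure(list(
    males = list(age = st$age_m, geno = st$geno_m),
    females = list(age = st$age_f, geno = st$geno_f),
    period = pop$period + 1L
  ), class = "population")
  attr(out, "deaths") <- c(male = st$deaths_m, female = st$deaths_f)
  attr(out, "attempts") <- st$attempts
  out
}

#' Run the burn-in phase
#'
#' Advances the population `config$burn_in` periods with mutation disabled,
#' so the age distribution relaxes to its approximate steady state while
#' genotypes stay as initialised.
#'
#' @inheritParams step_population
#' @return The burned-in population (period counter reset to 0).
#' @export
run_burn_in <- function(pop, config) {
  par <- sim_params(config)
  M <- unclass(config$matrix)
  for (b in seq_len(config$burn_in))
    pop <- step_population_(pop, par, M, mutation_on = FALSE)
  pop$period <- 0L
  pop
}

#' Run one simulation
#'
#' Initialise, burn in, then advance `n_periods` recorded periods, applying
#' the configured preference shift if any.  Records the mutant-allele
#' frequency per locus and sex each period, and averages end-state
#' effective survivorship and fertility curves over the final
#' `curve_periods` periods.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (default `config$seed`); identical seeds give
#'   bit-identical results.
#' @param stop_when_fixed logical; if `TRUE` and all mutation rates are 0,
#'   the run stops early once every locus is absorbed (frequency 0 or 1 in
#'   the whole population) and the trajectory is padded with the absorbed
#'   values.  Used for drift experiments.
#' @return A list of class `"sim_result"`: `freq` (array
#'   `(n_periods + 1) x loci x sex`, row 1 = state after burn-in),
#'   `curves` (per-sex data frame of end-state survival and fertility by
#'   age class), `deaths` (per-period per-sex death counts), `attempts`
#'   (per-period birth-loop draws), `absorbed_at` (period of fixation/loss
#'   or `NA`), `config`, `seed`.
#' @examples
#' cfg <- sim_config(N = 50, loci = locus_set("mortality", "both", 6:10),
#'                   n_periods = 50, burn_in = 20)
#' res <- run_sim(cfg, seed = 1)
#' summary(res)
#' @export
run_sim <- function(config, seed = config$seed, stop_when_fixed = FALSE) {
  set.seed(seed)
  par <- sim_params(config)
  if (stop_when_fixed && any(par$mu > 0))
    stop("stop_when_fixed requires all mutation rates 0", call. = FALSE)
  L <- nrow(config$loci)
  np <- config$n_periods

  pop <- init_population(config)
  pop <- run_burn_in(pop, config)

  freq <- array(NA_real_, dim = c(np + 1L, L, 2L),
                dimnames = list(NULL, locus_labels(config$loci),
                                c("male", "female")))
  freq[1L, , ] <- cbind(colMeans(pop$males$geno) / 2,
                        colMeans(pop$females$geno) / 2)
  deaths <- matrix(NA_integer_, np, 2L,
                   dimnames = list(NULL, c("male", "female")))
  attempts <- numeric(np)

  M_base <- unclass(config$matrix)
  M_shift <- if (!is.null(config$shift)) unclass(config$shift$matrix)
  shift_at <- if (!is.null(config$shift)) config$shift$period else Inf

  curve_from <- max(1L, np - config$curve_periods + 1L)
  curve_m <- matrix(0, 18L, 3L)
  curve_f <- matrix(0, 18L, 3L)

  absorbed_at <- NA_integer_
  for (t in seq_len(np)) {
    M <- if (t >= shift_at) M_shift else M_base
    pop <- step_population_(pop, par, M, mutation_on = TRUE)
    fm <- colMeans(pop$males$geno) / 2
    ff <- colMeans(pop$females$geno) / 2
    freq[t + 1L, , ] <- cbind(fm, ff)
    deaths[t, ] <- attr(pop, "deaths")
    attempts[t] <- attr(pop, "attempts")
    if (t >= curve_from) {
      cs <- cpp_curve_sums(pop$males$age, pop$males$geno,
                           pop$females$age, pop$females$geno,
                           par$surv_m, par$surv_f, par$fert_m, par$fert_f,
                           par$onset, par$e, par$effect, par$scope, par$h)
      curve_m <- curve_m + cs$male
      curve_f <- curve_f + cs$female
    }
    if (stop_when_fixed) {
      tot <- (fm + ff) / 2
      if (all(tot == 0 | tot == 1)) {
        absorbed_at <- t
        if (t < np)
          freq[(t + 2L):(np + 1L), , ] <-
            freq[rep(t + 1L, np - t), , , drop = FALSE]
        break
      }
    }
  }

  curves <- data.frame(
    age_class = rep(1:18, 2L),
    sex = rep(c("male", "female"), each = 18L),
    survival = c(curve_m[, 2] / curve_m[, 1], curve_f[, 2] / curve_f[, 1]),
    fertility = c(curve_m[, 3] / curve_m[, 1], curve_f[, 3] / curve_f[, 1])
  )

  structure(list(freq = freq, curves = curves, deaths = deaths,
                 attempts = attempts, absorbed_at = absorbed_at,
                 config = config, seed = seed),
            class = "sim_result")
}

locus_labels <- function(loci) {
  paste0("L", loci$id, "_", substr(loci$effect, 1, 4), "_",
         substr(loci$scope, 1, 1), loci$onset)
}

#' Final-period allele frequencies
#'
#' @param result a `sim_result`.
#' @return Matrix loci x sex of mutant-allele frequencies at the final
#'   recorded period.
#' @export
final_frequencies <- function(result) {
  f <- result$freq[dim(result$freq)[1], , , drop = FALSE]
  matrix(f, dim(result$freq)[2], 2L,
         dimnames = dimnames(result$freq)[2:3])
}

#' Run replicate simulations and summarise
#'
#' Replicate `r` runs with seed `seed_base + r`.  Reports per-locus,
#' per-sex mean and standard error (`sd / sqrt(n_reps)`; `NA` for a single
#' replicate) of final-period mutant frequencies, the across-replicate mean
#' frequency trajectory, and the mean end-state curves.
#'
#' @param config a [sim_config()].
#' @param n_reps number of replicates (`>= 1`).
#' @param seed_base base seed; replicate `r` uses `seed_base + r`.
#' @param keep_results keep the individual `sim_result` objects
#'   (default `FALSE`).
#' @param stop_when_fixed passed to [run_sim()].
#' @return A list of class `"sim_replicates"`: `summary` (data frame with
#'   locus id, effect, scope, onset, sex, mean_freq, se), `final` (array
#'   reps x loci x sex), `mean_trajectory`, `mean_curves`, `n_reps`,
#'   `seed_base`, `config`, and optionally `results`.
#' @export
run_replicates <- function(config, n_reps, seed_base = config$seed,
                           keep_results = FALSE, stop_when_fixed = FALSE) {
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  L <- nrow(config$loci)
  final <- array(NA_real_, c(n_reps, L, 2L),
                 dimnames = list(NULL, locus_labels(config$loci),
                                 c("male", "female")))
  traj_sum <- NULL
  curve_sum <- NULL
  results <- if (keep_results) vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    res <- run_sim(config, seed = seed_base + r,
                   stop_when_fixed = stop_when_fixed)
    final[r, , ] <- final_frequencies(res)
    traj_sum <- if (is.null(traj_sum)) res$freq else traj_sum + res$freq
    cv <- res$curves[, c("survival", "fertility")]
    curve_sum <- if (is.null(curve_sum)) cv else curve_sum + cv
    if (keep_results) results[[r]] <- res
  }
  mean_curves <- res$curves
  mean_curves[, c("survival", "fertility")] <- curve_sum / n_reps

  mn <- apply(final, c(2, 3), mean)
  se <- if (n_reps > 1L) apply(final, c(2, 3), stats::sd) / sqrt(n_reps)
        else matrix(NA_real_, L, 2L)
  loci <- config$loci
  summary <- data.frame(
    locus = rep(loci$id, 2L),
    effect = rep(loci$effect, 2L),
    scope = rep(loci$scope, 2L),
    onset = rep(loci$onset, 2L),
    sex = rep(c("male", "female"), each = L),
    mean_freq = c(mn[, "male"], mn[, "female"]),
    se = c(se[, 1], se[, 2])
  )
  structure(list(summary = summary, final = final,
                 mean_trajectory = traj_sum / n_reps,
                 mean_curves = mean_curves, n_reps = n_reps,
                 seed_base = seed_base, config = config,
                 results = results),
            class = "sim_replicates")
}
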
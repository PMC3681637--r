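# Reduced-scale behaviour of the pre-registered scenarios.  Full-scale
# quantitative checks live in test-acceptance.R; here the runs are small
# (N = 100-200, few thousand periods) and assert orderings that are robust
# at that scale.

test_that("scenario outputs carry the documented structure", {
  out <- scenario_mortality_only("AP", N = 60, n_periods = 50, n_reps = 2,
                                 seed = 5, burn_in = 20)
  expect_s3_class(out, "sim_replicates")
  expect_equal(attr(out, "scenario"), "mortality_only_AP")
  expect_equal(nrow(out$summary), 10)   # 5 loci x 2 sexes
  expect_true(all(out$summary$mean_freq >= 0 & out$summary$mean_freq <= 1))
  expect_equal(dim(out$mean_trajectory), c(51, 5, 2))

  out2 <- scenario_fertility_mortality("YF", N = 60, n_periods = 50,
                                       n_reps = 2, seed = 5, burn_in = 20)
  expect_equal(nrow(out2$summary), 30)  # 15 loci x 2 sexes
  expect_setequal(unique(out2$config$loci$scope),
                  c("both", "male", "female"))
})

test_that("young-pairs mating lets late-onset mortality load accumulate", {
  # under YP, onset-10 mortality is beyond every mating age and
  # accumulates by recurrent mutation; under AP extended male mating keeps
  # it rarer.  2000 periods at N = 200 separates the two regimes clearly.
  yp <- scenario_mortality_only("YP", N = 200, n_periods = 2000,
                                n_reps = 3, seed = 17, burn_in = 100)
  ap <- scenario_mortality_only("AP", N = 200, n_periods = 2000,
                                n_reps = 3, seed = 27, burn_in = 100)
  f <- function(x, onset)
    x$summary$mean_freq[x$summary$sex == "female" &
                          x$summary$onset == onset]
  expect_gt(f(yp, 10), f(ap, 10) + 0.1)
  # and YP end-state female survival collapses at late classes relative
  # to AP (the death barrier direction)
  surv_late <- function(x) {
    cv <- x$mean_curves
    mean(cv$survival[cv$sex == "female" & cv$age_class %in% 12:16],
         na.rm = TRUE)
  }
  expect_lt(surv_late(yp), surv_late(ap))
})

test_that("young-female preference drives female-specific infertility, not male", {
  yf <- scenario_fertility_mortality("YF", N = 200, n_periods = 2000,
                                     n_reps = 3, seed = 37, burn_in = 100)
  s <- yf$summary[yf$summary$sex == "female", ]
  fem10 <- s$mean_freq[s$scope == "female" & s$onset == 10]
  mal10 <- s$mean_freq[s$scope == "male" & s$onset == 10]
  expect_gt(fem10, mal10 + 0.1)
})

test_that("under age-indifferent preference the sexes are exchangeable", {
  # AP is symmetric, so male-only and female-only fertility loci at the
  # same onset face the same selection; with short runs their frequencies
  # must agree within drift noise.  Averaged over onsets and replicates.
  ap <- scenario_fertility_mortality("AP", N = 200, n_periods = 1000,
                                     n_reps = 4, seed = 47, burn_in = 100)
  s <- ap$summary[ap$summary$sex == "female", ]
  m_mean <- mean(s$mean_freq[s$scope == "male"])
  f_mean <- mean(s$mean_freq[s$scope == "female"])
  pooled_se <- sqrt(sum(s$se[s$scope != "both"]^2, na.rm = TRUE) / 5)
  expect_lt(abs(m_mean - f_mean), 3 * pooled_se + 0.05)
})

test_that("an above-window female fertility locus drifts like an inert locus under YF", {
  # selection-free oracle inside the same demography: a mortality locus
  # with onset 18 is inert (class 18 dies regardless), so its trajectory
  # is pure mutation pressure + drift.  A female-only fertility locus
  # with onset above the female mating window must be statistically
  # indistinguishable from it.
  loci <- c(locus_set("fertility", "female", onset = 8),
            locus_set("mortality", "both", onset = 18))
  cfg <- sim_config(N = 100, loci = loci,
                    tables = default_life_tables("prolonged"),
                    matrix = mating_matrix("YF", young = c(4, 7)),
                    n_periods = 1500, burn_in = 100)
  reps <- run_replicates(cfg, n_reps = 12, seed_base = 600)
  s <- reps$summary[reps$summary$sex == "female", ]
  diff <- s$mean_freq[1] - s$mean_freq[2]
  se <- sqrt(sum(s$se^2))
  expect_lt(abs(diff), 3 * se)
})

test_that("the preference shift relaxes selection at the stated period", {
  out <- scenario_matrix_shift(N = 150, mu = 0.005, e = 0.025, onset = 6,
                               shift_period = 400, n_periods = 1600,
                               n_reps = 4, seed = 57, burn_in = 100)
  traj <- out$mean_trajectory[, 1, "female"]
  pre <- mean(traj[300:400])
  post <- mean(traj[1500:1600])
  # selection held the allele down before the shift; once males prefer
  # young females, recurrent mutation lifts it toward fixation
  expect_gt(post, pre + 0.15)
})
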
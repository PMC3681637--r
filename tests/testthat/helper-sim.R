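# Shared miniature inputs for the unit and property suites.

flat_tables <- function(surv = 0.95, fert = 0.9, fert_from = 3L,
                        fert_to = 17L) {
  s <- c(rep(surv, 17), 0)
  f <- numeric(18)
  f[fert_from:fert_to] <- fert
  life_tables(survival = s, fertility = f)
}

# Mating matrix that accepts every pair (classes 1..18), for tests where
# pair rejection should never occur.
all_ones_matrix <- function() {
  mating_matrix("custom", M = matrix(1, 18, 18))
}

# A pool in the population layout: ages + genotype matrix.
pool <- function(ages, geno) {
  geno <- matrix(as.integer(geno), nrow = length(ages))
  list(age = as.integer(ages), geno = geno)
}

small_config <- function(N = 30, loci = locus_set("mortality", "both", 6),
                         n_periods = 10, burn_in = 5, ...) {
  sim_config(N = N, loci = loci, tables = flat_tables(),
             matrix = all_ones_matrix(), n_periods = n_periods,
             burn_in = burn_in, ...)
}
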
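# Preference matrices and the birth rejection loop.

test_that("stylised matrices have the right support", {
  ap <- mating_matrix("AP", adult_min = 3)
  expect_equal(ap[2, 10], 0)   # pre-adult male never pairs
  expect_equal(ap[3, 3], 1)
  expect_equal(ap[17, 17], 1)

  yf <- mating_matrix("YF", young = c(4, 7))
  expect_equal(yf[15, 5], 1)   # old male, young female
  expect_equal(yf[5, 15], 0)   # young male, old female
  expect_true(all(yf[, c(1:3, 8:18)] == 0))

  yp <- mating_matrix("YP", young = c(4, 7))
  nz <- which(unclass(yp) > 0, arr.ind = TRUE)
  expect_true(all(nz >= 4 & nz <= 7))

  expect_error(mating_matrix("YP", young = c(8, 7)), "young window")
  expect_error(mating_matrix("AP", adult_min = 2), "adult_min")
})

test_that("custom matrices round-trip and validate", {
  m <- matrix(stats::runif(18 * 18), 18, 18)
  mm <- mating_matrix("custom", M = m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mating_matrix(mm, path)
  back <- read_mating_matrix(path)
  expect_equal(unclass(back)[1:18, 1:18], m, tolerance = 1e-12)

  bad <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(m[1:17, ], bad, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  expect_error(read_mating_matrix(bad), "18 x 18")
  expect_error(mating_matrix("custom", M = m * 2), "\\[0, 1\\]")
})

test_that("all-accepting configuration succeeds on the first attempt", {
  tab <- flat_tables(fert = 1, fert_from = 1L, fert_to = 17L)
  loci <- locus_set("mortality", "both", 6)
  males <- pool(c(5, 9, 12), rep(0, 3))
  females <- pool(c(4, 8), rep(0, 2))
  set.seed(5)
  draws <- replicate(300, simplify = FALSE,
    simulate_birth(males, females, all_ones_matrix(), tab, loci))
  expect_true(all(vapply(draws, `[[`, 0, "attempts") == 1))
  # parents uniform over pools: father index 1..3 roughly equally often
  fa <- vapply(draws, `[[`, 0, "father")
  expect_gt(min(table(fa)), 60)   # expected 100 each, 3 SE ~ 24
})

test_that("an infertile population raises a no-fertile-pairs error", {
  tab <- flat_tables(fert = 0, fert_from = 3L, fert_to = 17L)
  loci <- locus_set("mortality", "both", 6)
  males <- pool(5, 0); females <- pool(5, 0)
  set.seed(1)
  expect_error(
    simulate_birth(males, females, all_ones_matrix(), tab, loci,
                   max_attempts = 100),
    "no fertile pairs")
})

test_that("matrix-rejected males can never father", {
  # AP matrix: class-2 male always rejected, class-5 male always accepted
  tab <- flat_tables(fert = 1, fert_from = 1L, fert_to = 17L)
  loci <- locus_set("mortality", "both", 6)
  males <- pool(c(2, 5), rep(0, 2))
  females <- pool(5, 0)
  set.seed(9)
  fa <- replicate(200,
    simulate_birth(males, females, mating_matrix("AP"), tab, loci)$father)
  expect_true(all(fa == 2))
})

test_that("accepted pair ages follow the enumerated product distribution", {
  # pools of <= 5 per sex with mixed ages and genotypes; conditional on
  # acceptance, P(father i, mother j) is proportional to
  # M[age_i, age_j] * F_m(i) * F_f(j) -- enumerate exactly and compare.
  tab <- flat_tables(fert = 0.8, fert_from = 3L, fert_to = 9L)
  loci <- locus_set("fertility", "both", onset = 5, e = 0.5)
  males <- pool(c(4, 5, 6, 8), c(0, 1, 2, 0))
  females <- pool(c(4, 6, 7), c(2, 0, 1))
  M <- mating_matrix("YF", young = c(4, 7))

  fert_of <- function(sex, age, cnt)
    effective_fertility(individual(sex, age, cnt), tab, loci)
  fm <- mapply(fert_of, "male", males$age, males$geno)
  ff <- mapply(fert_of, "female", females$age, females$geno)
  w <- outer(seq_along(fm), seq_along(ff),
             function(i, j) unclass(M)[cbind(males$age[i], females$age[j])] *
               fm[i] * ff[j])
  p_exact <- w / sum(w)

  set.seed(123)
  n <- 4000
  counts <- matrix(0, length(fm), length(ff))
  for (k in seq_len(n)) {
    b <- simulate_birth(males, females, M, tab, loci)
    counts[b$father, b$mother] <- counts[b$father, b$mother] + 1
  }
  p_hat <- counts / n
  se <- sqrt(p_exact * (1 - p_exact) / n)
  expect_true(all(abs(p_hat - p_exact) <= 3 * se + 1e-9))
})

test_that("a late-onset female fertility locus is invisible to young-female mating", {
  # onset above the YF female window: carriers' birth probabilities match
  # wild types exactly, so the matrix exerts no selection on the locus
  tab <- default_life_tables("prolonged")
  loci <- locus_set("fertility", "female", onset = 9, e = 0.5)
  M <- mating_matrix("YF", young = c(4, 7))
  for (age in 4:7) {
    mut <- effective_fertility(individual("female", age, 2), tab, loci)
    wt <- effective_fertility(individual("female", age, 0), tab, loci)
    expect_identical(mut, wt)
  }
})
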
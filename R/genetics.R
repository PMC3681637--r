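#' Construct an individual
#'
#' An individual is a sex, an age class (1..18), and a diploid genotype:
#' the count of mutant alleles (0, 1, or 2) at each locus.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_class integer age class in 1..18.
#' @param genotype integer vector of per-locus mutant-allele counts.
#' @return A list of class `"individual"`.
#' @export
individual <- function(sex = c("male", "female"), age_class, genotype) {
  sex <- match.arg(sex)
  age_class <- as.integer(age_class)
  genotype <- as.integer(genotype)
  if (age_class < 1L || age_class > 18L)
    stop("age_class must lie in 1..18", call. = FALSE)
  if (any(genotype < 0L | genotype > 2L))
    stop("genotype counts must be 0, 1, or 2", call. = FALSE)
  structure(list(sex = sex, age_class = age_class, genotype = genotype),
            class = "individual")
}

#' Mendelian gamete from a diploid parent
#'
#' Per locus: a homozygous mutant parent transmits the mutant allele with
#' certainty, a heterozygote with probability 1/2, a wild-type homozygote
#' never.  Loci segregate independently (free recombination, autosomal).
#'
#' @param genotype integer vector of mutant-allele counts (0/1/2 per locus).
#' @return Integer 0/1 vector: the transmitted allele at each locus.
#' @examples
#' set.seed(1)
#' transmit_gamete(c(2, 0, 1))
#' @export
transmit_gamete <- function(genotype) {
  genotype <- as.integer(genotype)
  if (any(genotype < 0L | genotype > 2L))
    stop("genotype counts must be 0, 1, or 2", call. = FALSE)
  cpp_gamete(genotype, numeric(length(genotype)), FALSE)
}

#' Form a newborn genotype from two gametes, with new mutations
#'
#' Each wild-type allele copy mutates independently to the mutant state with
#' its locus rate `mu`; mutant alleles never revert (no back mutation).  The
#' newborn's count at a locus is the sum of its two post-mutation alleles.
#'
#' @param gamete_father,gamete_mother integer 0/1 vectors of equal length.
#' @param loci a [locus_set()] supplying per-locus `mu`.
#' @param mutation_on logical; `FALSE` suppresses mutation (burn-in).
#' @return Integer vector of mutant-allele counts (a newborn genotype).
#' @export
mutate_newborn <- function(gamete_father, gamete_mother, loci,
                           mutation_on = TRUE) {
  gf <- as.integer(gamete_father)
  gm <- as.integer(gamete_mother)
  mu <- as.numeric(loci$mu)
  if (length(gf) != length(gm) || length(gf) != length(mu))
    stop("gametes and loci must have the same number of loci", call. = FALSE)
  if (!mutation_on) return(gf + gm)
  cpp_mutate_alleles(gf, mu) + cpp_mutate_alleles(gm, mu)
}

# Pure-R multiplicative load on a vital rate; reference implementation,
# cross-checked in tests against the C++ engine's load factor.
load_factor_r <- function(ind, loci, type) {
  f <- 1
  for (k in seq_len(nrow(loci))) {
    if (loci$effect[k] != type) next
    sc <- loci$scope[k]
    if (sc == "male" && ind$sex != "male") next
    if (sc == "female" && ind$sex != "female") next
    if (ind$age_class < loci$onset[k]) next
    cnt <- ind$genotype[k]
    if (cnt == 1L) f <- f * (1 - loci$h[k] * loci$e[k])
    else if (cnt == 2L) f <- f * (1 - loci$e[k])^2
  }
  min(max(f, 0), 1)
}

#' Effective survival and fertility of an individual
#'
#' The intrinsic per-age-class probability from the life tables, multiplied
#' by the individual's genetic load: each expressed mutant allele at an
#' active locus of the matching effect type scales the probability by
#' `1 - e` (codominant default; see [locus_set()]).  A locus is active when
#' the individual's age class has reached the locus onset and its sex falls
#' within the locus scope.  Class-18 individuals have survival 0.
#'
#' @param ind an [individual()].
#' @param tables a [life_tables()] object.
#' @param loci a [locus_set()].
#' @return A probability in `[0, 1]`.
#' @examples
#' tab <- default_life_tables()
#' loci <- locus_set("mortality", "both", onset = 6, e = 0.025)
#' old <- individual("female", 10, genotype = 2)
#' effective_survival(old, tab, loci) # intrinsic * (1 - 0.025)^2
#' @export
effective_survival <- function(ind, tables, loci) {
  s <- tables$survival[ind$age_class, ind$sex]
  min(max(s * load_factor_r(ind, loci, "mortality"), 0), 1)
}

#' @rdname effective_survival
#' @export
effective_fertility <- function(ind, tables, loci) {
  f <- tables$fertility[ind$age_class, ind$sex]
  min(max(f * load_factor_r(ind, loci, "fertility"), 0), 1)
}
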
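#' Define a set of mutable loci
#'
#' Each locus carries a deleterious mutant allele with an age-dependent
#' effect: at and beyond `onset` (an age class in 1..18) the allele reduces
#' either survival (`effect = "mortality"`) or the probability of
#' contributing to a birth when mated (`effect = "fertility"`), in the sexes
#' selected by `scope`.  Effects are multiplicative per genotype: a
#' heterozygote's rate is scaled by `1 - h * e`, a homozygote's by
#' `(1 - e)^2` (`h = 1` gives codominant per-copy action `(1 - e)` per
#' allele).
#'
#' Arguments are recycled to a common length, one locus per element.
#'
#' @param effect `"mortality"` or `"fertility"`.
#' @param scope `"both"`, `"male"`, or `"female"`: the sexes in which the
#'   allele is expressed.
#' @param onset age class (integer in 1..18) at which expression begins.
#' @param e selection strength per allele, in `[0, 1]`: each expressed
#'   allele multiplies the affected probability by `1 - e`.
#' @param mu mutation rate toward the mutant allele, in `[0, 1)`; see
#'   [sim_config()]'s `mu_convention` for the per-copy vs per-locus reading.
#' @param h dominance coefficient in `[0, 1]` for the heterozygote
#'   (default 1, codominant per-copy multiplicative action).
#' @param init_freq initial mutant allele frequency assigned at population
#'   initialisation (default 0: founders are wild type).
#' @return A data frame of class `"locus_set"` with one row per locus and
#'   columns `id`, `effect`, `scope`, `onset`, `e`, `mu`, `h`, `init_freq`.
#' @examples
#' # Five sex-indifferent mortality loci with onsets spanning mid life
#' locus_set(effect = "mortality", scope = "both", onset = 6:10)
#' @export
locus_set <- function(effect = "mortality", scope = "both", onset,
                      e = 0.025, mu = 0.005, h = 1, init_freq = 0) {
  effect <- match_each(effect, c("mortality", "fertility"))
  scope <- match_each(scope, c("both", "male", "female"))
  n <- max(length(effect), length(scope), length(onset), length(e),
           length(mu), length(h), length(init_freq))
  loci <- data.frame(
    id = seq_len(n),
    effect = rep_len(effect, n),
    scope = rep_len(scope, n),
    onset = as.integer(rep_len(onset, n)),
    e = rep_len(e, n),
    mu = rep_len(mu, n),
    h = rep_len(h, n),
    init_freq = rep_len(init_freq, n),
    stringsAsFactors = FALSE
  )
  validate_locus_set(loci)
  class(loci) <- c("locus_set", "data.frame")
  loci
}

#' @rdname locus_set
#' @export
locus <- function(effect = "mortality", scope = "both", onset,
                  e = 0.025, mu = 0.005, h = 1, init_freq = 0) {
  stopifnot(length(onset) == 1L)
  locus_set(effect, scope, onset, e, mu, h, init_freq)
}

match_each <- function(x, choices) {
  vapply(as.character(x), function(v) match.arg(v, choices), "")
}

validate_locus_set <- function(loci) {
  with(loci, {
    if (any(onset < 1L | onset > 18L))
      stop("locus onset class must lie in 1..18", call. = FALSE)
    if (any(e < 0 | e > 1)) stop("e must lie in [0, 1]", call. = FALSE)
    if (any(mu < 0 | mu >= 1)) stop("mu must lie in [0, 1)", call. = FALSE)
    if (any(h < 0 | h > 1)) stop("h must lie in [0, 1]", call. = FALSE)
    if (any(init_freq < 0 | init_freq > 1))
      stop("init_freq must lie in [0, 1]", call. = FALSE)
  })
  invisible(loci)
}

#' Combine locus sets
#'
#' @param ... `locus_set` objects.
#' @return A single `locus_set`; ids are renumbered 1..L.
#' @export
c.locus_set <- function(...) {
  parts <- lapply(list(...), as.data.frame)
  loci <- do.call(rbind, parts)
  loci$id <- seq_len(nrow(loci))
  validate_locus_set(loci)
  class(loci) <- c("locus_set", "data.frame")
  loci
}

# Integer encodings shared with the C++ engine.
loci_codes <- function(loci) {
  list(
    onset = as.integer(loci$onset),
    e = as.numeric(loci$e),
    mu = as.numeric(loci$mu),
    effect = ifelse(loci$effect == "mortality", 0L, 1L),
    scope = c(both = 0L, male = 1L, female = 2L)[loci$scope],
    h = as.numeric(loci$h)
  )
}
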
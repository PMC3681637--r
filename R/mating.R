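#' Mating preference matrices
#'
#' An 18 x 18 matrix `M[i, j]` giving the probability that a randomly drawn
#' male of age class `i` and female of age class `j` form a pair.  Three
#' stylised preference models are built in (binary entries):
#'
#' * `"AP"` (all pairs): any male and female at or beyond `adult_min` pair
#'   with probability 1 — age-indifferent preference.
#' * `"YP"` (young pairs): pairing only when both sexes fall inside the
#'   young window `young[1]..young[2]`.
#' * `"YF"` (young females): males of any adult class pair only with
#'   females inside the young window — male preference for young females.
#'
#' @param model `"AP"`, `"YP"`, `"YF"`, or `"custom"` (then supply `M`).
#' @param young integer length-2: first and last young age class
#'   (default `c(4, 7)`, i.e. roughly ages 15-35).
#' @param adult_min first adult (mating-eligible) age class, `>= 3`
#'   (default 3: mating allowed at all classes after the second).
#' @param M for `model = "custom"`, an 18 x 18 numeric matrix with entries
#'   in `[0, 1]`.
#' @return An 18 x 18 matrix of class `"mating_matrix"` with a `"label"`
#'   attribute.
#' @examples
#' mating_matrix("YF")[15, 5]  # old male, young female: allowed
#' mating_matrix("YF")[5, 15]  # young male, old female: never
#' @export
mating_matrix <- function(model = c("AP", "YP", "YF", "custom"),
                          young = c(4L, 7L), adult_min = 3L, M = NULL) {
  model <- match.arg(model)
  young <- as.integer(young)
  adult_min <- as.integer(adult_min)
  if (length(young) != 2L || young[1] < 1L || young[1] > young[2] ||
      young[2] > 18L)
    stop("young window must satisfy 1 <= young[1] <= young[2] <= 18",
         call. = FALSE)
  if (adult_min < 3L)
    stop("adult_min must be >= 3 (classes 1-2 never mate)", call. = FALSE)
  i <- matrix(1:18, 18, 18)         # male age class (rows)
  j <- t(i)                         # female age class (columns)
  m <- switch(model,
    AP = (i >= adult_min) & (j >= adult_min),
    YP = (i >= young[1] & i <= young[2]) & (j >= young[1] & j <= young[2]),
    YF = (i >= adult_min) & (j >= young[1] & j <= young[2]),
    custom = {
      if (is.null(M)) stop("custom model requires M", call. = FALSE)
      NULL
    })
  m <- if (model == "custom") as.matrix(M) else m + 0
  if (!all(dim(m) == c(18L, 18L)))
    stop("mating matrix must be 18 x 18", call. = FALSE)
  if (any(is.na(m)) || any(m < 0 | m > 1))
    stop("mating matrix entries must lie in [0, 1]", call. = FALSE)
  dimnames(m) <- NULL
  structure(m, class = c("mating_matrix", "matrix"), label = model,
            young = young, adult_min = adult_min)
}

#' Read / write a mating matrix as delimited text
#'
#' An 18 x 18 tab-separated numeric table, rows = male age class 1..18,
#' columns = female age class 1..18, no header.
#'
#' @param path file path.
#' @param matrix a [mating_matrix()].
#' @return `read_mating_matrix()` a `"custom"`-labelled [mating_matrix()];
#'   `write_mating_matrix()` the path, invisibly.
#' @export
read_mating_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  if (!all(dim(m) == c(18L, 18L)))
    stop("mating matrix file must be 18 x 18 (got ",
         paste(dim(m), collapse = " x "), ")", call. = FALSE)
  mating_matrix("custom", M = m)
}

#' @rdname read_mating_matrix
#' @export
write_mating_matrix <- function(matrix, path) {
  utils::write.table(unclass(matrix)[, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.mating_matrix <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Mating preference matrix (", lab, "), 18 x 18\n", sep = "")
  nz <- which(unclass(x) > 0, arr.ind = TRUE)
  if (nrow(nz)) {
    cat("  male classes ", min(nz[, 1]), "-", max(nz[, 1]),
        " x female classes ", min(nz[, 2]), "-", max(nz[, 2]),
        " (", nrow(nz), " nonzero entries)\n", sep = "")
  } else cat("  all entries zero\n")
  invisible(x)
}

#' Draw one mating pair and birth by rejection sampling
#'
#' Repeats the birth loop: draw a father uniformly from the male pool and a
#' mother uniformly from the female pool, accept the pair with probability
#' `M[i, j]` for their age classes, then let a birth occur with probability
#' `effective_fertility(father) * effective_fertility(mother)` — both
#' parents must be fertile.  The loop runs until a birth occurs; after
#' `max_attempts` failures it errors (a degenerate configuration in which
#' reproduction is impossible, e.g. all fertilities zero).
#'
#' Pools are sampled with replacement and are not depleted: one individual
#' may parent several newborns within a period.
#'
#' @param males,females parent pools: lists with integer vector `age` and
#'   integer genotype matrix `geno` (individuals x loci), as in the
#'   population object returned by [init_population()].
#' @param matrix a [mating_matrix()].
#' @param tables a [life_tables()] object.
#' @param loci a [locus_set()].
#' @param max_attempts attempts before declaring no fertile pairs
#'   (default 1e6).
#' @return List with `father` and `mother` (indices into the pools) and
#'   `attempts` (draws used).
#' @export
simulate_birth <- function(males, females, matrix, tables, loci,
                           max_attempts = 1e6) {
  if (!length(males$age) || !length(females$age))
    stop("both parent pools must be non-empty", call. = FALSE)
  cd <- loci_codes(loci)
  cpp_simulate_birth(
    as.integer(males$age), geno_matrix(males$geno, nrow(loci)),
    as.integer(females$age), geno_matrix(females$geno, nrow(loci)),
    tables$fertility[, "male"], tables$fertility[, "female"],
    unclass(matrix),
    cd$onset, cd$e, cd$mu, cd$effect, cd$scope, cd$h,
    max_attempts
  )
}

geno_matrix <- function(g, L) {
  g <- as.matrix(g)
  storage.mode(g) <- "integer"
  if (ncol(g) != L) stop("genotype matrix has wrong locus count",
                         call. = FALSE)
  g
}
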
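#' Gompertz-Makeham per-period survival probabilities
#'
#' Discrete-age survival under a Gompertz-Makeham hazard: the probability of
#' surviving age class `x` (and advancing to `x + 1`) is
#' `exp(-(A + B * exp(C * x)))`.  `A` is the age-independent (Makeham)
#' hazard per period, `B` the baseline age-dependent hazard, and `C` the
#' exponential rate of senescence per age class.  The final class always
#' has survival 0 (the life cycle is truncated there).
#'
#' @param A age-independent hazard per period, `>= 0`.
#' @param B baseline age-dependent hazard, `> 0`.
#' @param C exponential hazard rate per age class, `> 0`.
#' @param n_classes number of age classes (default 18).
#' @return Numeric vector of length `n_classes`; strictly decreasing over
#'   classes `1..n_classes-1`, with 0 in the last class.
#' @examples
#' gompertz_makeham_survival(A = 0.01, B = 1e-4, C = 0.5)
#' @export
gompertz_makeham_survival <- function(A = 0.01, B = 1e-4, C = 0.5,
                                      n_classes = 18L) {
  if (A < 0) stop("A must be >= 0", call. = FALSE)
  if (B <= 0) stop("B must be > 0", call. = FALSE)
  if (C <= 0) stop("C must be > 0", call. = FALSE)
  if (n_classes < 1) stop("n_classes must be >= 1", call. = FALSE)
  x <- seq_len(n_classes)
  s <- exp(-(A + B * exp(C * x)))
  s[n_classes] <- 0
  s
}

#' Intrinsic life tables
#'
#' Per-sex, per-age-class intrinsic survival and fertility probabilities.
#' `survival[x, sex]` is the probability that an individual in age class
#' `x` survives the period and advances to class `x + 1`;
#' `fertility[x, sex]` the probability that an individual of class `x`, if
#' mated, contributes to a birth.  Class-18 survival must be 0: all
#' individuals in the final class die.
#'
#' Vectors are recycled to both sexes; supply 18 x 2 matrices (columns
#' `male`, `female`) for sex-specific tables.
#'
#' @param survival,fertility length-18 vectors or 18 x 2 matrices of
#'   probabilities.
#' @return A list of class `"life_tables"` with 18 x 2 matrices `survival`
#'   and `fertility` (columns `male`, `female`).
#' @seealso [default_life_tables()], [gompertz_makeham_survival()]
#' @export
life_tables <- function(survival, fertility) {
  as_tab <- function(x, what) {
    if (is.vector(x)) x <- cbind(male = x, female = x)
    x <- as.matrix(x)
    if (!all(dim(x) == c(18L, 2L)))
      stop(what, " table must be length 18 (or 18 x 2)", call. = FALSE)
    colnames(x) <- c("male", "female")
    rownames(x) <- NULL
    if (any(x < 0 | x > 1))
      stop(what, " probabilities must lie in [0, 1]", call. = FALSE)
    x
  }
  survival <- as_tab(survival, "survival")
  fertility <- as_tab(fertility, "fertility")
  if (any(survival[18L, ] != 0))
    stop("survival in age class 18 must be 0 (forced death)", call. = FALSE)
  structure(list(survival = survival, fertility = fertility),
            class = "life_tables")
}

#' Default intrinsic life tables
#'
#' Survival follows a Gompertz-Makeham schedule (`A = 0.01`, `B = 1e-4`,
#' `C = 0.5`) for both sexes: high (> 0.9) through mid life, declining at
#' late classes, 0 at class 18.  Two fertility schedules are provided:
#'
#' * `"prolonged"`: fertility 0 in juvenile classes 1-3, a plateau of 0.9
#'   over classes 4-17, 0 at 18, identical in both sexes — the ancestral
#'   state in which neither sex has an intrinsic fertility decline.
#' * `"declining_female"`: males as in `"prolonged"`; female fertility
#'   plateaus at 0.9 over classes 4-9 and is 0 from class 10 on — a fixed
#'   intrinsic loss of late female fertility, used in mortality-only
#'   experiments.
#'
#' @param fertility `"prolonged"` or `"declining_female"`.
#' @param plateau fertility level on the fertile plateau (default 0.9).
#' @return A [life_tables()] object.
#' @export
default_life_tables <- function(fertility = c("prolonged",
                                              "declining_female"),
                                plateau = 0.9) {
  fertility <- match.arg(fertility)
  surv <- gompertz_makeham_survival()
  fert_prolonged <- c(rep(0, 3), rep(plateau, 14), 0)
  fert_f <- if (fertility == "prolonged") fert_prolonged
            else c(rep(0, 3), rep(plateau, 6), rep(0, 9))
  life_tables(survival = surv,
              fertility = cbind(male = fert_prolonged, female = fert_f))
}

#' Read / write life tables as delimited text
#'
#' Tab-separated with columns `age_class`, `male_survival`,
#' `female_survival`, `male_fertility`, `female_fertility`, one row per age
#' class 1..18.
#'
#' @param path file path.
#' @param tables a [life_tables()] object.
#' @return `read_life_tables()` a [life_tables()] object;
#'   `write_life_tables()` the path, invisibly.
#' @export
read_life_tables <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("age_class", "male_survival", "female_survival",
            "male_fertility", "female_fertility")
  if (!identical(names(d), need))
    stop("life-table file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!identical(as.integer(d$age_class), 1:18))
    stop("life-table file must have age classes 1..18 in order",
         call. = FALSE)
  life_tables(
    survival = cbind(male = d$male_survival, female = d$female_survival),
    fertility = cbind(male = d$male_fertility, female = d$female_fertility)
  )
}

#' @rdname read_life_tables
#' @export
write_life_tables <- function(tables, path) {
  d <- data.frame(
    age_class = 1:18,
    male_survival = tables$survival[, "male"],
    female_survival = tables$survival[, "female"],
    male_fertility = tables$fertility[, "male"],
    female_fertility = tables$fertility[, "female"]
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.life_tables <- function(x, ...) {
  cat("Intrinsic life tables (18 age classes, 5-year periods)\n")
  cat("  survival : male", format_range(x$survival[, "male"]),
      "| female", format_range(x$survival[, "female"]), "\n")
  cat("  fertility: male", format_range(x$fertility[, "male"]),
      "| female", format_range(x$fertility[, "female"]), "\n")
  invisible(x)
}

format_range <- function(v) {
  pos <- which(v > 0)
  if (!length(pos)) return("all zero")
  sprintf("classes %d-%d (max %.3g)", min(pos), max(pos), max(v))
}
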
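#' Deterministic miniature fixtures for tests and examples
#'
#' * `"tiny_pop"`: an N = 10 configuration (two mortality loci) plus an
#'   initialised population drawn under `seed`.
#' * `"toy_tables"`: life tables with 6 effective age classes (survival 0
#'   from class 6 on), survival 0.95 and fertility 0.9 on classes the
#'   schedule leaves open — small enough for exhaustive oracle checks.
#' * `"toy_matrix"`: the age-indifferent (AP) matrix.
#'
#' @param kind `"tiny_pop"`, `"toy_tables"`, or `"toy_matrix"`.
#' @param seed RNG seed used for `"tiny_pop"`.
#' @param dir optional directory; if given, the fixture is also written
#'   there as delimited text / YAML.
#' @return The fixture object (a list for `"tiny_pop"`).
#' @export
make_fixture <- function(kind = c("tiny_pop", "toy_tables", "toy_matrix"),
                         seed = 1L, dir = NULL) {
  kind <- match.arg(kind)
  out <- switch(kind,
    toy_matrix = mating_matrix("AP"),
    toy_tables = {
      surv <- c(rep(0.95, 5), rep(0, 13))
      fert <- c(0, 0, rep(0.9, 3), rep(0, 13))
      life_tables(survival = surv, fertility = fert)
    },
    tiny_pop = {
      cfg <- sim_config(
        N = 10L,
        loci = locus_set("mortality", "both", onset = c(3L, 5L)),
        tables = make_fixture("toy_tables"),
        matrix = mating_matrix("AP"),
        n_periods = 10L, burn_in = 5L, seed = as.integer(seed)
      )
      set.seed(seed)
      list(config = cfg, pop = init_population(cfg))
    })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    switch(kind,
      toy_matrix = write_mating_matrix(out, file.path(dir, "matrix.tsv")),
      toy_tables = write_life_tables(out, file.path(dir, "tables.tsv")),
      tiny_pop = save_config(out$config, file.path(dir, "config.yaml")))
  }
  out
}
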
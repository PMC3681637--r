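#' Load / save a run configuration
#'
#' Configurations are YAML key/value files.  Recognised top-level keys:
#' `N`, `loci`, `tables`, `matrix`, `n_periods`, `burn_in`, `seed`,
#' `shift`, `mu_convention`, `max_attempts`, `curve_periods`, `young`,
#' `adult_min`.  Unknown keys are rejected with their key path.
#'
#' `loci` is a list of maps with keys `effect`, `scope`, `onset` and
#' optional `e`, `mu`, `h`, `init_freq`.  `matrix` is `"AP"`, `"YP"`,
#' `"YF"`, a path to an 18 x 18 delimited table, or an inline list of 18
#' rows.  `tables` is `"prolonged"`, `"declining_female"`, a path to a
#' delimited life table (see [read_life_tables()]), or an inline map with
#' `male_survival`, `female_survival`, `male_fertility`,
#' `female_fertility`.  `shift` is a map with `period` and `matrix`.
#' Omitted keys take the [sim_config()] defaults.
#'
#' `save_config()` writes the fully expanded configuration (tables and
#' matrices inline), so a saved file reloads to an equal configuration.
#'
#' @param path file path.
#' @param config a [sim_config()].
#' @return `load_config()` a validated [sim_config()]; `save_config()` the
#'   path, invisibly.
#' @export
load_config <- function(path) {
  # keep bare Y/N/yes/no tokens (e.g. the key "N") as strings, not booleans
  raw <- yaml::read_yaml(path,
                         handlers = list("bool#no" = function(x) x,
                                         "bool#yes" = function(x) x))
  known <- c("N", "loci", "tables", "matrix", "n_periods", "burn_in",
             "seed", "shift", "mu_convention", "max_attempts",
             "curve_periods", "young", "adult_min")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (key in c("N", "loci", "n_periods"))
    if (is.null(raw[[key]]))
      stop("config key '", key, "' is required", call. = FALSE)

  young <- if (is.null(raw$young)) c(4L, 7L) else as.integer(raw$young)
  adult_min <- if (is.null(raw$adult_min)) 3L else as.integer(raw$adult_min)

  loci <- parse_loci(raw$loci)
  matrix <- parse_matrix(raw$matrix, young, adult_min)
  tables <- parse_tables(raw$tables)
  shift <- if (!is.null(raw$shift)) {
    if (is.null(raw$shift$period) || is.null(raw$shift$matrix))
      stop("config key 'shift' needs 'shift.period' and 'shift.matrix'",
           call. = FALSE)
    list(period = raw$shift$period,
         matrix = parse_matrix(raw$shift$matrix, young, adult_min))
  }

  args <- list(N = raw$N, loci = loci, tables = tables, matrix = matrix,
               n_periods = raw$n_periods, shift = shift)
  for (key in c("burn_in", "seed", "mu_convention", "max_attempts",
                "curve_periods"))
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  do.call(sim_config, args)
}

parse_loci <- function(x) {
  if (is.null(x) || !is.list(x) || !length(x))
    stop("config key 'loci' must be a non-empty list", call. = FALSE)
  rows <- lapply(seq_along(x), function(k) {
    lc <- x[[k]]
    bad <- setdiff(names(lc),
                   c("effect", "scope", "onset", "e", "mu", "h",
                     "init_freq"))
    if (length(bad))
      stop("unknown key(s) in loci[", k, "]: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (is.null(lc$onset))
      stop("loci[", k, "].onset is required", call. = FALSE)
    do.call(locus_set, lc)
  })
  do.call(c, rows)
}

parse_matrix <- function(x, young, adult_min) {
  if (is.null(x)) x <- "AP"
  if (is.character(x) && length(x) == 1L) {
    if (x %in% c("AP", "YP", "YF"))
      return(mating_matrix(x, young = young, adult_min = adult_min))
    return(read_mating_matrix(x))
  }
  m <- do.call(rbind, lapply(x, as.numeric))
  mating_matrix("custom", M = m)
}

parse_tables <- function(x) {
  if (is.null(x)) x <- "prolonged"
  if (is.character(x) && length(x) == 1L) {
    if (x %in% c("prolonged", "declining_female"))
      return(default_life_tables(x))
    return(read_life_tables(x))
  }
  need <- c("male_survival", "female_survival", "male_fertility",
            "female_fertility")
  if (!all(need %in% names(x)))
    stop("inline 'tables' needs keys: ", paste(need, collapse = ", "),
         call. = FALSE)
  life_tables(
    survival = cbind(male = as.numeric(x$male_survival),
                     female = as.numeric(x$female_survival)),
    fertility = cbind(male = as.numeric(x$male_fertility),
                      female = as.numeric(x$female_fertility))
  )
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  loci <- lapply(seq_len(nrow(config$loci)), function(k) {
    r <- config$loci[k, ]
    list(effect = r$effect, scope = r$scope, onset = r$onset,
         e = r$e, mu = r$mu, h = r$h, init_freq = r$init_freq)
  })
  mat_out <- function(m) lapply(seq_len(18L),
                                function(i) as.numeric(unclass(m)[i, ]))
  out <- list(
    N = config$N,
    loci = loci,
    tables = list(
      male_survival = as.numeric(config$tables$survival[, "male"]),
      female_survival = as.numeric(config$tables$survival[, "female"]),
      male_fertility = as.numeric(config$tables$fertility[, "male"]),
      female_fertility = as.numeric(config$tables$fertility[, "female"])
    ),
    matrix = mat_out(config$matrix),
    n_periods = config$n_periods,
    burn_in = config$burn_in,
    seed = config$seed,
    mu_convention = config$mu_convention,
    max_attempts = config$max_attempts,
    curve_periods = config$curve_periods
  )
  if (!is.null(config$shift))
    out$shift <- list(period = config$shift$period,
                      matrix = mat_out(config$shift$matrix))
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Write / read simulation outputs as delimited text
#'
#' `write_result()` writes `trajectory.tsv` (period, locus, sex,
#' frequency) and `curves.tsv` (sex, age_class, survival, fertility) into
#' `dir`; for replicate summaries it also writes `summary.tsv` (locus,
#' onset, effect, scope, sex, mean_freq, se).  `read_result()` reads them
#' back as data frames.
#'
#' @param result a `sim_result` or `sim_replicates`.
#' @param dir output directory (created if missing).
#' @return `write_result()` the directory, invisibly; `read_result()` a
#'   list of data frames.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  freq <- if (inherits(result, "sim_replicates")) result$mean_trajectory
          else result$freq
  curves <- if (inherits(result, "sim_replicates")) result$mean_curves
            else result$curves
  np1 <- dim(freq)[1]
  traj <- data.frame(
    period = rep(seq_len(np1) - 1L, times = dim(freq)[2] * 2L),
    locus = rep(rep(dimnames(freq)[[2]], each = np1), 2L),
    sex = rep(c("male", "female"), each = np1 * dim(freq)[2]),
    frequency = as.vector(freq)
  )
  utils::write.table(traj, file.path(dir, "trajectory.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(curves[, c("sex", "age_class", "survival",
                                "fertility")],
                     file.path(dir, "curves.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (inherits(result, "sim_replicates"))
    utils::write.table(result$summary, file.path(dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_result
#' @export
read_result <- function(dir) {
  out <- list(
    trajectory = utils::read.table(file.path(dir, "trajectory.tsv"),
                                   header = TRUE, sep = "\t"),
    curves = utils::read.table(file.path(dir, "curves.tsv"),
                               header = TRUE, sep = "\t")
  )
  sf <- file.path(dir, "summary.tsv")
  if (file.exists(sf))
    out$summary <- utils::read.table(sf, header = TRUE, sep = "\t")
  out
}
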
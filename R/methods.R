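#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat("  N           :", x$N, "per sex\n")
  cat("  loci        :", nrow(x$loci), "(",
      sum(x$loci$effect == "mortality"), "mortality,",
      sum(x$loci$effect == "fertility"), "fertility )\n")
  cat("  matrix      :", attr(x$matrix, "label"), "\n")
  cat("  periods     :", x$n_periods, "( burn-in", x$burn_in, ")\n")
  if (!is.null(x$shift))
    cat("  shift       : to", attr(x$shift$matrix, "label"),
        "at period", x$shift$period, "\n")
  cat("  mu convention:", x$mu_convention, "\n")
  invisible(x)
}

#' @export
print.population <- function(x, ...) {
  cat("Population at period", x$period, ":",
      length(x$males$age), "males,", length(x$females$age), "females,",
      ncol(x$males$geno), "loci\n")
  invisible(x)
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Two-sex simulation result:", x$config$n_periods, "periods, N =",
      x$config$N, "per sex, seed", x$seed, "\n")
  if (!is.na(x$absorbed_at))
    cat("  all loci absorbed at period", x$absorbed_at, "\n")
  ff <- final_frequencies(x)
  cat("Final mutant-allele frequencies:\n")
  print(round(ff, 4))
  invisible(x)
}

#' @export
summary.sim_result <- function(object, ...) {
  ff <- final_frequencies(object)
  loci <- object$config$loci
  out <- data.frame(locus = loci$id, effect = loci$effect,
                    scope = loci$scope, onset = loci$onset,
                    freq_male = ff[, "male"], freq_female = ff[, "female"])
  class(out) <- c("summary.sim_result", "data.frame")
  out
}

#' @export
print.summary.sim_result <- function(x, ...) {
  cat("Final mutant-allele frequencies by locus\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
print.sim_replicates <- function(x, ...) {
  cat("Replicate summary:", x$n_reps, "replicates, N =", x$config$N,
      "per sex,", x$config$n_periods, "periods\n")
  s <- x$summary[x$summary$sex == "female", ]
  cat("Female mutant-allele frequencies (mean over replicates, SE):\n")
  print.data.frame(s, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.sim_replicates <- function(object, ...) object$summary

#' Plot a simulation result
#'
#' `type = "trajectory"` draws per-locus female (solid) and male (dashed)
#' mutant-frequency trajectories; `type = "curves"` draws the end-state
#' effective survivorship and fertility curves against the intrinsic
#' tables (dotted), one panel per sex.
#'
#' @param x a `sim_result`.
#' @param type `"trajectory"` or `"curves"`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sim_result <- function(x, type = c("trajectory", "curves"), ...) {
  type <- match.arg(type)
  if (type == "trajectory") {
    plot_trajectory(x$freq, x$config, ...)
  } else {
    plot_curves(x$curves, x$config)
  }
  invisible(x)
}

#' Plot replicate means
#'
#' Like [plot.sim_result()] but for across-replicate mean trajectories and
#' mean end-state curves.
#'
#' @param x a `sim_replicates`.
#' @param type `"trajectory"` or `"curves"`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sim_replicates <- function(x, type = c("trajectory", "curves"), ...) {
  type <- match.arg(type)
  if (type == "trajectory") {
    plot_trajectory(x$mean_trajectory, x$config, ...)
  } else {
    plot_curves(x$mean_curves, x$config)
  }
  invisible(x)
}

plot_trajectory <- function(freq, config, ...) {
  L <- dim(freq)[2]
  periods <- seq_len(dim(freq)[1]) - 1L
  cols <- grDevices::hcl.colors(max(L, 2L), "Dark 3")[seq_len(L)]
  graphics::matplot(periods, freq[, , "female"], type = "l", lty = 1,
                    col = cols, ylim = c(0, 1), xlab = "period",
                    ylab = "mutant allele frequency", ...)
  graphics::matlines(periods, freq[, , "male"], lty = 2, col = cols)
  if (!is.null(config$shift))
    graphics::abline(v = config$shift$period, col = "grey40", lty = 3)
  graphics::legend("topleft", legend = dimnames(freq)[[2]], col = cols,
                   lty = 1, bty = "n", cex = 0.8)
}

plot_curves <- function(curves, config) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (sx in c("female", "male")) {
    d <- curves[curves$sex == sx, ]
    graphics::plot(d$age_class, d$survival, type = "b", pch = 16,
                   ylim = c(0, 1), xlab = "age class", ylab = "probability",
                   main = sx)
    graphics::lines(d$age_class, d$fertility, type = "b", pch = 1)
    graphics::lines(1:18, config$tables$survival[, sx], lty = 3)
    graphics::lines(1:18, config$tables$fertility[, sx], lty = 2)
    if (sx == "female")
      graphics::legend("bottomleft",
                       c("end survival", "end fertility",
                         "intrinsic survival", "intrinsic fertility"),
                       pch = c(16, 1, NA, NA), lty = c(1, 1, 3, 2),
                       bty = "n", cex = 0.7)
  }
}
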
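# S3 methods for the experiment and report containers.

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  cat("  engine:     ", x$engine, "\n")
  cat("  scheme:     ", x$fitness$scheme, "\n")
  cat("  mutation:   ", x$mutation$mode,
      sprintf("(rate %g/parameter/generation)", x$mutation$per_param_rate), "\n")
  if (x$engine == "explicit")
    cat("  population: N =", x$pop_size, "\n")
  else
    cat("  origin-fixation: Ne =", format(x$origin_fixation$Ne),
        " p0 =", x$origin_fixation$p_init, "\n")
  cat("  generations:", x$total_generations,
      sprintf("(equilibrium at %d)", x$equilibrium_generation), "\n")
  cat("  replicates: ", x$replicates, "  seed:", x$seed, "\n")
  invisible(x)
}

#' @export
print.fluxdrift_experiment <- function(x, ...) {
  print(x$config)
  cat("completed replicates:", length(x$replicates), "\n")
  invisible(x)
}

#' @export
summary.fluxdrift_experiment <- function(object, n_perm = 1e4, n_boot = 1e3,
                                         ...) {
  summarize_experiment(object, n_perm = n_perm, n_boot = n_boot, ...)
}

#' Plot experiment trajectories
#'
#' Median-individual flux and fitness per generation, one line per
#' replicate, with the equilibrium generation marked.
#'
#' @param x A `fluxdrift_experiment`.
#' @param what `"fitness"`, `"flux"`, or `"rate_limiting"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fluxdrift_experiment <- function(x, what = c("fitness", "flux",
                                                  "rate_limiting"), ...) {
  what <- match.arg(what)
  cols <- rainbow(length(x$replicates))
  rng <- range(unlist(lapply(x$replicates, `[[`, what)), na.rm = TRUE)
  plot(NA, xlim = c(0, x$config$total_generations), ylim = rng,
       xlab = "generation", ylab = what, ...)
  for (i in seq_along(x$replicates)) {
    tr <- x$replicates[[i]]
    lines(tr$generation, tr[[what]], col = cols[i])
  }
  abline(v = x$config$equilibrium_generation, lty = 2)
  invisible(x)
}

#' @export
print.fluxdrift_report <- function(x, ...) {
  cat("<fluxdrift report>", x$engine, "engine,", x$scheme, "scheme\n")
  if (x$no_selection)
    cat("  [no selection: run-length statistics are descriptive only]\n")
  tab <- data.frame(mean_run = round(x$mean_run_length, 2),
                    ci_lower = round(x$bootstrap_ci[, "lower"], 2),
                    ci_upper = round(x$bootstrap_ci[, "upper"], 2),
                    proportion = round(x$proportions, 4))
  print(tab)
  cat("permutation p-value (equal mean run lengths):",
      format.pval(x$permutation_p), "\n")
  cat("equilibrium sign balance (share of upward fitness changes):",
      paste(round(x$equilibrium_sign_balance, 3), collapse = " "), "\n")
  if (!is.null(x$alleles)) {
    a <- x$alleles
    cat(sprintf("alleles/parameter: %.2f (sd %.2f, range %.2f-%.2f); forward-only %.2f; neutral expectation %.2f\n",
                a$all_parameters["mean"], a$all_parameters["sd"],
                a$all_parameters["min"], a$all_parameters["max"],
                a$forward_only["mean"], a$expected))
  }
  invisible(x)
}

#' @export
print.allele_summary <- function(x, ...) {
  cat("<allele segregation>", x$n_points, "time points\n")
  cat(sprintf("  all parameters:     mean %.3f sd %.3f min %.3f max %.3f\n",
              x$all_parameters["mean"], x$all_parameters["sd"],
              x$all_parameters["min"], x$all_parameters["max"]))
  cat(sprintf("  forward-only:       mean %.3f sd %.3f min %.3f max %.3f\n",
              x$forward_only["mean"], x$forward_only["sd"],
              x$forward_only["min"], x$forward_only["max"]))
  cat(sprintf("  neutral expectation (2*Ne*mu + 1): %.3f\n", x$expected))
  invisible(x)
}

#' @export
print.runlength_summary <- function(x, ...) {
  cat("<run lengths over", x$n, "generations>\n")
  print(data.frame(mean_run = round(x$mean_run_length, 3),
                   n_runs = lengths(x$runs),
                   proportion = round(x$proportions, 4)))
  invisible(x)
}

#' @export
print.coevolution_result <- function(x, ...) {
  cat("<co-evolution clustering>", ncol(x$correlation), "parameters,",
      x$n_boot, "bootstrap trees\n")
  if (nrow(x$significant)) {
    cat("significant clusters (support >=", 1 - x$alpha, "):\n")
    print(x$significant, row.names = FALSE)
  } else cat("no significant clusters\n")
  if (length(x$unclustered))
    cat("unclustered:", paste(x$unclustered, collapse = ", "), "\n")
  invisible(x)
}

#' Plot the co-evolution dendrogram
#'
#' @param x A `coevolution_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.coevolution_result <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "",
       main = "complete linkage on 1 - |correlation|", ...)
  invisible(x)
}
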
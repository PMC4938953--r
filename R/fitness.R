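# Fitness schemes mapping steady-state behavior to fitness in (0, 1].
# F1: logistic in flux; F2: exponential penalty on the deleterious
# intermediate B; F3: hyperbolic penalty on protein + mRNA synthesis cost.

.default_lengths <- c(A = 450, B = 390, C = 350, D = 510, E = 330)

.schemes <- c("mutation_only", "flux_only", "flux_intermediate", "flux_cost",
              "positive_control")

#' Fitness configuration
#'
#' Constants of the three fitness components and the selection scheme that
#' composes them: `mutation_only` (constant fitness 1, pure mutational
#' process), `flux_only` (F1), `flux_intermediate` (F1*F2, biological
#' mutation), `flux_cost` (F1*F3), `positive_control` (F1*F2 with a neutral
#' mutational distribution, selecting for reaction 1 to become rate
#' limiting).
#'
#' @param scheme One of the five scheme names.
#' @param flux_mid Midpoint of the flux-fitness logistic (650 mmol/l/s).
#' @param flux_slope Slope of the logistic (0.07).
#' @param s_intermediate Toxicity scalar for the deleterious intermediate B
#'   (9.4e-4 l/mmol).
#' @param s_cost Normalizing constant of the expression-cost penalty (1e-6).
#' @param cost_AA Per-residue protein synthesis cost (30.3).
#' @param cost_nuc Per-nucleotide mRNA synthesis cost (49.2).
#' @param lengths Amino-acid lengths of enzymes A-E. The defaults are
#'   surrogate values spanning a realistic glycolytic-enzyme range, distinct
#'   so length-dependent effects are testable.
#' @return List of class `fitness_config`.
#' @export
fitness_config <- function(scheme = "flux_only", flux_mid = 650,
                           flux_slope = 0.07, s_intermediate = 9.4e-4,
                           s_cost = 1.0e-6, cost_AA = 30.3, cost_nuc = 49.2,
                           lengths = .default_lengths) {
  scheme <- match.arg(scheme, .schemes)
  if (length(lengths) != 5L || any(lengths <= 0))
    stop("lengths must be 5 positive enzyme lengths")
  sc <- c(flux_mid, flux_slope, s_intermediate, s_cost, cost_AA, cost_nuc)
  if (any(!is.finite(sc)) || any(sc <= 0))
    stop("all fitness constants must be positive")
  structure(list(scheme = scheme, flux_mid = flux_mid,
                 flux_slope = flux_slope, s_intermediate = s_intermediate,
                 s_cost = s_cost, cost_AA = cost_AA, cost_nuc = cost_nuc,
                 lengths = setNames(as.numeric(lengths), names(.default_lengths))),
            class = "fitness_config")
}

#' Flux component of fitness (F1)
#'
#' The logistic `1 / (1 + exp(-flux_slope * (flux - flux_mid)))`: fitness
#' 0.5 at the midpoint flux of 650 mmol/l/s, rising with slope 0.07 toward
#' an asymptote of 1. Strictly increasing in flux.
#'
#' @param flux Steady-state flux (mmol/l/s), vectorized, non-negative.
#' @param cfg A [fitness_config()].
#' @return Fitness in (0, 1).
#' @export
fitness_flux <- function(flux, cfg = fitness_config()) {
  if (any(flux < 0)) stop("flux must be non-negative")
  1 / (1 + exp(-cfg$flux_slope * (flux - cfg$flux_mid)))
}

#' Deleterious-intermediate component of fitness (F2)
#'
#' `exp(-s_intermediate * [B])`, a strictly decreasing penalty on the
#' concentration of the toxic intermediate B (the product of reaction 1,
#' analogous to methylglyoxal).
#'
#' @param conc_B Concentration of B (mmol/l), vectorized, non-negative.
#' @inheritParams fitness_flux
#' @return Fitness in (0, 1].
#' @export
fitness_intermediate <- function(conc_B, cfg = fitness_config()) {
  if (any(conc_B < 0)) stop("conc_B must be non-negative")
  exp(-cfg$s_intermediate * conc_B)
}

#' Expression-cost component of fitness (F3)
#'
#' `1 / (1 + s_cost * (cost_protein + cost_mRNA))` with
#' `cost_protein = cost_AA * sum([E_i] * length_i)` and
#' `cost_mRNA = cost_nuc * sum(3 * length_i * [E_i] / 1000)` over the five
#' enzymes.
#'
#' @param g A [genotype()] (or matrix of genotypes, one per row).
#' @inheritParams fitness_flux
#' @return Fitness in (0, 1].
#' @export
fitness_cost <- function(g, cfg = fitness_config()) {
  m <- if (is.matrix(g)) g else matrix(as.numeric(g), nrow = 1)
  conc <- m[, 5L * (0:4) + 1L, drop = FALSE]
  cost_protein <- cfg$cost_AA * as.vector(conc %*% cfg$lengths)
  cost_mRNA <- cfg$cost_nuc * as.vector(conc %*% (3 * cfg$lengths / 1000))
  1 / (1 + cfg$s_cost * (cost_protein + cost_mRNA))
}

#' Fitness of a genotype under the configured scheme
#'
#' Scheme composition: `mutation_only` is constant 1; `flux_only` is F1;
#' `flux_intermediate` and `positive_control` are F1*F2; `flux_cost` is
#' F1*F3. A non-converged steady state (a mutant that destroys the pathway)
#' receives fitness 0; negative flux is treated as 0.
#'
#' @param g A [genotype()].
#' @param st A `steady_state` for `g`, from [solve_steady_state()].
#' @param cfg A [fitness_config()].
#' @return Fitness in \[0, 1\].
#' @export
fitness <- function(g, st, cfg = fitness_config()) {
  if (cfg$scheme == "mutation_only") return(1)
  if (!isTRUE(st$converged)) return(0)
  fl <- max(st$flux, 0)
  f1 <- fitness_flux(fl, cfg)
  switch(cfg$scheme,
         flux_only = f1,
         flux_intermediate = ,
         positive_control = f1 * fitness_intermediate(st$concentrations[["B"]], cfg),
         flux_cost = f1 * fitness_cost(g, cfg))
}

# Vectorized fitness over a population's batch evaluation (matrix columns:
# B, C, D, E, F, flux, converged), matching `fitness()` exactly.
fitness_batch <- function(pop, ev, cfg) {
  n <- nrow(ev)
  if (cfg$scheme == "mutation_only") return(rep(1, n))
  f1 <- fitness_flux(pmax(ev[, 6L], 0), cfg)
  f <- switch(cfg$scheme,
              flux_only = f1,
              flux_intermediate = ,
              positive_control = f1 * fitness_intermediate(ev[, 1L], cfg),
              flux_cost = f1 * fitness_cost(pop, cfg))
  f * (ev[, 7L] == 1)
}
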
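# Population-genetic engines: explicit Wright-Fisher sampling and the
# origin-fixation approximation (one proposal per generation, fixed with the
# Kimura probability).

#' Initialize a homogeneous population
#'
#' Generation 0 consists of `N` identical copies of the founding genotype.
#'
#' @param g A [genotype()].
#' @param N Population size (default 100).
#' @return Numeric matrix `N x 26` of class `population`, one genotype per
#'   row.
#' @export
population <- function(g = default_genotype(), N = 100L) {
  m <- matrix(rep(as.numeric(g), each = N), nrow = N,
              dimnames = list(NULL, param_names()))
  structure(m, class = c("population", "matrix", "array"))
}

#' Evaluate a population's steady states
#'
#' Solves the pathway steady state for every individual (compiled batch
#' solver, warm-started across similar genotypes).
#'
#' @param pop A `population` matrix (or any `n x 26` matrix of genotypes).
#' @param env A [kinetic_env()].
#' @return Matrix `n x 7` with columns `B, C, D, E, F, flux, converged`.
#' @export
evaluate_population <- function(pop, env = kinetic_env()) {
  ev <- .ss_batch_cpp(unclass(pop), .env_list(env))
  colnames(ev) <- c("B", "C", "D", "E", "F", "flux", "converged")
  ev
}

#' One Wright-Fisher generation
#'
#' Samples the next generation of identical size with replacement, with
#' probability proportional to fitness (uniformly under the
#' `mutation_only` scheme), then mutates the offspring with
#' [apply_mutations()] so that new mutations can elicit fitness effects
#' before the next round of selection.
#'
#' @param pop A `population` matrix.
#' @param fit Fitness vector of the current individuals (all evaluated).
#' @param mut_cfg A [mutation_config()].
#' @param uniform If `TRUE`, parents are sampled uniformly regardless of
#'   `fit` (the `mutation_only` scheme).
#' @return The next-generation `population`.
#' @export
wright_fisher_step <- function(pop, fit, mut_cfg = mutation_config(),
                               uniform = FALSE) {
  N <- nrow(pop)
  if (!uniform && all(fit <= 0))
    stop("degenerate population: every individual has zero fitness")
  parents <- if (uniform) sample.int(N, N, replace = TRUE)
             else sample.int(N, N, replace = TRUE, prob = fit)
  nxt <- pop[parents, , drop = FALSE]
  nxt <- mutate_population(nxt, mut_cfg)
  structure(nxt, class = c("population", "matrix", "array"),
            dimnames = list(NULL, param_names()))
}

# Vectorized apply_mutations over a population matrix. Same model as
# apply_mutations(): each (individual, parameter) cell mutates independently.
mutate_population <- function(pop, cfg) {
  cls <- param_classes()
  free_cols <- if (cfg$mode == "haldane") which(cls != "k_catr") else 1:26
  N <- nrow(pop)
  sub <- pop[, free_cols, drop = FALSE]
  hit <- which(matrix(runif(length(sub)) < cfg$per_param_rate, nrow = N))
  if (!length(hit)) return(pop)
  col <- (hit - 1L) %/% N + 1L                 # column within `sub`
  pcls <- cls[free_cols][col]
  if (cfg$mode == "haldane") {
    trio <- pcls %in% c("k_cat", "K_M", "K_Mr")
    mult <- numeric(length(hit))
    if (any(trio))
      mult[trio] <- pmax(1 + rnorm(sum(trio), cfg$haldane$haldane_mean,
                                   cfg$haldane$haldane_sd) / 100,
                         cfg$mult_floor)
    if (any(!trio))
      mult[!trio] <- sample_effect(cfg, pcls[!trio], sub[hit[!trio]],
                                   n = sum(!trio))
    sub[hit] <- sub[hit] * mult
    pop[, free_cols] <- sub
    row <- (hit - 1L) %% N + 1L
    enz <- (free_cols[col] - 1L) %/% 5L + 1L
    touched <- unique(cbind(row, enz)[trio, , drop = FALSE])
    for (k in seq_len(nrow(touched))) {
      r <- touched[k, 1L]; e <- touched[k, 2L]; i <- 5L * (e - 1L)
      pop[r, i + 4L] <- pop[r, i + 2L] * pop[r, i + 5L] /
        (cfg$haldane$Keq_per_reaction[e] * pop[r, i + 3L])
    }
  } else {
    sub[hit] <- sub[hit] * sample_effect(cfg, pcls, sub[hit], n = length(hit))
    pop[, free_cols] <- sub
  }
  pop
}

#' Median individual of a population
#'
#' The population member at rank `floor(N/2)` (0-based) of the fitness
#' ordering, ties broken by stable population index. This is the
#' per-generation representative genotype used by the analysis layer.
#'
#' @param pop A `population` matrix.
#' @param fit Fitness vector.
#' @return Row index of the median individual.
#' @export
median_individual <- function(pop, fit) {
  ord <- order(fit)               # stable for ties
  ord[floor(nrow(pop) / 2) + 1L]
}

#' Kimura fixation probability
#'
#' `psi = (1 - exp(-2 c Ne s p)) / (1 - exp(-2 c Ne s))` for an allele at
#' initial frequency `p` with selection coefficient `s` in a haploid
#' population of effective size `Ne`. The analytic limit `psi -> p` is
#' returned as `s -> 0`, so a neutral mutation at `p = 1/2` fixes with
#' probability one half.
#'
#' @param s Selection coefficient (`f'/f0 - 1`), vectorized; must exceed -1
#'   for a finite fitness ratio (deleterious values below are admitted and
#'   give vanishing probabilities).
#' @param Ne Effective population size.
#' @param ploidy Ploidy `c` (1 = haploid).
#' @param p Initial allele frequency in (0, 1); defaults to 1/2.
#' @return Fixation probability in \[0, 1\].
#' @examples
#' kimura_fixation_prob(0, Ne = 100)            # 0.5
#' kimura_fixation_prob(1e-6, Ne = 1e6, p = 0.5)
#' @export
kimura_fixation_prob <- function(s, Ne, ploidy = 1, p = 0.5) {
  if (Ne < 1) stop("Ne must be at least 1")
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  a <- 2 * ploidy * Ne * s
  out <- numeric(length(a))
  tiny <- abs(a) < 1e-12
  out[tiny] <- p
  del <- !tiny & (-a * p > 700)       # strongly deleterious: exp overflow
  out[del] <- exp(a[del] * (1 - p))
  ben <- !tiny & !del & (a > 700)
  out[ben] <- 1
  rest <- !tiny & !del & !ben
  out[rest] <- expm1(-a[rest] * p) / expm1(-a[rest])
  pmin(pmax(out, 0), 1)
}

# Free (proposable) parameter indices under a mutation mode.
.free_params <- function(mode) {
  if (mode == "haldane") which(param_classes() != "k_catr") else 1:26
}

#' One origin-fixation generation
#'
#' Proposes a single mutation (one parameter chosen uniformly among the free
#' parameters), evaluates the mutant, and fixes it with the Kimura
#' probability at selection coefficient `s = f'/f0 - 1`. Consumes exactly
#' three random draws (index, effect, acceptance) so runs are reproducible
#' against the fused compiled loop used by [run_experiment()].
#'
#' @param g Current (resident) [genotype()].
#' @param f0 Resident fitness (must be positive).
#' @param env A [kinetic_env()].
#' @param fit_cfg A [fitness_config()].
#' @param mut_cfg A [mutation_config()] (mode `"haldane"` requires
#'   `mut_cfg$haldane`).
#' @param Ne,ploidy,p Origin-fixation parameters (see
#'   [kimura_fixation_prob()]).
#' @return List: `genotype` (resident after the step), `fitness`, `flux`,
#'   `accepted` (logical).
#' @export
origin_fixation_step <- function(g, f0, env = kinetic_env(),
                                 fit_cfg = fitness_config(),
                                 mut_cfg = mutation_config(),
                                 Ne = 100, ploidy = 1, p = 0.5) {
  if (f0 <= 0) stop("resident fitness f0 must be positive")
  free <- .free_params(mut_cfg$mode)
  j <- free[floor(runif(1) * length(free)) %% length(free) + 1L]
  cls <- param_classes()[j]
  if (mut_cfg$mode == "haldane" && cls %in% c("k_cat", "K_M", "K_Mr")) {
    m <- mut_cfg$haldane$haldane_mean
    s_eff <- mut_cfg$haldane$haldane_sd
  } else {
    m <- effect_mean(cls, unclass(g)[j], mut_cfg)
    s_eff <- mut_cfg$effect_sd
  }
  delta <- m + s_eff * rnorm(1)
  mult <- max(1 + delta / 100, mut_cfg$mult_floor)
  q <- unclass(g)
  q[j] <- q[j] * mult
  if (mut_cfg$mode == "haldane" && cls %in% c("k_cat", "K_M", "K_Mr")) {
    enz <- (j - 1L) %/% 5L + 1L
    i <- 5L * (enz - 1L)
    q[i + 4L] <- q[i + 2L] * q[i + 5L] /
      (mut_cfg$haldane$Keq_per_reaction[enz] * q[i + 3L])
  }
  q <- validate_genotype(q)
  st <- solve_steady_state(q, env)
  fm <- fitness(q, st, fit_cfg)
  psi <- kimura_fixation_prob(fm / f0 - 1, Ne = Ne, ploidy = ploidy, p = p)
  if (runif(1) < psi)
    list(genotype = q, fitness = fm,
         flux = if (st$converged) max(st$flux, 0) else 0, accepted = TRUE)
  else
    list(genotype = g, fitness = f0, flux = NA_real_, accepted = FALSE)
}

.scheme_id <- function(scheme) {
  match(scheme, .schemes) - 1L   # 0-based id used by the compiled loop
}

.mode_id <- function(mode) {
  match(mode, c("biological", "neutral", "haldane")) - 1L
}

#' Run a full simulation experiment
#'
#' Executes every replicate of the configured experiment with independently
#' derived seeds and records a per-generation trajectory. The explicit
#' engine records the median individual's genotype, flux, fitness, the
#' rate-limiting reaction, and per-parameter distinct-allele counts; the
#' origin-fixation engine records the resident's flux, fitness and
#' rate-limiting reaction each generation plus periodic genotype snapshots.
#' Given `(config, seed)` the output is deterministic.
#'
#' @param cfg An [experiment_config()].
#' @param progress Emit a progress line every 1000 generations.
#' @return Object of class `fluxdrift_experiment`: list with `config`,
#'   `replicate_seeds`, and `replicates` (one trajectory data.frame each).
#' @export
run_experiment <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  set.seed(cfg$seed)
  rep_seeds <- sample.int(.Machine$integer.max, cfg$replicates)
  reps <- vector("list", cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    set.seed(rep_seeds[r])
    reps[[r]] <- if (cfg$engine == "explicit")
      run_explicit_replicate(cfg, progress = progress)
    else
      run_origin_fixation_replicate(cfg)
  }
  structure(list(config = cfg, replicate_seeds = rep_seeds,
                 replicates = reps),
            class = "fluxdrift_experiment")
}

# One explicit Wright-Fisher replicate (RNG state set by caller).
run_explicit_replicate <- function(cfg, progress = FALSE) {
  G <- cfg$total_generations
  pop <- population(cfg$genotype, cfg$pop_size)
  uniform <- cfg$fitness$scheme == "mutation_only"
  np <- 26L
  pn <- param_names()
  params <- matrix(NA_real_, G, np, dimnames = list(NULL, pn))
  alleles <- matrix(NA_integer_, G, np,
                    dimnames = list(NULL, paste0("n_", pn)))
  fluxv <- fitv <- numeric(G)
  rl <- integer(G)
  envl <- .env_list(cfg$env)
  for (g in seq_len(G)) {
    ev <- evaluate_population(pop, cfg$env)
    fit <- fitness_batch(pop, ev, cfg$fitness)
    if (!uniform && all(fit <= 0))
      stop(sprintf("degenerate population (all fitness 0) at generation %d", g))
    med <- median_individual(pop, fit)
    params[g, ] <- pop[med, ]
    fluxv[g] <- if (ev[med, 7L] == 1) max(ev[med, 6L], 0) else 0
    fitv[g] <- fit[med]
    sen <- .sensitivities_cpp(pop[med, ], envl, 0.9, cfg$sensitivity_mode)
    rl[g] <- if (isTRUE(sen$converged) && !anyNA(sen$sensitivities))
      which.max(sen$sensitivities) else NA_integer_
    alleles[g, ] <- apply(pop, 2L, function(v) length(unique(v)))
    pop <- wright_fisher_step(pop, fit, cfg$mutation, uniform = uniform)
    if (progress && g %% 1000L == 0L)
      message(sprintf("  gen %d: flux %.1f fitness %.4f rl %d",
                      g, fluxv[g], fitv[g], rl[g]))
  }
  out <- data.frame(generation = seq_len(G) - 1L, params, flux = fluxv,
                    fitness = fitv, rate_limiting = rl, alleles,
                    check.names = FALSE)
  out
}

# One origin-fixation replicate via the fused compiled loop.
run_origin_fixation_replicate <- function(cfg) {
  fc <- cfg$fitness
  mut <- cfg$mutation
  of <- cfg$origin_fixation
  hal <- if (!is.null(mut$haldane)) mut$haldane
         else haldane_config(vapply(1:5, function(i)
           keq(genotype_enzyme(cfg$genotype, i)), numeric(1)))
  res <- .of_run_cpp(as.numeric(cfg$genotype), .env_list(cfg$env),
                     .scheme_id(fc$scheme),
                     list(flux_mid = fc$flux_mid, flux_slope = fc$flux_slope,
                          s_intermediate = fc$s_intermediate,
                          s_cost = fc$s_cost, cost_AA = fc$cost_AA,
                          cost_nuc = fc$cost_nuc, lengths = fc$lengths),
                     .mode_id(mut$mode),
                     as.numeric(mut$c_table[c("enzyme_conc", "k_cat", "K_M",
                                              "k_catr", "K_Mr", "K_I")]),
                     mut$effect_sd, mut$mult_floor,
                     hal$Keq_per_reaction, hal$haldane_mean, hal$haldane_sd,
                     of$Ne, of$ploidy, of$p_init,
                     cfg$total_generations, cfg$snapshot_every)
  traj <- data.frame(generation = seq_len(cfg$total_generations),
                     flux = res$flux, fitness = res$fitness,
                     rate_limiting = res$rate_limiting)
  attr(traj, "snapshots") <- res$snapshots
  attr(traj, "snapshot_generation") <- res$snapshot_generation
  attr(traj, "accepted") <- res$accepted
  attr(traj, "final_genotype") <- as_genotype(res$final)
  traj
}
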
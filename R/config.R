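# Experiment configuration, presets, JSON round-tripping, fixtures, and the
# combined analysis report.

#' Full specification of one simulation experiment
#'
#' Bundles engine, selection scheme, mutation model, kinetics and run
#' lengths into a single validated object. All randomness downstream flows
#' from `seed` (replicate seeds are derived from it).
#'
#' @param engine `"explicit"` (Wright-Fisher population) or
#'   `"origin_fixation"` (Kimura fixation of single proposals).
#' @param scheme Selection scheme (see [fitness_config()]).
#' @param mutation A [mutation_config()].
#' @param fitness A [fitness_config()]; its `scheme` is overridden by
#'   `scheme`.
#' @param env A [kinetic_env()].
#' @param genotype Founding [genotype()].
#' @param pop_size Explicit-engine population size N (default 100).
#' @param total_generations Generations per replicate (22000 explicit /
#'   200000 origin-fixation at full scale).
#' @param equilibrium_generation Generation by which mutation-selection
#'   balance is assumed reached; the post-equilibrium window feeds the
#'   analysis layer.
#' @param replicates Number of independent replicates.
#' @param Ne,ploidy,p_init Origin-fixation parameters (effective size,
#'   ploidy c, initial allele frequency; defaults 100, 1, 1/2).
#' @param snapshot_every Origin-fixation genotype snapshot stride.
#' @param sensitivity_mode Perturbation used to identify the rate-limiting
#'   step: `"enzyme_conc"` or `"kcat"`.
#' @param seed Master seed.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(engine = c("explicit", "origin_fixation"),
                              scheme = "flux_only",
                              mutation = mutation_config(),
                              fitness = fitness_config(),
                              env = kinetic_env(),
                              genotype = default_genotype(),
                              pop_size = 100L,
                              total_generations = NULL,
                              equilibrium_generation = NULL,
                              replicates = NULL,
                              Ne = 100, ploidy = 1, p_init = 0.5,
                              snapshot_every = 100L,
                              sensitivity_mode = c("enzyme_conc", "kcat"),
                              seed = 1L) {
  engine <- match.arg(engine)
  sensitivity_mode <- match.arg(sensitivity_mode)
  fitness$scheme <- match.arg(scheme, .schemes)
  if (is.null(total_generations))
    total_generations <- if (engine == "explicit") 22000L else 200000L
  if (is.null(equilibrium_generation))
    equilibrium_generation <- max(total_generations - 2000L, 0L)
  if (is.null(replicates))
    replicates <- if (engine == "explicit") 5L else 30L
  if (equilibrium_generation >= total_generations)
    stop("equilibrium_generation must be below total_generations")
  if (Ne < 1) stop("Ne must be at least 1")
  if (p_init <= 0 || p_init >= 1) stop("p_init must lie in (0, 1)")
  if (mutation$mode == "haldane" && is.null(mutation$haldane))
    mutation$haldane <- haldane_config(
      vapply(1:5, function(i) keq(genotype_enzyme(genotype, i)), numeric(1)))
  structure(list(engine = engine, fitness = fitness, mutation = mutation,
                 env = env, genotype = genotype,
                 pop_size = as.integer(pop_size),
                 total_generations = as.integer(total_generations),
                 equilibrium_generation = as.integer(equilibrium_generation),
                 replicates = as.integer(replicates),
                 origin_fixation = list(Ne = Ne, ploidy = ploidy,
                                        p_init = p_init),
                 snapshot_every = as.integer(snapshot_every),
                 sensitivity_mode = if (sensitivity_mode == "enzyme_conc") 0L
                                    else 1L,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

.preset_names <- c("mutation_only", "flux_only", "flux_intermediate",
                   "flux_cost", "positive_control", "origin_fixation_small",
                   "origin_fixation_large", "haldane")

#' Preset experiment configurations
#'
#' The eight canonical experiments: the five explicit-engine selection
#' schemes (22000 generations, equilibrium at 20000, 5 replicates, N = 100;
#' `positive_control` uses the neutral mutational distribution, as does
#' `mutation_only`), the two origin-fixation population sizes (Ne 1e2 and
#' 1e6, 200000 generations, 30 replicates), and the Haldane-constrained
#' origin-fixation experiment at Ne = 1e6. The `scale` modifier divides
#' generations and replicates for reduced-scale runs while keeping every
#' rate constant fixed; mutation-selection-balance properties, not absolute
#' durations, are what reduced runs probe.
#'
#' @param name Preset name.
#' @param seed Master seed.
#' @param scale Divisor applied to generations and replicates (default 1).
#' @param ... Overrides passed on to [experiment_config()].
#' @return An [experiment_config()].
#' @export
preset <- function(name, seed = 1L, scale = 1, ...) {
  name <- match.arg(name, .preset_names)
  args <- switch(
    name,
    mutation_only = list(engine = "explicit", scheme = "mutation_only",
                         mutation = mutation_config(mode = "neutral")),
    flux_only = list(engine = "explicit", scheme = "flux_only"),
    flux_intermediate = list(engine = "explicit",
                             scheme = "flux_intermediate"),
    flux_cost = list(engine = "explicit", scheme = "flux_cost"),
    positive_control = list(engine = "explicit", scheme = "positive_control",
                            mutation = mutation_config(mode = "neutral")),
    origin_fixation_small = list(engine = "origin_fixation",
                                 scheme = "flux_only", Ne = 1e2),
    origin_fixation_large = list(engine = "origin_fixation",
                                 scheme = "flux_only", Ne = 1e6),
    haldane = list(engine = "origin_fixation", scheme = "flux_only",
                   Ne = 1e6,
                   mutation = mutation_config(mode = "haldane")))
  args <- modifyList(args, list(seed = seed, ...))
  cfg <- do.call(experiment_config, args)
  if (scale != 1) {
    cfg$total_generations <- max(2L, as.integer(cfg$total_generations / scale))
    cfg$replicates <- max(1L, as.integer(ceiling(cfg$replicates / scale)))
    cfg$equilibrium_generation <-
      max(cfg$total_generations - 2000L,
          as.integer(cfg$total_generations * 0.9))
    if (cfg$equilibrium_generation >= cfg$total_generations)
      cfg$equilibrium_generation <- cfg$total_generations - 1L
  }
  cfg
}

#' Write an experiment configuration to JSON
#'
#' The resolved configuration round-trips exactly through
#' [load_config()] and is persisted beside simulation outputs for
#' provenance.
#'
#' @param cfg An [experiment_config()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$fitness <- unclass(x$fitness)
  x$fitness$lengths <- as.list(x$fitness$lengths)   # keep names in JSON
  x$mutation <- unclass(x$mutation)
  x$mutation$c_table <- as.list(x$mutation$c_table)
  if (!is.null(x$mutation$haldane))
    x$mutation$haldane <- unclass(x$mutation$haldane)
  x$env <- unclass(x$env)
  x$genotype <- as.list(unclass(x$genotype))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load an experiment configuration from JSON
#'
#' Reads a document written by [write_config()] (or hand-written with the
#' same keys), fills defaults, validates, and rejects unknown keys by name.
#'
#' @param path JSON file path.
#' @return An [experiment_config()].
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("engine", "fitness", "mutation", "env", "genotype", "pop_size",
             "total_generations", "equilibrium_generation", "replicates",
             "origin_fixation", "snapshot_every", "sensitivity_mode", "seed",
             "scheme")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  fit <- if (!is.null(x$fitness)) {
    fa <- x$fitness
    fa$lengths <- unlist(fa$lengths)
    do.call(fitness_config, fa)
  } else fitness_config()
  mut <- if (!is.null(x$mutation)) {
    ma <- x$mutation
    ma$c_table <- unlist(ma$c_table)
    ma$mean_clamp <- unlist(ma$mean_clamp)
    if (!is.null(ma$haldane) && !length(ma$haldane)) ma$haldane <- NULL
    if (!is.null(ma$haldane)) {
      ha <- ma$haldane
      ma$haldane <- haldane_config(unlist(ha$Keq_per_reaction),
                                   ha$haldane_mean, ha$haldane_sd)
    }
    if (!is.null(ma$per_param_rate) &&
        (ma$per_param_rate < 0 || ma$per_param_rate > 1))
      stop("invalid value for key 'mutation.per_param_rate'")
    do.call(mutation_config, ma)
  } else mutation_config()
  env <- if (!is.null(x$env)) {
    ea <- x$env
    if (is.numeric(ea$inhib_species))
      ea$inhib_species <- c("B", "C", "D", "E", "F")[ea$inhib_species]
    do.call(kinetic_env, ea)
  } else kinetic_env()
  g <- if (!is.null(x$genotype)) as_genotype(unlist(x$genotype))
       else default_genotype()
  of <- x$origin_fixation
  experiment_config(
    engine = if (is.null(x$engine)) "explicit" else x$engine,
    scheme = if (!is.null(x$scheme)) x$scheme else fit$scheme,
    mutation = mut, fitness = fit, env = env, genotype = g,
    pop_size = if (is.null(x$pop_size)) 100L else x$pop_size,
    total_generations = x$total_generations,
    equilibrium_generation = x$equilibrium_generation,
    replicates = x$replicates,
    Ne = if (is.null(of$Ne)) 100 else of$Ne,
    ploidy = if (is.null(of$ploidy)) 1 else of$ploidy,
    p_init = if (is.null(of$p_init)) 0.5 else of$p_init,
    snapshot_every = if (is.null(x$snapshot_every)) 100L else x$snapshot_every,
    sensitivity_mode = if (is.null(x$sensitivity_mode) ||
                             x$sensitivity_mode %in% c(0, "enzyme_conc"))
      "enzyme_conc" else "kcat",
    seed = if (is.null(x$seed)) 1L else x$seed)
}

#' Deterministic test fixtures
#'
#' Toy inputs for exercising the analysis layer in isolation:
#' \describe{
#'   \item{`"default"`}{the default pathway genotype;}
#'   \item{`"bottleneck"`}{enzyme `reaction`'s concentration reduced
#'     100-fold, planting a known rate-limiting step;}
#'   \item{`"symmetric"`}{five identical enzymes with negligible reverse
#'     rates (exercises the lowest-index tie-break);}
#'   \item{`"broken"`}{enzyme C concentration 0 (broken chain, zero flux);}
#'   \item{`"runlength_series"`}{the hand-enumerable series
#'     `c(1, 1, 2, 2, 2, 1)`;}
#'   \item{`"planted_rates"`}{a rate matrix of 15 white-noise series with 3
#'     planted correlation blocks of 5 (within-block correlation `r`).}
#' }
#'
#' @param type Fixture name.
#' @param reaction Bottlenecked reaction (1-5) for `"bottleneck"`.
#' @param n_gen,r,n_rep Rows per replicate, within-block correlation and
#'   replicate count for `"planted_rates"` (`r = 0` gives independent
#'   noise).
#' @return A genotype, integer series, or rate matrix, per `type`.
#' @export
make_fixture <- function(type = c("default", "bottleneck", "symmetric",
                                  "broken", "runlength_series",
                                  "planted_rates"),
                         reaction = 2L, n_gen = 500L, r = 0.9, n_rep = 1L) {
  type <- match.arg(type)
  if (type == "default") return(default_genotype())
  if (type == "bottleneck") {
    g <- unclass(default_genotype())
    g[5L * (reaction - 1L) + 1L] <- g[5L * (reaction - 1L) + 1L] / 100
    return(validate_genotype(g))
  }
  if (type == "symmetric") {
    e <- lapply(1:5, function(i)
      enzyme_params(3, 400, 50, 1e-6, 1e4,
                    K_I = if (i == 1L) 1e9 else NA_real_))
    return(genotype(e))
  }
  if (type == "broken") {
    g <- unclass(default_genotype())
    g[11L] <- 0   # C_conc
    names(g) <- param_names()
    return(structure(g, class = "genotype"))
  }
  if (type == "runlength_series") return(c(1L, 1L, 2L, 2L, 2L, 1L))
  # planted_rates: 3 blocks of 5 parameters, shared factor per block
  keep <- .coevo_params()
  blocks <- rep(1:3, each = 5L)
  out <- do.call(rbind, lapply(seq_len(n_rep), function(rep) {
    z <- matrix(rnorm(n_gen * 3L), n_gen, 3L)
    eps <- matrix(rnorm(n_gen * 15L), n_gen, 15L)
    sqrt(r) * z[, blocks] + sqrt(1 - r) * eps
  }))
  colnames(out) <- keep
  attr(out, "replicate") <- rep(seq_len(n_rep), each = n_gen)
  attr(out, "blocks") <- split(keep, blocks)
  out
}

#' Combined analysis report for an experiment
#'
#' Runs the full post-simulation analysis over the post-equilibrium window
#' of every replicate: per-reaction run-length means with nested-bootstrap
#' confidence intervals and the label-permutation p-value, the pooled
#' proportion of generations each reaction spent rate limiting, the
#' equilibrium diagnostic (sign balance of median-fitness changes in the
#' final window), and, for the explicit engine, the allele-segregation
#' summary.
#'
#' @param exp A `fluxdrift_experiment` from [run_experiment()].
#' @param n_perm,n_boot Resampling sizes (defaults 1e5 and 1e4).
#' @param window Post-equilibrium generations analysed (default: from the
#'   configured `equilibrium_generation` onward).
#' @return List of class `fluxdrift_report`.
#' @export
summarize_experiment <- function(exp, n_perm = 1e5, n_boot = 1e4,
                                 window = NULL) {
  stopifnot(inherits(exp, "fluxdrift_experiment"))
  cfg <- exp$config
  start <- if (is.null(window)) cfg$equilibrium_generation
           else max(cfg$total_generations - window, 0L)
  per_rep <- lapply(exp$replicates, function(tr) {
    run_lengths(tr$rate_limiting[tr$generation >= start])
  })
  runs_by_rep <- lapply(per_rep, `[[`, "runs")
  mean_runs <- do.call(rbind, lapply(per_rep, `[[`, "mean_run_length"))
  pooled_runs <- lapply(seq_len(5L), function(j)
    unlist(lapply(runs_by_rep, `[[`, j)))
  names(pooled_runs) <- paste0("reaction_", 1:5)
  pooled_mean <- vapply(pooled_runs, function(x)
    if (length(x)) mean(x) else NA_real_, numeric(1))
  totals <- vapply(pooled_runs, sum, numeric(1))
  proportions <- totals / sum(totals)
  perm <- permutation_test(mean_runs, n_perm = n_perm)
  ci <- bootstrap_ci(runs_by_rep, n_boot = n_boot)
  equil <- vapply(exp$replicates, function(tr) {
    d <- diff(tr$fitness[tr$generation >= start])
    d <- d[d != 0]
    if (!length(d)) 0.5 else mean(d > 0)
  }, numeric(1))
  alleles <- if (cfg$engine == "explicit")
    allele_segregation(exp, Ne = cfg$pop_size,
                       mu = cfg$mutation$per_param_rate)
  else NULL
  structure(list(scheme = cfg$fitness$scheme, engine = cfg$engine,
                 window_start = start,
                 mean_run_length = pooled_mean,
                 mean_runs_by_replicate = mean_runs,
                 proportions = proportions,
                 permutation_p = perm$p_value,
                 permutation_observed = perm$observed,
                 bootstrap_ci = ci,
                 equilibrium_sign_balance = equil,
                 no_selection = cfg$fitness$scheme == "mutation_only",
                 alleles = alleles),
            class = "fluxdrift_report")
}

#' Write report tables to a directory
#'
#' Emits `runlengths.tsv` (per-reaction means, CIs, permutation p),
#' `proportions.tsv`, `alleles.tsv` (explicit engine), and, when a
#' co-evolution result is supplied, `clusters.json` and `dendrogram.nwk`.
#'
#' @param report A `fluxdrift_report`.
#' @param dir Output directory (created if needed).
#' @param clusters Optional `coevolution_result`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, clusters = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rl <- data.frame(reaction = 1:5,
                   mean_run_length = report$mean_run_length,
                   ci_lower = report$bootstrap_ci[, "lower"],
                   ci_upper = report$bootstrap_ci[, "upper"],
                   permutation_p = report$permutation_p)
  write.table(rl, file.path(dir, "runlengths.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  pr <- data.frame(reaction = 1:5, proportion = report$proportions,
                   no_selection = report$no_selection)
  write.table(pr, file.path(dir, "proportions.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (!is.null(report$alleles)) {
    al <- data.frame(parameter = names(report$alleles$per_parameter_mean),
                     mean_alleles = report$alleles$per_parameter_mean,
                     expected_neutral = report$alleles$expected)
    write.table(al, file.path(dir, "alleles.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  if (!is.null(clusters)) {
    jsonlite::write_json(
      list(significant = clusters$significant,
           unclustered = clusters$unclustered,
           alpha = clusters$alpha, n_boot = clusters$n_boot),
      file.path(dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
    dendrogram_newick(clusters, file.path(dir, "dendrogram.nwk"))
  }
  invisible(dir)
}

#' Write an experiment's trajectories to a directory
#'
#' One gzip-compressed TSV per replicate (`replicate_1.tsv.gz`, ...) plus a
#' JSON sidecar (`experiment.json`) holding the resolved configuration and
#' the derived replicate seeds, so any run can be reproduced or re-analysed
#' from its outputs alone.
#'
#' @param exp A `fluxdrift_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  stopifnot(inherits(exp, "fluxdrift_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(exp$replicates)) {
    con <- gzfile(file.path(dir, sprintf("replicate_%d.tsv.gz", r)), "w")
    write.table(exp$replicates[[r]], con, sep = "\t", row.names = FALSE,
                quote = FALSE)
    close(con)
  }
  write_config(exp$config, file.path(dir, "experiment.json"))
  jsonlite::write_json(list(replicate_seeds = exp$replicate_seeds),
                       file.path(dir, "seeds.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_experiment
#' @return `read_experiment()` returns the reassembled
#'   `fluxdrift_experiment` (trajectory attributes such as genotype
#'   snapshots are not persisted).
#' @export
read_experiment <- function(dir) {
  cfg <- load_config(file.path(dir, "experiment.json"))
  seeds <- unlist(jsonlite::read_json(file.path(dir, "seeds.json"),
                                      simplifyVector = TRUE))
  files <- sort(list.files(dir, pattern = "^replicate_.*\\.tsv\\.gz$",
                           full.names = TRUE))
  if (!length(files)) stop("no replicate_*.tsv.gz files in ", dir)
  reps <- lapply(files, function(f)
    read.table(gzfile(f), header = TRUE, sep = "\t", check.names = FALSE))
  structure(list(config = cfg, replicate_seeds = seeds, replicates = reps),
            class = "fluxdrift_experiment")
}
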
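# Population-genetic engines: Wright-Fisher sampling, the median-individual
# convention, the Kimura fixation probability, and origin-fixation dynamics.

test_that("weighted sampling limit: a sole fit individual takes over", {
  pop <- population(default_genotype(), 12)
  pop[3, "A_kcat"] <- 999  # tag the fit individual
  fit <- rep(0, 12); fit[3] <- 1
  nxt <- wright_fisher_step(pop, fit, mutation_config(per_param_rate = 0))
  expect_true(all(nxt[, "A_kcat"] == 999))
  expect_error(wright_fisher_step(pop, rep(0, 12), mutation_config()),
               "degenerate")
})

test_that("uniform fitness gives multinomial offspring counts", {
  set.seed(701)
  N <- 10L
  pop <- population(default_genotype(), N)
  pop[, "A_conc"] <- seq_len(N)  # tag parents by value
  counts <- numeric(N)
  trials <- 2000L
  m0 <- mutation_config(per_param_rate = 0)
  for (t in seq_len(trials)) {
    nxt <- wright_fisher_step(pop, rep(1, N), m0)
    counts <- counts + tabulate(nxt[, "A_conc"], N)
  }
  expected <- trials * N / N
  chisq <- sum((counts - expected)^2 / expected)
  # chi-square with N-1 = 9 df; 99.9th percentile ~ 27.9
  expect_lt(chisq, qchisq(0.999, df = N - 1))
})

test_that("pure drift loses heterozygosity at rate about 1/N", {
  set.seed(702)
  N <- 10L; t_end <- 10L; trials <- 300L
  m0 <- mutation_config(per_param_rate = 0)
  het <- function(m) {
    p <- table(m[, "A_conc"]) / nrow(m)
    1 - sum(p^2)
  }
  h_ratio <- replicate(trials, {
    pop <- population(default_genotype(), N)
    pop[, "A_conc"] <- seq_len(N)
    h0 <- het(pop)
    for (i in seq_len(t_end)) pop <- wright_fisher_step(pop, rep(1, N), m0)
    het(pop) / h0
  })
  expected <- (1 - 1 / N)^t_end
  expect_lt(abs(mean(h_ratio) - expected), 4 * sd(h_ratio) / sqrt(trials))
})

test_that("median individual follows the documented rank convention", {
  pop3 <- population(default_genotype(), 3)
  expect_identical(median_individual(pop3, c(0.1, 0.5, 0.9)), 2L)
  pop4 <- population(default_genotype(), 4)
  # 0-based rank floor(4/2) = 2 of the ordering -> fitness 3
  expect_identical(median_individual(pop4, c(1, 2, 3, 4)), 3L)
  # stable tie-break by population index
  expect_identical(median_individual(pop4, c(1, 1, 1, 1)), 3L)
  # homogeneous population: any index returns the shared genotype
  i <- median_individual(pop4, rep(0.7, 4))
  expect_equal(unname(pop4[i, ]), unname(unclass(default_genotype())))
})

test_that("Kimura fixation probability: limits and direct evaluation", {
  expect_equal(kimura_fixation_prob(0, Ne = 100), 0.5)
  expect_equal(kimura_fixation_prob(1e-14, Ne = 10), 0.5)
  expect_equal(kimura_fixation_prob(1e-6, Ne = 1e6, p = 0.5),
               (1 - exp(-1)) / (1 - exp(-2)))
  expect_equal(kimura_fixation_prob(100, Ne = 1e6), 1)
  expect_lt(kimura_fixation_prob(-0.01, Ne = 1e6), 1e-12)
  expect_equal(kimura_fixation_prob(0, Ne = 50, p = 0.25), 0.25)
})

test_that("neutral origin-fixation proposals fix at the initial frequency", {
  set.seed(703)
  env <- default_env()
  g <- default_genotype()
  f0 <- fitness(g, solve_steady_state(g, env), fitness_config("flux_only"))
  mcfg <- mutation_config(mode = "neutral", effect_sd = 0)  # f' = f0 exactly
  n <- 2000L
  acc <- vapply(seq_len(n), function(i)
    origin_fixation_step(g, f0, env, fitness_config("flux_only"), mcfg,
                         Ne = 1e6)$accepted, logical(1))
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(acc) - 0.5), 3 * se)
})

test_that("lethal proposals are rejected at large Ne", {
  set.seed(704)
  env <- default_env()
  g <- default_genotype()
  f0 <- fitness(g, solve_steady_state(g, env), fitness_config("flux_only"))
  # a mutation destroying enzyme C's concentration is effectively lethal
  res <- replicate(50, {
    q <- unclass(g); q[11] <- q[11] * 1e-9
    st <- solve_steady_state(validate_genotype(q), env)
    fm <- fitness(validate_genotype(q), st, fitness_config("flux_only"))
    kimura_fixation_prob(fm / f0 - 1, Ne = 1e6)
  })
  expect_true(all(res < 1e-12))
})

test_that("the fused origin-fixation loop matches the R single-step path", {
  env <- default_env()
  cfg <- preset("origin_fixation_large", seed = 99, total_generations = 300L,
                replicates = 1L)
  ex <- run_experiment(cfg)
  tr <- ex$replicates[[1]]
  # replay with the R-level step using the same derived replicate seed
  set.seed(ex$replicate_seeds[1])
  g <- cfg$genotype
  f0 <- fitness(g, solve_steady_state(g, env), cfg$fitness)
  acc <- 0L
  for (i in 1:300) {
    stp <- origin_fixation_step(g, f0, env, cfg$fitness, cfg$mutation,
                                Ne = cfg$origin_fixation$Ne)
    if (stp$accepted) acc <- acc + 1L
    g <- stp$genotype; f0 <- stp$fitness
  }
  expect_identical(acc, as.integer(attr(tr, "accepted")))
  expect_equal(unname(unclass(attr(tr, "final_genotype"))), unname(unclass(g)),
               tolerance = 1e-12)
  expect_equal(tail(tr$fitness, 1), f0, tolerance = 1e-9)
})

test_that("runs are deterministic given (config, seed)", {
  cfg <- preset("flux_only", seed = 42, total_generations = 60L,
                replicates = 2L, pop_size = 12L, equilibrium_generation = 30L)
  ex1 <- run_experiment(cfg)
  ex2 <- run_experiment(cfg)
  expect_identical(ex1$replicates, ex2$replicates)
  cfg2 <- preset("haldane", seed = 42, total_generations = 500L,
                 replicates = 2L)
  o1 <- run_experiment(cfg2)
  o2 <- run_experiment(cfg2)
  expect_identical(o1$replicates[[1]]$rate_limiting,
                   o2$replicates[[1]]$rate_limiting)
  expect_identical(o1$replicates[[2]]$fitness, o2$replicates[[2]]$fitness)
})

test_that("without selection the median fitness is constant while parameters wander", {
  ex <- small_run("mutation_only", seed = 13, gens = 150L, N = 20L)
  tr <- ex$replicates[[1]]
  expect_true(all(tr$fitness == 1))
  p0 <- unlist(tr[1, param_names()])
  p1 <- unlist(tr[nrow(tr), param_names()])
  expect_false(identical(p0, p1))
})

test_that("selection on flux reaches a fitness plateau with balanced changes", {
  ex <- small_run("flux_only", seed = 17, gens = 6000L, N = 50L)
  tr <- ex$replicates[[1]]
  window <- tr[tr$generation >= 4000, ]
  # fitted drift over the final window is small relative to the plateau
  sl <- coef(lm(fitness ~ generation, data = window))["generation"]
  expect_lt(abs(sl) * nrow(window), 0.15)
  # approximately equal rates of positive and negative fitness changes
  d <- diff(window$fitness); d <- d[d != 0]
  expect_gt(mean(d > 0), 0.35)
  expect_lt(mean(d > 0), 0.65)
  expect_gt(tail(tr$fitness, 1), tr$fitness[1])
})

test_that("flux-only runs converge to one fitness band from both sides", {
  low <- unclass(default_genotype()); low[5 * (0:4) + 2] <- low[5 * (0:4) + 2] * 0.8
  high <- unclass(default_genotype()); high[5 * (0:4) + 2] <- high[5 * (0:4) + 2] * 1.6
  exl <- small_run("flux_only", seed = 19, gens = 6000L, N = 50L,
                   genotype = as_genotype(low))
  exh <- small_run("flux_only", seed = 23, gens = 6000L, N = 50L,
                   genotype = as_genotype(high))
  ml <- mean(tail(exl$replicates[[1]]$fitness, 500))
  mh <- mean(tail(exh$replicates[[1]]$fitness, 500))
  expect_gt(mh, 0.5); expect_gt(ml, 0.5)
  expect_lt(abs(ml - mh), 0.15)
})
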
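# Fitness components and scheme composition.

test_that("flux-fitness logistic has the stated midpoint, slope, asymptote", {
  cfg <- fitness_config()
  expect_equal(fitness_flux(650, cfg), 0.5)
  expect_equal(fitness_flux(700, cfg), 1 / (1 + exp(-3.5)))
  expect_equal(fitness_flux(1e6, cfg), 1)
  fl <- seq(0, 800, by = 25)
  expect_true(all(diff(fitness_flux(fl, cfg)) > 0))
  expect_true(all(diff(fitness_flux(seq(800, 5000, 100), cfg)) >= 0))
  expect_error(fitness_flux(-1, cfg), "non-negative")
})

test_that("intermediate toxicity penalty is exponential in [B]", {
  cfg <- fitness_config()
  expect_equal(fitness_intermediate(0, cfg), 1)
  expect_equal(fitness_intermediate(1000, cfg), exp(-0.94))
  b <- c(10, 250, 900)
  expect_equal(fitness_intermediate(2 * b, cfg),
               fitness_intermediate(b, cfg)^2)
})

test_that("expression-cost penalty matches the hand-evaluated example", {
  # one enzyme at 1 mmol/l, length 400: protein 30.3*400, mRNA 49.2*3*400/1000
  cfg <- fitness_config(lengths = c(400, 1, 1, 1, 1))
  g <- unclass(default_genotype())
  g[5 * (0:4) + 1] <- c(1, 0, 0, 0, 0)
  g <- validate_genotype(g)
  expect_equal(fitness_cost(g, cfg), 1 / (1 + 1e-6 * (12120 + 59.04)))
  # zero expression, zero cost
  g0 <- g; g0[5 * (0:4) + 1] <- 0
  expect_equal(fitness_cost(validate_genotype(unclass(g0)), cfg), 1)
  # doubling expression strictly decreases F3
  g2 <- unclass(default_genotype())
  cfgd <- fitness_config()
  gd <- g2; gd[5 * (0:4) + 1] <- 2 * gd[5 * (0:4) + 1]
  expect_lt(fitness_cost(validate_genotype(gd), cfgd),
            fitness_cost(default_genotype(), cfgd))
})

test_that("scheme dispatch composes the components correctly", {
  env <- default_env()
  g <- default_genotype()
  st <- solve_steady_state(g, env)
  f1 <- fitness_flux(st$flux, fitness_config())
  expect_identical(fitness(g, st, fitness_config("mutation_only")), 1)
  expect_equal(fitness(g, st, fitness_config("flux_only")), f1)
  expect_equal(fitness(g, st, fitness_config("flux_intermediate")),
               f1 * fitness_intermediate(st$concentrations[["B"]]))
  expect_equal(fitness(g, st, fitness_config("positive_control")),
               fitness(g, st, fitness_config("flux_intermediate")))
  expect_equal(fitness(g, st, fitness_config("flux_cost")),
               f1 * fitness_cost(g))
  # F2 = 1 at [B] = 0 makes flux_intermediate collapse onto flux_only
  st0 <- st
  st0$concentrations[["B"]] <- 0
  expect_equal(fitness(g, st0, fitness_config("flux_intermediate")),
               fitness(g, st0, fitness_config("flux_only")))
  # fitness at the logistic midpoint
  stm <- st; stm$flux <- 650
  expect_equal(fitness(g, stm, fitness_config("flux_only")), 0.5)
  # destroyed pathway: floor fitness
  stbad <- st; stbad$converged <- FALSE
  expect_identical(fitness(g, stbad, fitness_config("flux_only")), 0)
  expect_error(fitness_config("no_such_scheme"))
})

test_that("all schemes stay within [0, 1] and below their F1 factor", {
  set.seed(601)
  env <- default_env()
  for (k in 1:10) {
    g <- random_genotype()
    st <- solve_steady_state(g, env)
    f1 <- fitness(g, st, fitness_config("flux_only"))
    for (sc in c("mutation_only", "flux_only", "flux_intermediate",
                 "flux_cost", "positive_control")) {
      f <- fitness(g, st, fitness_config(sc))
      expect_gte(f, 0); expect_lte(f, 1)
      if (sc %in% c("flux_intermediate", "flux_cost", "positive_control"))
        expect_lte(f, f1 + 1e-12)
    }
  }
})

test_that("vectorized population fitness matches the scalar path", {
  set.seed(602)
  env <- default_env()
  pop <- population(default_genotype(), 8)
  pop <- fluxdrift:::mutate_population(pop, mutation_config(per_param_rate = 0.3))
  ev <- evaluate_population(pop, env)
  for (sc in c("flux_only", "flux_intermediate", "flux_cost")) {
    cfg <- fitness_config(sc)
    fb <- fluxdrift:::fitness_batch(pop, ev, cfg)
    fs <- vapply(seq_len(nrow(pop)), function(i)
      fitness(as_genotype(pop[i, ]), solve_steady_state(as_genotype(pop[i, ]), env), cfg),
      numeric(1))
    expect_equal(fb, fs, tolerance = 1e-6)
  }
})
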
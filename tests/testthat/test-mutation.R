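# Mutation models: activity-dependent means, sampling, genotype application,
# and the Haldane constraint.

test_that("biological effect means match direct evaluation", {
  cfg <- mutation_config()
  # e^0 = 1 at p -> 0 for the mu_1 classes
  expect_equal(effect_mean_biological("enzyme_conc", 1e-12, cfg), -0.01,
               tolerance = 1e-9)
  expect_equal(effect_mean_biological("k_catr", 1e-12, cfg), -0.01,
               tolerance = 1e-9)
  # k_cat at p = 250, c = 0.01: -0.01 * e^2.5
  expect_equal(effect_mean_biological("k_cat", 250, cfg), -0.01 * exp(2.5))
  # binding constants: reciprocal form, clamped
  expect_equal(effect_mean_biological("K_M", 10, cfg),
               max(1 / (-0.01 * exp(10)), -25))
  expect_error(effect_mean_biological("not_a_class", 1, cfg), "unknown")
  expect_error(effect_mean_biological("k_cat", -1, cfg), "positive")
})

test_that("degradation bias: means are non-positive and activity-dependent", {
  cfg <- mutation_config()
  grid <- c(0.01, 0.1, 1, 10, 100, 300, 1000)
  for (cls in c("enzyme_conc", "k_cat", "k_catr", "K_M", "K_Mr", "K_I")) {
    m <- effect_mean_biological(cls, grid, cfg)
    expect_true(all(m <= 0))
    expect_true(all(m >= -25))
    if (cls %in% c("enzyme_conc", "k_cat", "k_catr"))
      expect_true(all(diff(m) <= 1e-12))  # magnitude non-decreasing in p
  }
})

test_that("sampler hits the stated means (Monte Carlo)", {
  set.seed(501)
  n <- 1e5
  cfg <- mutation_config()
  # mu_1 class at tiny p: mean -0.01
  delta <- (sample_effect(cfg, "k_cat", 1e-9, n = n) - 1) * 100
  se <- cfg$effect_sd / sqrt(n)
  expect_lt(abs(mean(delta) - (-0.01)), 3 * se)
  # neutral control: mean 0 for every class
  ncfg <- mutation_config(mode = "neutral")
  for (cls in c("k_cat", "K_M")) {
    d0 <- (sample_effect(ncfg, cls, 123, n = n) - 1) * 100
    expect_lt(abs(mean(d0)), 3 * se)
  }
})

test_that("degenerate sampler returns the mean multiplier exactly", {
  # choose p so that mu_1 = -1 percent: p = 100 ln(100) / c with c = 0.01
  cfg <- mutation_config(effect_sd = 0)
  p <- log(100) / 0.01
  expect_equal(sample_effect(cfg, "k_cat", p), 0.99, tolerance = 1e-12)
})

test_that("apply_mutations touches parameters at the configured rate", {
  g <- default_genotype()
  expect_identical(apply_mutations(g, mutation_config(per_param_rate = 0)), g)
  # rate 1, neutral, sd 0: every parameter multiplied by exactly 1
  quiet <- mutation_config(per_param_rate = 1, mode = "neutral", effect_sd = 0)
  expect_equal(unclass(apply_mutations(g, quiet)), unclass(g))
  # binomial expectation: 26 * 3e-3 mutated parameters per genotype
  set.seed(502)
  cfg <- mutation_config()
  n <- 1e4
  hits <- vapply(seq_len(n), function(i)
    sum(unclass(apply_mutations(g, cfg)) != unclass(g)), numeric(1))
  expected <- 26 * cfg$per_param_rate
  se <- sqrt(expected * (1 - cfg$per_param_rate)) / sqrt(n)
  expect_lt(abs(mean(hits) - expected), 3 * se)
})

test_that("no mutation chain can produce a non-positive parameter", {
  set.seed(503)
  cfg <- mutation_config(per_param_rate = 1, effect_sd = 5)
  g <- default_genotype()
  for (i in 1:400) {
    g <- apply_mutations(g, cfg)
    expect_true(all(unclass(g) > 0))
  }
})

test_that("Haldane identity and mutation closure", {
  e <- enzyme_params(1, 100, 0.5, 10, 2)
  expect_equal(keq(e), 40)   # (100 * 2) / (10 * 0.5)
  hcfg <- haldane_config(40, haldane_sd = 0)
  m <- mutate_haldane(e, hcfg)
  expect_equal(unname(m[c("k_cat", "K_M", "K_Mr")]),
               unname(e[c("k_cat", "K_M", "K_Mr")]) * 0.99)
  expect_equal(keq(m), 40, tolerance = 1e-14)
  # long chains preserve Keq to machine precision
  set.seed(504)
  hcfg2 <- haldane_config(40, haldane_sd = 1)
  x <- e
  for (i in 1:1000) x <- mutate_haldane(x, hcfg2)
  expect_lt(abs(keq(x) - 40) / 40, 1e-9)
  # precondition: input must satisfy the configured Keq
  bad <- enzyme_params(1, 100, 0.5, 11, 2)
  expect_error(mutate_haldane(bad, hcfg), "Keq")
})

test_that("haldane-mode genotype mutation reprojects k_catr", {
  set.seed(505)
  g <- default_genotype()
  Keq <- vapply(1:5, function(i) keq(genotype_enzyme(g, i)), numeric(1))
  cfg <- mutation_config(mode = "haldane", per_param_rate = 0.5,
                         haldane = haldane_config(Keq))
  x <- g
  for (i in 1:50) x <- apply_mutations(x, cfg)
  expect_false(identical(unclass(x), unclass(g)))
  for (i in 1:5)
    expect_equal(keq(genotype_enzyme(x, i)), Keq[i], tolerance = 1e-12)
})
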
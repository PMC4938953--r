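# Analysis layer: rate-limiting identification, run-length statistics,
# resampling inference, allele segregation, co-evolution clustering.

test_that("planted bottlenecks are identified as rate limiting", {
  env <- default_env()
  for (r in 1:5) {
    g <- make_fixture("bottleneck", reaction = r)
    expect_identical(identify_rate_limiting(g, env)$reaction, r)
  }
})

test_that("a symmetric pathway resolves to reaction 1 by the tie-break rule", {
  g <- make_fixture("symmetric")
  res <- identify_rate_limiting(g, default_env())
  expect_identical(res$reaction, 1L)
})

test_that("sensitivities agree with exhaustive perturb-and-resolve (ODE oracle)", {
  set.seed(801)
  env <- default_env()
  for (k in 1:5) {
    g <- random_genotype(sdlog = 0.1)
    res <- identify_rate_limiting(g, env)
    base <- ode_flux(g, env)
    oracle <- vapply(1:5, function(i) {
      q <- unclass(g)
      q[5 * (i - 1) + 1] <- q[5 * (i - 1) + 1] * 0.9
      base - ode_flux(as_genotype(q), env)
    }, numeric(1))
    expect_equal(res$sensitivities, oracle, tolerance = 1e-4)
    expect_identical(res$reaction, which.max(oracle))
  }
})

test_that("sensitivities are non-negative along a monotone chain", {
  set.seed(802)
  env <- default_env()
  for (k in 1:20) {
    res <- identify_rate_limiting(random_genotype(), env)
    expect_true(all(res$sensitivities > -1e-6))
  }
})

test_that("kcat-mode perturbation is available and consistent", {
  g <- make_fixture("bottleneck", reaction = 3)
  expect_identical(identify_rate_limiting(g, default_env(), mode = "kcat")$reaction, 3L)
})

test_that("run lengths match hand enumeration", {
  rl <- run_lengths(make_fixture("runlength_series"))
  expect_equal(rl$runs$reaction_1, c(2L, 1L))
  expect_equal(rl$runs$reaction_2, 3L)
  expect_equal(unname(rl$mean_run_length[1:2]), c(1.5, 3))
  expect_equal(unname(rl$proportions[1:2]), c(0.5, 0.5))
  # constant series: one run, proportion 1
  rlc <- run_lengths(rep(4L, 37))
  expect_equal(rlc$runs$reaction_4, 37L)
  expect_equal(unname(rlc$proportions[4]), 1)
  # partition property on random series
  set.seed(803)
  for (k in 1:20) {
    s <- sample.int(5, 200, replace = TRUE)
    expect_equal(sum(run_lengths(s)$proportions), 1)
    expect_true(all(unlist(run_lengths(s)$runs) >= 1))
  }
})

test_that("permutation test: degenerate and powered cases", {
  M <- matrix(5, nrow = 4, ncol = 5)   # identical means everywhere
  expect_equal(permutation_test(M, n_perm = 200)$p_value, 1)
  set.seed(804)
  M2 <- matrix(rexp(25, rate = 1) + 2, 5, 5)
  M2[, 3] <- M2[, 3] * 10              # one reaction far above the rest
  expect_lt(permutation_test(M2, n_perm = 1e4)$p_value, 0.01)
})

test_that("permutation p-values are uniform under an exchangeable null", {
  set.seed(805)
  pvals <- replicate(200, {
    M <- matrix(rexp(25, 0.2), 5, 5)   # fully exchangeable across labels
    permutation_test(M, n_perm = 199)$p_value
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  expect_gt(min(pvals), 1 / 200)       # +1 correction: never exactly zero
})

test_that("nested bootstrap CI: degenerate interval and plug-in coverage", {
  runs1 <- list(list(reaction_1 = rep(7, 12)))
  ci <- bootstrap_ci(runs1, n_boot = 100)
  expect_equal(unname(ci[1, ]), c(7, 7))
  # interval contains the plug-in pooled mean on well-behaved data
  set.seed(806)
  runs <- lapply(1:6, function(r) list(reaction_1 = rexp(40, 1 / 8) + 1))
  ci2 <- bootstrap_ci(runs, n_boot = 500)
  plug <- mean(unlist(runs))
  expect_lt(ci2[1, "lower"], plug)
  expect_gt(ci2[1, "upper"], plug)
  # a reaction never rate limiting yields an absent (NA) interval
  runs3 <- list(list(reaction_1 = c(2, 3), reaction_2 = numeric(0)))
  ci3 <- bootstrap_ci(runs3, n_boot = 50)
  expect_true(all(is.na(ci3[2, ])))
})

test_that("nested bootstrap CI coverage is near nominal on synthetic runs", {
  set.seed(807)
  true_mean <- 6   # exponential(1/5) + 1
  hits <- replicate(150, {
    runs <- lapply(1:10, function(r) list(reaction_1 = rexp(40, 1 / 5) + 1))
    ci <- bootstrap_ci(runs, n_boot = 300)
    ci[1, "lower"] <= true_mean && true_mean <= ci[1, "upper"]
  })
  expect_gte(mean(hits), 0.90)
})

test_that("allele counting and the Kimura-Crow expectation", {
  expect_identical(expected_alleles(100, 3e-3), 1.6)
  # synthetic trajectory with known distinct-value counts
  pn <- param_names()
  G <- 2000L
  counts <- matrix(1L, G, 26, dimnames = list(NULL, paste0("n_", pn)))
  counts[, 1] <- 3L     # one parameter holds 3 alleles throughout
  traj <- data.frame(generation = seq_len(G) - 1L,
                     matrix(1, G, 26, dimnames = list(NULL, pn)),
                     flux = 1, fitness = 1, rate_limiting = 1L, counts,
                     check.names = FALSE)
  al <- allele_segregation(traj, Ne = 100, mu = 3e-3)
  expect_equal(al$n_points, 200L)
  expect_equal(unname(al$per_parameter_mean[pn[1]]), 3)
  expect_equal(unname(al$per_parameter_mean[pn[2]]), 1)
  expect_equal(unname(al$all_parameters["mean"]), mean(c(3, rep(1, 25))))
  expect_equal(al$expected, 1.6)
  # homogeneous population: every count 1
  expect_equal(unname(al$forward_only["min"]), 1)
  # distinct-value definition
  expect_identical(length(unique(c(1.0, 1.0, 2.0))), 2L)
})

test_that("co-evolution rates: differencing and group detrending", {
  pn <- param_names()
  G <- 40L
  m <- matrix(5, G, 26, dimnames = list(NULL, pn))
  tr <- data.frame(generation = seq_len(G) - 1L, m, check.names = FALSE)
  r0 <- coevolution_rates(list(tr), window = Inf)
  expect_true(all(r0 == 0))
  expect_equal(ncol(r0), 15L)
  # shared linear trend in all K_M plus independent noise: the trend is
  # removed while inter-parameter noise correlations survive
  set.seed(808)
  km_cols <- grep("_KM$", pn, value = TRUE)
  noise <- matrix(rnorm(G * 5, sd = 0.05), G, 5)
  m2 <- m
  m2[, km_cols] <- 10 + 0.3 * seq_len(G) + apply(noise, 2, cumsum)
  tr2 <- data.frame(generation = seq_len(G) - 1L, m2, check.names = FALSE)
  r2 <- coevolution_rates(list(tr2), window = Inf)
  km_rates <- r2[, km_cols]
  expect_equal(max(abs(rowMeans(km_rates))), 0, tolerance = 1e-12)
  centred <- (noise - rowMeans(noise))[-1, ]   # diff() drops the first row
  expect_equal(unname(km_rates), unname(centred), tolerance = 1e-9)
})

test_that("clustering recovers planted blocks and rejects independent noise", {
  set.seed(809)
  rates <- make_fixture("planted_rates", n_gen = 400, r = 0.9)
  res <- coevolution_clusters(rates, n_boot = 300)
  blocks <- lapply(attr(rates, "blocks"), sort)
  found <- res$members
  expect_identical(length(found), 3L)
  expect_setequal(vapply(found, paste, character(1), collapse = "|"),
                  vapply(blocks, paste, character(1), collapse = "|"))
  expect_identical(length(res$unclustered), 0L)
  # identical series always co-cluster with full support
  rates2 <- rates
  rates2[, 2] <- rates2[, 1]
  res2 <- coevolution_clusters(rates2, n_boot = 100)
  pair <- paste(sort(colnames(rates2)[1:2]), collapse = "|")
  expect_true(pair %in% res2$clades$clade[res2$clades$support == 1])
  # independent white noise: no significant clusters
  noise <- make_fixture("planted_rates", n_gen = 400, r = 0)
  resn <- coevolution_clusters(noise, n_boot = 300)
  expect_identical(nrow(resn$significant), 0L)
  expect_identical(length(resn$unclustered), 15L)
})

test_that("zero-variance parameters are excluded with a warning", {
  set.seed(810)
  rates <- make_fixture("planted_rates", n_gen = 100, r = 0.5)
  rates[, 4] <- 0
  expect_warning(res <- coevolution_clusters(rates, n_boot = 50),
                 "zero-variance")
  expect_identical(res$dropped, colnames(rates)[4])
})

test_that("the dendrogram exports as parseable Newick", {
  set.seed(811)
  rates <- make_fixture("planted_rates", n_gen = 120, r = 0.7)
  res <- coevolution_clusters(rates, n_boot = 50)
  txt <- dendrogram_newick(res)
  phy <- ape::read.tree(text = txt)
  expect_identical(sort(phy$tip.label), sort(colnames(rates)))
  f <- tempfile(fileext = ".nwk")
  dendrogram_newick(res, f)
  expect_true(file.exists(f))
  unlink(f)
})
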
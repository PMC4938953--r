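# Shared fixtures for the test suite. Everything is generated in code; the
# random-genotype helper jitters the default parameterization so solver
# properties are probed across a neighbourhood, not a single point.

default_env <- function(...) kinetic_env(...)

# lognormal jitter around the default genotype (keeps K_I on enzyme A)
random_genotype <- function(sdlog = 0.15) {
  g <- unclass(default_genotype())
  as_genotype(g * exp(rnorm(26, 0, sdlog)))
}

# enzyme used in several hand-evaluated rate-law examples
example_enzyme <- function() enzyme_params(1, 100, 0.5, 10, 1)

# independent steady-state oracle: long-time forward integration of the ODE
# system with deSolve (tight tolerances), returning the flux
ode_flux <- function(g, env, t_end = 5000) {
  y0 <- setNames(rep(0.1, 5), c("B", "C", "D", "E", "F"))
  out <- deSolve::ode(y = y0, times = c(0, t_end), func = pathway_derivs,
                      parms = list(g = g, env = env), method = "lsoda",
                      rtol = 1e-11, atol = 1e-11, maxsteps = 5e5)
  y <- tail(out, 1)[1, -1]
  e5 <- genotype_enzyme(g, 5)
  reaction_rate(e5, S = y[["E"]], P = y[["F"]],
                I = if (env$inhib_reaction == 5L) y[["F"]] else 0)
}

# compact explicit run used by several engine/analysis tests
small_run <- function(scheme = "flux_only", seed = 11, gens = 300L, N = 30L,
                      reps = 1L, ...) {
  cfg <- preset(scheme, seed = seed, total_generations = gens,
                replicates = reps, pop_size = N,
                equilibrium_generation = max(1L, gens - 200L), ...)
  run_experiment(cfg)
}
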
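# Steady-state kinetics of the linear pathway A -> B -> C -> D -> E -> F.
# The heavy lifting (damped Newton with a pseudo-transient fallback) is done
# in compiled code; this file provides the user-facing surface and a pure-R
# rate law used as an independent formulation for ODE-based cross-checks.

#' Kinetic environment of the pathway
#'
#' Boundary conditions and solver settings: compound A is held at a fixed
#' concentration (constantly replenished) and the end product F is utilized
#' by first-order mass action. The feedback loop is wired, by default, as
#' end-product inhibition of reaction 1 by F (a glycolysis-like regulation);
#' both ends of the loop are configurable.
#'
#' @param conc_A Fixed boundary concentration of A (mmol/l). The default is a
#'   saturating multiple (10x) of enzyme A's default `K_M`.
#' @param k_use First-order rate constant for utilization of F (1/s).
#' @param solver_tol Steady-state residual tolerance (mmol/l/s): at
#'   convergence every d\[X\]/dt is below this in magnitude.
#' @param max_time Pseudo-time cap (s) for the integration fallback; hitting
#'   it yields `converged = FALSE`, never an error.
#' @param inhib_reaction Reaction (1-5) carrying the `K_I` term.
#' @param inhib_species Inhibitory metabolite, one of `"B"`-`"F"`.
#' @return A list of class `kinetic_env`.
#' @export
kinetic_env <- function(conc_A = 500, k_use = 1, solver_tol = 1e-6,
                        max_time = 1e6, inhib_reaction = 1L,
                        inhib_species = "F") {
  sp <- match(inhib_species, c("B", "C", "D", "E", "F"))
  if (is.na(sp)) stop("inhib_species must be one of B, C, D, E, F")
  if (conc_A <= 0 || k_use <= 0 || solver_tol <= 0 || max_time <= 0)
    stop("conc_A, k_use, solver_tol and max_time must be positive")
  if (!inhib_reaction %in% 1:5) stop("inhib_reaction must be in 1..5")
  structure(list(conc_A = conc_A, k_use = k_use, solver_tol = solver_tol,
                 max_time = max_time, inhib_reaction = as.integer(inhib_reaction),
                 inhib_species = sp),
            class = "kinetic_env")
}

#' Reversible Michaelis-Menten reaction rate
#'
#' Net rate of one enzymatic reaction,
#' \deqn{v = [E] \frac{k_{cat} S/K_M - k_{catr} P/K_{Mr}}
#'                    {1 + S/K_M + P/K_{Mr} + I/K_I},}
#' with the inhibitor term present only when the enzyme carries `K_I` and an
#' inhibitor concentration is supplied. The sign of \eqn{v} is the sign of
#' the thermodynamic driving force \eqn{k_{cat} S/K_M - k_{catr} P/K_{Mr}};
#' in particular \eqn{v = 0} at the Haldane equilibrium ratio
#' \eqn{P/S = K_{eq} = k_{cat} K_{Mr} / (k_{catr} K_M)}.
#'
#' @param e An [enzyme_params()] object (or named vector with the same
#'   fields).
#' @param S,P Substrate and product concentrations (mmol/l), vectorized.
#' @param I Inhibitor concentration (mmol/l); ignored unless `e` carries a
#'   finite `K_I`.
#' @return Net rate (mmol/l/s).
#' @examples
#' e <- enzyme_params(1, 100, 0.5, 10, 1)
#' reaction_rate(e, S = 0.5, P = 0)   # 50
#' @export
reaction_rate <- function(e, S, P, I = 0) {
  if (any(!is.finite(S)) || any(!is.finite(P)) || any(S < 0) || any(P < 0))
    stop("substrate and product concentrations must be finite and non-negative")
  if (any(!is.finite(I)) || any(I < 0))
    stop("inhibitor concentration must be finite and non-negative")
  a <- S / e[["K_M"]]
  b <- P / e[["K_Mr"]]
  den <- 1 + a + b
  ki <- if ("K_I" %in% names(e)) e[["K_I"]] else NA_real_
  if (!is.na(ki)) den <- den + I / ki
  unname(e[["enzyme_conc"]] * (e[["k_cat"]] * a - e[["k_catr"]] * b) / den)
}

.env_list <- function(env) {
  list(conc_A = env$conc_A, k_use = env$k_use, solver_tol = env$solver_tol,
       max_time = env$max_time, inhib_reaction = env$inhib_reaction,
       inhib_species = env$inhib_species)
}

#' Steady state of the pathway
#'
#' Finds metabolite concentrations at which d\[X\]/dt = 0 for X in B..F with
#' \[A\] fixed and utilization k_use*\[F\], by damped Newton iteration on the
#' rate-balance system with a pseudo-transient (implicit Euler) fallback for
#' stiff cases. Non-convergence is reported in-band (`converged = FALSE`),
#' never as an error, so that the evolutionary engines can assign mutants
#' that destroy the pathway their floor fitness.
#'
#' @param g A [genotype()].
#' @param env A [kinetic_env()].
#' @param x0 Optional warm-start concentrations (length 5, B..F).
#' @return List of class `steady_state`: `concentrations` (named, B..F),
#'   `rates` (net rate of each reaction), `flux` (net rate of reaction 5,
#'   equal within tolerance to all others and to `k_use * F`), `converged`.
#' @export
solve_steady_state <- function(g, env = kinetic_env(), x0 = NULL) {
  st <- .ss_solve_cpp(as.numeric(g), .env_list(env),
                      if (is.null(x0)) NULL else as.numeric(x0))
  names(st$concentrations) <- c("B", "C", "D", "E", "F")
  names(st$rates) <- paste0("v", 1:5)
  structure(st, class = "steady_state")
}

#' Steady-state pathway flux
#'
#' Convenience wrapper over [solve_steady_state()]: returns only the flux,
#' and 0 when the solver did not converge.
#'
#' @inheritParams solve_steady_state
#' @return Flux (mmol/l/s).
#' @export
flux <- function(g, env = kinetic_env()) {
  st <- solve_steady_state(g, env)
  if (!st$converged) 0 else st$flux
}

#' Time derivatives of the pathway metabolites
#'
#' Right-hand side of the pathway ODE system in the signature expected by
#' [deSolve::ode()]. This is an independent pure-R formulation of the model
#' (built on [reaction_rate()]) intended for cross-checking the compiled
#' steady-state solver by long-time forward integration.
#'
#' @param t Time (unused; the system is autonomous).
#' @param y Named or unnamed concentrations of B..F (length 5).
#' @param parms List with elements `g` (genotype) and `env` (kinetic_env).
#' @return List holding the derivative vector, per deSolve convention.
#' @export
pathway_derivs <- function(t, y, parms) {
  g <- parms$g
  env <- parms$env
  conc <- c(A = env$conc_A, setNames(pmax(y, 0), c("B", "C", "D", "E", "F")))
  inhib <- conc[[env$inhib_species + 1L]]
  v <- numeric(5)
  for (i in 1:5) {
    e <- genotype_enzyme(g, i)
    v[i] <- reaction_rate(e, S = conc[[i]], P = conc[[i + 1L]],
                          I = if (i == env$inhib_reaction) inhib else 0)
  }
  list(c(v[1] - v[2], v[2] - v[3], v[3] - v[4], v[4] - v[5],
         v[5] - env$k_use * conc[["F"]]))
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady state>", if (x$converged) "converged" else "NOT converged", "\n")
  cat("flux:", format(signif(x$flux, 6)), "mmol/l/s\n")
  print(signif(x$concentrations, 5))
  invisible(x)
}
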
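# Mutation models. Effects are percent changes applied multiplicatively.
# Under the biological regime the mean effect depends on the current
# parameter value (activity-dependent degradation bias); the neutral control
# has mean zero everywhere; the Haldane regime ties k_catr to the other
# three kinetic constants through the equilibrium constant.

.default_c_table <- c(enzyme_conc = 2.5e-2, K_I = 2.5e-2, k_cat = 1.0e-2,
                      k_catr = 3.33e-4, K_M = 1.0, K_Mr = 3.33e-2)

#' Mutation model configuration
#'
#' @param per_param_rate Mutation probability per parameter per individual
#'   per generation (default 3e-3).
#' @param c_table Named scaling indices `c` per parameter class; the defaults
#'   are `enzyme_conc` 2.5e-2, `K_I` 2.5e-2, `k_cat` 1.0e-2, `k_catr`
#'   3.33e-4, `K_M` 1, `K_Mr` 3.33e-2.
#' @param effect_sd Standard deviation of the percent-effect distribution
#'   (default 1, i.e. a standard normal on the percent scale).
#' @param mode `"biological"` (activity-dependent degradation bias),
#'   `"neutral"` (mean zero, parameter-independent), or `"haldane"`
#'   (thermodynamically constrained; see [mutate_haldane()]).
#' @param mult_floor Lower bound on the multiplier `1 + delta/100`, so no
#'   draw can flip a parameter's sign (default 1e-3).
#' @param mean_clamp Range to which the percent mean is clamped. The
#'   activity-dependent means grow without bound in the current value; the
#'   clamp keeps only the bias direction and saturates its magnitude.
#' @param haldane Optional [haldane_config()], required when
#'   `mode = "haldane"` mutations are applied through [apply_mutations()].
#' @return List of class `mutation_config`.
#' @export
mutation_config <- function(per_param_rate = 3e-3, c_table = .default_c_table,
                            effect_sd = 1, mode = c("biological", "neutral",
                                                    "haldane"),
                            mult_floor = 1e-3, mean_clamp = c(-25, 0),
                            haldane = NULL) {
  mode <- match.arg(mode)
  if (per_param_rate < 0 || per_param_rate > 1)
    stop("per_param_rate must lie in [0, 1]")
  miss <- setdiff(names(.default_c_table), names(c_table))
  if (length(miss)) stop("c_table is missing classes: ",
                         paste(miss, collapse = ", "))
  if (any(c_table <= 0)) stop("all c_table values must be positive")
  if (effect_sd < 0) stop("effect_sd must be non-negative")
  structure(list(per_param_rate = per_param_rate,
                 c_table = c_table[names(.default_c_table)],
                 effect_sd = effect_sd, mode = mode, mult_floor = mult_floor,
                 mean_clamp = mean_clamp, haldane = haldane),
            class = "mutation_config")
}

#' Haldane-constraint configuration
#'
#' Under the Haldane regime `K_M`, `K_Mr` and `k_cat` receive independent
#' percent effects drawn from Normal(`haldane_mean`, `haldane_sd`) and
#' `k_catr` is recomputed from the equilibrium constant, so that
#' `Keq = k_cat * K_Mr / (k_catr * K_M)` holds exactly along the whole
#' mutational trajectory.
#'
#' @param Keq_per_reaction Equilibrium constant of each of the five
#'   reactions (positive, length 5, recycled if length 1).
#' @param haldane_mean Mean percent effect (default -1).
#' @param haldane_sd Percent standard deviation (default 1).
#' @return List of class `haldane_config`.
#' @export
haldane_config <- function(Keq_per_reaction, haldane_mean = -1,
                           haldane_sd = 1) {
  Keq <- rep_len(as.numeric(Keq_per_reaction), 5L)
  if (any(!is.finite(Keq)) || any(Keq <= 0))
    stop("every Keq must be finite and positive")
  if (haldane_sd < 0) stop("haldane_sd must be non-negative")
  structure(list(Keq_per_reaction = Keq, haldane_mean = haldane_mean,
                 haldane_sd = haldane_sd), class = "haldane_config")
}

#' Equilibrium constant of an enzyme's reaction
#'
#' Haldane's relationship: `Keq = (k_cat * K_Mr) / (k_catr * K_M)`.
#'
#' @param e An [enzyme_params()] object or named vector with those fields.
#' @return Keq (dimensionless).
#' @export
keq <- function(e) {
  unname(e[["k_cat"]] * e[["K_Mr"]] / (e[["k_catr"]] * e[["K_M"]]))
}

#' Expected percent mutational effect under the biological regime
#'
#' Concentration-like and catalytic parameters have mean
#' `mu_1 = -0.01 * exp(c * p)`; binding constants (`K_M`, `K_Mr`, `K_I`)
#' have mean `mu_2 = 1 / (-0.01 * exp(c * K))`. Both are clamped to
#' `cfg$mean_clamp` (default \[-25, 0\] percent): the means are unbounded in
#' the raw forms, and only the degradation-bias direction and its
#' activity-dependence carry meaning. The mean is therefore always <= 0 and
#' its magnitude is non-decreasing in the current value for the `mu_1`
#' classes.
#'
#' @param param_class One of `"enzyme_conc"`, `"k_cat"`, `"k_catr"`,
#'   `"K_M"`, `"K_Mr"`, `"K_I"` (vectorized).
#' @param current_value Current parameter value(s), positive.
#' @param cfg A [mutation_config()].
#' @return Mean percent effect (<= 0), vectorized.
#' @examples
#' cfg <- mutation_config()
#' effect_mean_biological("k_cat", 250, cfg)  # -0.01 * exp(2.5)
#' @export
effect_mean_biological <- function(param_class, current_value,
                                   cfg = mutation_config()) {
  if (any(!param_class %in% names(cfg$c_table)))
    stop("unknown parameter class: ",
         paste(setdiff(param_class, names(cfg$c_table)), collapse = ", "))
  if (any(current_value <= 0)) stop("current_value must be positive")
  n <- max(length(param_class), length(current_value))
  param_class <- rep_len(param_class, n)
  current_value <- rep_len(current_value, n)
  cc <- cfg$c_table[param_class]
  binding <- param_class %in% c("K_M", "K_Mr", "K_I")
  m <- ifelse(binding,
              1 / (-0.01 * exp(cc * current_value)),
              -0.01 * exp(cc * current_value))
  unname(pmin(pmax(m, cfg$mean_clamp[1]), cfg$mean_clamp[2]))
}

# Mean percent effect under the configured mode (0 for neutral).
effect_mean <- function(param_class, current_value, cfg) {
  if (cfg$mode == "neutral") return(rep(0, length(param_class)))
  effect_mean_biological(param_class, current_value, cfg)
}

#' Sample a multiplicative mutational effect
#'
#' Draws a percent effect `delta ~ Normal(mean, effect_sd)` where the mean
#' follows the configured regime, and returns the multiplier
#' `max(1 + delta/100, mult_floor)`, always strictly positive.
#'
#' @inheritParams effect_mean_biological
#' @param n Number of draws.
#' @return Multiplier(s), strictly positive.
#' @export
sample_effect <- function(cfg, param_class, current_value, n = 1) {
  m <- effect_mean(param_class, current_value, cfg)
  delta <- rnorm(n, mean = m, sd = cfg$effect_sd)
  pmax(1 + delta / 100, cfg$mult_floor)
}

#' Mutate a genotype
#'
#' Each of the 26 parameters mutates independently with probability
#' `per_param_rate`; mutated values are multiplied by a draw from
#' [sample_effect()]. `K_M` and `k_cat` evolve independently. Untouched
#' parameters are returned bit-identical. Under the Haldane mode `k_catr` is
#' not a free parameter: it is recomputed from the equilibrium constant
#' whenever any of its enzyme's `k_cat`, `K_M`, `K_Mr` mutate, and is never
#' itself a mutation target.
#'
#' @param g A [genotype()].
#' @param cfg A [mutation_config()].
#' @return The mutated genotype.
#' @export
apply_mutations <- function(g, cfg) {
  cls <- param_classes()
  free <- if (cfg$mode == "haldane") which(cls != "k_catr") else seq_len(26L)
  hit <- free[runif(length(free)) < cfg$per_param_rate]
  if (!length(hit)) return(g)
  out <- unclass(g)
  if (cfg$mode == "haldane") {
    if (is.null(cfg$haldane))
      stop("mode 'haldane' requires cfg$haldane (a haldane_config)")
    trio <- cls[hit] %in% c("k_cat", "K_M", "K_Mr")
    n_tr <- sum(trio)
    mult <- numeric(length(hit))
    if (n_tr)
      mult[trio] <- pmax(1 + rnorm(n_tr, cfg$haldane$haldane_mean,
                                   cfg$haldane$haldane_sd) / 100,
                         cfg$mult_floor)
    if (any(!trio))
      mult[!trio] <- sample_effect(cfg, cls[hit[!trio]], out[hit[!trio]],
                                   n = sum(!trio))
    out[hit] <- out[hit] * mult
    for (enz in unique((hit[trio] - 1L) %/% 5L + 1L)) {
      i <- 5L * (enz - 1L)
      out[i + 4L] <- out[i + 2L] * out[i + 5L] /
        (cfg$haldane$Keq_per_reaction[enz] * out[i + 3L])
    }
  } else {
    out[hit] <- out[hit] * sample_effect(cfg, cls[hit], out[hit],
                                         n = length(hit))
  }
  validate_genotype(out)
}

#' Haldane-constrained mutation of one enzyme
#'
#' Applies independent percent effects ~ Normal(`haldane_mean`,
#' `haldane_sd`) to `K_M`, `K_Mr` and `k_cat`, then sets
#' `k_catr = (k_cat * K_Mr) / (Keq * K_M)` so the output satisfies the
#' Haldane identity exactly, for the reaction's configured `Keq`.
#'
#' @param e An [enzyme_params()] object whose current parameters satisfy the
#'   configured `Keq` to within 1e-9 relative.
#' @param hcfg A [haldane_config()].
#' @param reaction Which reaction's `Keq` applies (1-5, default 1).
#' @return Mutated `enzyme_params`.
#' @export
mutate_haldane <- function(e, hcfg, reaction = 1L) {
  Keq <- hcfg$Keq_per_reaction[reaction]
  if (abs(keq(e) - Keq) > 1e-9 * Keq)
    stop("input enzyme violates the configured Keq (relative error > 1e-9)")
  mult <- pmax(1 + rnorm(3, hcfg$haldane_mean, hcfg$haldane_sd) / 100, 1e-3)
  kc <- e[["k_cat"]] * mult[1]
  km <- e[["K_M"]] * mult[2]
  kmr <- e[["K_Mr"]] * mult[3]
  kcr <- kc * kmr / (Keq * km)
  enzyme_params(e[["enzyme_conc"]], kc, km, kcr, kmr,
                K_I = if ("K_I" %in% names(e)) e[["K_I"]] else NA_real_)
}
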
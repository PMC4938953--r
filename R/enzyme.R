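# Genotype representation: a named numeric vector of 26 kinetic parameters,
# five per enzyme (conc, kcat, KM, kcatr, KMr for enzymes A..E) plus the
# single inhibition constant KI carried by the feedback-inhibited enzyme.

.enzymes <- c("A", "B", "C", "D", "E")
.par_suffixes <- c("conc", "kcat", "KM", "kcatr", "KMr")

#' Canonical parameter names of a genotype
#'
#' Internal storage order is the five kinetic parameters of each enzyme A-E
#' (`conc`, `kcat`, `KM`, `kcatr`, `KMr`) followed by the inhibition constant
#' `A_KI`. Serialization (TSV) reorders so that `A_KI` follows enzyme A's
#' block.
#'
#' @return Character vector of length 26.
#' @export
param_names <- function() {
  c(as.vector(t(outer(.enzymes, .par_suffixes, paste, sep = "_"))), "A_KI")
}

#' Parameter class of each genotype entry
#'
#' Maps each of the 26 parameters to its mutational class, the key used in a
#' mutation configuration's `c_table`.
#'
#' @return Character vector of length 26 with values in
#'   `c("enzyme_conc", "k_cat", "K_M", "k_catr", "K_Mr", "K_I")`.
#' @export
param_classes <- function() {
  cls <- c("enzyme_conc", "k_cat", "K_M", "k_catr", "K_Mr")
  setNames(c(rep(cls, 5L), "K_I"), param_names())
}

#' Kinetic parameters of one enzyme
#'
#' Bundles the five reversible Michaelis-Menten parameters of a single
#' enzyme, with an optional inhibition constant for the enzyme that carries
#' the feedback loop. All values are strictly positive.
#'
#' @param enzyme_conc Enzyme concentration (mmol/l).
#' @param k_cat Forward catalytic constant (mmol/l/s).
#' @param K_M Substrate Michaelis constant (mmol/l).
#' @param k_catr Reverse catalytic constant (mmol/l/s).
#' @param K_Mr Product Michaelis constant (mmol/l).
#' @param K_I Inhibition constant (mmol/l), or `NA` for uninhibited enzymes.
#' @return A named numeric vector of class `enzyme_params`.
#' @examples
#' enzyme_params(1, 100, 0.5, 10, 1)
#' @export
enzyme_params <- function(enzyme_conc, k_cat, K_M, k_catr, K_Mr, K_I = NA_real_) {
  e <- c(enzyme_conc = enzyme_conc, k_cat = k_cat, K_M = K_M,
         k_catr = k_catr, K_Mr = K_Mr, K_I = K_I)
  pos <- e[!is.na(e)]
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("all enzyme parameters must be finite and strictly positive")
  structure(e, class = "enzyme_params")
}

#' Assemble a genotype from five enzymes
#'
#' A genotype is the full heritable state of one individual: the ordered
#' kinetic parameters of enzymes A-E (catalyzing reactions 1-5) plus the
#' inhibition constant, 26 mutable parameters in total. Exactly one enzyme
#' must carry `K_I`.
#'
#' @param ... Five `enzyme_params` objects (or a single list of five), in
#'   pathway order A-E.
#' @return Named numeric vector of length 26 with class `genotype`.
#' @seealso [default_genotype()], [enzyme_params()]
#' @export
genotype <- function(...) {
  enz <- list(...)
  if (length(enz) == 1L && is.list(enz[[1]]) &&
      !inherits(enz[[1]], "enzyme_params"))
    enz <- enz[[1]]
  if (length(enz) != 5L)
    stop("a genotype requires exactly 5 enzymes")
  ki <- vapply(enz, function(e) unname(e["K_I"]), numeric(1))
  if (sum(!is.na(ki)) != 1L)
    stop("exactly one enzyme must carry the inhibition constant K_I")
  g <- unlist(lapply(enz, function(e) unname(e[1:5])))
  g <- c(g, ki[!is.na(ki)])
  names(g) <- param_names()
  validate_genotype(g)
}

#' @rdname genotype
#' @param g Numeric vector of length 26 in canonical order (see
#'   [param_names()]).
#' @export
as_genotype <- function(g) {
  g <- as.numeric(g)
  names(g) <- param_names()
  validate_genotype(g)
}

validate_genotype <- function(g) {
  if (length(g) != 26L) stop("a genotype has exactly 26 parameters")
  if (any(!is.finite(g)) || any(g < 0))
    stop("genotype parameters must be finite and non-negative")
  structure(g, class = "genotype")
}

#' Default pathway parameterization
#'
#' Surrogate initial kinetic values for the five-enzyme pathway. They are
#' package choices (not measured constants), calibrated jointly so that (i)
#' the initial steady-state flux falls in the rising region of the
#' flux-fitness logistic, just below its midpoint of 650 mmol/l/s, so
#' selection pressure exists at generation zero; (ii) intermediate pools sit
#' on the concentration scale at which the toxicity scalar of the
#' deleterious-intermediate scheme (9.4e-4 l/mmol) exerts real selection;
#' and (iii) reactions are substantially reversible (Keq = 20 per step), so
#' a downstream bottleneck propagates backpressure that accumulates the
#' early intermediates, as the positive-control scheme presumes. Enzymes are
#' given slightly different constants so the pathway is not artificially
#' symmetric.
#'
#' @return A `genotype`.
#' @export
default_genotype <- function() {
  as_genotype(c(
    3.2, 400, 50, 20.0, 50,   # A (reaction 1, feedback-inhibited)
    3.2, 410, 55, 20.5, 50,   # B
    3.2, 390, 45, 19.5, 50,   # C
    3.2, 420, 60, 21.0, 50,   # D
    3.2, 400, 50, 20.0, 50,   # E
    2000))                    # A_KI
}

#' Extract one enzyme's parameters from a genotype
#'
#' @param g A `genotype`.
#' @param which Enzyme letter `"A"`-`"E"` or index 1-5.
#' @return An `enzyme_params` object.
#' @export
genotype_enzyme <- function(g, which) {
  i <- if (is.character(which)) match(which, .enzymes) else as.integer(which)
  if (is.na(i) || i < 1L || i > 5L) stop("enzyme must be A-E or 1-5")
  e <- unname(g[(5L * (i - 1L) + 1L):(5L * i)])
  enzyme_params(e[1], e[2], e[3], e[4], e[5],
                K_I = if (i == 1L) unname(g[26L]) else NA_real_)
}

# TSV serialization order: K_I follows enzyme A's block.
.tsv_order <- function() {
  c(paste("A", c(.par_suffixes, "KI"), sep = "_"),
    as.vector(t(outer(.enzymes[-1], .par_suffixes, paste, sep = "_"))))
}

#' Serialize genotypes to a flat table
#'
#' One row per genotype, 26 named columns (`A_conc`, `A_kcat`, `A_KM`,
#' `A_kcatr`, `A_KMr`, `A_KI`, `B_conc`, ...).
#'
#' @param g A `genotype` or a matrix with 26 columns in canonical order.
#' @return A data.frame in serialization column order.
#' @export
genotype_to_row <- function(g) {
  m <- if (is.matrix(g)) g else matrix(g, nrow = 1)
  colnames(m) <- param_names()
  as.data.frame(m)[, .tsv_order(), drop = FALSE]
}

#' @rdname genotype_to_row
#' @param row A one-row data.frame or named vector with the 26 serialization
#'   columns.
#' @export
genotype_from_row <- function(row) {
  v <- unlist(row)
  as_genotype(v[param_names()])
}

#' @export
print.genotype <- function(x, ...) {
  cat("<genotype> 26 kinetic parameters (5 enzymes + K_I)\n")
  m <- matrix(x[1:25], nrow = 5, byrow = TRUE,
              dimnames = list(.enzymes, .par_suffixes))
  print(signif(m, 4))
  cat("A_KI:", format(signif(x[26], 4)), "\n")
  invisible(x)
}
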
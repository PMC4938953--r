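# Post-simulation statistics: rate-limiting-step identification and
# stability (run lengths, permutation test, nested bootstrap), allele
# segregation against the Kimura-Crow neutral expectation, and co-evolution
# clustering of kinetic-parameter rates of change.

#' Identify the rate-limiting (flux-controlling) step
#'
#' Scales each reaction's capacity by `factor` (default 0.9, a 10 percent
#' reduction) while holding the others fixed, re-solves the steady state,
#' and scores each reaction by the flux drop it causes. The rate-limiting
#' step is the reaction with the largest drop, ties broken by lowest index.
#' Capacity is scaled through the enzyme concentration, which multiplies the
#' whole rate law by `factor` exactly; scaling `k_cat` and `k_catr` jointly
#' is available as an alternative.
#'
#' @param g A [genotype()].
#' @param env A [kinetic_env()].
#' @param factor Capacity scaling (default 0.9).
#' @param mode `"enzyme_conc"` (default) or `"kcat"` perturbation.
#' @return List: `reaction` (1-5, or `NA` when the base genotype does not
#'   converge), `sensitivities` (flux drop per reaction), `flux` (base).
#' @export
identify_rate_limiting <- function(g, env = kinetic_env(), factor = 0.9,
                                   mode = c("enzyme_conc", "kcat")) {
  mode <- match.arg(mode)
  sen <- .sensitivities_cpp(as.numeric(g), .env_list(env), factor,
                            if (mode == "enzyme_conc") 0L else 1L)
  reaction <- if (isTRUE(sen$converged) && !anyNA(sen$sensitivities))
    which.max(sen$sensitivities) else NA_integer_
  list(reaction = reaction, sensitivities = sen$sensitivities,
       flux = sen$flux, converged = sen$converged)
}

#' Run lengths of the rate-limiting step
#'
#' Extracts maximal constant runs from a per-generation series of
#' rate-limiting reaction indices: the number of consecutive generations a
#' reaction remained rate limiting, once it became so. Also reports the
#' pooled proportion of generations each reaction spent rate limiting
#' (the Table-1-style partition, summing to 1).
#'
#' @param series Integer vector of reaction indices in 1..5 (NAs dropped).
#' @param n_reactions Number of reactions (default 5).
#' @return List of class `runlength_summary`: `runs` (list of run-length
#'   vectors per reaction), `mean_run_length`, `proportions`, `n`.
#' @examples
#' run_lengths(c(1, 1, 2, 2, 2, 1))
#' @export
run_lengths <- function(series, n_reactions = 5L) {
  series <- series[!is.na(series)]
  if (!length(series)) stop("series contains no rate-limiting calls")
  if (any(!series %in% seq_len(n_reactions)))
    stop("series values must be reaction indices in 1..", n_reactions)
  r <- rle(as.integer(series))
  runs <- lapply(seq_len(n_reactions),
                 function(i) r$lengths[r$values == i])
  names(runs) <- paste0("reaction_", seq_len(n_reactions))
  mrl <- vapply(runs, function(x) if (length(x)) mean(x) else NA_real_,
                numeric(1))
  prop <- vapply(runs, sum, numeric(1)) / length(series)
  structure(list(runs = runs, mean_run_length = mrl, proportions = prop,
                 n = length(series)),
            class = "runlength_summary")
}

#' Permutation test for rate-limiting-step stability
#'
#' Null hypothesis: no stability, i.e. every reaction has the same average
#' run length. The observed statistic is the average absolute deviation of
#' the per-reaction mean run lengths (averaged across replicates) from their
#' overall mean; the null distribution permutes the reaction labels within
#' each replicate. The empirical p-value carries the standard +1 correction.
#'
#' @param mean_runs Matrix, replicates x reactions, of per-replicate
#'   per-reaction mean run lengths (`NA` allowed for reactions never rate
#'   limiting in a replicate).
#' @param n_perm Number of permutation replicates (default 1e5).
#' @return List: `p_value`, `observed`, `n_perm`.
#' @export
permutation_test <- function(mean_runs, n_perm = 1e5) {
  M <- as.matrix(mean_runs)
  if (ncol(M) < 2L) stop("need at least 2 reactions")
  stat <- function(m) {
    cm <- colMeans(m, na.rm = TRUE)
    mean(abs(cm - mean(cm, na.rm = TRUE)), na.rm = TRUE)
  }
  obs <- stat(M)
  k <- ncol(M)
  ge <- 0L
  perm <- M
  for (b in seq_len(n_perm)) {
    for (r in seq_len(nrow(M))) perm[r, ] <- M[r, sample.int(k)]
    if (stat(perm) >= obs) ge <- ge + 1L
  }
  list(p_value = (1 + ge) / (1 + n_perm), observed = obs, n_perm = n_perm)
}

#' Nested bootstrap confidence intervals for mean run lengths
#'
#' Resamples replicates with replacement, then resamples the consecutive
#' runs within each selected replicate, and takes the 2.5th and 97.5th
#' percentiles of the resulting mean run length per reaction.
#'
#' @param runs_by_replicate List over replicates; each element a list of
#'   per-reaction run-length vectors (as in `run_lengths()$runs`).
#' @param n_boot Bootstrap replicates (default 1e4).
#' @param conf Confidence level (default 0.95).
#' @return Matrix `n_reactions x 2` (`lower`, `upper`); rows are `NA` for
#'   reactions never observed rate limiting.
#' @export
bootstrap_ci <- function(runs_by_replicate, n_boot = 1e4, conf = 0.95) {
  R <- length(runs_by_replicate)
  if (!R) stop("need at least one replicate")
  k <- length(runs_by_replicate[[1]])
  draws <- matrix(NA_real_, n_boot, k)
  for (b in seq_len(n_boot)) {
    sel <- sample.int(R, R, replace = TRUE)
    for (j in seq_len(k)) {
      pooled <- unlist(lapply(sel, function(r) {
        x <- runs_by_replicate[[r]][[j]]
        if (length(x)) x[sample.int(length(x), length(x), replace = TRUE)]
        else numeric(0)
      }))
      if (length(pooled)) draws[b, j] <- mean(pooled)
    }
  }
  a <- (1 - conf) / 2
  ci <- t(apply(draws, 2L, function(d)
    if (all(is.na(d))) c(NA_real_, NA_real_)
    else quantile(d, c(a, 1 - a), na.rm = TRUE, names = FALSE)))
  dimnames(ci) <- list(names(runs_by_replicate[[1]]), c("lower", "upper"))
  ci
}

#' Kimura-Crow expected number of segregating alleles
#'
#' Neutral expectation `n = 2 Ne mu + 1` alleles per parameter.
#'
#' @param Ne Effective population size.
#' @param mu Per-parameter mutation rate.
#' @return Expected allele count.
#' @export
expected_alleles <- function(Ne, mu) 2 * Ne * mu + 1

#' Allele segregation summary
#'
#' Distinct-allele counts per parameter, sampled every `every` generations
#' across a window (200 time points over 2000 generations at the defaults),
#' summarised per parameter (time mean) and across parameters (mean, sd,
#' min, max), both for all 26 parameters and for the forward-only set
#' (`enzyme_conc`, `k_cat`, `K_M`). Allele identity is exact value identity:
#' every mutation draws a continuous multiplier, so recurrent identical
#' alleles have probability zero. Compared against the neutral expectation
#' `2 Ne mu + 1`.
#'
#' @param traj Explicit-engine trajectory data.frame (with `n_*` allele
#'   columns), or a `fluxdrift_experiment` whose replicate trajectories are
#'   averaged after summarising each.
#' @param Ne,mu Population size and per-parameter mutation rate for the
#'   neutral expectation.
#' @param window Generations to use (default: the last 2000).
#' @param every Sampling stride in generations (default 10).
#' @return List of class `allele_summary`.
#' @export
allele_segregation <- function(traj, Ne = 100, mu = 3e-3, window = 2000L,
                               every = 10L) {
  if (inherits(traj, "fluxdrift_experiment")) {
    per <- lapply(traj$replicates, allele_segregation, Ne = Ne, mu = mu,
                  window = window, every = every)
    per_param <- rowMeans(vapply(per, `[[`, numeric(26L), "per_parameter_mean"))
    return(.allele_summarise(per_param, Ne, mu, length(per[[1]]$generations),
                             per[[1]]$generations))
  }
  acols <- grep("^n_", names(traj), value = TRUE)
  if (length(acols) != 26L)
    stop("trajectory lacks the 26 allele-count columns (explicit engine only)")
  gmax <- max(traj$generation)
  keep <- traj$generation > gmax - window &
    (traj$generation %% every == 0L)
  sub <- traj[keep, acols, drop = FALSE]
  per_param <- colMeans(sub)
  names(per_param) <- sub("^n_", "", names(per_param))
  .allele_summarise(per_param, Ne, mu, nrow(sub), traj$generation[keep])
}

.allele_summarise <- function(per_param, Ne, mu, n_points, generations) {
  fwd <- names(per_param)[param_classes()[names(per_param)] %in%
                            c("enzyme_conc", "k_cat", "K_M")]
  summ <- function(x) c(mean = mean(x), sd = sd(x), min = min(x), max = max(x))
  structure(list(per_parameter_mean = per_param,
                 all_parameters = summ(per_param),
                 forward_only = summ(per_param[fwd]),
                 expected = expected_alleles(Ne, mu),
                 n_points = n_points, generations = generations),
            class = "allele_summary")
}

# The 15 parameters retained for co-evolution analysis (reversible and
# inhibitory constants excluded) and their groups.
.coevo_params <- function() {
  cls <- param_classes()
  names(cls)[cls %in% c("enzyme_conc", "k_cat", "K_M")]
}

#' Rates of change of kinetic parameters, detrended within groups
#'
#' Computes the per-generation rate of change (first difference by default,
#' percent change optionally) of each retained parameter of the median
#' individual, then removes the per-generation mean of each parameter group
#' (enzyme concentrations, catalytic constants, binding constants) to
#' control for shared directional change. Reversible (`k_catr`, `K_Mr`) and
#' inhibitory (`K_I`) constants are excluded. Replicates are stacked row-wise.
#'
#' @param trajectories A `fluxdrift_experiment` (explicit engine) or list of
#'   trajectory data.frames carrying the 26 parameter columns.
#' @param window Generations from the end of each trajectory to use
#'   (default 2000); `Inf` uses all.
#' @param relative If `TRUE`, rates are percent changes rather than raw
#'   differences.
#' @return Matrix (stacked generations x 15 parameters) with attribute
#'   `replicate` marking each row's source replicate.
#' @export
coevolution_rates <- function(trajectories, window = 2000L, relative = FALSE) {
  if (inherits(trajectories, "fluxdrift_experiment"))
    trajectories <- trajectories$replicates
  keep <- .coevo_params()
  groups <- param_classes()[keep]
  blocks <- lapply(trajectories, function(tr) {
    if (!all(keep %in% names(tr)))
      stop("trajectory lacks median-individual parameter columns")
    m <- as.matrix(tr[, keep, drop = FALSE])
    if (is.finite(window) && nrow(m) > window + 1L)
      m <- m[(nrow(m) - window):nrow(m), , drop = FALSE]
    d <- diff(m)
    if (relative) d <- 100 * d / m[-nrow(m), , drop = FALSE]
    for (gcls in unique(groups)) {
      j <- which(groups == gcls)
      d[, j] <- d[, j] - rowMeans(d[, j, drop = FALSE])
    }
    d
  })
  out <- do.call(rbind, blocks)
  attr(out, "replicate") <- rep(seq_along(blocks),
                                vapply(blocks, nrow, integer(1)))
  out
}

# All internal clades (leaf-label sets) of an hclust tree, smallest first.
.hclust_clades <- function(h) {
  n <- length(h$labels)
  sets <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    m <- h$merge[k, ]
    grab <- function(i) if (i < 0) h$labels[-i] else sets[[i]]
    sets[[k]] <- sort(c(grab(m[1]), grab(m[2])))
  }
  sets
}

#' Bootstrap complete-linkage clustering of co-evolving parameters
#'
#' Clusters parameters by complete linkage on the distance
#' `1 - |correlation|` between their detrended rates of change, and assesses
#' cluster support by bootstrap: generation rows are resampled within each
#' replicate, the tree is rebuilt, and a cluster's support is the fraction
#' of bootstrap trees containing the identical leaf set. Clusters (of 2 or
#' more parameters, smaller than the full set) recurring in at least
#' `1 - alpha` of bootstrap trees are called significant; parameters outside
#' every significant cluster are reported as unclustered.
#'
#' @param rates Detrended rate matrix from [coevolution_rates()].
#' @param n_boot Bootstrap replicates (default 1e4).
#' @param alpha Significance level (default 0.05).
#' @return List of class `coevolution_result`: `hclust`, `correlation`,
#'   `clades` (data.frame of leaf sets with support), `significant` (the
#'   maximal significant, non-nested clusters), `unclustered`, `dropped`
#'   (zero-variance parameters excluded, with a warning).
#' @export
coevolution_clusters <- function(rates, n_boot = 1e4, alpha = 0.05) {
  repl <- attr(rates, "replicate")
  if (is.null(repl)) repl <- rep(1L, nrow(rates))
  sds <- apply(rates, 2L, sd)
  dropped <- colnames(rates)[!is.finite(sds) | sds == 0]
  if (length(dropped)) {
    warning("excluding zero-variance parameters: ",
            paste(dropped, collapse = ", "))
    rates <- rates[, setdiff(colnames(rates), dropped), drop = FALSE]
  }
  if (ncol(rates) < 3L) stop("need at least 3 parameters with variance")
  cm <- cor(rates)
  h <- hclust(as.dist(1 - abs(cm)), method = "complete")
  clades <- .hclust_clades(h)
  keys <- vapply(clades, paste, character(1), collapse = "|")
  hits <- integer(length(clades))
  idx_by_rep <- split(seq_len(nrow(rates)), repl)
  for (b in seq_len(n_boot)) {
    take <- unlist(lapply(idx_by_rep, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    cb <- suppressWarnings(cor(rates[take, , drop = FALSE]))
    cb[!is.finite(cb)] <- 0
    hb <- hclust(as.dist(1 - abs(cb)), method = "complete")
    bk <- vapply(.hclust_clades(hb), paste, character(1), collapse = "|")
    hits <- hits + (keys %in% bk)
  }
  support <- hits / n_boot
  sizes <- lengths(clades)
  ok <- support >= 1 - alpha & sizes >= 2L & sizes < ncol(rates)
  # maximal significant clades: drop those nested inside a larger one
  sig <- clades[ok]
  sup <- support[ok]
  if (length(sig) > 1L) {
    keep <- !vapply(seq_along(sig), function(i)
      any(vapply(seq_along(sig), function(j)
        j != i && length(sig[[i]]) < length(sig[[j]]) &&
          all(sig[[i]] %in% sig[[j]]), logical(1))), logical(1))
    sig <- sig[keep]
    sup <- sup[keep]
  }
  clustered <- unique(unlist(sig))
  structure(list(
    hclust = h, correlation = cm,
    clades = data.frame(clade = keys, size = sizes, support = support,
                        stringsAsFactors = FALSE),
    significant = if (length(sig))
      data.frame(clade = vapply(sig, paste, character(1), collapse = "|"),
                 size = lengths(sig), support = sup,
                 stringsAsFactors = FALSE)
      else data.frame(clade = character(0), size = integer(0),
                      support = numeric(0)),
    members = sig,
    unclustered = setdiff(colnames(rates), clustered),
    dropped = dropped, alpha = alpha, n_boot = n_boot),
    class = "coevolution_result")
}

#' Export a clustering dendrogram as Newick text
#'
#' @param res A `coevolution_result`.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(res, path = NULL) {
  phy <- ape::as.phylo(res$hclust)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
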
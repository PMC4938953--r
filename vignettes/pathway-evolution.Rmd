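---
title: "Simulating the evolution of rate-limiting steps in a metabolic pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the evolution of rate-limiting steps in a metabolic pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxdrift)
```

## The question

Biochemical intuition often treats the rate-limiting (flux-controlling) step
of a metabolic pathway as a conserved, selectable feature: the bottleneck a
cell regulates, and therefore a step evolution should stabilize. Population
genetics suggests a complication. Mutation constantly degrades enzyme
activity, purifying selection on pathway function resists that degradation,
and drift lets mildly deleterious changes fix anyway. At this
mutation-selection-drift balance every enzyme's kinetic parameters keep
wandering, so the identity of the most flux-controlling reaction can itself
wander. `fluxdrift` implements a complete simulation framework for this
question on a five-enzyme linear pathway, together with the statistics
needed to quantify how long any step stays rate limiting.

## The kinetic model

The pathway converts a boundary metabolite A through intermediates B, C, D,
E into a final product F (reactions 1-5, catalyzed by enzymes A-E). A is
held at a fixed concentration (constant replenishment); F is consumed by
first-order mass action with rate constant $k_{use}$. Each reaction obeys
reversible Michaelis-Menten kinetics,

$$ v = [E]\,\frac{k_{cat} S/K_M - k_{catr} P/K_{Mr}}
                 {1 + S/K_M + P/K_{Mr} + I/K_I}, $$

where the inhibitor term exists only on the single feedback-inhibited
reaction. The feedback loop is wired by default as end-product inhibition of
reaction 1 by F, the glycolysis-like regulation; both ends of the loop are
configurable in `kinetic_env()`. Each enzyme therefore carries five mutable
parameters, and the genotype — 5 x 5 parameters plus $K_I$, 26 in all — is
the heritable state of one individual.

Thermodynamics enters through Haldane's relationship,
$K_{eq} = k_{cat} K_{Mr} / (k_{catr} K_M)$: the net rate is zero exactly at
$P/S = K_{eq}$, and the thermodynamically constrained mutation mode (below)
holds every reaction's $K_{eq}$ fixed along the mutational trajectory.

Steady states are found by damped Newton iteration on the five-dimensional
rate-balance system, with a pseudo-transient (implicit Euler) continuation
as a fallback for the stiff systems that extreme mutants produce, and a
final cap (`max_time`) after which non-convergence is reported in-band
(`converged = FALSE`) rather than as an error — a mutant that destroys the
pathway must be selectable against, not crash the run. The pathway flux is
reported as the net rate of reaction 5, which at convergence equals every
other net rate and $k_{use}[F]$ within `solver_tol`. The solver is
implemented in compiled code because the evolutionary engines need on the
order of $10^5$–$10^6$ solves per experiment; the test suite independently
verifies it against long-time integration of the same ODE system with
`deSolve` (relative flux agreement better than $10^{-6}$ across randomly
perturbed genotypes).

Two numerical guards matter at evolutionary time scales: saturation ratios
$S/K$ are capped at $10^{150}$ so that binding constants driven toward zero
by mutation cannot overflow the rate law, and Newton steps are projected
onto non-negative concentrations.

## The mutation model

Mutations hit each of the 26 parameters independently with probability
$3\times10^{-3}$ per parameter per individual per generation. Effects are
percent changes applied multiplicatively, drawn from a normal distribution
with standard deviation 1 (percent) and a mean that depends on the current
parameter value — the activity-dependent degradation bias. For
concentration-like and catalytic parameters the mean is
$\mu_1 = -0.01\,e^{c p}$; for binding constants it is
$\mu_2 = 1/(-0.01\,e^{c K})$. The scaling index $c$ is class-specific:
2.5e-2 for enzyme concentration and $K_I$, 1.0e-2 for $k_{cat}$, 3.33e-4
for $k_{catr}$, 1 for $K_M$, and 3.33e-2 for $K_{Mr}$.

Both raw forms are unbounded (at $k_{cat}$ of a few hundred, $\mu_1$ alone
would exceed -100%), so the package clamps the mean to $[-25, 0]$ percent.
The clamp preserves everything that carries meaning — the bias is always
degrading and its magnitude non-decreasing in the current value — while
keeping multipliers finite; a per-draw floor of $10^{-3}$ on the multiplier
guarantees no parameter ever becomes non-positive. The neutral control mode
sets every mean to zero, making the mutational distribution
parameter-independent.

The Haldane mode replaces the scheme for the kinetic constants: $K_M$,
$K_{Mr}$ and $k_{cat}$ receive independent Normal(-1, 1)% effects and
$k_{catr}$ is then recomputed as $k_{cat} K_{Mr} / (K_{eq} K_M)$, so the
equilibrium constant is preserved exactly (to machine precision over
arbitrarily long chains, since it is imposed rather than accumulated).
$k_{catr}$ is consequently not itself a mutational target in this mode:
proposals are uniform over the 21 free parameters, with enzyme
concentration and $K_I$ retaining the biological scheme. This is the
package's resolution of an ambiguity — the constraint removes one degree of
freedom per reaction, and reprojecting the dependent parameter is the one
scheme that satisfies every stated property of the constrained model.

## Fitness schemes

Five selection schemes map the steady state to fitness:

* `mutation_only` — constant fitness 1 (pure mutational pressure, sampling
  uniform);
* `flux_only` — $F_1 = 1/(1+e^{-0.07(flux-650)})$, a logistic with midpoint
  650 mmol/l/s and slope 0.07. (The midpoint/slope reading is the only
  interpretation of these two constants that yields a function defined for
  all fluxes and increasing throughout; fitness of a non-converged or
  negative-flux mutant is 0.)
* `flux_intermediate` — $F_1 F_2$ with $F_2 = e^{-s[B]}$,
  $s = 9.4\times10^{-4}$ l/mmol: selection against accumulation of the
  toxic intermediate B (the methylglyoxal analogue), with the biological
  mutation mode;
* `flux_cost` — $F_1 F_3$ with
  $F_3 = 1/(1 + s\,(cost_{protein} + cost_{mRNA}))$, $s = 10^{-6}$,
  $cost_{protein} = 30.3\sum_i [E_i]\,length_i$ and
  $cost_{mRNA} = 49.2\sum_i 3\,length_i [E_i]/1000$: selection against
  expression cost;
* `positive_control` — $F_1 F_2$ with the *neutral* mutation mode:
  selection for reaction 1 to become and stay rate limiting by preventing
  buildup of its product.

Enzyme lengths default to {A 450, B 390, C 350, D 510, E 330} amino acids —
surrogate values spanning a realistic glycolytic-enzyme range, distinct so
length-dependent effects are testable, and config-overridable.

## Population-genetic engines

The explicit engine is a Wright-Fisher simulation: a homogeneous population
of N = 100 individuals (N limited by the cost of one steady-state solve per
individual per generation), fitness-weighted sampling with replacement, and
mutation applied to offspring after sampling so that new mutations can
elicit fitness effects before the next round of selection. Each generation
records the median individual — the member at 0-based rank
$\lfloor N/2 \rfloor$ of the fitness ordering, ties broken by stable
population index, the only ordering the model defines — plus its flux,
fitness, rate-limiting reaction, and the count of distinct alleles per
parameter. Full-scale experiments run 22,000 generations with
mutation-selection balance assessed by generation 20,000 (the package's
equilibrium diagnostic is the sign balance of median-fitness changes over
the final window), five replicates each.

The origin-fixation engine eliminates the explicit population: one mutation
is proposed per generation (one parameter chosen uniformly among the free
parameters) and fixes with the Kimura probability

$$ \psi = \frac{1 - e^{-2 c N_e s p}}{1 - e^{-2 c N_e s}}, $$

with ploidy $c = 1$, selection coefficient $s = f'/f_0 - 1$, and initial
frequency $p = 1/2$ — so a neutral mutation fixes with probability one
half, which rescales the effective strength of selection but leaves the
mutational process independent of $N_e$. The analytic limit $\psi \to p$ as
$s \to 0$ is used below $|2cN_e s| < 10^{-12}$, and saturated exponentials
are handled in closed form. Full-scale runs are 200,000 generations and 30
replicates at $N_e = 10^2$ or $10^6$. The engine consumes exactly three
random draws per generation (parameter index, effect, acceptance), a
deliberate contract: the compiled inner loop and the exported
single-generation R function reproduce each other draw for draw, and the
test suite replays one against the other.

Each experiment derives independent replicate seeds from the master seed,
and `(config, seed)` fully determines every trajectory.

## Analysis layer

**Rate-limiting step.** Each reaction's capacity is scaled by 0.9 and the
steady state re-solved; the sensitivity is the flux drop, and the
rate-limiting step is the argmax, ties to the lowest index. Scaling the
enzyme concentration is the default because it multiplies the entire rate
law — forward and reverse capacity together — by exactly 0.9; scaling
$k_{cat}$ and $k_{catr}$ jointly is available as an option and is
equivalent for this rate law up to the enzyme-bound terms. This is a finite
10% perturbation, deliberately not an infinitesimal control coefficient.

**Run lengths.** The stability statistic is the number of consecutive
generations a reaction remains rate limiting once it becomes so. The
package reports per-reaction run-length means, the pooled proportion of
generations each reaction spent rate limiting (a probability vector over
reactions), a label-permutation test (observed statistic: average absolute
deviation of per-reaction means from their overall mean; labels permuted
within each replicate; 100,000 permutations at full scale, with the
standard +1 empirical correction so p is never exactly zero), and nested
bootstrap confidence intervals (resample replicates, then runs within each
selected replicate; 2.5th/97.5th percentiles of the pooled mean).

**Allele segregation.** Distinct-value counts per parameter, sampled every
10 generations over the 2,000 post-equilibrium generations (200 points),
summarised per parameter and across parameters, and compared with the
Kimura-Crow neutral expectation $n = 2N_e\mu + 1$ (1.6 at $N_e = 100$,
$\mu = 3\times10^{-3}$). Allele identity is exact floating-point equality,
valid because every mutation draws a continuous multiplier, so recurrent
identical alleles have probability zero.

**Co-evolution.** Rates of change (per-generation first differences of the
median individual's parameters; percent differences are a config option)
are computed for the 15 forward parameters — enzyme concentrations,
catalytic constants, substrate binding constants; reversible and inhibitory
constants are excluded as having minimal impact on the system. To control
for shared directional change, the per-generation mean of each parameter
group is subtracted within the group. Complete-linkage clustering on
$1 - |r|$ follows, with cluster support assessed by bootstrapping
generation rows within each replicate: a cluster's support is the fraction
of bootstrap trees containing the identical leaf set, clusters at support
$\geq 0.95$ are called significant, and maximal significant clusters are
reported with all remaining parameters flagged unclustered. "Identical leaf
set" support is the package's definition of cluster significance; the
underlying choice is documented here because other support definitions
exist.

## The default parameterization, and what it does and does not emulate

The network's quantitative initial values are not published, so the
package's defaults are surrogate choices, and they were derived from the
constants that *are* printed, since those fix the scales the pathway must
operate on:

* the flux-fitness logistic (midpoint 650 mmol/l/s) requires initial flux
  in its rising region: the defaults give 565 mmol/l/s, inside the
  calibration band 300-640 the fixture layer asserts;
* the toxicity scalar $s = 9.4\times10^{-4}$ l/mmol only exerts selection
  if intermediate pools reach hundreds of mmol/l: with $K_M, K_{Mr}$ of
  45-60 mmol/l the default steady state holds [B] near 500 mmol/l, where
  $F_2 \approx 0.62$;
* the positive-control scheme presumes that a bottleneck anywhere
  downstream accumulates the early intermediate; with $K_{eq} = 20$ per
  step ($k_{catr} = k_{cat}/20$) backpressure propagates, and constricting
  reaction 3 demonstrably raises [B];
* the cost constants put $F_3 \approx 0.84$ at the default expression
  levels, so expression cost is a real but not dominant pressure.

Enzymes get slightly different constants so the pathway is not artificially
symmetric. All defaults are config-overridable.

What passing tests show is that the implemented mechanisms interact as the
model intends — they do not show that any real pathway has these kinetic
values. In particular, the absolute magnitude of emergent quantities (for
example the mean number of generations a step stays rate limiting, which
depends on how closely enzyme capacities are bunched) is sensitive to the
unpublished initial values; qualitative contrasts between schemes and
engines are the robust output. The synthetic fixtures for the analysis
layer (planted correlation blocks, hand-enumerable run-length series,
bottlenecked genotypes) exercise the statistics in isolation and carry no
biological content at all.

## Problem sizes

The full-scale experiments (22,000 x 5 explicit; 200,000 x 30
origin-fixation; 100,000-permutation / 10,000-bootstrap inference) are the
presets' defaults. The test suite and the acceptance script run the same
machinery at reduced sizes chosen as the package's own test design:
explicit runs of 4,000-6,000 generations at N = 50-100, origin-fixation
runs of 50,000 generations x 5 replicates, and resampling sizes of a few
hundred, which preserve every mutation-selection-balance property the
statistics probe while completing in minutes. The `scale` argument of
`preset()` makes the same reduction available to users.

## Known limitations

* The pathway is strictly linear: no branches, cycles, isoenzymes, or
  network growth.
* Only steady-state flux is read out; transient dynamics carry no fitness.
* The explicit engine is haploid and asexual, with no recombination and no
  sequence-level mutation model; allele counts track distinct parameter
  values only.
* The origin-fixation approximation excludes segregating variation by
  construction, which is precisely why its run-length scale differs from
  the explicit engine's.
* The mixed-effects models sometimes used for slope comparisons between
  selection regimes are out of scope; the per-replicate trajectory tables
  the package emits are the input such models would consume.
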
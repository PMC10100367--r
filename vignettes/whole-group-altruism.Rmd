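---
title: "Whole-group trait altruism under an ecological scaffold: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-group trait altruism under an ecological scaffold: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoscaffold)
```

## The model and its assumptions

Two microbial genotypes share a well-mixed group: a selfish S-type that
consumes a growth-limiting nutrient at rate $c_S$ per cell per generation,
and an altruistic A-type that consumes at the reduced rate
$c_A = \delta c_S$, $\delta \in (0,1]$, but produces a public good that
lowers the death rate of every cell in the group. A cell reproduces when it
captures one nutrient unit, so with influx $R_{in}$ per group per
generation, the whole group produces $R_{in}$ offspring in expectation —
*all* of the influx is consumed and converted to cells. The assumptions
worth keeping in mind:

* groups are well-mixed; the public good benefits all members equally
  (whole-group trait altruism, the `alpha = 1` default), so there is no
  within-group assortment of any kind;
* generations are discrete and non-overlapping in the accounting sense,
  though ancestors may survive a mapping (fitness = offspring + survival);
* exactly two genotypes, connected by a symmetric "genetic switch" mutation
  with probability `P_mut` per cell per generation;
* the environment is exogenous: influx, death rates, grid, and dispersal
  schedule are imposed, never evolved.

One generation of the engine (`step_groups()`): (i) the A-subpopulation's
consumption ratio $cR = \delta n_A / (\delta n_A + n_S)$ is computed from
the *ancestral* counts; (ii) per-type offspring totals are drawn as a single
Poisson with the aggregate mean ($cR \cdot R_{in}$ for A), which is
distributionally identical to one Poisson draw per ancestral cell — sums of
independent Poissons are Poisson — and is what makes the engine vectorize
across thousands of replicates or grid patches; (iii) each ancestral cell
survives a Bernoulli draw at the ancestral death rate
$D(\pi) = D_{max} + \pi(D_{min} - D_{max})$; offspring are not culled in
their birth generation, consistent with the fitness convention
$w = \beta + (1 - D)$; (iv) mutation applies to every cell present after
birth and death, newborns included — the switch probability is "per cell per
generation" with no exclusion.

Groups equilibrate at $N_{cap}(\pi) = R_{in}/D(\pi)$, where mean fitness is
one. At the defaults ($D_{min} = 0.05$, $D_{max} = 0.30$) a pure A-type
group is six times larger than a pure S-type group — the "weight of
numbers" that drives everything downstream.

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `R_in` | nutrient influx | 5 (or 50 for the abundant regime) | units / group / generation |
| `delta` | consumption deficit $c_A/c_S$ | 0.98 | — |
| `D_min` | death probability in a pure A group | 0.05 | / cell / generation |
| `D_max` | death probability in a pure S group | 0.30 | / cell / generation |
| `alpha` | S-type share of the benefit | 1 | — |
| `P_mut` | switch-mutation probability | $10^{-6}$ | / cell / generation |
| `delta_g` | generations between dispersal rounds | 100 | generations |
| propagule shape | Beta parameters for the propagule fraction | (5, 15), mean 0.25 | — |
| viscosity | 1 = Moore neighbors only, 0 = all pairs | 1 | — |

`R_in = 5` is the "severe limitation" regime: S-type groups hold ~17 cells,
drift dominates the $\sim 10^{-3}$ fitness gap, and a lone altruist mutant
fixes almost as often as a neutral one. `R_in = 50` is the contrast regime
where selection sees the same gap clearly.

## Fitness structures and the strong/weak boundary

Under unlimited growth (hard selection) the fitness gap
$w_A - w_S = \beta_A - \beta_S$ is composition-independent. Under shared
nutrient limitation (soft selection) the per-capita forms give the exact
closed-form gap $-R_{in}(1-\delta)/(\delta n_A + n_S)$; the package
evaluates both routes and the test suite holds them to $10^{-12}$ agreement.
Note the gap's magnitude *grows* with $\pi$ at fixed group size (the
denominator loses weight as slow consumers replace fast ones); the familiar
"selection softens as altruists fix" picture emerges along equilibrium
sizes, where $N_{cap}(\pi)$ grows from 17 to 100 and dominates.

`switch_gain()` classifies the altruism: the fitness change of one focal
S-type cell converting to A-type in a group of constant size combines a
consumption cost proportional to $R_{in}$ with a death-rate benefit
$(D_{max}-D_{min})/N$. Because $N \propto R_{in}$, the benefit wins at low
influx: altruism is *effectively weak* (class II) at `R_in = 5` and
*strong* (class I) at `R_in = 50`. `critical_influx()` locates the boundary
by root-finding on continuous (unrounded) equilibrium sizes; rounding would
make the gain a step function of `R_in` and the root ill-defined, while the
continuous version is smooth and monotone so the root is unique —
`uniroot()` on `[0.1, 1000]` is reliable here.

## The Price decomposition and its weighting convention

`price_decomposition()` returns the MLS1 decomposition twice. The generic
form computes, from per-individual character states ($z = 1$ for altruists)
and fitnesses, the between-group covariance $\mathrm{Cov}(\bar w_k, \bar
z_k)$ plus the expected within-group covariance; group-level moments are
weighted by group size so that every individual counts equally — the
decomposition's right-hand side is a sum over individuals, and any other
weighting breaks it. The model-specialized form replaces the between term
with $(D_{max} - D_{min})\mathrm{Var}(\pi_k)$. The two totals coincide
exactly *when groups share a common size*: with unequal sizes the
specialized between term omits $\mathrm{Cov}(R_{in}/n_k, \pi_k)$, the
covariance between composition and per-capita nutrient share. Both forms
are reported so the discrepancy is visible rather than silent, and the
dual-evaluation identity is enforced in the tests on ensembles with a
common size.

## Dispersal operators and their conventions

Several integerization and bookkeeping details are deliberate choices:

* **Propagule integerization.** A propagule moves
  `round_half_up(p * n_type)` cells of each type. Half-up rounding (17 from
  16.5) keeps the rule deterministic given `p`; banker's rounding would make
  equal-split cases depend on parity.
* **Random migration.** Per round, up to 10 events. Donors are drawn
  uniformly from non-empty groups that have not yet been donor *or*
  recipient this round; the same "unused" rule applies to recipients. A
  donor whose neighbors are all used forfeits its event but still counts as
  used — otherwise a blocked donor could be redrawn indefinitely. Empty
  patches may be recolonized (they can receive) but never donate.
* **Selective migration.** The ten largest non-empty groups are candidates,
  fixed at round start; size ties at the candidacy boundary are broken
  uniformly at random (sizes fluctuate stochastically, so ties are rare and
  any symmetric rule is equivalent). Each candidate donates at most once per
  round; recipients are the donor's neighbors excluding the other
  candidates, and may receive more than once. Excluding candidates as
  recipients is what protects a lone A-type group from being invaded while
  it is the largest group on the grid.
* **Trait-group selection.** Pooling-and-redistribution is implemented as
  one multinomial draw per type over all 49 patches — equivalent to
  assigning each cell an independent uniform patch label, and conserving
  counts exactly.
* **Scheduling.** One metapopulation iteration is dispersal *then*
  `delta_g` within-group generations; a run's first generation is preceded
  by a dispersal round.

## Numerical choices

* **Absorption runs** require `P_mut = 0` (enforced), since recurrent
  mutation makes "fixation" ill-defined. The generation cap defaults to
  $10^6$; absorption at these group sizes takes tens to a few thousand
  generations, so a timeout signals misconfiguration and is reported as its
  own outcome category, never dropped. Whole-group extinction (possible,
  rare) is tallied separately and excluded from fixation numerators only.
* **The exact oracle** (`absorption_oracle()`) enumerates states
  $(n_A, n_S)$ up to caps, builds each type's descendant distribution as a
  Poisson–binomial convolution with the Poisson tail truncated at cumulative
  mass $1 - 10^{-12}$, lumps any probability beyond the caps into the cap
  state, and solves $(I - Q)h = b$ densely. Caps are set at 3–6 standard
  deviations above the largest equilibrium size so the lumped mass is
  negligible. This is feasible for $R_{in} \le 2$ and exists purely to
  cross-check the Monte Carlo engine.
* **Seeding.** Every experiment driver takes a `seed`; per-trial or
  per-grid-point seeds are spawned from it with a single `sample.int()`
  sweep, so runs are bit-reproducible and trials are independent.
  Confidence intervals are 95% Wilson score intervals.

## What the simulations emulate — and what they do not

The generator reproduces the study conditions: Beta(5, 15) propagules,
$7\times 7$ grids, viscosity 1, $\Delta g \in \{1, 25, 50, 100\}$,
$P_{mut} = 10^{-6}$, and the two influx regimes. It does *not* emulate
spatial structure within groups, more than two genotypes, continuous-time
demography, resource carryover between generations, or any
environment-responsive behavior (quorum sensing, assortment). Passing tests
therefore demonstrate the drift-amplification mechanism under the model's
idealizations, not quantitative predictions for any real microbial system.

## Problem sizes and expected behavior

The test suite and acceptance script run at "desk scale": $10^4$–$3\times
10^4$ replicates for single-group fixation probabilities (three-standard-
error agreement with the reference values), 8–30 trials of $2\times 10^4$
generations for the metapopulation contrasts, and one $10^6$-generation
no-dispersal run for the mutation–drift equilibrium, checked against the
occupancy predicted from independently estimated transition rates. Full-
scale runs ($10^5$ replicates, 100 trials) use the same code paths via the
`n_reps`/`n_trials` arguments or the CLI `--scale` flag.

Two behaviors deserve flagging. First, at `R_in = 50` an "A-fixed"
metapopulation is not absorbing: S-type mutants are favored within groups
(fixation probability $1.6\times 10^{-2}$, tenfold neutral), so segregating
selfish lineages and occasional whole-group reversions hold the long-run
A-cell proportion a few percent below one. Under selective migration with
$\Delta g = 100$ the 20 000-generation endpoint consequently sits close to
the 0.95 fixation threshold itself, and per-trial classification against
that threshold is noisier than the mean composition; at $\Delta g = 50$ or
25 the endpoint is comfortably above it. Second, the trait-group outcome
distribution at `R_in = 5` is strongly bimodal (most trials end near 0 or
near 1), so its mean carries a standard deviation of about 0.5 and only
stabilizes over many trials.

## Known limitations

* The dense oracle solve is $O((a_{max} s_{max})^3)$ and memory-bound
  beyond roughly $R_{in} = 2$.
* Metapopulation runs are single-threaded; 100-trial full-scale sweeps over
  all $\Delta g$ values take hours, not minutes.
* The `alpha < 1` generalization is implemented in the analytics and the
  engine's death rates, but the dispersal experiments are only exercised at
  `alpha = 1` (whole-group altruism proper).
* Nutrient cycling between influx regimes, cost-reducing mutations, and
  group-level reproduction (MLS2) are out of scope; the configuration
  format can express influx changes only between runs, not within one.
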
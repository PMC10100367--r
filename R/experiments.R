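# Experiment drivers. Every driver accepts a `seed`; when supplied, replicate
# or trial seeds are spawned from it with one `sample.int()` sweep so runs are
# bit-reproducible and trials remain independent.

spawn_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Fixation probability of a single switch mutant
#'
#' Initializes a resident pure population at birth-death equilibrium size,
#' converts one cell to the opposite type, and runs to absorption `n_reps`
#' times. Mutation is forced off for the absorption runs.
#'
#' @param direction `"A_into_S"` (an A-type mutant in an S-type group of size
#'   `round(R_in / D_max)`) or `"S_into_A"` (an S-type mutant in an A-type
#'   group of size `round(R_in / D_min)`).
#' @param params A [model_params()] object.
#' @param n_reps Number of Monte Carlo replicates.
#' @param seed Optional integer seed.
#' @param max_gens Per-replicate generation cap.
#' @return A [fixation_estimate()] for the mutant type's fixation.
#' @examples
#' p <- model_params(R_in = 5, delta = 0.98)
#' estimate_single_mutant_fixation("A_into_S", p, n_reps = 1000, seed = 1)
#' @export
estimate_single_mutant_fixation <- function(direction = c("A_into_S",
                                                          "S_into_A"),
                                            params, n_reps = 1e5,
                                            seed = NULL, max_gens = 1e6) {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  params$P_mut <- 0
  if (direction == "A_into_S") {
    n0 <- equilibrium_size(0, params)
    batch <- run_absorption_batch(1, n0 - 1, params, n_reps, max_gens)
    est <- fixation_estimate(batch, "fixed_A")
  } else {
    n0 <- equilibrium_size(1, params)
    batch <- run_absorption_batch(n0 - 1, 1, params, n_reps, max_gens)
    est <- fixation_estimate(batch, "fixed_S")
  }
  est$direction <- direction
  est
}

mixed_start <- function(pi, params) {
  pi <- unname(pi)
  N <- equilibrium_size(pi, params)
  n_A <- round_half_up(pi * N)
  c(n_A = n_A, n_S = N - n_A)
}

#' Fixation probability of the A-type in a mixed group
#'
#' For each starting proportion `pi`, a group is initialized at the
#' birth-death equilibrium size `round(R_in / D(pi))` with
#' `round(pi * N)` A-type cells, and run to absorption `n_reps` times.
#' Under severe nutrient limitation the resulting curve hugs the neutral
#' (identity) line; under abundant nutrients it stays low until `pi` is
#' close to 1.
#'
#' @param pi_grid Starting A-proportions.
#' @param params A [model_params()] object.
#' @param n_reps Replicates per grid point.
#' @param seed Optional integer seed.
#' @param max_gens Per-replicate generation cap.
#' @return A data frame with one row per grid point: `pi`, `N`, `n_A0`,
#'   `p_fix_A`, `ci_low`, `ci_high`, `n_extinct`, `n_timeout`.
#' @export
fixation_curve <- function(pi_grid = seq(0.05, 0.95, by = 0.05), params,
                           n_reps = 1e5, seed = NULL, max_gens = 1e6) {
  seeds <- spawn_seeds(seed, length(pi_grid))
  params$P_mut <- 0
  rows <- lapply(seq_along(pi_grid), function(i) {
    set.seed(seeds[i])
    st <- mixed_start(pi_grid[i], params)
    batch <- run_absorption_batch(st["n_A"], st["n_S"], params, n_reps,
                                  max_gens)
    est <- fixation_estimate(batch, "fixed_A")
    data.frame(pi = pi_grid[i], N = sum(st), n_A0 = unname(st["n_A"]),
               p_fix_A = est$p_hat, ci_low = est$ci_low,
               ci_high = est$ci_high, n_extinct = est$n_extinct,
               n_timeout = est$n_timeout)
  })
  do.call(rbind, rows)
}

#' Probability that a donor group is re-produced after migration
#'
#' Computes the expected post-migration mixing proportions `pi_AS` and
#' `pi_SA` from the propagule fraction and the equilibrium size ratio, then
#' estimates by Monte Carlo (i) the probability that an A-type donor is
#' re-produced — the A-type fixes in a recipient patch starting at `pi_AS` —
#' and (ii) the probability that an S-type donor is re-produced — the A-type
#' is eliminated starting at `pi_SA`.
#'
#' @param p Propagule fraction of the donor group.
#' @param params A [model_params()] object.
#' @param R_in Nutrient influx values to tabulate.
#' @param n_reps Replicates per estimate.
#' @param seed Optional integer seed.
#' @param max_gens Per-replicate generation cap.
#' @param pi_max Largest starting proportion used in the tabulation. The
#'   table follows the fixation-curve protocol, whose grid of starting
#'   proportions ends at 0.95; a mixing proportion above `pi_max` is
#'   evaluated there.
#' @return A data frame with one row per influx: `R_in`, `pi_AS`, `pi_SA`,
#'   `p_A_reproduced` (+ CI), `p_S_reproduced` (+ CI).
#' @export
migration_table <- function(p = 0.25, params = model_params(),
                            R_in = c(5, 50), n_reps = 1e5, seed = NULL,
                            max_gens = 1e6, pi_max = 0.95) {
  seeds <- spawn_seeds(seed, 2L * length(R_in))
  mix <- pmin(migration_mix_proportions(p, params), pi_max)
  params$P_mut <- 0
  rows <- lapply(seq_along(R_in), function(i) {
    pr <- params
    pr$R_in <- R_in[i]
    set.seed(seeds[2L * i - 1L])
    stA <- mixed_start(mix["pi_AS"], pr)
    estA <- fixation_estimate(
      run_absorption_batch(stA["n_A"], stA["n_S"], pr, n_reps, max_gens),
      "fixed_A")
    set.seed(seeds[2L * i])
    stS <- mixed_start(mix["pi_SA"], pr)
    estS <- fixation_estimate(
      run_absorption_batch(stS["n_A"], stS["n_S"], pr, n_reps, max_gens),
      "fixed_S")
    data.frame(R_in = R_in[i], pi_AS = unname(mix["pi_AS"]),
               pi_SA = unname(mix["pi_SA"]),
               p_A_reproduced = estA$p_hat, a_ci_low = estA$ci_low,
               a_ci_high = estA$ci_high,
               p_S_reproduced = estS$p_hat, s_ci_low = estS$ci_low,
               s_ci_high = estS$ci_high)
  })
  do.call(rbind, rows)
}

run_metapop_trials <- function(init_fn, params, cfg, n_trials, n_gens, seed,
                               pure_threshold = 0.95) {
  seeds <- spawn_seeds(seed, n_trials)
  rows <- lapply(seq_len(n_trials), function(t) {
    set.seed(seeds[t])
    run <- run_metapopulation(init_fn(), params, cfg, n_gens,
                              record_every = n_gens,
                              pure_threshold = pure_threshold)
    sm <- metapop_summary(run$state, pure_threshold)
    data.frame(trial = t, seed = seeds[t], final_pi = sm$pi,
               n_A_groups = sum(sm$group_sizes > 0) * sm$F_A,
               n_extinct = sm$n_extinct,
               fixed = !is.na(sm$pi) && sm$pi > pure_threshold)
  })
  trials <- do.call(rbind, rows)
  structure(list(
    trials = trials,
    pi_mean = mean(trials$final_pi, na.rm = TRUE),
    pi_sd = stats::sd(trials$final_pi, na.rm = TRUE),
    n_fixed = sum(trials$fixed), n_trials = n_trials,
    params = params, cfg = cfg, n_gens = n_gens, seed = seed),
    class = "metapop_trials")
}

#' @export
print.metapop_trials <- function(x, ...) {
  cat(sprintf(
    "%d metapopulation trials (%s, delta_g = %d, R_in = %g, %g generations)\n",
    x$n_trials, x$cfg$mode, x$cfg$delta_g, x$params$R_in, x$n_gens))
  cat(sprintf("  final pi: %.2f +/- %.2f;  fixed (pi > 0.95): %d/%d\n",
              x$pi_mean, x$pi_sd, x$n_fixed, x$n_trials))
  invisible(x)
}

#' One A-type group invading an S-type metapopulation
#'
#' Initializes a grid of S-type groups at equilibrium size with a single
#' A-type group at equilibrium size placed at the center, then runs the
#' metapopulation under the configured dispersal mode. With abundant
#' nutrients the A-type can spread only under selective migration.
#'
#' @param params A [model_params()] object (the reference setting uses
#'   `R_in = 50`).
#' @param cfg A [dispersal_config()].
#' @param n_trials Number of independent trials.
#' @param n_gens Generations per trial.
#' @param seed Optional integer seed.
#' @param nrow,ncol Grid dimensions.
#' @return A `metapop_trials` object: per-trial final metapopulation `pi`,
#'   and the mean, SD, and count of trials with `pi > 0.95` (fixation or
#'   nearly so).
#' @export
run_sim1 <- function(params = model_params(R_in = 50),
                     cfg = dispersal_config("SM"),
                     n_trials = 100, n_gens = 2e4, seed = NULL,
                     nrow = 7L, ncol = 7L) {
  nS <- equilibrium_size(0, params)
  nA <- equilibrium_size(1, params)
  center <- (ncol %/% 2L) * nrow + nrow %/% 2L + 1L
  init_fn <- function() {
    a <- numeric(nrow * ncol)
    s <- rep.int(nS, nrow * ncol)
    a[center] <- nA
    s[center] <- 0
    metapop_state(a, s, nrow, ncol)
  }
  run_metapop_trials(init_fn, params, cfg, n_trials, n_gens, seed)
}

#' Isolated groups under severe nutrient limitation
#'
#' Runs an all-S-type metapopulation with no dispersal and switch mutation
#' enabled. Individual groups episodically flip between pure types; the
#' metapopulation approaches a dynamic equilibrium in which the expected
#' fraction of A-type groups is the two-state occupancy
#' `P_SA / (P_SA + P_AS)`.
#'
#' @param params A [model_params()] object (reference setting `R_in = 5`,
#'   `P_mut = 1e-6`).
#' @param n_gens Generations to simulate.
#' @param seed Optional integer seed.
#' @param record_every Trajectory thinning interval.
#' @param nrow,ncol Grid dimensions.
#' @return A `metapop_run` object (trajectory of A-cell and A-group counts
#'   plus the final grid).
#' @export
run_sim2 <- function(params = model_params(R_in = 5), n_gens = 1e6,
                     seed = NULL, record_every = NULL,
                     nrow = 7L, ncol = 7L) {
  if (!is.null(seed)) set.seed(seed)
  if (params$P_mut <= 0) stop("run_sim2 requires P_mut > 0")
  nS <- equilibrium_size(0, params)
  state <- metapop_state(numeric(nrow * ncol), rep.int(nS, nrow * ncol),
                         nrow, ncol)
  run_metapopulation(state, params, dispersal_config("none"), n_gens,
                     record_every = record_every)
}

#' Mutation-driven fixation of altruism under dispersal
#'
#' Starts from an all-S-type metapopulation with switch mutation enabled and
#' applies random migration or trait-group selection. Under severe nutrient
#' limitation an A-type group that arises by within-group drift can propagate
#' through the whole metapopulation.
#'
#' @param params A [model_params()] object (reference setting `R_in = 5`,
#'   `P_mut = 1e-6`).
#' @param cfg A [dispersal_config()] (RM or TG in the reference setting).
#' @param n_trials Number of independent trials.
#' @param n_gens Generations per trial.
#' @param seed Optional integer seed.
#' @param nrow,ncol Grid dimensions.
#' @return A `metapop_trials` object.
#' @export
run_sim3 <- function(params = model_params(R_in = 5),
                     cfg = dispersal_config("TG"),
                     n_trials = 100, n_gens = 2e4, seed = NULL,
                     nrow = 7L, ncol = 7L) {
  nS <- equilibrium_size(0, params)
  init_fn <- function() {
    metapop_state(numeric(nrow * ncol), rep.int(nS, nrow * ncol), nrow, ncol)
  }
  run_metapop_trials(init_fn, params, cfg, n_trials, n_gens, seed)
}
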
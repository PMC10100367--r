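#' State of one well-mixed group
#'
#' @param n_A,n_S Non-negative integer counts of altruistic (A-type) and
#'   selfish (S-type) cells.
#' @return An object of class `group_state`.
#' @export
group_state <- function(n_A, n_S) {
  if (length(n_A) != 1L || length(n_S) != 1L ||
      !is.finite(n_A) || !is.finite(n_S) ||
      n_A < 0 || n_S < 0 || n_A != floor(n_A) || n_S != floor(n_S)) {
    stop("n_A and n_S must be single non-negative integers")
  }
  structure(list(n_A = as.numeric(n_A), n_S = as.numeric(n_S)),
            class = "group_state")
}

#' @export
print.group_state <- function(x, ...) {
  tot <- x$n_A + x$n_S
  pi <- if (tot > 0) x$n_A / tot else NA_real_
  cat(sprintf("Group: n_A = %d, n_S = %d (pi = %s)\n",
              as.integer(x$n_A), as.integer(x$n_S),
              if (is.na(pi)) "undefined, extinct" else format(pi, digits = 4)))
  invisible(x)
}

#' Consumption ratio of the A-type subpopulation
#'
#' Fraction of the nutrient influx captured by the A-type subpopulation,
#' `delta * n_A / (delta * n_A + n_S)`. Equals 0 when no A-types are present
#' and 1 when no S-types are present.
#'
#' @param n_A,n_S Cell counts (vectorized).
#' @param params A [model_params()] object.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
consumption_ratio <- function(n_A, n_S, params) {
  if (any(n_A + n_S <= 0)) stop("empty group: the population is extinct")
  params$delta * n_A / (params$delta * n_A + n_S)
}

#' Death probabilities as a function of group composition
#'
#' The common death rate declines linearly from `D_max` in a pure S-type group
#' to `D_min` in a pure A-type group. When `alpha < 1` the S-type receives only
#' a fraction `alpha` of the reduction.
#'
#' @param pi Proportion of A-type cells, in `[0, 1]` (vectorized).
#' @param params A [model_params()] object.
#' @return A list with components `D_A` and `D_S`.
#' @export
death_rates <- function(pi, params) {
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]")
  dd <- params$D_min - params$D_max
  list(D_A = params$D_max + pi * dd,
       D_S = params$D_max + params$alpha * pi * dd)
}

#' Group size at birth-death equilibrium
#'
#' Mean number of cells, `round(R_in / D(pi))`, at which the mean fitness of
#' the group is one. Uses the common (whole-group benefit) death rate
#' `D(pi) = D_max + pi * (D_min - D_max)`; rounding is half away from zero.
#'
#' @inheritParams death_rates
#' @return Integer-valued numeric vector of cell counts.
#' @export
equilibrium_size <- function(pi, params) {
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]")
  D <- params$D_max + pi * (params$D_min - params$D_max)
  round_half_up(params$R_in / D)
}

# One ancestor-descendant mapping for a vector of independent groups.
#
# Offspring per type are drawn as a single Poisson with the aggregate mean
# (cR * R_in for the A subpopulation, (1 - cR) * R_in for S), which is
# distributionally identical to one Poisson draw per ancestral cell. Each
# ancestral cell then survives with probability 1 - D(pi) computed from the
# *ancestral* composition; offspring are not culled in their birth generation.
# Finally every cell present (including newborns) switches type independently
# with probability P_mut. Extinct groups map to extinct groups.
step_counts <- function(n_A, n_S, params) {
  k <- length(n_A)
  tot <- n_A + n_S
  live <- tot > 0
  cR <- numeric(k)
  cR[live] <- params$delta * n_A[live] /
    (params$delta * n_A[live] + n_S[live])
  lamA <- cR * params$R_in / params$T_unit
  lamS <- (1 - cR) * params$R_in / params$T_unit
  lamA[!live] <- 0
  lamS[!live] <- 0
  pi <- numeric(k)
  pi[live] <- n_A[live] / tot[live]
  dd <- params$D_min - params$D_max
  D_A <- params$D_max + pi * dd
  D_S <- params$D_max + params$alpha * pi * dd
  a <- stats::rpois(k, lamA) + stats::rbinom(k, n_A, 1 - D_A)
  s <- stats::rpois(k, lamS) + stats::rbinom(k, n_S, 1 - D_S)
  if (params$P_mut > 0) {
    mAS <- stats::rbinom(k, a, params$P_mut)
    mSA <- stats::rbinom(k, s, params$P_mut)
    a <- a - mAS + mSA
    s <- s - mSA + mAS
  }
  list(n_A = a, n_S = s)
}

#' Advance many independent groups by one generation
#'
#' Vectorized single-generation update: each element of `n_A`/`n_S` is an
#' independent well-mixed group. One generation consists of (i) Poisson
#' offspring with per-type aggregate means `cR * R_in` and `(1 - cR) * R_in`
#' set by the ancestral composition, (ii) Bernoulli survival of each ancestral
#' cell at the ancestral death rate (offspring are not culled in their birth
#' generation), and (iii) independent type-switch mutation of every cell,
#' newborns included, with probability `P_mut`.
#'
#' @param n_A,n_S Equal-length vectors of cell counts.
#' @param params A [model_params()] object.
#' @return A list with updated `n_A` and `n_S` vectors.
#' @export
step_groups <- function(n_A, n_S, params) {
  if (length(n_A) != length(n_S)) stop("n_A and n_S must have equal length")
  if (any(n_A < 0) || any(n_S < 0)) stop("cell counts must be non-negative")
  step_counts(n_A, n_S, params)
}

#' Advance a single group by one generation
#'
#' @param state A [group_state()].
#' @param params A [model_params()] object.
#' @return The descendant [group_state()].
#' @seealso [step_groups()] for the vectorized update this wraps.
#' @export
step_group <- function(state, params) {
  ns <- step_counts(state$n_A, state$n_S, params)
  group_state(ns$n_A, ns$n_S)
}

classify_absorbed <- function(a, s) {
  # 1 = fixed_A, 2 = fixed_S, 3 = extinct; only valid when a == 0 | s == 0
  ifelse(a > 0, 1L, ifelse(s > 0, 2L, 3L))
}

outcome_levels <- c("fixed_A", "fixed_S", "extinct", "timeout")

#' Run one group until one type is lost
#'
#' Iterates the single-generation update until the A-type is fixed
#' (`n_S = 0`), eliminated (`n_A = 0`), the whole group is extinct, or
#' `max_gens` is reached. Mutation must be disabled (`P_mut = 0`) for
#' absorption to be well defined.
#'
#' @param state Starting [group_state()].
#' @param params A [model_params()] object with `P_mut = 0`.
#' @param max_gens Generation cap; hitting it is reported as `"timeout"`,
#'   never silently dropped.
#' @return A list of class `absorption_outcome` with `result` (one of
#'   `"fixed_A"`, `"fixed_S"`, `"extinct"`, `"timeout"`), `generations`, and
#'   the final `state`.
#' @export
run_until_absorption <- function(state, params, max_gens = 1e6) {
  if (params$P_mut != 0) {
    stop("P_mut must be 0 for an absorption run (set P_mut = 0)")
  }
  if (max_gens <= 0) stop("max_gens must be positive")
  a <- state$n_A
  s <- state$n_S
  g <- 0L
  while (a > 0 && s > 0 && g < max_gens) {
    ns <- step_counts(a, s, params)
    a <- ns$n_A
    s <- ns$n_S
    g <- g + 1L
  }
  res <- if (a > 0 && s > 0) 4L else classify_absorbed(a, s)
  structure(list(result = outcome_levels[res], generations = g,
                 state = group_state(a, s)),
            class = "absorption_outcome")
}

#' @export
print.absorption_outcome <- function(x, ...) {
  cat(sprintf("Absorption outcome: %s after %d generations (n_A = %d, n_S = %d)\n",
              x$result, x$generations, as.integer(x$state$n_A),
              as.integer(x$state$n_S)))
  invisible(x)
}

#' Run many absorption replicates from a common starting state
#'
#' All replicates are stepped in lockstep with vectorized draws; a replicate
#' drops out of the batch as soon as one type is lost. This is the workhorse
#' behind every fixation-probability estimate in the package.
#'
#' @param n_A,n_S Starting counts shared by all replicates.
#' @param params A [model_params()] object with `P_mut = 0`.
#' @param n_reps Number of replicates.
#' @param max_gens Generation cap per replicate; survivors are reported as
#'   `"timeout"`.
#' @return A list of class `absorption_batch` with `outcome` (factor over
#'   `fixed_A`, `fixed_S`, `extinct`, `timeout`), `generations` (integer
#'   vector), the starting counts, and `n_reps`.
#' @examples
#' p <- model_params(R_in = 5, delta = 0.98, P_mut = 0)
#' set.seed(1)
#' b <- run_absorption_batch(1, 16, p, n_reps = 500)
#' fixation_estimate(b, "fixed_A")
#' @export
run_absorption_batch <- function(n_A, n_S, params, n_reps, max_gens = 1e6) {
  if (params$P_mut != 0) {
    stop("P_mut must be 0 for an absorption run (set P_mut = 0)")
  }
  if (n_reps < 1) stop("n_reps must be at least 1")
  outcome <- integer(n_reps)
  gens <- integer(n_reps)
  a <- rep.int(as.numeric(n_A), n_reps)
  s <- rep.int(as.numeric(n_S), n_reps)
  idx <- seq_len(n_reps)
  done <- a == 0 | s == 0
  if (any(done)) {
    outcome[idx[done]] <- classify_absorbed(a[done], s[done])
    keep <- !done
    a <- a[keep]; s <- s[keep]; idx <- idx[keep]
  }
  g <- 0L
  while (length(idx) && g < max_gens) {
    g <- g + 1L
    ns <- step_counts(a, s, params)
    a <- ns$n_A
    s <- ns$n_S
    done <- a == 0 | s == 0
    if (any(done)) {
      oi <- idx[done]
      outcome[oi] <- classify_absorbed(a[done], s[done])
      gens[oi] <- g
      keep <- !done
      a <- a[keep]; s <- s[keep]; idx <- idx[keep]
    }
  }
  if (length(idx)) {
    outcome[idx] <- 4L
    gens[idx] <- g
  }
  structure(list(outcome = factor(outcome_levels[outcome],
                                  levels = outcome_levels),
                 generations = gens,
                 start = c(n_A = as.numeric(n_A), n_S = as.numeric(n_S)),
                 n_reps = n_reps),
            class = "absorption_batch")
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level.
#' @return Numeric vector `c(low, high)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Monte Carlo fixation-probability estimate from an absorption batch
#'
#' The estimate is the fraction of *all* replicates ending in `event`;
#' replicates that went extinct (or timed out) are excluded from the numerator
#' only and tallied separately for transparency.
#'
#' @param batch An [run_absorption_batch()] result.
#' @param event `"fixed_A"` or `"fixed_S"`.
#' @param conf Confidence level for the Wilson score interval.
#' @return A list of class `fixation_estimate` with `p_hat`, `n_reps`,
#'   `ci_low`, `ci_high`, `n_event`, `n_extinct`, `n_timeout`, `conf`.
#' @export
fixation_estimate <- function(batch, event = c("fixed_A", "fixed_S"),
                              conf = 0.95) {
  event <- match.arg(event)
  tab <- table(batch$outcome)
  n_event <- as.integer(tab[[event]])
  n <- batch$n_reps
  ci <- wilson_ci(n_event, n, conf)
  structure(list(p_hat = n_event / n, n_reps = n,
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 n_event = n_event,
                 n_extinct = as.integer(tab[["extinct"]]),
                 n_timeout = as.integer(tab[["timeout"]]),
                 event = event, conf = conf, start = batch$start),
            class = "fixation_estimate")
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("P(%s) = %.4g  [%.4g, %.4g] %d%% Wilson CI, %d reps",
              x$event, x$p_hat, x$ci_low, x$ci_high,
              round(100 * x$conf), x$n_reps))
  if (x$n_extinct > 0 || x$n_timeout > 0) {
    cat(sprintf("  (%d extinct, %d timeout)", x$n_extinct, x$n_timeout))
  }
  cat("\n")
  invisible(x)
}

#' Long-run trajectory of a single group with switch mutation
#'
#' Runs the single-group model with `P_mut > 0` and records the cell counts
#' each generation together with the generations at which switch mutations
#' occurred. With a small nutrient influx the group is bistable: it
#' episodically transitions between a pure S-type state (size near
#' `R_in / D_max`) and a much larger pure A-type state (size near
#' `R_in / D_min`), with mutants fixed or eliminated rapidly in between.
#'
#' @param state Starting [group_state()].
#' @param params A [model_params()] object with `P_mut > 0`.
#' @param n_gens Number of generations to simulate.
#' @param record_every Thinning interval for the recorded trajectory
#'   (mutation events are always recorded at full resolution).
#' @return A list of class `macroevolution` with `trajectory` (data frame
#'   `generation`, `n_A`, `n_S`) and `mutations` (data frame `generation`,
#'   `n_switches`).
#' @export
run_macroevolution <- function(state, params, n_gens, record_every = 1L) {
  if (params$P_mut <= 0) stop("run_macroevolution requires P_mut > 0")
  if (n_gens < 1) stop("n_gens must be at least 1")
  record_every <- max(1L, as.integer(record_every))
  a <- state$n_A
  s <- state$n_S
  Rin <- params$R_in / params$T_unit
  delta <- params$delta
  dd <- params$D_min - params$D_max
  Dmax <- params$D_max
  alpha <- params$alpha
  Pmut <- params$P_mut
  n_rec <- n_gens %/% record_every
  rec <- matrix(0, nrow = n_rec, ncol = 3L)
  ri <- 0L
  mut_g <- integer(0)
  mut_n <- integer(0)
  for (g in seq_len(n_gens)) {
    tot <- a + s
    if (tot > 0) {
      cR <- if (a > 0) delta * a / (delta * a + s) else 0
      pi <- a / tot
      D_A <- Dmax + pi * dd
      D_S <- Dmax + alpha * pi * dd
      a2 <- (if (a > 0) stats::rpois(1L, cR * Rin) else 0) +
        stats::rbinom(1L, a, 1 - D_A)
      s2 <- (if (s > 0) stats::rpois(1L, (1 - cR) * Rin) else 0) +
        stats::rbinom(1L, s, 1 - D_S)
      mAS <- stats::rbinom(1L, a2, Pmut)
      mSA <- stats::rbinom(1L, s2, Pmut)
      if (mAS + mSA > 0) {
        mut_g <- c(mut_g, g)
        mut_n <- c(mut_n, mAS + mSA)
      }
      a <- a2 - mAS + mSA
      s <- s2 - mSA + mAS
    }
    if (g %% record_every == 0L) {
      ri <- ri + 1L
      rec[ri, ] <- c(g, a, s)
    }
  }
  structure(list(
    trajectory = data.frame(generation = rec[, 1], n_A = rec[, 2],
                            n_S = rec[, 3]),
    mutations = data.frame(generation = mut_g, n_switches = mut_n),
    final_state = group_state(a, s),
    params = params),
    class = "macroevolution")
}
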
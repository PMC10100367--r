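#' Fitness under hard selection (unlimited nutrients)
#'
#' With intrinsic per-capita birth rates `beta_A` and `beta_S`, the fitness of
#' each type is its expected offspring number plus its survival probability,
#' `w = beta + (1 - D(pi))`. The difference `w_A - w_S = beta_A - beta_S` is
#' independent of the group composition: hard selection.
#'
#' @param pi Proportion of A-type cells, in `[0, 1]` (vectorized).
#' @param beta_A,beta_S Intrinsic birth rates (expected offspring per cell per
#'   generation).
#' @param params A [model_params()] object (supplies the death rates).
#' @return A list with `w_A`, `w_S`, and `difference`.
#' @export
fitness_hard <- function(pi, beta_A, beta_S, params) {
  D <- death_rates(pi, params)
  w_A <- beta_A + (1 - D$D_A)
  w_S <- beta_S + (1 - D$D_S)
  list(w_A = w_A, w_S = w_S, difference = w_A - w_S)
}

#' Fitness under soft selection (shared nutrient limitation)
#'
#' When both types compete for a fixed influx `R_in`, per-capita birth rates
#' are `cR * R_in / n_A` for the A-type and `(1 - cR) * R_in / n_S` for the
#' S-type, where `cR` is the A-subpopulation's consumption ratio. A type with
#' zero cells has an undefined per-capita term and is reported as `NA`.
#'
#' @param n_A,n_S Cell counts (vectorized).
#' @param params A [model_params()] object.
#' @return A list with `w_A`, `w_S`, and `difference`.
#' @seealso [fitness_soft_difference()] for the equivalent closed form of the
#'   difference.
#' @export
fitness_soft <- function(n_A, n_S, params) {
  if (any(n_A + n_S <= 0)) stop("empty group: fitness undefined")
  cR <- params$delta * n_A / (params$delta * n_A + n_S)
  pi <- n_A / (n_A + n_S)
  D <- death_rates(pi, params)
  w_A <- ifelse(n_A > 0, cR * params$R_in / n_A + (1 - D$D_A), NA_real_)
  w_S <- ifelse(n_S > 0, (1 - cR) * params$R_in / n_S + (1 - D$D_S), NA_real_)
  list(w_A = w_A, w_S = w_S, difference = w_A - w_S)
}

#' Closed form of the soft-selection fitness difference
#'
#' `w_A - w_S = -R_in * (1 - delta) / (delta * n_A + n_S)`, algebraically
#' identical to the difference of the per-capita forms when the common death
#' rate is shared (`alpha = 1`). Always non-positive, and shrinking in
#' magnitude as the group grows: selection softens.
#'
#' @inheritParams fitness_soft
#' @return Numeric vector.
#' @export
fitness_soft_difference <- function(n_A, n_S, params) {
  if (any(n_A + n_S <= 0)) stop("empty group: fitness undefined")
  -params$R_in * (1 - params$delta) / (params$delta * n_A + n_S)
}

#' Fitness difference when the S-type receives a reduced benefit
#'
#' Generalizes the soft-selection difference to `alpha < 1`, where S-type
#' cells receive only a share `alpha` of the public-good death-rate reduction:
#' `w_A - w_S = pi * (1 - alpha) * (D_max - D_min)
#'              - R_in * (1 - delta) / (delta * n_A + n_S)`.
#' Reduces to [fitness_soft_difference()] at `alpha = 1`; for small enough
#' `alpha` the difference turns positive and the A-type is no longer an
#' altruist.
#'
#' @inheritParams fitness_soft
#' @return Numeric vector (signed difference `w_A - w_S`).
#' @export
fitness_difference_alpha <- function(n_A, n_S, params) {
  if (any(n_A + n_S <= 0)) stop("empty group: fitness undefined")
  pi <- n_A / (n_A + n_S)
  pi * (1 - params$alpha) * (params$D_max - params$D_min) -
    params$R_in * (1 - params$delta) / (params$delta * n_A + n_S)
}

#' Benefit share below which the A-type is favored
#'
#' Solves the linear threshold `alpha*` at which
#' [fitness_difference_alpha()] crosses zero for a given group state:
#' `alpha* = 1 - R_in * (1 - delta) /
#'           ((delta * n_A + n_S) * pi * (D_max - D_min))`.
#'
#' @inheritParams fitness_soft
#' @return The threshold (may be below 0 when no `alpha` in `(0, 1]` favors
#'   the A-type, e.g. at `pi = 0`).
#' @export
alpha_threshold <- function(n_A, n_S, params) {
  if (any(n_A <= 0)) stop("alpha threshold requires n_A > 0 (pi > 0)")
  pi <- n_A / (n_A + n_S)
  1 - params$R_in * (1 - params$delta) /
    ((params$delta * n_A + n_S) * pi * (params$D_max - params$D_min))
}

#' Fitness change of a focal S-type that switches to the A-type
#'
#' In a group of constant size `N = n_A + n_S`, a focal S-type that converts
#' to an A-type loses consumption (a cost proportional to `R_in`) but lowers
#' the common death rate by `(D_max - D_min) / N` (a benefit that grows as
#' the group shrinks). A negative value marks strong altruism (class I
#' fitness structure); a positive value marks effectively weak altruism
#' (class II).
#'
#' @param n_A Cell counts before the switch; `n_S` must be at least 1 (the
#'   focal cell).
#' @inheritParams fitness_soft
#' @return Signed fitness change `w_A(pi') - w_S(pi)` with
#'   `pi' = (n_A + 1) / N`.
#' @export
switch_gain <- function(n_A, n_S, params) {
  if (any(n_S < 1)) stop("no focal S-type exists (n_S must be >= 1)")
  N <- n_A + n_S
  d <- params$delta
  denom1 <- d * n_A + n_S
  denom2 <- d * (n_A + 1) + n_S - 1
  -((denom1 - 1) * (1 - d) * params$R_in) / (denom1 * denom2) +
    (params$D_max - params$D_min) / N
}

#' Switch gain at birth-death equilibrium size
#'
#' Evaluates [switch_gain()] at the group size implied by
#' [equilibrium_size()] for the given composition: `N = round(R_in / D(pi))`,
#' `n_A = round(pi * N)`. This is the natural frame for asking whether
#' altruism is strong or weak at a given nutrient influx.
#'
#' @inheritParams death_rates
#' @return Signed fitness change (vectorized over `pi`).
#' @export
switch_gain_at <- function(pi, params) {
  N <- equilibrium_size(pi, params)
  n_A <- round_half_up(pi * N)
  n_S <- N - n_A
  if (any(n_S < 1)) {
    stop("pi too close to 1: the equilibrium group has no focal S-type")
  }
  switch_gain(n_A, n_S, params)
}

#' Nutrient influx at which altruism shifts from weak to strong
#'
#' Finds the influx `R_in*` at which the switch gain changes sign at a given
#' composition, using continuous equilibrium sizes `N = R_in / D(pi)` (no
#' rounding) so the gain is a smooth, monotone function of `R_in`. Below the
#' threshold altruism is effectively weak; above it, strong.
#'
#' @param pi Proportion of A-type cells (scalar, in `[0, 1)`).
#' @param params A [model_params()] object with `delta < 1`.
#' @param interval Search interval for the root.
#' @return The critical influx (scalar).
#' @export
critical_influx <- function(pi, params, interval = c(0.1, 1000)) {
  if (params$delta >= 1) stop("delta must be < 1 for a cost-benefit tradeoff")
  D <- params$D_max + pi * (params$D_min - params$D_max)
  gain <- function(Rin) {
    N <- Rin / D
    n_A <- pi * N
    n_S <- (1 - pi) * N
    d <- params$delta
    denom1 <- d * n_A + n_S
    denom2 <- d * (n_A + 1) + n_S - 1
    -((denom1 - 1) * (1 - d) * Rin) / (denom1 * denom2) +
      (params$D_max - params$D_min) / N
  }
  stats::uniroot(gain, interval)$root
}

#' Expected mixing proportions after a migration event
#'
#' A propagule of fraction `p` of a donor group at birth-death equilibrium is
#' transferred into a recipient group of the opposite pure type. Since an
#' A-type group is `D_max / D_min` times larger than an S-type group, the
#' expected A-proportion in the mixed recipient patch is
#' `pi_AS = p / (p + D_min / D_max)` for an A-type donor and
#' `pi_SA = 1 / (1 + p * D_min / D_max)` for an S-type donor.
#'
#' @param p Propagule fraction of the donor group, in `(0, 1]`.
#' @param params A [model_params()] object.
#' @return Named numeric vector `c(pi_AS, pi_SA)`.
#' @examples
#' migration_mix_proportions(0.25, model_params())   # 0.60 and 0.96
#' @export
migration_mix_proportions <- function(p, params) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  r <- params$D_min / params$D_max
  c(pi_AS = p / (p + r), pi_SA = 1 / (1 + p * r))
}

#' Per-generation group transition rates between pure types
#'
#' A pure group of one type transitions to the other when a switch mutant
#' arises (`P_mut` per cell over `N_cap` cells) and reaches fixation. The
#' ratio of the two transition rates reduces to
#' `(D_max / D_min) * fix_S / fix_A` because the group-size ratio is
#' `N_cap(pi = 1) / N_cap(pi = 0) = D_max / D_min`.
#'
#' @param fix_A Fixation probability of a single A-type mutant in an S-type
#'   group at equilibrium size.
#' @param fix_S Fixation probability of a single S-type mutant in an A-type
#'   group at equilibrium size.
#' @param params A [model_params()] object.
#' @return A list of class `transition_rates` with `P_AS`, `P_SA`, and
#'   `ratio` (`P_AS / P_SA`).
#' @export
transition_rates <- function(fix_A, fix_S, params) {
  if (any(fix_A < 0 | fix_A > 1 | fix_S < 0 | fix_S > 1)) {
    stop("fixation probabilities must lie in [0, 1]")
  }
  if (any(fix_A == 0)) {
    stop("fix_A = 0: the transition ratio P_AS / P_SA is undefined")
  }
  P_AS <- params$P_mut * equilibrium_size(1, params) * fix_S
  P_SA <- params$P_mut * equilibrium_size(0, params) * fix_A
  structure(list(P_AS = P_AS, P_SA = P_SA,
                 ratio = (params$D_max / params$D_min) * fix_S / fix_A),
            class = "transition_rates")
}

#' @export
print.transition_rates <- function(x, ...) {
  cat(sprintf("P_AS = %.4g, P_SA = %.4g, P_AS/P_SA = %.4g\n",
              x$P_AS, x$P_SA, x$ratio))
  invisible(x)
}

#' Nominal group fitness under migration
#'
#' In a metapopulation of pure groups with A-type fraction `F_A`, the nominal
#' fitness of a group type is the probability that it is chosen as a donor,
#' meets a recipient of the opposite type, and has its propagule fixed there
#' ("re-produces" the donor group). Under random migration both donor-recipient
#' pairings have probability proportional to `F_A * (1 - F_A)`; under
#' selective migration only (larger) A-type groups can donate, so `W_S = 0`.
#'
#' @param F_A Fraction of A-type groups, in `[0, 1]` (vectorized).
#' @param reproduce_A Probability that an A-type donor is re-produced in an
#'   S-type recipient patch.
#' @param reproduce_S Probability that an S-type donor is re-produced in an
#'   A-type recipient patch.
#' @param selective If `TRUE`, model selective migration (`W_S = 0`).
#' @return A list with `W_A`, `W_S`, and `W_diff`.
#' @export
nominal_group_fitness <- function(F_A, reproduce_A, reproduce_S,
                                  selective = FALSE) {
  if (any(F_A < 0 | F_A > 1)) stop("F_A must lie in [0, 1]")
  base <- F_A * (1 - F_A)
  W_A <- reproduce_A * base
  W_S <- if (selective) 0 * base else reproduce_S * base
  list(W_A = W_A, W_S = W_S, W_diff = W_A - W_S)
}
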
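#' Model parameters for the two-type nutrient-limited birth-death model
#'
#' Bundles the biological and ecological constants of the model: a selfish
#' S-type consumes a growth-limiting nutrient at rate `c_S` per cell per
#' generation, while an altruistic A-type consumes at the reduced rate
#' `c_A = delta * c_S` but produces a public good that lowers the common death
#' rate as the proportion of A-types (`pi`) in the group rises.
#'
#' @param R_in Nutrient influx, units per group per generation. A cell of
#'   either type reproduces when it captures `T_unit` units, so `R_in` is the
#'   expected number of offspring produced by the whole group per generation.
#' @param delta Consumption-rate deficit `c_A / c_S` in `(0, 1]`; the cost of
#'   altruism. `delta = 1` makes the two types selectively neutral.
#' @param D_min Death probability per cell per generation in a pure A-type
#'   group (`pi = 1`), where the public good is at full strength.
#' @param D_max Death probability per cell per generation in a pure S-type
#'   group (`pi = 0`).
#' @param alpha Share of the public-good benefit received by S-type cells, in
#'   `(0, 1]`. The default `alpha = 1` is whole-group trait altruism: the
#'   benefit is conferred to all cells equally.
#' @param P_mut Probability per cell per generation of a "genetic switch"
#'   mutation converting one type into the other.
#' @param T_unit Nutrient units required to produce one offspring (kept at 1).
#'
#' @return An object of class `model_params` (a validated named list).
#' @examples
#' p <- model_params(R_in = 5, delta = 0.98)
#' equilibrium_size(0, p)   # S-type group at birth-death equilibrium
#' equilibrium_size(1, p)   # A-type group is D_max/D_min times larger
#' @export
model_params <- function(R_in = 5, delta = 0.98, D_min = 0.05, D_max = 0.30,
                         alpha = 1, P_mut = 1e-6, T_unit = 1) {
  p <- list(R_in = R_in, delta = delta, D_min = D_min, D_max = D_max,
            alpha = alpha, P_mut = P_mut, T_unit = T_unit)
  validate_params(p)
  structure(p, class = "model_params")
}

#' Validate a parameter list against the model invariants
#'
#' @param p A list with the fields of [model_params()].
#' @return `p`, invisibly; signals an error naming every violated field.
#' @export
validate_params <- function(p) {
  required <- c("R_in", "delta", "D_min", "D_max", "alpha", "P_mut", "T_unit")
  missing <- setdiff(required, names(p))
  if (length(missing)) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  }
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(p$R_in) && p$R_in > 0, "R_in must be a positive number")
  chk(num1(p$delta) && p$delta > 0 && p$delta <= 1,
      "delta must lie in (0, 1]")
  chk(num1(p$D_min) && num1(p$D_max) && p$D_min > 0 &&
        p$D_min <= p$D_max && p$D_max <= 1,
      "death rates must satisfy 0 < D_min <= D_max <= 1")
  chk(num1(p$alpha) && p$alpha > 0 && p$alpha <= 1,
      "alpha must lie in (0, 1]")
  chk(num1(p$P_mut) && p$P_mut >= 0 && p$P_mut < 1,
      "P_mut must lie in [0, 1)")
  chk(num1(p$T_unit) && p$T_unit > 0, "T_unit must be a positive number")
  if (length(bad)) stop("invalid model parameters:\n  ",
                        paste(bad, collapse = "\n  "))
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters (two-type nutrient-limited birth-death model)\n")
  cat(sprintf("  R_in  = %g nutrient units / group / generation\n", x$R_in))
  cat(sprintf("  delta = %g (consumption deficit c_A/c_S)\n", x$delta))
  cat(sprintf("  D_min = %g, D_max = %g (death prob. at pi = 1 / pi = 0)\n",
              x$D_min, x$D_max))
  cat(sprintf("  alpha = %g (S-type share of the public-good benefit)\n",
              x$alpha))
  cat(sprintf("  P_mut = %g (type-switch mutation prob. / cell / generation)\n",
              x$P_mut))
  invisible(x)
}

#' Round half away from zero
#'
#' Deterministic integerization used throughout the package for equilibrium
#' group sizes and propagule counts (`round_half_up(16.5)` is 17, whereas
#' base `round()` would give 16 by round-half-to-even).
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @return `floor(x + 0.5)`.
#' @export
round_half_up <- function(x) floor(x + 0.5)
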
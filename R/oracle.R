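#' Exact absorption probabilities for small systems
#'
#' Builds the full transition matrix of the two-type birth-death chain on the
#' truncated state space `(n_A, n_S)` with `1 <= n_A <= a_max`,
#' `1 <= n_S <= s_max`, and solves the absorbing-chain linear system
#' `(I - Q) h = b` for the probabilities of A-fixation, S-fixation, and
#' whole-group extinction from every transient state. Per-type descendant
#' counts are the convolution of a Poisson offspring distribution (tail
#' truncated at cumulative mass `1 - tail_mass`) with a binomial survivor
#' distribution; probability mass on counts above the cap is lumped into the
#' cap state, so the caps should sit far above the equilibrium sizes.
#'
#' Feasible only for small nutrient influx (roughly `R_in <= 2`); it serves as
#' an independent cross-check of the Monte Carlo engine, never as a
#' replacement for it.
#'
#' @param params A [model_params()] object with `P_mut = 0`.
#' @param a_max,s_max State-space caps for each type.
#' @param tail_mass Poisson tail mass discarded (then renormalized) per draw.
#' @return A list of class `absorption_oracle` with matrices `fix_A`, `fix_S`,
#'   `extinct` indexed `[n_A, n_S]` over transient states.
#' @examples
#' p <- model_params(R_in = 1, delta = 0.98, P_mut = 0)
#' orc <- absorption_oracle(p, a_max = 40, s_max = 20)
#' orc$fix_A[1, 2]   # single A mutant among 2 S-types
#' @export
absorption_oracle <- function(params, a_max, s_max, tail_mass = 1e-12) {
  if (params$P_mut != 0) stop("the absorption oracle requires P_mut = 0")
  if (a_max < 2 || s_max < 2) stop("caps must be at least 2")
  m <- a_max * s_max
  Q <- matrix(0, m, m)
  bA <- numeric(m)
  bS <- numeric(m)
  bE <- numeric(m)
  dd <- params$D_min - params$D_max
  for (s in seq_len(s_max)) {
    for (a in seq_len(a_max)) {
      i <- (s - 1L) * a_max + a
      cR <- params$delta * a / (params$delta * a + s)
      pi <- a / (a + s)
      D_A <- params$D_max + pi * dd
      D_S <- params$D_max + params$alpha * pi * dd
      pA <- count_dist(cR * params$R_in, a, 1 - D_A, a_max, tail_mass)
      pS <- count_dist((1 - cR) * params$R_in, s, 1 - D_S, s_max, tail_mass)
      bA[i] <- (1 - pA[1]) * pS[1]
      bS[i] <- pA[1] * (1 - pS[1])
      bE[i] <- pA[1] * pS[1]
      Q[i, ] <- as.vector(outer(pA[-1], pS[-1]))
    }
  }
  H <- solve(diag(m) - Q, cbind(bA, bS, bE))
  structure(list(
    fix_A = matrix(H[, 1], a_max, s_max),
    fix_S = matrix(H[, 2], a_max, s_max),
    extinct = matrix(H[, 3], a_max, s_max),
    a_max = a_max, s_max = s_max, params = params),
    class = "absorption_oracle")
}

# Distribution of one type's descendant count: Poisson(lambda) offspring
# plus Binomial(n, surv) surviving ancestors, clamped at `cap`.
count_dist <- function(lambda, n, surv, cap, tail_mass) {
  if (lambda > 0) {
    kmax <- stats::qpois(1 - tail_mass, lambda)
    po <- stats::dpois(0:kmax, lambda)
  } else {
    po <- 1
  }
  bi <- stats::dbinom(0:n, n, surv)
  out <- numeric(length(po) + length(bi) - 1L)
  for (k in seq_along(bi)) {
    if (bi[k] > 0) {
      span <- k:(k + length(po) - 1L)
      out[span] <- out[span] + bi[k] * po
    }
  }
  if (length(out) > cap + 1L) {
    out[cap + 1L] <- sum(out[(cap + 1L):length(out)])
    out <- out[seq_len(cap + 1L)]
  } else if (length(out) < cap + 1L) {
    out <- c(out, numeric(cap + 1L - length(out)))
  }
  out / sum(out)
}

#' @export
print.absorption_oracle <- function(x, ...) {
  cat(sprintf(
    "Exact absorption solve on (n_A, n_S) in [1, %d] x [1, %d], R_in = %g\n",
    x$a_max, x$s_max, x$params$R_in))
  invisible(x)
}
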
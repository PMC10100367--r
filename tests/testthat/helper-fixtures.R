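# Shared fixtures: reference parameterizations and random-state generators.

p_ref <- function(R_in = 5, delta = 0.98, P_mut = 1e-6, ...) {
  model_params(R_in = R_in, delta = delta, P_mut = P_mut, ...)
}

# Random non-degenerate group states (both types present).
random_states <- function(n, max_n = 200) {
  data.frame(n_A = sample.int(max_n, n, replace = TRUE),
             n_S = sample.int(max_n, n, replace = TRUE))
}

# Random metapopulation with a mix of empty, pure, and mixed patches.
random_metapop <- function(nrow = 7, ncol = 7, max_n = 150) {
  k <- nrow * ncol
  kind <- sample(c("empty", "pureA", "pureS", "mixed"), k, replace = TRUE,
                 prob = c(0.1, 0.3, 0.4, 0.2))
  a <- ifelse(kind %in% c("pureA", "mixed"),
              sample.int(max_n, k, replace = TRUE), 0)
  s <- ifelse(kind %in% c("pureS", "mixed"),
              sample.int(max_n, k, replace = TRUE), 0)
  metapop_state(a, s, nrow, ncol)
}

# 3-standard-error Monte Carlo band around a reference probability.
mc_band <- function(p, n) 3 * sqrt(p * (1 - p) / n)
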
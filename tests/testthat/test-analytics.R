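test_that("hard selection keeps a composition-independent fitness gap", {
  p <- p_ref()
  w <- fitness_hard(c(0, 0.5, 1), beta_A = 0.3, beta_S = 0.35, p)
  expect_equal(w$difference, rep(-0.05, 3))
  weq <- fitness_hard(0.7, beta_A = 0.3, beta_S = 0.3, p)
  expect_identical(weq$difference, 0)
  # with birth rates exceeding death rates the mean fitness stays above one
  pi <- seq(0, 1, by = 0.25)
  w2 <- fitness_hard(pi, beta_A = 0.4, beta_S = 0.5, p)
  expect_true(all(pi * w2$w_A + (1 - pi) * w2$w_S > 1))
})

test_that("per-capita soft fitness difference equals its closed form", {
  set.seed(10)
  st <- random_states(1000)
  p <- p_ref(delta = 0.98)
  soft <- fitness_soft(st$n_A, st$n_S, p)
  expect_equal(soft$difference, fitness_soft_difference(st$n_A, st$n_S, p),
               tolerance = 1e-12)
  # neutral cost: the gap vanishes at delta = 1
  p1 <- p_ref(delta = 1)
  expect_equal(fitness_soft(st$n_A, st$n_S, p1)$difference,
               rep(0, nrow(st)), tolerance = 1e-12)
  # selection softens: along birth-death equilibrium sizes the gap shrinks
  # as pi grows (groups with more altruists are larger)
  pi <- seq(0.1, 0.9, by = 0.1)
  N <- equilibrium_size(pi, p)
  nA <- round_half_up(pi * N)
  d <- fitness_soft_difference(nA, N - nA, p)
  expect_true(all(d < 0))
  expect_true(all(diff(abs(d)) < 0))
})

test_that("a reduced S-type benefit share can flip the sign of selection", {
  p <- p_ref()
  st <- random_states(200)
  # alpha = 1 reduces to the shared-benefit closed form
  expect_equal(fitness_difference_alpha(st$n_A, st$n_S, p),
               fitness_soft_difference(st$n_A, st$n_S, p), tolerance = 1e-12)
  # pi = 0: pure cost
  expect_equal(fitness_difference_alpha(0, 20, p), -p$R_in * 0.02 / 20)
  # crossing the analytic threshold alpha* flips the sign
  athr <- alpha_threshold(40, 60, p)
  expect_true(athr > 0 && athr < 1)
  lo <- model_params(alpha = max(athr - 0.05, 1e-3))
  hi <- model_params(alpha = min(athr + 0.05, 1))
  expect_gt(fitness_difference_alpha(40, 60, lo), 0)
  expect_lt(fitness_difference_alpha(40, 60, hi), 0)
})

test_that("switch gain separates strong from effectively weak altruism", {
  # no cost at delta = 1: the gain is the pure death-rate benefit
  p1 <- p_ref(delta = 1)
  expect_equal(switch_gain(30, 20, p1), (0.30 - 0.05) / 50)
  expect_error(switch_gain(10, 0, p_ref()), "focal")
  pi <- seq(0, 0.9, by = 0.05)
  # abundant nutrients: strong altruism (class I), gain negative everywhere
  expect_true(all(switch_gain_at(pi, p_ref(R_in = 50)) < 0))
  # severe limitation: effectively weak (class II), gain positive everywhere
  expect_true(all(switch_gain_at(pi, p_ref(R_in = 5)) > 0))
})

test_that("the influx threshold between weak and strong altruism is unique", {
  p <- p_ref()
  for (pi in c(0.1, 0.5, 0.9)) {
    rstar <- critical_influx(pi, p)
    expect_true(rstar > 5 && rstar < 50)
    # sign flips across the root and nowhere else on a coarse sweep
    gain_at <- function(Rin) {
      pr <- p
      pr$R_in <- Rin
      N <- Rin / (p$D_max + pi * (p$D_min - p$D_max))
      switch_gain(pi * N, (1 - pi) * N, pr)
    }
    sweep <- vapply(seq(1, 200, by = 1), gain_at, numeric(1))
    expect_identical(sum(diff(sign(sweep)) != 0), 1L)
  }
})

test_that("migration mixing proportions follow the group-size ratio", {
  p <- p_ref()
  mix <- migration_mix_proportions(0.25, p)
  expect_equal(unname(mix["pi_AS"]), 0.60, tolerance = 1e-12)
  expect_equal(unname(mix["pi_SA"]), 0.96, tolerance = 1e-12)
  # the underlying size ratio N_A / N_S is 6
  expect_equal(equilibrium_size(1, p) / equilibrium_size(0, p), 100 / 17)
  expect_equal(p$D_max / p$D_min, 6)
  # whole-group exchange between equal-sized groups mixes half and half
  peq <- model_params(D_min = 0.3, D_max = 0.3)
  expect_equal(unname(migration_mix_proportions(1, peq)), c(0.5, 0.5))
  expect_error(migration_mix_proportions(0, p), "p must")
})

test_that("group transition rates reproduce the printed ratios", {
  p <- p_ref()
  # single-mutant fixation probabilities as tabulated at delta = 0.98
  r50 <- transition_rates(fix_A = 4.0e-5, fix_S = 1.6e-2,
                          p_ref(R_in = 50))
  expect_equal(r50$ratio, 2400)
  r5 <- transition_rates(fix_A = 4.4e-2, fix_S = 1.6e-2, p)
  expect_equal(r5$ratio, 2.18, tolerance = 0.005)
  expect_equal(r5$P_AS, 1e-6 * 100 * 1.6e-2)
  expect_equal(r5$P_SA, 1e-6 * 17 * 4.4e-2)
  peq <- model_params(D_min = 0.3, D_max = 0.3)
  expect_equal(transition_rates(0.1, 0.1, peq)$ratio, 1)
  expect_error(transition_rates(0, 0.1, p), "undefined")
})

test_that("nominal group fitness weighs re-production against pairing odds", {
  FA <- seq(0, 1, by = 0.1)
  # severe limitation favors the A-type under random migration
  w5 <- nominal_group_fitness(FA, reproduce_A = 0.52, reproduce_S = 0.07)
  expect_equal(w5$W_diff, 0.45 * FA * (1 - FA))
  # abundant nutrients reverse the sign
  w50 <- nominal_group_fitness(FA, reproduce_A = 0.03, reproduce_S = 0.50)
  expect_equal(w50$W_diff, -0.47 * FA * (1 - FA))
  # selective migration zeroes the S-type's chance to donate
  wsm <- nominal_group_fitness(FA, 0.03, 0.50, selective = TRUE)
  expect_equal(wsm$W_diff, 0.03 * FA * (1 - FA))
  # no opposite-type pairs at the boundaries
  expect_identical(w5$W_A[c(1, 11)], c(0, 0))
  expect_identical(w5$W_S[c(1, 11)], c(0, 0))
})
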
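test_that("experiments are bit-reproducible given a seed", {
  p <- p_ref(R_in = 5)
  cfg <- dispersal_config("TG", delta_g = 50)
  a <- run_sim3(p, cfg, n_trials = 2, n_gens = 200, seed = 123)
  b <- run_sim3(p, cfg, n_trials = 2, n_gens = 200, seed = 123)
  expect_identical(a$trials, b$trials)
  e1 <- estimate_single_mutant_fixation("A_into_S", p, n_reps = 500,
                                        seed = 9)
  e2 <- estimate_single_mutant_fixation("A_into_S", p, n_reps = 500,
                                        seed = 9)
  expect_identical(e1$p_hat, e2$p_hat)
})

test_that("single-mutant runs start from equilibrium-size residents", {
  p <- p_ref(R_in = 5)
  est <- estimate_single_mutant_fixation("A_into_S", p, n_reps = 200,
                                         seed = 21)
  expect_identical(unname(est$start), c(1, 16))
  est2 <- estimate_single_mutant_fixation("S_into_A", p, n_reps = 200,
                                          seed = 22)
  expect_identical(unname(est2$start), c(99, 1))
  expect_identical(est$event, "fixed_A")
  expect_identical(est2$event, "fixed_S")
})

test_that("fixation approaches certainty as the group becomes pure A", {
  set.seed(23)
  curve <- fixation_curve(0.95, p_ref(R_in = 5), n_reps = 2000)
  expect_gt(curve$p_fix_A, 0.85)
  expect_identical(curve$N, 80)        # round(5 / D(0.95))
  expect_identical(curve$n_A0, 76)
})

test_that("the migration table pairs mixing proportions with fixation", {
  tab <- migration_table(0.25, model_params(), R_in = 5, n_reps = 500,
                         seed = 24)
  expect_equal(tab$pi_AS, 0.60, tolerance = 1e-12)
  expect_equal(tab$pi_SA, 0.95, tolerance = 1e-12)  # capped at the grid end
  expect_true(tab$p_A_reproduced > tab$p_S_reproduced)
})

test_that("an all-S metapopulation stays S-type without mutation", {
  p <- p_ref(R_in = 5, P_mut = 0)
  out <- run_sim3(p, dispersal_config("RM", delta_g = 10), n_trials = 2,
                  n_gens = 100, seed = 25)
  expect_identical(out$pi_mean, 0)
  expect_identical(out$n_fixed, 0L)
})

test_that("a bistable group honors the two-state occupancy prediction", {
  # Faster switch mutation makes transitions observable at test scale while
  # keeping sweeps much faster than waits between mutations.
  p <- p_ref(R_in = 5, P_mut = 1e-4)
  eA <- estimate_single_mutant_fixation("A_into_S", p, n_reps = 1e4,
                                        seed = 26)
  eS <- estimate_single_mutant_fixation("S_into_A", p, n_reps = 1e4,
                                        seed = 27)
  tr <- transition_rates(eA$p_hat, eS$p_hat, p)
  q <- tr$P_SA / (tr$P_SA + tr$P_AS)
  set.seed(28)
  mac <- run_macroevolution(group_state(0, 17), p, n_gens = 3e5)
  traj <- mac$trajectory
  tot <- traj$n_A + traj$n_S
  piv <- ifelse(tot > 0, traj$n_A / tot, 0)
  occ <- mean(piv > 0.5)
  expect_lt(abs(occ - q), 0.25)
  # phase means sit near the two carrying capacities
  expect_lt(abs(mean(tot[piv > 0.5]) - 100), 15)
  expect_lt(abs(mean(tot[piv < 0.5]) - 16.7), 3)
  # mutation stamps are recorded
  expect_gt(nrow(mac$mutations), 0)
  expect_error(run_macroevolution(group_state(0, 17), p_ref(P_mut = 0), 10),
               "P_mut")
})
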
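test_that("grid neighborhoods have 3, 5, or 8 members under viscosity", {
  expect_length(neighbors(1, 7, 7, viscosity = 1), 3)          # corner
  expect_length(neighbors(4, 7, 7, viscosity = 1), 5)          # edge
  expect_length(neighbors(25, 7, 7, viscosity = 1), 8)         # interior
  expect_length(neighbors(25, 7, 7, viscosity = 0), 48)        # all-to-all
  expect_error(neighbors(50, 7, 7), "out of range")
  # neighborhood relation is symmetric
  for (i in c(1, 4, 25, 49)) {
    for (j in neighbors(i, 7, 7)) {
      expect_true(i %in% neighbors(j, 7, 7))
    }
  }
})

test_that("a pinned propagule moves the rounded share of each type", {
  st <- metapop_state(c(100, rep(0, 48)), c(0, rep(10, 48)))
  out <- transfer_propagule(st, donor = 1, recipient = 2, p = 0.25)
  expect_identical(out$n_A[1], 75)
  expect_identical(out$n_A[2], 25)
  expect_identical(out$n_S[2], 10)
})

test_that("every dispersal operator conserves cells exactly", {
  set.seed(12)
  for (i in 1:20) {
    st <- random_metapop()
    totA <- sum(st$n_A)
    totS <- sum(st$n_S)
    rm_ <- random_migration_round(st, dispersal_config("RM"))
    expect_identical(c(sum(rm_$n_A), sum(rm_$n_S)), c(totA, totS))
    sm_ <- selective_migration_round(st, dispersal_config("SM"))
    expect_identical(c(sum(sm_$n_A), sum(sm_$n_S)), c(totA, totS))
    tg_ <- trait_group_shuffle(st)
    expect_identical(c(sum(tg_$n_A), sum(tg_$n_S)), c(totA, totS))
    expect_true(all(rm_$n_A >= 0 & rm_$n_S >= 0 & sm_$n_A >= 0 &
                      sm_$n_S >= 0))
  }
})

test_that("random migration never reuses a donor or recipient in a round", {
  set.seed(13)
  for (i in 1:20) {
    st <- random_metapop()
    out <- random_migration_round(st, dispersal_config("RM"))
    log <- attr(out, "dispersal_log")
    if (is.null(log)) next
    roles <- c(log[, "donor"], log[, "recipient"])
    expect_identical(anyDuplicated(roles), 0L)
    expect_lte(nrow(log), 10)
  }
})

test_that("selective migration donates only from the largest groups", {
  set.seed(14)
  # one dominant group with a single candidate slot donates every event
  a <- c(rep(0, 24), 1000, rep(0, 24))
  s <- rep(17, 49)
  s[25] <- 0
  st <- metapop_state(a, s)
  cfg <- dispersal_config("SM", sm_candidates = 1)
  out <- selective_migration_round(st, cfg)
  log <- attr(out, "dispersal_log")
  expect_identical(unname(unique(log[, "donor"])), 25)
  expect_identical(nrow(log), 1L)                      # donors donate once
  # with the default ten candidates, donors are among the ten largest
  sizes <- st$n_A + st$n_S
  out2 <- selective_migration_round(st, dispersal_config("SM"))
  log2 <- attr(out2, "dispersal_log")
  expect_true(all(sizes[log2[, "donor"]] >= sort(sizes, decreasing = TRUE)[10]))
  expect_identical(anyDuplicated(log2[, "donor"]), 0L)
})

test_that("empty patches may be recolonized but never donate", {
  set.seed(15)
  a <- numeric(49)
  s <- numeric(49)
  s[25] <- 170
  st <- metapop_state(a, s)
  out <- random_migration_round(st, dispersal_config("RM"))
  log <- attr(out, "dispersal_log")
  expect_identical(unname(log[, "donor"]), 25)
  expect_true(out$n_S[log[1, "recipient"]] > 0)
  # an all-empty metapopulation is a no-op
  empty <- metapop_state(numeric(49), numeric(49))
  out2 <- random_migration_round(empty, dispersal_config("RM"))
  expect_identical(sum(out2$n_A) + sum(out2$n_S), 0)
})

test_that("trait-group pooling homogenizes group composition", {
  set.seed(16)
  st <- metapop_state(c(rep(100, 25), rep(0, 24)),
                      c(rep(0, 25), rep(17, 24)))
  pi_k <- function(x) {
    tot <- x$n_A + x$n_S
    (x$n_A / pmax(tot, 1))[tot > 0]
  }
  pre <- stats::var(pi_k(st))
  post <- stats::var(pi_k(trait_group_shuffle(st)))
  expect_lt(post, pre)
  expect_lt(post, 0.02)
  # redistribution is uniform: long-run per-patch share is N / 49
  a <- numeric(49)
  a[1] <- 490
  st2 <- metapop_state(a, numeric(49))
  acc <- numeric(49)
  for (i in 1:300) acc <- acc + trait_group_shuffle(st2)$n_A
  expect_lt(max(abs(acc / 300 - 10)), 1)
})

test_that("metapopulation stepping composes dispersal and group dynamics", {
  set.seed(17)
  p <- p_ref(P_mut = 0)
  st <- metapop_state(numeric(49), rep(17, 49))
  # without mutation an all-S metapopulation can never produce A-types
  run <- run_metapopulation(st, p, dispersal_config("RM", delta_g = 10),
                            n_gens = 100)
  expect_equal(sum(run$state$n_A), 0)
  expect_equal(run$state$generation, 100)
  # extinct patches persist as empty patches under isolation
  a <- numeric(49)
  a[1] <- 100
  st2 <- metapop_state(a, numeric(49))
  out <- step_metapopulation(st2, p, dispersal_config("none", delta_g = 5))
  expect_equal(sum(out$n_A[-1] + out$n_S[-1]), 0)
})

test_that("metapopulation summaries report composition and extinctions", {
  a <- c(100, numeric(48))
  s <- c(0, rep(17, 48))
  sm <- metapop_summary(metapop_state(a, s))
  expect_equal(sm$pi, 100 / 916)
  expect_equal(sm$F_A, 1 / 49)
  expect_identical(sm$n_extinct, 0L)
  expect_identical(metapop_summary(metapop_state(rep(1, 49),
                                                 numeric(49)))$pi, 1)
  expect_identical(metapop_summary(metapop_state(numeric(49),
                                                 rep(1, 49)))$pi, 0)
  expect_warning(sm0 <- metapop_summary(metapop_state(numeric(49),
                                                      numeric(49))),
                 "extinct")
  expect_true(is.na(sm0$pi))
  # tabular snapshot covers the full grid
  tab <- metapop_to_table(metapop_state(a, s, generation = 10))
  expect_identical(nrow(tab), 49L)
  expect_identical(sum(tab$n_A), 100)
  expect_identical(unique(tab$generation), 10)
})
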
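test_that("the solved table reproduces the worked stage-1 example", {
  qt <- solve_condition("MULTIPLY_BIG")
  s <- trial_state("MULTIPLY_BIG", revealed_A = 2, trial_type = "AA")
  expect_equal(q_guess(qt, s, "B"), 110 * (738 / 966) - 50)     # ~34.04
  expect_equal(round(q_sample(qt, s, "A2"), 1), 28.8)
  expect_equal(round(relative_value_of_guessing(qt, s), 1), 5.2)
  # SMALL mirror: identical values with rows relabelled
  qts <- solve_condition("MULTIPLY_SMALL")
  sm <- trial_state("MULTIPLY_SMALL", revealed_A = 2, trial_type = "AA")
  expect_identical(q_guess(qts, sm, "A"), q_guess(qt, s, "B"))
  expect_identical(q_sample(qts, sm, "A2"), q_sample(qt, s, "A2"))
})

test_that("stage-3 values are the direct one-step expectation", {
  qt <- solve_condition("ADD_BIG")
  # sampling the last card always reveals the winner: value 15 = 60 - 45
  expect_equal(qt$s3b$q_sample, 15)
  expect_equal(qt$s3a$q_sample, 15)
  set.seed(11)
  for (k in 1:8) {
    ra <- sort(sample(10, 2, replace = TRUE)); rb <- sample(10, 1)
    s <- trial_state("ADD_BIG", ra, rb)
    expect_equal(max(q_guess(qt, s, "A"), q_guess(qt, s, "B"), q_sample(qt, s, "B2")),
                 oracle_value("ADD_BIG", ra, rb, 25), tolerance = 1e-9)
  }
})

test_that("recursion agrees with brute-force expectimax at stage 2", {
  set.seed(5)
  for (cond in c("MULTIPLY_BIG", "ADD_SMALL", "SINGLE_BIG")) {
    qt <- solve_condition(cond)
    for (k in 1:4) {
      a1 <- sample(10, 1); b1 <- sample(10, 1)
      s <- trial_state(cond, a1, b1)
      got <- max(q_guess(qt, s, "A"), q_guess(qt, s, "B"),
                 q_sample(qt, s, "A2"), q_sample(qt, s, "B2"))
      expect_equal(got, oracle_value(cond, a1, b1, 10), tolerance = 1e-9,
                   info = paste(cond, a1, b1))
      ra <- sort(sample(10, 2, replace = TRUE))
      s2 <- trial_state(cond, ra)
      got2 <- max(q_guess(qt, s2, "A"), q_guess(qt, s2, "B"), q_sample(qt, s2, "B1"))
      expect_equal(got2, oracle_value(cond, ra, integer(), 10), tolerance = 1e-9,
                   info = paste(cond, ra[1], ra[2]))
    }
  }
})

test_that("stage-1 sample values are transition-weighted child optima", {
  # independent check of the conditioned transition probabilities
  cond <- "MULTIPLY_BIG"
  qt <- solve_condition(cond)
  for (c1 in c(2, 5, 9)) {
    num <- den <- 0
    for (v in 1:10) {
      w <- sum(infoseek:::.winner_array(cond)[c1, v, , ] != 0L)
      num <- num + w * oracle_value(cond, sort(c(c1, v)), integer(), 10)
      den <- den + w
    }
    s <- trial_state(cond, c1, trial_type = "AA")
    expect_equal(q_sample(qt, s, "A2"), num / den, tolerance = 1e-9)
  }
})

test_that("BIG and SMALL directions have identical tables up to relabeling", {
  for (op in c("ADD", "MULTIPLY")) {
    qb <- solve_condition(paste0(op, "_BIG"))
    qs <- solve_condition(paste0(op, "_SMALL"))
    expect_identical(qb$s1$q_guess_A, qs$s1$q_guess_B)
    expect_identical(qb$s1$q_guess_B, qs$s1$q_guess_A)
    expect_identical(qb$s1$q_sample, qs$s1$q_sample)
    expect_identical(qb$s2ab$q_sample_A, qs$s2ab$q_sample_A)
    expect_identical(qb$s2ab$q_sample_B, qs$s2ab$q_sample_B)
    expect_identical(qb$s2ab$q_guess_A, qs$s2ab$q_guess_B)
    expect_identical(qb$s2aa$q_star, qs$s2aa$q_star)
    expect_identical(qb$s3b$q_star, qs$s3b$q_star)
  }
})

test_that("a subjective sampling cost lowers sampling values monotonically", {
  q0 <- solve_condition("MULTIPLY_BIG")
  q5 <- solve_condition("MULTIPLY_BIG", extra_sample_cost = 5)
  expect_true(all(q5$s1$q_sample < q0$s1$q_sample))
  expect_true(all(q5$s2aa$q_sample < q0$s2aa$q_sample))
  expect_true(all(q5$s2ab$q_sample_A < q0$s2ab$q_sample_A, na.rm = TRUE))
  expect_true(q5$s3b$q_sample < q0$s3b$q_sample)
  # guessing regions can only grow
  p0 <- optimal_policy(q0); p5 <- optimal_policy(q5)
  expect_true(all(p5$p_guess1 >= p0$p_guess1))
  expect_true(all(p5$p_guess2ab >= p0$p_guess2ab, na.rm = TRUE))
  # and the expected sampling depth drops
  expect_lt(expected_cards_optimal(q5), expected_cards_optimal(q0))
})

test_that("relative value of guessing is U-shaped in the first card", {
  qt <- solve_condition("MULTIPLY_BIG")
  rv <- function(c1) relative_value_of_guessing(
    qt, trial_state("MULTIPLY_BIG", c1, trial_type = "AA"))
  expect_gt(rv(1), rv(5))
  expect_gt(rv(10), rv(5))
})

test_that("expected cards under the optimal policy match simulation", {
  qt <- solve_condition("MULTIPLY_BIG")
  ec <- expected_cards_optimal(qt)
  expect_gte(ec, 0); expect_lte(ec, 3)
  spec <- population_spec(2500, policy = "OPTIMAL",
                          conditions = c("MULTIPLY_BIG", "MULTIPLY_SMALL"))
  ds <- generate_population(spec, seed = 21)
  sub <- ds[ds$condition == "MULTIPLY_BIG", ]
  cards <- sub$guess_stage - 1
  se <- sd(cards) / sqrt(length(cards))
  expect_lt(abs(mean(cards) - ec), 3 * se)
})

test_that("qtable exports a complete tidy table", {
  df <- as.data.frame(solve_condition("ADD_BIG"))
  expect_equal(nrow(df), 60 + 300 + 400 + 3000 + 3000)
  expect_true(all(is.finite(df$value) | is.nan(df$value)))
  expect_error(q_sample(solve_condition("ADD_BIG"),
                        trial_state("ADD_BIG", 5, 3), "B1"),
               class = "infoseek_illegal_action")
})
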
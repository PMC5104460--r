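test_that("row scores and winners follow the six-condition rules", {
  expect_equal(row_score("MULTIPLY_BIG", c(7, 2)), 14)
  expect_equal(row_score("ADD_BIG", c(7, 2)), 9)
  expect_equal(row_score("SINGLE_BIG", c(7, 2)), 7)
  expect_equal(row_score("SINGLE_SMALL", c(7, 2)), 2)
  expect_error(row_score("MULTIPLY_BIG", c(0, 5)), class = "infoseek_invalid_card")
  expect_error(row_score("MULTIPLY_BIG", c(3, 11)), class = "infoseek_invalid_card")

  expect_equal(winner("MULTIPLY_BIG", c(7, 2), c(3, 5)), "B")
  expect_equal(winner("ADD_SMALL", c(1, 1), c(10, 10)), "A")
  expect_equal(winner("MULTIPLY_BIG", c(2, 6), c(3, 4)), "TIE")
  expect_equal(winner("SINGLE_BIG", c(9, 1), c(8, 8)), "A")
  expect_equal(winner("SINGLE_SMALL", c(9, 1), c(8, 8)), "A")
})

test_that("win probability reproduces the enumeration oracle", {
  # the worked example: first card 2 in MULTIPLY BIG, 738/966 non-tied wins
  s <- trial_state("MULTIPLY_BIG", revealed_A = 2, trial_type = "AA")
  expect_equal(win_probability(s, "B"), 738 / 966)
  expect_equal(round(win_probability(s, "B"), 3), 0.764)
  # mirrored SMALL state: same probability for the other row
  sm <- trial_state("MULTIPLY_SMALL", revealed_A = 2, trial_type = "AA")
  expect_identical(win_probability(sm, "A"), win_probability(s, "B"))

  # random states at every stage against the independent oracle
  set.seed(41)
  for (k in 1:12) {
    cond <- sample(infoseek_conditions(), 1)
    shape <- sample(list(c(1, 0), c(2, 0), c(1, 1), c(2, 1), c(1, 2)), 1)[[1]]
    ra <- sample(10, shape[1], replace = TRUE)
    rb <- if (shape[2]) sample(10, shape[2], replace = TRUE) else integer()
    st <- trial_state(cond, ra, rb, trial_type = if (sum(shape) == 1) "AA")
    for (row in c("A", "B"))
      expect_equal(win_probability(st, row),
                   oracle_win_prob(cond, sort(ra), sort(rb), row),
                   info = paste(cond, paste(ra, collapse = ","), paste(rb, collapse = ",")))
    expect_equal(win_probability(st, "A") + win_probability(st, "B"), 1)
  }
})

test_that("BIG/SMALL information symmetry holds for ADD and MULTIPLY", {
  set.seed(7)
  for (k in 1:10) {
    op <- sample(c("ADD", "MULTIPLY"), 1)
    ra <- sample(10, sample(1:2, 1), replace = TRUE)
    rb <- if (runif(1) < 0.5) sample(10, 1) else integer()
    tt <- if (length(ra) + length(rb) == 1) "AA"
    sb <- trial_state(paste0(op, "_BIG"), ra, rb, trial_type = tt)
    ss <- trial_state(paste0(op, "_SMALL"), ra, rb, trial_type = tt)
    expect_identical(win_probability(sb, "A"), win_probability(ss, "B"))
  }
})

test_that("legal actions follow the stage structure", {
  s1 <- trial_state("ADD_BIG", 5, trial_type = "AA")
  a1 <- legal_actions(s1)
  expect_length(a1, 3)
  expect_equal(sum(vapply(a1, function(a) a$kind == "SAMPLE", logical(1))), 1)
  expect_equal(a1[[1]]$target, "A2")
  s1b <- trial_state("ADD_BIG", 5, trial_type = "AB")
  expect_equal(legal_actions(s1b)[[1]]$target, "B1")

  s2 <- trial_state("ADD_BIG", 5, 3)            # AB path: one card per row
  a2 <- legal_actions(s2)
  expect_length(a2, 4)
  expect_setequal(vapply(a2[1:2], `[[`, character(1), "target"), c("A2", "B2"))
  s2aa <- trial_state("ADD_BIG", c(5, 6))
  # the two face-down row-B cards are exchangeable: one canonical sample action
  expect_length(legal_actions(s2aa), 3)

  s3 <- trial_state("ADD_BIG", c(5, 6), 3)
  expect_length(legal_actions(s3), 3)
  s4 <- trial_state("ADD_BIG", c(5, 6), c(3, 4))
  expect_length(legal_actions(s4), 2)           # choice stage: guesses only
  expect_error(legal_actions(trial_state("ADD_BIG", c(5, 5), c(4, 6))),
               class = "infoseek_no_actions")
})

test_that("apply_action enforces the cost schedule and payoff formula", {
  s1 <- trial_state("MULTIPLY_BIG", 2, trial_type = "AA")
  s2 <- apply_action(s1, action("SAMPLE", "A2"), drawn = 7)
  expect_equal(s2$total_cost, 10)
  expect_equal(s2$revealed_A, c(2L, 7L))
  s3 <- apply_action(s2, action("SAMPLE", "B1"), drawn = 3)
  expect_equal(s3$total_cost, 25)
  s4 <- apply_action(s3, action("SAMPLE", "B2"), drawn = 4)
  expect_equal(s4$total_cost, 45)
  out <- apply_action(s4, action("GUESS", "A"))   # 14 > 12: A wins
  expect_s3_class(out, "trial_outcome")
  expect_equal(out$points, 15)                    # 60 - 10 - 15 - 20
  expect_equal(out$winning_row, "A")
  wrong <- apply_action(s4, action("GUESS", "B"))
  expect_equal(wrong$points, -95)

  # guessing early resolves against the supplied hidden cards
  out1 <- apply_action(s1, action("GUESS", "B"), hidden = c(10, 1, 1))
  expect_equal(out1$points, -50)                  # A = {2,10} = 20 beats {1,1}
  expect_equal(out1$total_cost, 0)
  expect_error(apply_action(s1, action("SAMPLE", "B1"), drawn = 5),
               class = "infoseek_illegal_action")
  expect_error(apply_action(s1, action("GUESS", "A"), hidden = 5),
               class = "infoseek_illegal_action")
  # tied full board has no defined winner
  st <- trial_state("MULTIPLY_BIG", c(2, 6), c(3, 4))
  expect_error(apply_action(st, action("GUESS", "A")),
               class = "infoseek_undefined_winner")
})

test_that("state construction validates its invariants", {
  expect_error(trial_state("MULTIPLY_BIG", 2), class = "infoseek_invalid_state")
  expect_error(trial_state("MULTIPLY_BIG", c(1, 2, 3)), class = "infoseek_invalid_state")
  expect_error(trial_state("NOT_A_CONDITION", 2, trial_type = "AA"),
               class = "infoseek_invalid_condition")
  s <- trial_state("MULTIPLY_BIG", c(9, 2), 5)
  expect_equal(s$revealed_A, c(2L, 9L))           # multiset: stored sorted
  expect_equal(s$stage, "STAGE3")
  expect_equal(s$total_cost, 25)
})
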
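test_that("aggregation matches hand counts on a built fixture", {
  tabs <- aggregate_tables(hand_fixture())
  expect_equal(tabs$pGuess["MULTIPLY_BIG", "AA", 5], 2 / 3)
  expect_equal(tabs$nGuess["MULTIPLY_BIG", "AA", 5], 3)
  expect_equal(tabs$pChooseA["MULTIPLY_BIG", "AA", 5], 1 / 2)
  expect_equal(tabs$pGuess["MULTIPLY_BIG", "AB", 2], 1 / 5)
  expect_equal(tabs$pGuess2["MULTIPLY_BIG", 2, 9], 1 / 4)
  expect_equal(tabs$pSampleA["MULTIPLY_BIG", 2, 9], 2 / 3)
  expect_equal(tabs$nSampleA["MULTIPLY_BIG", 2, 9], 3)
  expect_equal(tabs$pGuess["MULTIPLY_BIG", "AA", 8], 1)
  # unobserved cells are missing, not zero
  expect_true(is.na(tabs$pGuess["ADD_BIG", "AA", 5]))
  expect_true(is.na(tabs$pSampleA["MULTIPLY_BIG", 3, 3]))
})

test_that("the three statistics are exactly zero for the optimal policy", {
  tp <- aggregate_from_policy()
  for (pair in c("MULTIPLY", "ADD")) {
    expect_identical(positive_evidence_approach(tp, pair, "AA")$value, 0)
    expect_identical(positive_evidence_approach(tp, pair, "AB")$value, 0)
    expect_identical(sampling_favorite(tp, pair, "strong", "omit")$value, 0)
    expect_identical(sampling_favorite(tp, pair, "weak", "omit")$value, 0)
  }
  for (cond in infoseek_conditions())
    expect_identical(rejecting_unsampled(tp, cond)$value, 0)
})

test_that("statistics respond to their bias parameter in model predictions", {
  tabs_at <- function(b4 = 0, b5 = 0, b6 = 0) {
    p1 <- model_params(0.7, 2, 1, 1, b4, b5, b6, stage = 1, pair = "MULTIPLY")
    p2 <- model_params(0.7, 2, 1, 1, b4, b5, b6, stage = 2, pair = "MULTIPLY")
    predict_aggregate(p2, predict_aggregate(p1))
  }
  pea <- function(t, tt) positive_evidence_approach(t, "MULTIPLY", tt, "omit")$value
  # beta5 drives positive evidence approach on AA trials, increasing
  v <- vapply(c(0, 0.05, 0.1), function(b) pea(tabs_at(b5 = b), "AA"), numeric(1))
  expect_identical(v[1], 0)
  expect_true(all(diff(v) > 0))
  # beta4 drives rejecting-unsampled and AB positive evidence approach
  v4 <- vapply(c(0, 0.03, 0.06), function(b)
    rejecting_unsampled(tabs_at(b4 = b), "MULTIPLY_BIG", "omit")$value, numeric(1))
  expect_identical(v4[1], 0)
  expect_true(all(diff(v4) > 0))
  expect_gt(pea(tabs_at(b4 = 0.05), "AB"), 0)
  # beta6 drives sampling-the-favorite, strong band exceeding weak
  v6 <- vapply(c(0, 0.03, 0.06), function(b)
    sampling_favorite(tabs_at(b6 = b), "MULTIPLY", "strong", "omit")$value, numeric(1))
  expect_identical(v6[1], 0)
  expect_true(all(diff(v6) > 0))
  t6 <- tabs_at(b6 = 0.06)
  s_strong <- sampling_favorite(t6, "MULTIPLY", "strong", "omit")
  s_weak <- sampling_favorite(t6, "MULTIPLY", "weak", "omit")
  expect_gt(s_strong$value / s_strong$cells_used, s_weak$value / s_weak$cells_used)
})

test_that("statistics are invariant to trial order and subject relabeling", {
  ds <- pop_multiply(150, seed = 31)
  t1 <- aggregate_tables(ds)
  set.seed(1)
  shuf <- ds[sample(nrow(ds)), ]
  shuf$uid <- match(shuf$uid, sample(unique(shuf$uid)))
  t2 <- aggregate_tables(shuf)
  expect_equal(t1$pGuess, t2$pGuess)
  expect_equal(t1$pSampleA, t2$pSampleA)
  expect_equal(positive_evidence_approach(t1, "MULTIPLY", "AA", "omit")$value,
               positive_evidence_approach(t2, "MULTIPLY", "AA", "omit")$value)
})

test_that("missing cells are omitted with a warning or raise an error", {
  tabs <- aggregate_tables(hand_fixture())
  expect_warning(r <- positive_evidence_approach(tabs, "MULTIPLY", "AA"),
                 "empty cell")
  expect_gt(r$cells_missing, 0)
  expect_error(positive_evidence_approach(tabs, "MULTIPLY", "AA", "error"),
               class = "infoseek_missing_cells")
})

test_that("gameplay bootstrap is seeded, centred and degenerate-safe", {
  ds <- pop_multiply(150, seed = 31)
  fn <- function(t) positive_evidence_approach(t, "MULTIPLY", "AA", "omit")
  b1 <- bootstrap_ci(ds, fn, n_boot = 60, sample_size = 400, seed = 9)
  b2 <- bootstrap_ci(ds, fn, n_boot = 60, sample_size = 400, seed = 9)
  expect_identical(b1$replicates, b2$replicates)
  expect_lte(b1$lower, b1$upper)
  # point estimate equals the full-sample statistic
  expect_equal(b1$value, suppressWarnings(fn(aggregate_tables(ds)))$value)
  # a constant statistic has a zero-width interval
  bc <- bootstrap_ci(ds, function(t) 1.5, n_boot = 20, sample_size = 50, seed = 2)
  expect_equal(bc$lower, 1.5); expect_equal(bc$upper, 1.5)
  # larger resamples concentrate the replicates around the point estimate
  b3 <- bootstrap_ci(ds, fn, n_boot = 60, sample_size = 4000, seed = 9)
  expect_lt(sd(b3$replicates), sd(b1$replicates))
})

test_that("sampling depth is zero for the optimal agent and replays policies", {
  dso <- cached("pop_opt", generate_population(
    population_spec(500, policy = "OPTIMAL",
                    conditions = c("MULTIPLY_BIG", "MULTIPLY_SMALL")), seed = 4))
  sdo <- sampling_depth(dso)
  expect_lt(abs(mean(sdo$per_gameplay$mean_relative)), 0.02)
  # always-guess agent: negative depth equal to minus the optimal expectation
  ag <- simulate_agent(agent_spec("ALWAYS_GUESS"), n_gameplays = 60,
                       conditions = c("MULTIPLY_BIG", "MULTIPLY_SMALL"), seed = 2)
  sda <- sampling_depth(ag)
  ec <- mean(c(expected_cards_optimal(solve_condition("MULTIPLY_BIG")),
               expected_cards_optimal(solve_condition("MULTIPLY_SMALL"))))
  expect_equal(mean(sda$per_gameplay$mean_relative), -ec, tolerance = 0.05)
  # per-state expectation variant agrees in aggregate
  sde <- sampling_depth(ag, method = "expected")
  expect_equal(mean(sde$per_gameplay$mean_relative),
               mean(sda$per_gameplay$mean_relative), tolerance = 0.05)
})

test_that("stable per-subject parameters reproduce across gameplays", {
  ds <- cached("pop_retest", generate_population(
    population_spec(250, n_gameplays = 2,
                    conditions = c("MULTIPLY_BIG", "MULTIPLY_SMALL")), seed = 13))
  r <- sampling_depth(ds)
  expect_equal(r$n_retest, 250)
  expect_gt(r$retest_r, 0.5)
})

test_that("per-subject averaging and marginal imputation variants work", {
  ds <- pop_multiply(150, seed = 31)
  tp <- aggregate_tables(ds)
  ts <- aggregate_tables(ds, average = "subjects")
  # one subject: the two conventions coincide exactly
  one <- ds[ds$uid == 1, ]
  expect_equal(aggregate_tables(one)$pGuess, aggregate_tables(one, average = "subjects")$pGuess)
  # population: same occupied cells, probabilities close but not identical
  expect_identical(is.na(tp$pGuess), is.na(ts$pGuess))
  occ <- !is.na(tp$pGuess)
  expect_lt(max(abs(tp$pGuess[occ] - ts$pGuess[occ])), 0.25)
  expect_true(max(ts$nGuess) <= 150)
  # imputation fills missing difference cells with the observed-cell mean
  sparse <- ds[!(ds$condition == "MULTIPLY_BIG" & ds$trial_type == "AA" &
                   ds$first_card == 7), ]
  hs <- aggregate_tables(sparse)
  expect_true(is.na(hs$pGuess["MULTIPLY_BIG", "AA", 7]))
  r_omit <- positive_evidence_approach(hs, "MULTIPLY", "AA", "omit")
  r_imp <- positive_evidence_approach(hs, "MULTIPLY", "AA", "impute")
  expect_equal(r_imp$value, r_omit$value * 10 / r_omit$cells_used)
})
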
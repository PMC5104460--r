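test_that("effective cards, omega and the softmax behave as specified", {
  expect_equal(effective_card(10, "SMALL"), 1)
  expect_equal(effective_card(1, "SMALL"), 10)
  expect_equal(effective_card(5, "BIG"), 5)
  expect_equal(effective_card(1:10, "SMALL"), 10:1)

  expect_equal(omega_uncertainty(2, 2), 0)
  expect_equal(omega_uncertainty(0, 50), -0.25, tolerance = 1e-9)
  d <- rnorm(20)
  expect_equal(omega_uncertainty(d, -d), omega_uncertainty(-d, d))
  expect_true(all(omega_uncertainty(d, -d) <= 0 & omega_uncertainty(d, -d) >= -0.25))

  expect_equal(unname(choice_probabilities(c(a = 1, b = 1, c = 1), tau = 2)),
               rep(1 / 3, 3))
  expect_equal(unname(choice_probabilities(c(a = 5, b = -3), tau = 0)), c(0.5, 0.5))
  p <- choice_probabilities(c(a = 0.3, b = -1, c = 2, d = 0), tau = 1.7)
  expect_equal(sum(p), 1)
  expect_error(choice_probabilities(numeric(), 1), class = "infoseek_illegal_option")
})

test_that("option values implement the published stage formulas", {
  p <- model_params(1, 0.5, 2, 1, stage = 1)
  v <- option_values(p, first_card = 7, trial_type = "AA")
  expect_equal(unname(v["A"]), 1.5)     # beta1 * (7 - 5.5)
  expect_equal(unname(v["B"]), -1.5)
  expect_named(v, c("A", "B", "sample_A"))
  vab <- option_values(p, 7, "AB")
  expect_named(vab, c("A", "B", "sample_B"))

  # approach bonus raises the unsampleable row's value
  pf <- model_params(1, 0.5, 2, 1, beta4 = 0.1, stage = 1)
  vaa <- option_values(pf, 7, "AA")
  expect_equal(unname(vaa["B"] - v["B"]), 0.1 * 5.5)

  p2 <- model_params(2, 0.5, 2, 1, beta6 = 0.5, stage = 2)
  v2 <- option_values(p2, first_card = 7, second_card = 3)
  expect_equal(unname(v2["A"]), 8)      # beta1 * (7 - 3)
  expect_equal(unname(v2["sample_A"] - v2["sample_B"]), 2 * 0.5 * 4)
  expect_error(option_values(p2, 7), class = "infoseek_illegal_option")
})

test_that("reduced-model predictions are direction-symmetric, full are not", {
  pr <- model_params(0.7, 2, 1, 1, stage = 1, pair = "MULTIPLY")
  pr2 <- model_params(0.7, 2, 1, 1, stage = 2, pair = "MULTIPLY")
  tr <- predict_aggregate(pr2, predict_aggregate(pr))
  expect_equal(positive_evidence_approach(tr, "MULTIPLY", "AA", "omit")$value, 0)
  expect_equal(rejecting_unsampled(tr, "MULTIPLY_BIG", "omit")$value, 0)
  expect_equal(sampling_favorite(tr, "MULTIPLY", "strong", "omit")$value, 0)
  # beta5 selectively raises guessing on AA over AB trials
  pf <- model_params(0.7, 2, 1, 1, beta5 = 0.1, stage = 1, pair = "MULTIPLY")
  tf <- predict_aggregate(pf)
  expect_true(all(tf$pGuess["MULTIPLY_BIG", "AA", ] >=
                  tf$pGuess["MULTIPLY_BIG", "AB", ]))
  expect_gt(mean(tf$pGuess["MULTIPLY_BIG", "AA", ] -
                 tf$pGuess["MULTIPLY_BIG", "AB", ]), 0.01)
})

test_that("fitting recovers noise-free model predictions", {
  truth <- model_params(0.6, 1.8, 1.2, 1.1, beta4 = 0.05, beta5 = 0.08,
                        stage = 1, pair = "MULTIPLY")
  obs <- predict_aggregate(truth)
  obs$nGuess[] <- 1000; obs$nChooseA[] <- 1000
  fit <- fit_aggregate(obs, 1, "MULTIPLY", full = TRUE, n_restarts = 12, seed = 3)
  expect_lt(fit$objective, 1e-6)
  expect_true(fit$converged)
  # identified quantities (softmax-gain products) match the truth
  expect_equal(fit$params$tau * fit$params$beta4, truth$tau * truth$beta4,
               tolerance = 0.05)
  expect_equal(fit$params$tau * fit$params$beta5, truth$tau * truth$beta5,
               tolerance = 0.05)
  # determinism under a fixed seed
  fit2 <- fit_aggregate(obs, 1, "MULTIPLY", full = TRUE, n_restarts = 12, seed = 3)
  expect_identical(fit$theta, fit2$theta)
})

test_that("binomial objective accepts counts and stays close to SSE fit", {
  ds <- pop_multiply(300, seed = 17)
  tabs <- aggregate_tables(ds)
  f1 <- fit_aggregate(tabs, 1, "MULTIPLY", n_restarts = 6, seed = 1)
  f2 <- fit_aggregate(tabs, 1, "MULTIPLY", n_restarts = 6, seed = 1,
                      objective = "binomial")
  expect_true(f2$converged)
  pg1 <- predict_aggregate(f1$params)$pGuess["MULTIPLY_BIG", "AA", ]
  pg2 <- predict_aggregate(f2$params)$pGuess["MULTIPLY_BIG", "AA", ]
  expect_lt(max(abs(pg1 - pg2)), 0.1)
})

test_that("cross-validation folds are reproducible and errors are sane", {
  ds <- pop_multiply(80, seed = 23)
  cv1 <- crossvalidate(ds, stage = 1, pair = "MULTIPLY", k = 3, seed = 5,
                       n_restarts = 3)
  cv2 <- crossvalidate(ds, stage = 1, pair = "MULTIPLY", k = 3, seed = 5,
                       n_restarts = 3)
  expect_identical(cv1, cv2)
  expect_equal(nrow(cv1), 6)
  expect_true(all(cv1$sse_holdout >= 0))
  expect_error(crossvalidate(ds[ds$uid == 1, ], k = 10),
               class = "infoseek_invalid_dataset")
})
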
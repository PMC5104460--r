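trials_of <- function(type, certain, o1, o2 = 0) {
  data.frame(trial_type = type, certain = certain, outcome1 = o1, outcome2 = o2)
}

test_that("p_gamble respects its bounds and recovers the plain softmax", {
  # equal utilities, no bias: indifference
  expect_equal(p_gamble(trials_of("GAIN", 1, 1, 1), gamble_params(0.5)), 0.5)
  # beta floors and ceilings
  pg <- gamble_params(mu = 0.2, beta_gain = 0.2)
  awful <- trials_of("GAIN", 500, 1, 0)       # gamble far worse than certain
  expect_equal(p_gamble(awful, pg), 0.2, tolerance = 1e-4)
  pl <- gamble_params(mu = 0.2, beta_loss = -0.3)
  great <- trials_of("LOSS", -500, -1, 0)     # gamble far better
  expect_equal(p_gamble(great, pl), 0.7, tolerance = 1e-4)
  # beta = 0 is exactly the softmax of the utility difference
  pz <- gamble_params(mu = 0.15)
  tg <- trials_of("GAIN", 25, 60, 0)
  ug <- 0.5 * 60^0.88; uc <- 25^0.88
  expect_equal(p_gamble(tg, pz), plogis(0.15 * (ug - uc)))
  # monotone in the utility difference
  certs <- seq(10, 70, by = 5)
  ps <- p_gamble(trials_of("GAIN", certs, 80, 0), pg)
  expect_true(all(diff(ps) < 0))
  expect_error(gamble_params(0.1, beta_gain = 1.2), class = "infoseek_invalid_params")
  expect_error(gamble_params(-1), class = "infoseek_invalid_params")
})

test_that("subject fitting is seeded and flags degenerate responders", {
  g <- simulate_gamble_population(2, trials_per_play = 60, seed = 4)
  tr <- g[g$uid == 1, ]
  f1 <- fit_gamble_subject(tr, n_restarts = 5, seed = 7)
  f2 <- fit_gamble_subject(tr, n_restarts = 5, seed = 7)
  expect_identical(f1$params, f2$params)
  expect_false(f1$degenerate)
  allg <- tr; allg$chose_gamble <- TRUE
  fd <- fit_gamble_subject(allg, n_restarts = 5, seed = 7)
  expect_true(fd$degenerate)
})

test_that("beta_gain and beta_loss are recovered on average", {
  est <- t(vapply(1:8, function(seed) {
    g <- simulate_gamble_population(1, mu_mean = 0.15, beta_gain_mean = 0.25,
                                    beta_loss_mean = -0.2, beta_sd = 0,
                                    trials_per_play = 300, seed = seed)
    f <- fit_gamble_subject(g, n_restarts = 10, seed = seed + 50)
    c(f$params$beta_gain, f$params$beta_loss)
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) / 0.25 - 1), 0.25)
  expect_lt(abs(mean(est[, 2]) / -0.2 - 1), 0.25)
})

test_that("median split halves the population and recovers clusters", {
  fits <- data.frame(uid = 1:10, beta_gain = c(rep(0.5, 5), rep(-0.4, 5)),
                     beta_loss = c(rep(-0.3, 5), rep(0.2, 5)))
  fits$beta_gain <- fits$beta_gain + seq(-0.01, 0.01, length.out = 10)
  sp <- split_by_approach_index(fits)
  expect_equal(sum(sp$group == "high"), 5)
  expect_true(all(sp$group[1:5] == "high") && all(sp$group[6:10] == "low"))
  # ties at the median go to the low group
  tied <- data.frame(uid = 1:4, beta_gain = c(0.1, 0.2, 0.2, 0.4),
                     beta_loss = c(0, 0, 0, 0))
  spt <- split_by_approach_index(tied)
  expect_equal(unname(table(spt$group)["low"]), 3L)
})

test_that("a linked population shows the split-group bias pattern", {
  # couple the approach index to beta4/beta5/beta6 through the latent factor
  spec <- population_spec(500, conditions = c("MULTIPLY_BIG", "MULTIPLY_SMALL"),
                          approach_link = 0.05)
  ds <- generate_population(spec, seed = 19)
  gam <- simulate_gamble_population(500, index_shift = attr(ds, "latent"),
                                    index_scale = 0.2, seed = 20)
  truep <- attr(gam, "true_params")
  sp <- split_by_approach_index(truep)       # split on true params: isolates the pipeline
  res <- approach_split_analysis(ds, sp, "MULTIPLY", n_boot = 4,
                                 sample_size = 500, n_restarts = 4, seed = 21)
  expect_equal(nrow(res), 6)
  hi <- res[res$group == "high", ]; lo <- res[res$group == "low", ]
  # the high-approach group expresses more positive-evidence-approach (beta5)
  # and more sampling-the-favorite (beta6)
  expect_gt(hi$estimate[hi$parameter == "beta5"], lo$estimate[lo$parameter == "beta5"])
  expect_gt(hi$estimate[hi$parameter == "beta6"], lo$estimate[lo$parameter == "beta6"])
  expect_true(all(is.finite(res$boot_sd)))
})
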
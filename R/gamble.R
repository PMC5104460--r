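# Approach-avoidance model of the companion risky-choice task.
#
# Expected utilities follow a power-law prospect-theory value function,
# u(x) = x^alpha for gains and -lambda * (-x)^alpha for losses (the exact
# parameterization is configurable; the companion model is not restated in
# full here). The probability of gambling is a softmax of the utility
# difference, shifted value-independently by beta_gain on gain trials and
# beta_loss on loss trials: for beta >= 0 the choice probability is bounded
# in (beta, 1), for beta < 0 in (0, 1 + beta).

#' Gamble model parameters
#'
#' @param mu choice sensitivity (>= 0).
#' @param beta_gain,beta_loss value-independent gambling biases on gain and
#'   loss trials, each in (-1, 1). Their difference `beta_gain - beta_loss`
#'   is the Pavlovian approach-avoid index.
#' @param alpha utility curvature.
#' @param lambda loss aversion.
#' @return an object of class `gamble_params`.
#' @export
gamble_params <- function(mu, beta_gain = 0, beta_loss = 0,
                          alpha = 0.88, lambda = 2.25) {
  if (mu < 0) .is_err("mu must be >= 0", "infoseek_invalid_params")
  if (abs(beta_gain) >= 1 || abs(beta_loss) >= 1)
    .is_err("|beta| must be < 1", "infoseek_invalid_params")
  structure(list(mu = mu, beta_gain = beta_gain, beta_loss = beta_loss,
                 alpha = alpha, lambda = lambda), class = "gamble_params")
}

.utility <- function(x, alpha, lambda)
  ifelse(x >= 0, abs(x)^alpha, -lambda * abs(x)^alpha)

#' Probability of choosing the gamble
#'
#' For each trial, computes prospect-theory utilities of the certain option
#' and the 50/50 gamble and applies the approach-avoidance choice rule:
#' `P = (1 - beta) * sigma(mu * (U_g - U_c)) + beta` when `beta >= 0`,
#' `P = (1 + beta) * sigma(mu * (U_g - U_c))` when `beta < 0`, with
#' `beta = beta_gain` on GAIN trials, `beta_loss` on LOSS trials and 0 on
#' MIXED trials.
#'
#' @param trials data.frame with columns `trial_type` (`"GAIN"`, `"MIXED"`,
#'   `"LOSS"`), `certain`, `outcome1`, `outcome2`.
#' @param params a [gamble_params()].
#' @return vector of probabilities.
#' @export
p_gamble <- function(trials, params) {
  stopifnot(all(c("trial_type", "certain", "outcome1", "outcome2") %in% names(trials)))
  u_c <- .utility(trials$certain, params$alpha, params$lambda)
  u_g <- 0.5 * .utility(trials$outcome1, params$alpha, params$lambda) +
         0.5 * .utility(trials$outcome2, params$alpha, params$lambda)
  base <- plogis(params$mu * (u_g - u_c))
  b <- ifelse(trials$trial_type == "GAIN", params$beta_gain,
              ifelse(trials$trial_type == "LOSS", params$beta_loss, 0))
  ifelse(b >= 0, (1 - b) * base + b, (1 + b) * base)
}

#' Fit the gamble model to one subject
#'
#' Maximum-likelihood estimation of `mu`, `beta_gain` and `beta_loss` by
#' Nelder-Mead with random restarts (utility curvature and loss aversion are
#' fixed at their defaults unless `fit_utility = TRUE`, which adds `alpha`
#' and `lambda`). Subjects who always gamble or always accept the certain
#' option yield boundary estimates and are flagged `degenerate`.
#'
#' @param trials data.frame as in [p_gamble()] plus `chose_gamble` (logical).
#' @param n_restarts random restarts.
#' @param seed RNG seed.
#' @param fit_utility also estimate `alpha` and `lambda`.
#' @param alpha,lambda fixed utility parameters when not fitted.
#' @return a list with `params` ([gamble_params()]), `nll`, `converged`,
#'   `degenerate`.
#' @export
fit_gamble_subject <- function(trials, n_restarts = 10, seed = NULL,
                               fit_utility = FALSE, alpha = 0.88, lambda = 2.25) {
  stopifnot("chose_gamble" %in% names(trials), nrow(trials) >= 1)
  if (!is.null(seed)) set.seed(seed)
  y <- as.logical(trials$chose_gamble)
  degenerate <- all(y) || all(!y)
  npar <- if (fit_utility) 5L else 3L
  lo <- c(0, -0.95, -0.95, 0.2, 0.5)[seq_len(npar)]
  hi <- c(1, 0.95, 0.95, 1.5, 4)[seq_len(npar)]
  fn <- function(theta) {
    th <- pmin(pmax(theta, lo), hi)
    pen <- 1e3 * sum((theta - th)^2)
    pars <- gamble_params(th[1], th[2], th[3],
                          alpha = if (fit_utility) th[4] else alpha,
                          lambda = if (fit_utility) th[5] else lambda)
    p <- pmin(pmax(p_gamble(trials, pars), 1e-10), 1 - 1e-10)
    -sum(log(ifelse(y, p, 1 - p))) + pen
  }
  best <- NULL; conv <- FALSE
  for (r in seq_len(n_restarts)) {
    start <- lo + runif(npar) * (hi - lo)
    o <- optim(start, fn, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-9))
    if (o$convergence == 0) conv <- TRUE
    if (is.null(best) || o$value < best$value) best <- o
  }
  th <- pmin(pmax(best$par, lo), hi)
  list(params = gamble_params(th[1], th[2], th[3],
                              alpha = if (fit_utility) th[4] else alpha,
                              lambda = if (fit_utility) th[5] else lambda),
       nll = best$value, converged = conv, degenerate = degenerate)
}

#' Median split on the approach-avoid index
#'
#' The index is `beta_gain - beta_loss`. Subjects at or below the population
#' median form the low-approach group; subjects above it the high group
#' (ties at the median go to the low group).
#'
#' @param fits data.frame with columns `uid`, `beta_gain`, `beta_loss`
#'   (e.g. built from per-subject [fit_gamble_subject()] results).
#' @return `fits` with added columns `approach_index` and `group`
#'   (`"low"`/`"high"`), plus the median as attribute `"split_at"`.
#' @export
split_by_approach_index <- function(fits) {
  stopifnot(all(c("uid", "beta_gain", "beta_loss") %in% names(fits)),
            nrow(fits) >= 2)
  idx <- fits$beta_gain - fits$beta_loss
  m <- median(idx)
  fits$approach_index <- idx
  fits$group <- ifelse(idx > m, "high", "low")
  attr(fits, "split_at") <- m
  fits
}

#' Group-wise bias-parameter comparison after a median split
#'
#' The downstream analysis of the split: subsets the gameplay dataset into
#' the high and low approach-avoid subpopulations, fits the full parametric
#' model to each group's aggregate behavior, and bootstraps the group fits
#' (resampling gameplays within group) to attach spreads to the beta4,
#' beta5 and beta6 comparisons.
#'
#' @param dataset a gameplay dataset.
#' @param split a data.frame from [split_by_approach_index()].
#' @param pair `"ADD"` or `"MULTIPLY"`.
#' @param n_boot bootstrap replicates per group (headline analysis: 100).
#' @param sample_size gameplays per bootstrap replicate.
#' @param n_restarts restarts per fit.
#' @param seed RNG seed.
#' @return data.frame with one row per group x parameter: estimate (on the
#'   identified scale, softmax gain times bias weight), bootstrap mean and sd.
#' @export
approach_split_analysis <- function(dataset, split, pair = c("MULTIPLY", "ADD"),
                                    n_boot = 100, sample_size = 10000,
                                    n_restarts = 10, seed = NULL) {
  pair <- match.arg(pair)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (grp in c("low", "high")) {
    uids <- split$uid[split$group == grp]
    sub <- dataset[dataset$uid %in% uids, ]
    if (!nrow(sub)) .is_err("empty group after split", "infoseek_invalid_dataset")
    tabs <- aggregate_tables(sub)
    f1 <- fit_aggregate(tabs, 1L, pair, full = TRUE, n_restarts = n_restarts,
                        seed = sample.int(1e6, 1))
    f2 <- fit_aggregate(tabs, 2L, pair, full = TRUE, n_restarts = n_restarts,
                        seed = sample.int(1e6, 1))
    cc <- .gameplay_counts(sub)
    boot <- matrix(NA_real_, n_boot, 3,
                   dimnames = list(NULL, c("beta4", "beta5", "beta6")))
    for (b in seq_len(n_boot)) {
      w <- tabulate(sample.int(cc$G, sample_size, replace = TRUE), nbins = cc$G)
      tb <- .tables_from_counts(as.vector(Matrix::crossprod(cc$num, w)),
                                as.vector(Matrix::crossprod(cc$den, w)))
      b1 <- fit_aggregate(tb, 1L, pair, full = TRUE, n_restarts = max(3, n_restarts %/% 3),
                          seed = sample.int(1e6, 1))
      b2 <- fit_aggregate(tb, 2L, pair, full = TRUE, n_restarts = max(3, n_restarts %/% 3),
                          seed = sample.int(1e6, 1))
      # report on the identified choice scale (softmax gain times weight):
      # raw betas are only defined up to a rescaling of the gain
      boot[b, ] <- c(b1$params$tau * b1$params$beta4,
                     b1$params$tau * b1$params$beta5,
                     b2$params$tau * b2$params$beta6)
    }
    est <- c(beta4 = f1$params$tau * f1$params$beta4,
             beta5 = f1$params$tau * f1$params$beta5,
             beta6 = f2$params$tau * f2$params$beta6)
    out[[grp]] <- data.frame(group = grp, parameter = names(est),
                             estimate = unname(est),
                             boot_mean = colMeans(boot), boot_sd = apply(boot, 2, sd),
                             row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
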
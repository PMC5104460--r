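# Empirical-Bayes hierarchical fit of the per-subject bias parameters
# (beta4, beta5, beta6) with a Gaussian population prior, alternating
# per-subject MAP estimates (Laplace approximation for posterior
# covariance) with updates of the population mean and covariance.
# The shared reduced-model parameters (beta1..beta3, tau, per stage) are
# fixed at their aggregate-fit values; with ~22 trials per subject only the
# three bias parameters are estimated subject-wise.

# per-subject design lists for the likelihood
.subject_designs <- function(dataset, pair) {
  conds <- paste0(pair, "_", c("BIG", "SMALL"))
  ds <- data.table::as.data.table(dataset)
  ds <- ds[condition %in% conds]
  if (!nrow(ds)) .is_err("no trials for this pair", "infoseek_invalid_dataset")
  ds[, dir := cond_direction(condition)]
  # stage-1 decision on every trial
  s1 <- ds[, .(uid, c_eff = ifelse(dir == "BIG", first_card, 11L - first_card),
               is_aa = trial_type == "AA",
               act = ifelse(guess_stage > 1L, 3L, ifelse(chosen_row == "A", 1L, 2L)))]
  # stage-2 decision on AB trials that reached stage 2
  ab <- ds[trial_type == "AB" & guess_stage >= 2L & !is.na(sample1_value)]
  s2 <- ab[, .(uid,
               ci = ifelse(dir == "BIG", first_card, 11L - first_card),
               cj = ifelse(dir == "BIG", sample1_value, 11L - sample1_value),
               act = ifelse(guess_stage == 2L, ifelse(chosen_row == "A", 1L, 2L),
                            ifelse(sample2_row == "A", 3L, 4L)))]
  uids <- unique(ds$uid)
  lapply(setNames(uids, uids), function(u)
    list(s1 = s1[uid == u], s2 = s2[uid == u]))
}

.subject_nll <- function(theta, des, sh1, sh2) {
  nll <- 0
  if (nrow(des$s1)) {
    p <- .stage1_probs(des$s1$c_eff, des$s1$is_aa, sh1$beta1, sh1$beta2,
                       sh1$beta3, sh1$tau, b4 = theta[1], b5 = theta[2])
    pr <- p[cbind(seq_len(nrow(p)), des$s1$act)]
    nll <- nll - sum(log(pmax(pr, 1e-12)))
  }
  if (nrow(des$s2)) {
    p <- .stage2_probs(des$s2$ci, des$s2$cj, sh2$beta1, sh2$beta2,
                       sh2$beta3, sh2$tau, b6 = theta[3])
    pr <- p[cbind(seq_len(nrow(p)), des$s2$act)]
    nll <- nll - sum(log(pmax(pr, 1e-12)))
  }
  nll
}

.nearest_psd <- function(S, eps = 1e-8) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values >= eps)) return(S)
  warning("covariance update not positive definite; eigenvalues clipped", call. = FALSE)
  e$vectors %*% diag(pmax(e$values, eps)) %*% t(e$vectors)
}

#' Hierarchical population fit of the bias parameters
#'
#' Fits per-subject `(beta4, beta5, beta6)` from sparse trial-level data
#' (around 22 trials per subject) using an iterative empirical-Bayes scheme:
#' each subject's parameters are estimated by penalized maximum likelihood
#' under a Gaussian population prior, and the population mean and covariance
#' are re-estimated from the subject posteriors (Laplace approximation)
#' until the hyperparameters stabilize. The shared stage-1 and stage-2
#' parameters are fixed at full-model aggregate fits (supplied or computed).
#' The covariance is normalized to correlation coefficients
#' `r(beta4, beta5)`, `r(beta4, beta6)`, `r(beta5, beta6)`.
#'
#' @param dataset a gameplay dataset (trial-level, per subject).
#' @param pair `"ADD"` or `"MULTIPLY"` (only this pair's conditions are used).
#' @param shared optional list with elements `stage1` and `stage2`, each a
#'   [model_params()] providing the shared parameters; computed from the
#'   pooled aggregate when omitted.
#' @param max_iter,tol hyperparameter iteration control (change in mean and
#'   covariance entries below `tol` stops).
#' @param n_restarts restarts for the aggregate fits when `shared` is omitted.
#' @param seed RNG seed for those fits.
#' @param init optional list with `mu` and/or `Sigma` overriding the default
#'   hyperparameter initialization (default: the aggregate-fit bias values
#'   and a deliberately over-dispersed diagonal covariance).
#' @return an object of class `population_fit`: `mu`, `Sigma`, `corr`,
#'   per-subject estimates, iteration count and convergence flag.
#' @export
hierarchical_fit <- function(dataset, pair = c("MULTIPLY", "ADD"), shared = NULL,
                             max_iter = 25, tol = 1e-3, n_restarts = 20,
                             seed = NULL, init = NULL) {
  pair <- match.arg(pair)
  if (is.null(shared)) {
    tabs <- aggregate_tables(dataset)
    shared <- list(
      stage1 = fit_aggregate(tabs, 1L, pair, full = TRUE,
                             n_restarts = n_restarts, seed = seed)$params,
      stage2 = fit_aggregate(tabs, 2L, pair, full = TRUE,
                             n_restarts = n_restarts, seed = seed)$params)
  }
  sh1 <- shared$stage1; sh2 <- shared$stage2
  des <- .subject_designs(dataset, pair)
  n <- length(des)
  if (n < 2L) .is_err("hierarchical fit needs >= 2 subjects", "infoseek_invalid_dataset")
  mu <- if (!is.null(init$mu)) init$mu else c(sh1$beta4, sh1$beta5, sh2$beta6)
  # start the prior wide: EM shrinks an over-dispersed covariance toward the
  # data-supported one much faster than it inflates an under-dispersed one
  Sigma <- if (!is.null(init$Sigma)) init$Sigma else
    diag(pmax(abs(mu), 0.08)^2)
  est <- matrix(rep(mu, each = n), n, 3)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iS <- solve(Sigma)
    post_cov_sum <- matrix(0, 3, 3)
    for (s in seq_len(n)) {
      pen <- function(theta) {
        d <- theta - mu
        .subject_nll(theta, des[[s]], sh1, sh2) + 0.5 * drop(d %*% iS %*% d)
      }
      o <- optim(est[s, ], pen, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-7))
      est[s, ] <- o$par
      H <- tryCatch(optimHess(o$par, pen), error = function(e) NULL)
      cv <- if (!is.null(H)) tryCatch(solve(.nearest_psd(H, 1e-6)),
                                      error = function(e) Sigma) else Sigma
      post_cov_sum <- post_cov_sum + cv
    }
    mu_new <- colMeans(est)
    ctr <- sweep(est, 2, mu_new)
    Sigma_new <- .nearest_psd(crossprod(ctr) / n + post_cov_sum / n)
    # relative change: Sigma entries live on the scale of tiny variances
    delta <- max(abs(mu_new - mu)) / max(max(abs(mu)), 1e-8) +
             max(abs(Sigma_new - Sigma)) / max(abs(Sigma))
    mu <- mu_new; Sigma <- Sigma_new
    if (delta < tol) { converged <- TRUE; break }
  }
  corr <- cov2cor(Sigma)
  dimnames(corr) <- dimnames(Sigma) <- list(c("beta4", "beta5", "beta6"),
                                            c("beta4", "beta5", "beta6"))
  names(mu) <- c("beta4", "beta5", "beta6")
  subjects <- data.frame(uid = names(des), beta4 = est[, 1], beta5 = est[, 2],
                         beta6 = est[, 3], row.names = NULL)
  structure(list(mu = mu, Sigma = Sigma, corr = corr, subjects = subjects,
                 shared = shared, iterations = it, converged = converged),
            class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("<population_fit> %d subjects, %d iterations (%sconverged)\n",
              nrow(x$subjects), x$iterations, if (x$converged) "" else "NOT "))
  cat("mu:\n"); print(round(x$mu, 4))
  cat("correlations:\n"); print(round(x$corr, 3))
  invisible(x)
}
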
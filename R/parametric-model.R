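# Reduced (beta1-beta3 + tau) and full (adds beta4-beta6) softmax choice
# models of stage-1 and stage-2 behavior.
#
# Values are linear in effective card values (direction-inverted in SMALL
# conditions so that the same code serves both directions); the value of
# sampling is an intercept plus an uncertainty bonus beta3 * omega, where
# omega is the negative squared deviation of the logistic choice probability
# from 0.5. Choice probabilities use a softmax with tau acting as a
# multiplicative gain on values, p(o) proportional to exp(V(o) * tau)
# (exp(V / tau') is the equivalent reparameterization; fits are invariant up
# to a rescaling of the betas).

.MEAN_CARD <- 5.5

#' Effective card value
#'
#' In SMALL conditions every card value is inverted (10 becomes 1, 9 becomes
#' 2, ...) so that larger effective values always favor approaching; BIG
#' conditions use the raw value.
#'
#' @param value card value(s) 1--10.
#' @param direction `"BIG"` or `"SMALL"`.
#' @export
effective_card <- function(value, direction = c("BIG", "SMALL")) {
  direction <- match.arg(direction)
  value <- .check_cards(value)
  if (direction == "BIG") value else 11L - value
}

#' Choice uncertainty
#'
#' `omega = -(sigma(V_B - V_A) - 0.5)^2` with `sigma` the logistic function:
#' 0 when the two options are equally valued, approaching -0.25 under
#' certainty, and symmetric in the sign of the value difference. Scales the
#' value of sampling via `beta3`.
#'
#' @param v_a,v_b option values.
#' @export
omega_uncertainty <- function(v_a, v_b) -(plogis(v_b - v_a) - 0.5)^2

#' Parametric model parameters
#'
#' `beta1` scales card-value differences into option values; `beta2` is the
#' sampling-value intercept; `beta3` weights the uncertainty bonus
#' [omega_uncertainty()]; `tau` is the softmax gain. The full model adds
#' `beta4` (approach bonus for the unsampleable row; generates rejecting
#' unsampled options), `beta5` (devaluation of sampling row A on AA trials,
#' scaled by the first card; generates positive evidence approach) and
#' `beta6` (bonus for sampling the currently stronger row at stage 2;
#' generates sampling the favorite). The reduced model is `beta4 = beta5 =
#' beta6 = 0`.
#'
#' @param beta1,beta2,beta3,tau reduced-model parameters (`tau >= 0`).
#' @param beta4,beta5,beta6 full-model bias parameters.
#' @param stage 1 or 2 (which decision stage these parameters describe).
#' @param pair `"ADD"` or `"MULTIPLY"`.
#' @return an object of class `model_params`.
#' @export
model_params <- function(beta1, beta2, beta3, tau,
                         beta4 = 0, beta5 = 0, beta6 = 0,
                         stage = 1L, pair = c("MULTIPLY", "ADD")) {
  pair <- match.arg(pair)
  if (tau < 0) .is_err("tau must be >= 0", "infoseek_invalid_params")
  stopifnot(stage %in% 1:2)
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3, tau = tau,
                 beta4 = beta4, beta5 = beta5, beta6 = beta6,
                 stage = as.integer(stage), pair = pair),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  full <- any(c(x$beta4, x$beta5, x$beta6) != 0)
  cat(sprintf("<model_params> stage %d, %s, %s model\n", x$stage, x$pair,
              if (full) "full" else "reduced"))
  v <- unlist(x[c("beta1", "beta2", "beta3", "tau", "beta4", "beta5", "beta6")])
  print(round(v, 4))
  invisible(x)
}

.softmax <- function(V, tau) {
  z <- V * tau
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# stage-1 option probabilities; all arguments vectors (recycled).
# c_eff: effective first-card value; is_aa: logical. Columns: A, B, sample.
.stage1_probs <- function(c_eff, is_aa, b1, b2, b3, tau, b4 = 0, b5 = 0) {
  n <- max(length(c_eff), length(is_aa))
  c_eff <- rep_len(c_eff, n)
  aa <- rep_len(as.logical(is_aa), n)
  vA <- b1 * (c_eff - .MEAN_CARD)
  vB <- -vA
  vA <- vA + (!aa) * b4 * c_eff                 # approach bonus: unsampleable row
  vB <- vB + aa * b4 * .MEAN_CARD
  om <- omega_uncertainty(vA, vB)
  vS <- b2 + b3 * om - aa * b5 * c_eff
  .softmax(cbind(A = vA, B = vB, S = vS), tau)
}

# stage-2 AB option probabilities. Columns: A, B, sample A, sample B.
.stage2_probs <- function(ci_eff, cj_eff, b1, b2, b3, tau, b6 = 0) {
  d <- ci_eff - cj_eff
  vA <- b1 * d
  vB <- -vA
  om <- omega_uncertainty(vA, vB)
  vSA <- b2 + b3 * om + b6 * d
  vSB <- b2 + b3 * om - b6 * d
  .softmax(cbind(A = vA, B = vB, SA = vSA, SB = vSB), tau)
}

#' Option values and choice probabilities
#'
#' `option_values()` returns the modelled values of the options available in
#' one state (effective, i.e. direction-inverted, card values are supplied);
#' `choice_probabilities()` maps a set of values through the softmax with
#' gain `tau`.
#'
#' @param params a [model_params()].
#' @param first_card effective first/row-A card value.
#' @param trial_type `"AA"` or `"AB"` (stage 1).
#' @param second_card effective second-card value (stage 2: the row-B card).
#' @return named numeric vector of option values.
#' @export
option_values <- function(params, first_card, trial_type = c("AA", "AB"),
                          second_card = NULL) {
  trial_type <- match.arg(trial_type)
  if (params$stage == 1L) {
    is_aa <- trial_type == "AA"
    vA <- params$beta1 * (first_card - .MEAN_CARD)
    vB <- -vA
    if (is_aa) vB <- vB + params$beta4 * .MEAN_CARD else vA <- vA + params$beta4 * first_card
    om <- omega_uncertainty(vA, vB)
    vS <- params$beta2 + params$beta3 * om - if (is_aa) params$beta5 * first_card else 0
    out <- c(A = vA, B = vB, vS)
    names(out)[3] <- if (is_aa) "sample_A" else "sample_B"
    return(out)
  }
  if (is.null(second_card))
    .is_err("stage-2 values need the second card", "infoseek_illegal_option")
  d <- first_card - second_card
  vA <- params$beta1 * d; vB <- -vA
  om <- omega_uncertainty(vA, vB)
  c(A = vA, B = vB,
    sample_A = params$beta2 + params$beta3 * om + params$beta6 * d,
    sample_B = params$beta2 + params$beta3 * om - params$beta6 * d)
}

#' @rdname option_values
#' @param values named vector of option values.
#' @param tau softmax gain (`tau = 0` gives uniform probabilities).
#' @export
choice_probabilities <- function(values, tau) {
  if (!length(values)) .is_err("empty option set", "infoseek_illegal_option")
  drop(.softmax(matrix(values, nrow = 1, dimnames = list(NULL, names(values))), tau))
}

#' Model-predicted aggregate tables
#'
#' Evaluates the model's choice probabilities for every cell of the
#' [aggregate_tables()] schema covered by `params`: stage-1 parameters fill
#' `pGuess`/`pChooseA` for both directions of the pair and both trial types;
#' stage-2 parameters fill `pGuess2`/`pSampleA`. Cells outside the pair/stage
#' stay `NA` so bias statistics can be evaluated directly on predictions.
#'
#' @param params a [model_params()].
#' @param tables optional existing `aggregate_tables` to fill into (so
#'   stage-1 and stage-2 predictions can be combined).
#' @return an `aggregate_tables` object.
#' @export
predict_aggregate <- function(params, tables = NULL) {
  conds <- infoseek_conditions()
  if (is.null(tables)) {
    dim3 <- c(6, 2, 10); dimn3 <- list(conds, .TYPES, .CARD)
    dimh <- c(6, 10, 10); dimnh <- list(conds, .CARD, .CARD)
    na3 <- array(NA_real_, dim3, dimn3); nah <- array(NA_real_, dimh, dimnh)
    tables <- structure(list(pGuess = na3, nGuess = na3, pChooseA = na3,
                             nChooseA = na3, pGuess2 = nah, nGuess2 = nah,
                             pSampleA = nah, nSampleA = nah, conditions = conds),
                        class = "aggregate_tables")
  }
  for (dir in c("BIG", "SMALL")) {
    cond <- paste0(params$pair, "_", dir)
    if (params$stage == 1L) {
      for (typ in .TYPES) {
        ce <- effective_card(.CARD, dir)
        p <- .stage1_probs(ce, typ == "AA", params$beta1, params$beta2,
                           params$beta3, params$tau, params$beta4, params$beta5)
        tables$pGuess[cond, typ, ] <- p[, "A"] + p[, "B"]
        tables$pChooseA[cond, typ, ] <- p[, "A"] / (p[, "A"] + p[, "B"])
        tables$nGuess[cond, typ, ] <- 1
        tables$nChooseA[cond, typ, ] <- 1
      }
    } else {
      g <- expand.grid(i = .CARD, j = .CARD)
      p <- .stage2_probs(effective_card(g$i, dir), effective_card(g$j, dir),
                         params$beta1, params$beta2, params$beta3, params$tau,
                         params$beta6)
      tables$pGuess2[cond, , ] <- matrix(p[, "A"] + p[, "B"], 10, 10)
      tables$pSampleA[cond, , ] <- matrix(p[, "SA"] / (p[, "SA"] + p[, "SB"]), 10, 10)
      tables$nGuess2[cond, , ] <- 1
      tables$nSampleA[cond, , ] <- 1
    }
  }
  tables
}

# observed/predicted cell vectors for one stage+pair, aligned; NA cells dropped
.fit_cells <- function(tables, stage, pair) {
  conds <- paste0(pair, "_", c("BIG", "SMALL"))
  if (stage == 1L) {
    obs <- c(tables$pGuess[conds, , ], tables$pChooseA[conds, , ])
    n <- c(tables$nGuess[conds, , ], tables$nChooseA[conds, , ])
  } else {
    obs <- c(tables$pGuess2[conds, , ], tables$pSampleA[conds, , ])
    n <- c(tables$nGuess2[conds, , ], tables$nSampleA[conds, , ])
  }
  keep <- !is.na(obs)
  list(obs = obs[keep], n = n[keep], keep = keep)
}

# free parameters per stage: the bias terms entering a stage's predictions
# (beta4/beta5 at stage 1, beta6 at stage 2); the rest are fixed at 0
.n_free <- function(full, stage) if (!full) 4L else if (stage == 1L) 6L else 5L

.theta_to_params <- function(theta, full, stage, pair) {
  b4 <- b5 <- b6 <- 0
  if (full) {
    if (stage == 1L) { b4 <- theta[5]; b5 <- theta[6] } else b6 <- theta[5]
  }
  model_params(beta1 = theta[1], beta2 = theta[2], beta3 = theta[3],
               tau = max(theta[4], 0), beta4 = b4, beta5 = b5, beta6 = b6,
               stage = stage, pair = pair)
}

.pred_vector <- function(theta, full, stage, pair, keep) {
  params <- .theta_to_params(theta, full, stage, pair)
  pt <- predict_aggregate(params)
  conds <- paste0(pair, "_", c("BIG", "SMALL"))
  pred <- if (stage == 1L) c(pt$pGuess[conds, , ], pt$pChooseA[conds, , ])
          else c(pt$pGuess2[conds, , ], pt$pSampleA[conds, , ])
  pred[keep]
}

#' Fit the parametric model to aggregate behavior
#'
#' Minimizes the sum of squared errors between observed and predicted cell
#' probabilities (or, optionally, a count-weighted binomial negative
#' log-likelihood) by Nelder-Mead simplex search restarted from
#' `n_restarts` random initializations drawn uniformly from documented
#' parameter boxes (`beta1..beta3` in [-5, 5], `tau` in [0, 10],
#' `beta4..beta6` in [-2, 2]). The best restart is returned; results are
#' deterministic given `seed`.
#'
#' @param tables observed [aggregate_tables()].
#' @param stage 1 or 2.
#' @param pair `"ADD"` or `"MULTIPLY"`.
#' @param full fit the full 7-parameter model (default: reduced 4-parameter).
#' @param n_restarts random restarts.
#' @param seed RNG seed.
#' @param objective `"sse"` (default) or `"binomial"`.
#' @return an object of class `fit_result` with elements `params`,
#'   `objective`, `converged`, `n_restarts`, `restart_objectives`.
#' @export
fit_aggregate <- function(tables, stage = 1L, pair = c("MULTIPLY", "ADD"),
                          full = FALSE, n_restarts = 50, seed = NULL,
                          objective = c("sse", "binomial")) {
  pair <- match.arg(pair); objective <- match.arg(objective)
  stage <- as.integer(stage)
  if (!is.null(seed)) set.seed(seed)
  cells <- .fit_cells(tables, stage, pair)
  if (!length(cells$obs)) .is_err("no observed cells to fit", "infoseek_missing_cells")
  npar <- .n_free(full, stage)
  lo <- c(-5, -5, -5, 0, -2, -2)[seq_len(npar)]
  hi <- c(5, 5, 5, 10, 2, 2)[seq_len(npar)]
  fn <- function(theta) {
    if (theta[4] < 0) return(1e6 * (1 - theta[4]))
    # soft box constraint: the documented boxes also bound the solution,
    # which tames the softmax-gain ridge
    over <- pmax(theta - hi, 0) + pmax(lo - theta, 0)
    pred <- .pred_vector(theta, full, stage, pair, cells$keep)
    base <- if (objective == "sse") sum((cells$obs - pred)^2)
    else {
      pred <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
      -sum(cells$n * (cells$obs * log(pred) + (1 - cells$obs) * log(1 - pred)))
    }
    base + 1e3 * sum(over^2)
  }
  best <- NULL; objs <- numeric(n_restarts); conv <- logical(n_restarts)
  for (r in seq_len(n_restarts)) {
    start <- lo + runif(npar) * (hi - lo)
    o <- optim(start, fn, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-9))
    objs[r] <- o$value; conv[r] <- o$convergence == 0
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish: Nelder-Mead profits from a restart at the incumbent optimum
  for (k in 1:2) {
    o <- optim(best$par, fn, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-10))
    if (o$value < best$value) best <- o else break
  }
  structure(list(params = .theta_to_params(best$par, full, stage, pair),
                 theta = best$par,
                 objective = best$value, objective_type = objective,
                 converged = any(conv), n_restarts = n_restarts,
                 restart_objectives = objs,
                 box = list(lower = lo, upper = hi)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s objective %.6g over %d restarts (%sconverged)\n",
              x$objective_type, x$objective, x$n_restarts,
              if (x$converged) "" else "NOT "))
  print(x$params)
  invisible(x)
}

#' k-fold cross-validation of reduced versus full model
#'
#' Partitions gameplays into `k` folds; for every fold fits both models to
#' the aggregate of the remaining folds and scores the sum of squared errors
#' on the held-out fold's aggregate (cells observed in the held-out data).
#'
#' @param dataset a gameplay dataset.
#' @param stage 1 or 2.
#' @param pair `"ADD"` or `"MULTIPLY"`.
#' @param k number of folds.
#' @param seed RNG seed (controls fold assignment and fit restarts).
#' @param n_restarts restarts per fit (smaller than the headline 50 to keep
#'   k-fold runtimes reasonable).
#' @return a data.frame with one row per fold and model.
#' @export
crossvalidate <- function(dataset, stage = 1L, pair = c("MULTIPLY", "ADD"),
                          k = 10, seed = NULL, n_restarts = 10) {
  pair <- match.arg(pair)
  if (!is.null(seed)) set.seed(seed)
  ds <- data.table::as.data.table(dataset)
  ds[, gp := .GRP, by = .(uid, gameplay)]
  G <- max(ds$gp)
  if (k > G) .is_err("more folds than gameplays", "infoseek_invalid_dataset")
  fold_of <- sample(rep_len(seq_len(k), G))
  out <- list()
  for (f in seq_len(k)) {
    train <- as.data.frame(ds[fold_of[gp] != f])
    test <- as.data.frame(ds[fold_of[gp] == f])
    ttrain <- aggregate_tables(train)
    ttest <- aggregate_tables(test)
    cells <- .fit_cells(ttest, stage, pair)
    for (full in c(FALSE, TRUE)) {
      fit <- fit_aggregate(ttrain, stage, pair, full = full,
                           n_restarts = n_restarts, seed = sample.int(1e6, 1))
      pred <- .pred_vector(fit$theta, full, stage, pair, cells$keep)
      out[[length(out) + 1L]] <- data.frame(
        fold = f, model = if (full) "full" else "reduced",
        sse_holdout = sum((cells$obs - pred)^2),
        train_objective = fit$objective)
    }
  }
  do.call(rbind, out)
}
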
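# Synthetic agent populations playing the full card game, so that every
# analysis stage can be exercised against data with known ground truth.
#
# Boards are dealt uniformly on 1..10 with replacement and tied boards are
# re-dealt, keeping generated data consistent with the tie-excluded win
# probabilities of the task engine. The stage-1 offer is drawn uniformly
# over the three face-down cards (AA with probability 1/3).
#
# Parametric agents follow the softmax choice model. The published model
# defines behavior at stage 1 and at stage 2 of AB trials; the generator
# extends it to the remaining states with the same functional form by using
# an evidence term d = (sum of revealed row-A effective values, hidden cards
# imputed at 5.5) - (same for row B), which reduces exactly to the published
# (1stCardValue - 5.5) and (1stCardValue - 2ndCardValue) terms at the
# published stages. The three bias statistics only read the published
# stages, so this extension does not touch what the tests measure.

.POLICIES <- c("OPTIMAL", "PARAMETRIC_REDUCED", "PARAMETRIC_FULL", "ALWAYS_GUESS")
.AGE_GROUPS <- c("18-25", "26-35", "36-45", "46-59", "60+")
.EDU_LEVELS <- c("GCSE", "ALev", "Bachelors", "Masters", "Doctorate")

#' Agent specification
#'
#' @param policy `"OPTIMAL"` (greedy on the solved action values),
#'   `"PARAMETRIC_REDUCED"`, `"PARAMETRIC_FULL"` (softmax model) or
#'   `"ALWAYS_GUESS"` (guesses immediately, choosing the evidence-favored row).
#' @param params a [model_params()] for parametric policies.
#' @param uid subject identifier.
#' @param age_group,education demographic labels (adults only: the youngest
#'   age category is 18-25).
#' @return an object of class `agent_spec`.
#' @export
agent_spec <- function(policy = .POLICIES, params = NULL, uid = 1L,
                       age_group = "26-35", education = "Bachelors") {
  policy <- match.arg(policy)
  if (startsWith(policy, "PARAMETRIC") && is.null(params))
    .is_err("parametric policies need params", "infoseek_invalid_params")
  age_group <- match.arg(age_group, .AGE_GROUPS)
  education <- match.arg(education, .EDU_LEVELS)
  structure(list(policy = policy, params = params, uid = uid,
                 age_group = age_group, education = education),
            class = "agent_spec")
}

#' Population specification
#'
#' Describes a population of agents whose parameters are drawn from a
#' multivariate Gaussian over `(beta1, beta2, beta3, tau, beta4, beta5,
#' beta6)`. Defaults emulate the population conditions the analyses assume:
#' 22 trials per gameplay (two 11-trial blocks of two randomly assigned
#' distinct conditions), moderate heterogeneity, and bias parameters of the
#' order of magnitude that reproduces the observed population statistics.
#'
#' @param n_subjects number of subjects.
#' @param policy agent policy for every subject.
#' @param mean named parameter mean vector.
#' @param Sigma 7x7 parameter covariance (default: diagonal with sd equal to
#'   25% of each mean's magnitude, floored at 0.01; must be positive
#'   semi-definite).
#' @param n_gameplays gameplays per subject (2 enables retest analyses).
#' @param conditions `NULL` for a random ordered pair of distinct conditions
#'   per gameplay, or a length-2 character vector fixing the schedule.
#' @param trials_per_block trials per block (task default 11).
#' @param approach_link standard deviation of a shared latent factor added
#'   to `beta4`, `beta5` and `beta6` and exposed as attribute `"latent"`,
#'   used to couple gameplay biases to the gamble-task approach index
#'   (0 disables the linkage).
#' @param demographic_effects when `TRUE`, education and age mildly raise the
#'   sampling intercept `beta2` (more information gathered), emulating the
#'   demographic trends; labels are otherwise inert.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_subjects,
                            policy = "PARAMETRIC_FULL",
                            mean = c(beta1 = 0.7, beta2 = 2.0, beta3 = 1.0,
                                     tau = 1.0, beta4 = 0.045, beta5 = 0.095,
                                     beta6 = 0.057),
                            Sigma = NULL,
                            n_gameplays = 1L,
                            conditions = NULL,
                            trials_per_block = 11L,
                            approach_link = 0,
                            demographic_effects = FALSE) {
  policy <- match.arg(policy, .POLICIES)
  nm <- c("beta1", "beta2", "beta3", "tau", "beta4", "beta5", "beta6")
  stopifnot(all(nm %in% names(mean)))
  mean <- mean[nm]
  if (is.null(Sigma)) Sigma <- diag(pmax(0.25 * abs(mean), 0.01)^2)
  Sigma <- as.matrix(Sigma)
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10))
    .is_err("parameter covariance must be positive semi-definite",
            "infoseek_invalid_params")
  if (!is.null(conditions)) {
    .check_condition(conditions)
    if (length(conditions) != 2L || conditions[1] == conditions[2])
      .is_err("conditions must be two distinct codes", "infoseek_invalid_params")
  }
  structure(list(n_subjects = as.integer(n_subjects), policy = policy,
                 mean = mean, Sigma = Sigma, n_gameplays = as.integer(n_gameplays),
                 conditions = conditions, trials_per_block = as.integer(trials_per_block),
                 approach_link = approach_link,
                 demographic_effects = isTRUE(demographic_effects)),
            class = "population_spec")
}

# draw from N(mean, Sigma) via Cholesky (with PSD jitter fallback)
.rmvnorm <- function(n, mean, Sigma) {
  p <- length(mean)
  L <- tryCatch(chol(Sigma), error = function(e) chol(Sigma + diag(1e-10, p)))
  sweep(matrix(rnorm(n * p), n, p) %*% L, 2, mean, "+")
}

# categorical draw from a row-stochastic probability matrix
.rcat <- function(P) {
  K <- ncol(P)
  u <- runif(nrow(P))
  act <- rep(1L, nrow(P))
  cs <- P[, 1L]
  for (k in seq_len(K - 1L)) {
    act <- act + (u > cs)
    if (k < K - 1L) cs <- cs + P[, k + 1L]
  }
  act
}

.eff <- function(x, big) ifelse(big, x, 11L - x)

# Simulate one trial per row of `tr` (data.table with uid, gameplay, block,
# trial, condition, policy, b1..b6, tau). Returns the gameplay dataset rows.
.simulate_cohort <- function(tr) {
  N <- nrow(tr)
  cond <- tr$condition
  big <- cond_direction(cond) == "BIG"

  # deal boards, re-dealing ties
  a1 <- a2 <- bb1 <- bb2 <- integer(N)
  wsgn <- integer(N)
  for (cd in unique(cond)) {
    W <- .winner_array(cd)
    idx <- which(cond == cd)
    todo <- idx
    while (length(todo)) {
      n <- length(todo)
      a1[todo] <- sample.int(10L, n, TRUE); a2[todo] <- sample.int(10L, n, TRUE)
      bb1[todo] <- sample.int(10L, n, TRUE); bb2[todo] <- sample.int(10L, n, TRUE)
      w <- W[cbind(a1[todo], a2[todo], bb1[todo], bb2[todo])]
      wsgn[todo] <- w
      todo <- todo[w == 0L]
    }
  }
  is_aa <- runif(N) < 1 / 3

  guess_stage <- integer(N)
  chosen <- character(N)
  s2row <- rep(NA_character_, N); s2val <- rep(NA_integer_, N)
  s3row <- rep(NA_character_, N); s3val <- rep(NA_integer_, N)
  v1 <- ifelse(is_aa, a2, bb1)  # card revealed by the stage-1 sample

  e_a1 <- .eff(a1, big); e_a2 <- .eff(a2, big)
  e_b1 <- .eff(bb1, big); e_b2 <- .eff(bb2, big)

  parametric <- startsWith(tr$policy, "PARAMETRIC")
  optimal <- tr$policy == "OPTIMAL"
  always <- tr$policy == "ALWAYS_GUESS"

  # ---- ALWAYS_GUESS: guess at stage 1, approach the evidence-favored row
  if (any(always)) {
    guess_stage[always] <- 1L
    chosen[always] <- ifelse(e_a1[always] > 5.5, "A", "B")
  }

  # ---- stage 1
  stage2 <- logical(N)
  if (any(parametric)) {
    i <- which(parametric)
    p <- .stage1_probs(e_a1[i], is_aa[i], tr$b1[i], tr$b2[i], tr$b3[i],
                       tr$tau[i], tr$b4[i], tr$b5[i])
    act <- .rcat(p)
    g <- act <= 2L
    guess_stage[i[g]] <- 1L
    chosen[i[g]] <- c("A", "B")[act[g]]
    stage2[i[!g]] <- TRUE
  }
  if (any(optimal)) {
    for (cd in unique(cond[optimal])) {
      pol <- optimal_policy(.solved(cd))
      i <- which(optimal & cond == cd)
      pg <- pol$p_guess1[cbind(a1[i], ifelse(is_aa[i], 1L, 2L))]
      g <- runif(length(i)) < pg
      pa <- pol$p_chooseA1[a1[i]]
      guess_stage[i[g]] <- 1L
      chosen[i[g]] <- ifelse(runif(sum(g)) < pa[g], "A", "B")
      stage2[i[!g]] <- TRUE
    }
  }

  # ---- stage 2
  stage3 <- logical(N)
  if (any(stage2 & parametric)) {
    # AB trials: published 4-way decision
    i <- which(stage2 & parametric & !is_aa)
    if (length(i)) {
      p <- .stage2_probs(e_a1[i], e_b1[i], tr$b1[i], tr$b2[i], tr$b3[i],
                         tr$tau[i], tr$b6[i])
      act <- .rcat(p)
      g <- act <= 2L
      guess_stage[i[g]] <- 2L
      chosen[i[g]] <- c("A", "B")[act[g]]
      smpA <- act == 3L
      s2row[i[!g]] <- ifelse(smpA[!g], "A", "B")
      s2val[i[!g]] <- ifelse(smpA[!g], a2[i[!g]], bb2[i[!g]])
      stage3[i[!g]] <- TRUE
    }
    # AA trials: generator extension, 3-way with the sum-evidence term
    i <- which(stage2 & parametric & is_aa)
    if (length(i)) {
      d <- e_a1[i] + e_a2[i] - 11
      vA <- tr$b1[i] * d
      om <- omega_uncertainty(vA, -vA)
      vS <- tr$b2[i] + tr$b3[i] * om
      p <- .softmax(cbind(vA, -vA, vS), tr$tau[i])
      act <- .rcat(p)
      g <- act <= 2L
      guess_stage[i[g]] <- 2L
      chosen[i[g]] <- c("A", "B")[act[g]]
      s2row[i[!g]] <- "B"
      s2val[i[!g]] <- bb1[i[!g]]
      stage3[i[!g]] <- TRUE
    }
  }
  if (any(stage2 & optimal)) {
    for (cd in unique(cond[stage2 & optimal])) {
      pol <- optimal_policy(.solved(cd))
      i <- which(stage2 & optimal & cond == cd & is_aa)
      if (length(i)) {
        pg <- pol$p_guess2aa[cbind(a1[i], a2[i])]
        g <- runif(length(i)) < pg
        pa <- pol$p_chooseA2aa[cbind(a1[i], a2[i])]
        guess_stage[i[g]] <- 2L
        chosen[i[g]] <- ifelse(runif(sum(g)) < pa[g], "A", "B")
        s2row[i[!g]] <- "B"; s2val[i[!g]] <- bb1[i[!g]]
        stage3[i[!g]] <- TRUE
      }
      i <- which(stage2 & optimal & cond == cd & !is_aa)
      if (length(i)) {
        pg <- pol$p_guess2ab[cbind(a1[i], bb1[i])]
        g <- runif(length(i)) < pg
        pa <- pol$p_chooseA2ab[cbind(a1[i], bb1[i])]
        guess_stage[i[g]] <- 2L
        chosen[i[g]] <- ifelse(runif(sum(g)) < pa[g], "A", "B")
        ns <- i[!g]
        psA <- pol$p_sampleA2ab[cbind(a1[ns], bb1[ns])]
        tookA <- runif(length(ns)) < psA
        s2row[ns] <- ifelse(tookA, "A", "B")
        s2val[ns] <- ifelse(tookA, a2[ns], bb2[ns])
        stage3[ns] <- TRUE
      }
    }
  }

  # ---- stage 3
  terminal <- logical(N)
  if (any(stage3)) {
    # board composition after two samples
    pathAA <- stage3 & is_aa                     # A={a1,a2}, B={bb1}
    pathABA <- stage3 & !is_aa & s2row == "A"    # A={a1,a2}, B={bb1}
    pathABB <- stage3 & !is_aa & s2row == "B"    # A={a1},    B={bb1,bb2}
    i <- which(stage3 & parametric)
    if (length(i)) {
      twoA <- is_aa[i] | s2row[i] == "A"
      dA <- ifelse(twoA, e_a1[i] + e_a2[i], e_a1[i] + 5.5)
      dB <- ifelse(twoA, e_b1[i] + 5.5, e_b1[i] + e_b2[i])
      d <- dA - dB
      vA <- tr$b1[i] * d
      om <- omega_uncertainty(vA, -vA)
      vS <- tr$b2[i] + tr$b3[i] * om
      p <- .softmax(cbind(vA, -vA, vS), tr$tau[i])
      act <- .rcat(p)
      g <- act <= 2L
      guess_stage[i[g]] <- 3L
      chosen[i[g]] <- c("A", "B")[act[g]]
      terminal[i[!g]] <- TRUE
    }
    if (any(stage3 & optimal)) {
      for (cd in unique(cond[stage3 & optimal])) {
        pol <- optimal_policy(.solved(cd))
        i <- which(stage3 & optimal & cond == cd)
        twoA <- is_aa[i] | s2row[i] == "A"
        pg <- pa <- numeric(length(i))
        if (any(twoA)) {
          k <- cbind(a1[i[twoA]], a2[i[twoA]], bb1[i[twoA]])
          pg[twoA] <- pol$p_guess3b[k]; pa[twoA] <- pol$p_chooseA3b[k]
        }
        if (any(!twoA)) {
          k <- cbind(a1[i[!twoA]], bb1[i[!twoA]], bb2[i[!twoA]])
          pg[!twoA] <- pol$p_guess3a[k]; pa[!twoA] <- pol$p_chooseA3a[k]
        }
        g <- runif(length(i)) < pg
        guess_stage[i[g]] <- 3L
        chosen[i[g]] <- ifelse(runif(sum(g)) < pa[g], "A", "B")
        terminal[i[!g]] <- TRUE
      }
    }
    # the stage-3 sample reveals the last face-down card
    t3 <- which(terminal)
    twoA3 <- is_aa[t3] | s2row[t3] == "A"
    s3row[t3] <- ifelse(twoA3, "B", "A")
    s3val[t3] <- ifelse(twoA3, bb2[t3], a2[t3])
  }

  # ---- terminal choice after three samples (all cards visible)
  if (any(terminal)) {
    i <- which(terminal)
    guess_stage[i] <- 4L
    if (any(terminal & parametric)) {
      j <- which(terminal & parametric)
      d <- (e_a1[j] + e_a2[j]) - (e_b1[j] + e_b2[j])
      pA <- drop(.softmax(cbind(tr$b1[j] * d, -tr$b1[j] * d), tr$tau[j])[, 1L])
      chosen[j] <- ifelse(runif(length(j)) < pA, "A", "B")
    }
    if (any(terminal & optimal))  # winner is known: choose it
      chosen[terminal & optimal] <- ifelse(wsgn[terminal & optimal] > 0, "A", "B")
  }

  cost <- c(0L, 10L, 25L, 45L)[guess_stage]
  winning <- ifelse(wsgn > 0L, "A", "B")
  points <- ifelse(chosen == winning, 60L, -50L) - cost
  data.frame(uid = tr$uid, gameplay = tr$gameplay, block = tr$block,
             trial = tr$trial, condition = cond,
             trial_type = ifelse(is_aa, "AA", "AB"),
             first_card = a1,
             sample1_value = ifelse(guess_stage >= 2L, v1, NA_integer_),
             sample2_row = s2row, sample2_value = s2val,
             sample3_row = s3row, sample3_value = s3val,
             guess_stage = guess_stage, chosen_row = chosen,
             winning_row = winning, points = points, total_cost = cost,
             stringsAsFactors = FALSE)
}

#' Simulate gameplays for a single agent
#'
#' Deals boards (re-dealing ties), runs the agent's policy to termination on
#' every trial and records the revealed sequence, actions and outcome.
#'
#' @param agent an [agent_spec()].
#' @param n_gameplays gameplays (two 11-trial blocks each).
#' @param conditions `NULL` for random assignment or two condition codes.
#' @param trials_per_block trials per block.
#' @param seed RNG seed.
#' @return a gameplay dataset (`data.frame`).
#' @export
simulate_agent <- function(agent, n_gameplays = 1, conditions = NULL,
                           trials_per_block = 11, seed = NULL) {
  stopifnot(inherits(agent, "agent_spec"))
  if (!is.null(seed)) set.seed(seed)
  pr <- agent$params
  pvec <- if (is.null(pr)) rep(0, 7) else
    unlist(pr[c("beta1", "beta2", "beta3", "tau", "beta4", "beta5", "beta6")])
  tr <- data.table::CJ(gameplay = seq_len(n_gameplays), block = 1:2,
                       trial = seq_len(trials_per_block))
  tr[, uid := agent$uid]
  cond_of <- function(gp) {
    cc <- if (is.null(conditions)) sample(infoseek_conditions(), 2L) else conditions
    cc
  }
  sched <- lapply(seq_len(n_gameplays), cond_of)
  tr[, condition := vapply(seq_len(.N), function(r) sched[[gameplay[r]]][block[r]],
                           character(1))]
  tr[, policy := agent$policy]
  tr[, `:=`(b1 = pvec[1], b2 = pvec[2], b3 = pvec[3], tau = pvec[4],
            b4 = pvec[5], b5 = pvec[6], b6 = pvec[7])]
  ds <- .simulate_cohort(tr)
  attr(ds, "demographics") <- data.frame(uid = agent$uid,
                                         age_group = agent$age_group,
                                         education = agent$education)
  class(ds) <- c("gameplay_dataset", "data.frame")
  ds
}

#' Generate a synthetic agent population
#'
#' Draws per-subject parameters from the population distribution of the
#' [population_spec()], assigns conditions and demographics, simulates every
#' trial and returns a trial-level gameplay dataset. Attributes:
#' `"demographics"` (uid, age group, education), `"true_params"` (the drawn
#' per-subject parameters) and `"latent"` (the shared approach factor when
#' `approach_link > 0`).
#'
#' @param spec a [population_spec()].
#' @param seed RNG seed.
#' @return a gameplay dataset (`data.frame` with class `gameplay_dataset`).
#' @export
generate_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  th <- .rmvnorm(n, spec$mean, spec$Sigma)
  colnames(th) <- names(spec$mean)
  latent <- rnorm(n)
  if (spec$approach_link > 0)
    th[, c("beta4", "beta5", "beta6")] <-
      th[, c("beta4", "beta5", "beta6")] + spec$approach_link * latent
  demo <- data.frame(
    uid = seq_len(n),
    age_group = sample(.AGE_GROUPS, n, TRUE, prob = c(0.35, 0.3, 0.18, 0.12, 0.05)),
    education = sample(.EDU_LEVELS, n, TRUE, prob = c(0.25, 0.3, 0.3, 0.1, 0.05)))
  if (spec$demographic_effects) {
    edu <- match(demo$education, .EDU_LEVELS)
    age <- match(demo$age_group, .AGE_GROUPS)
    th[, "beta2"] <- th[, "beta2"] + 0.06 * (edu - 3) + 0.05 * (age - 2)
  }
  th[, "tau"] <- pmax(th[, "tau"], 0.05)
  if (spec$policy == "PARAMETRIC_REDUCED") th[, c("beta4", "beta5", "beta6")] <- 0
  tr <- data.table::CJ(uid = seq_len(n), gameplay = seq_len(spec$n_gameplays),
                       block = 1:2, trial = seq_len(spec$trials_per_block))
  # condition schedule per (uid, gameplay)
  gps <- data.table::CJ(uid = seq_len(n), gameplay = seq_len(spec$n_gameplays))
  if (is.null(spec$conditions)) {
    cs <- t(vapply(seq_len(nrow(gps)), function(r) sample(infoseek_conditions(), 2L),
                   character(2)))
  } else cs <- matrix(spec$conditions, nrow(gps), 2, byrow = TRUE)
  gps[, `:=`(c1 = cs[, 1], c2 = cs[, 2])]
  tr <- merge(tr, gps, by = c("uid", "gameplay"), sort = FALSE)
  tr[, condition := ifelse(block == 1L, c1, c2)]
  tr[, c("c1", "c2") := NULL]
  tr[, policy := spec$policy]
  for (k in seq_len(7))
    tr[, (c("b1", "b2", "b3", "tau", "b4", "b5", "b6")[k]) := th[uid, k]]
  data.table::setorder(tr, uid, gameplay, block, trial)
  ds <- .simulate_cohort(tr)
  attr(ds, "demographics") <- demo
  attr(ds, "true_params") <- cbind(data.frame(uid = seq_len(n)), as.data.frame(th))
  attr(ds, "latent") <- latent
  class(ds) <- c("gameplay_dataset", "data.frame")
  ds
}

#' Simulate the companion gamble task for a population
#'
#' Each subject makes `trials_per_play` choices split evenly between gain,
#' mixed and loss trials with randomized amounts (spinner gambles, outcomes
#' 0.5/0.5); choices are drawn from [p_gamble()] under subject parameters
#' sampled around the supplied means. An optional `index_shift` per subject
#' (e.g. the `"latent"` attribute of [generate_population()]) is added to
#' `beta_gain` and subtracted from `beta_loss`, coupling the approach-avoid
#' index to the gameplay biases.
#'
#' @param n_subjects number of subjects (uids `1:n_subjects`).
#' @param mu_mean,beta_gain_mean,beta_loss_mean population means.
#' @param beta_sd population sd of the two beta parameters.
#' @param index_shift optional per-subject shift (length `n_subjects`),
#'   scaled by `index_scale`.
#' @param index_scale scale applied to `index_shift`.
#' @param trials_per_play choices per play (task default 30).
#' @param alpha,lambda utility parameters shared by all subjects.
#' @param seed RNG seed.
#' @return a data.frame of gamble trials with attribute `"true_params"`.
#' @export
simulate_gamble_population <- function(n_subjects, mu_mean = 0.15,
                                       beta_gain_mean = 0.1, beta_loss_mean = -0.05,
                                       beta_sd = 0.15, index_shift = NULL,
                                       index_scale = 0.15, trials_per_play = 30,
                                       alpha = 0.88, lambda = 2.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bg <- rnorm(n_subjects, beta_gain_mean, beta_sd)
  bl <- rnorm(n_subjects, beta_loss_mean, beta_sd)
  if (!is.null(index_shift)) {
    stopifnot(length(index_shift) == n_subjects)
    bg <- bg + index_scale * index_shift
    bl <- bl - index_scale * index_shift
  }
  bg <- pmin(pmax(bg, -0.9), 0.9); bl <- pmin(pmax(bl, -0.9), 0.9)
  mu <- pmax(rnorm(n_subjects, mu_mean, mu_mean / 3), 0.01)
  k <- trials_per_play %/% 3
  mk_trials <- function(u) {
    tt <- sample(rep(c("GAIN", "MIXED", "LOSS"), length.out = trials_per_play))
    certain <- integer(trials_per_play); o1 <- integer(trials_per_play)
    gain <- tt == "GAIN"; lossy <- tt == "LOSS"; mixed <- tt == "MIXED"
    certain[gain] <- sample(10:80, sum(gain), TRUE)
    o1[gain] <- round(certain[gain] * runif(sum(gain), 1.2, 4))
    certain[lossy] <- -sample(10:80, sum(lossy), TRUE)
    o1[lossy] <- round(certain[lossy] * runif(sum(lossy), 1.2, 4))
    o1[mixed] <- sample(20:80, sum(mixed), TRUE)
    o2 <- integer(trials_per_play)
    o2[mixed] <- -sample(20:80, sum(mixed), TRUE)
    data.frame(uid = u, trial = seq_len(trials_per_play), trial_type = tt,
               certain = certain, outcome1 = o1, outcome2 = o2,
               stringsAsFactors = FALSE)
  }
  ds <- do.call(rbind, lapply(seq_len(n_subjects), mk_trials))
  pars <- lapply(seq_len(n_subjects), function(s)
    gamble_params(mu[s], bg[s], bl[s], alpha, lambda))
  p <- numeric(nrow(ds))
  for (s in seq_len(n_subjects)) {
    rows <- ds$uid == s
    p[rows] <- p_gamble(ds[rows, ], pars[[s]])
  }
  ds$chose_gamble <- runif(nrow(ds)) < p
  attr(ds, "true_params") <- data.frame(uid = seq_len(n_subjects), mu = mu,
                                        beta_gain = bg, beta_loss = bl)
  ds
}
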
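# Population aggregate tables and the three approach-bias summary statistics.

.CARD <- 1:10
.TYPES <- c("AA", "AB")

# flattened cell layout shared by aggregation and gameplay-level bootstrap:
#   guess1   [cond x type x card]  120 cells, offset 0
#   chooseA1 [cond x type x card]  120 cells, offset 120
#   guess2   [cond x i x j]        600 cells, offset 240   (AB trials)
#   sampleA  [cond x i x j]        600 cells, offset 840   (AB stage-2 samples)
.N_CELLS <- 1440L

# per-gameplay sparse numerator/denominator count matrices
.gameplay_counts <- function(dataset) {
  ds <- data.table::as.data.table(dataset)
  conds <- infoseek_conditions()
  ds[, ci := match(condition, conds)]
  ds[, ti := match(trial_type, .TYPES)]
  ds[, gp := .GRP, by = .(uid, gameplay)]
  G <- max(ds$gp)
  trip <- list()
  # stage-1 guess cells: every trial contributes
  t1 <- ds[!is.na(ci) & !is.na(ti),
           .(num = sum(guess_stage == 1L), den = .N),
           by = .(gp, cell = ci + 6L * (ti - 1L) + 12L * (first_card - 1L))]
  trip[[1]] <- t1
  # stage-1 choice cells: stage-1 guessers only
  t2 <- ds[guess_stage == 1L & !is.na(ci) & !is.na(ti),
           .(num = sum(chosen_row == "A"), den = .N),
           by = .(gp, cell = 120L + ci + 6L * (ti - 1L) + 12L * (first_card - 1L))]
  trip[[2]] <- t2
  # stage-2 cells on AB trials: i = row-A card, j = row-B card
  ab2 <- ds[trial_type == "AB" & guess_stage >= 2L & !is.na(sample1_value)]
  if (nrow(ab2)) {
    t3 <- ab2[, .(num = sum(guess_stage == 2L), den = .N),
              by = .(gp, cell = 240L + ci + 6L * (first_card - 1L) + 60L * (sample1_value - 1L))]
    trip[[3]] <- t3
    ab3 <- ab2[guess_stage >= 3L & !is.na(sample2_row)]
    if (nrow(ab3)) {
      t4 <- ab3[, .(num = sum(sample2_row == "A"), den = .N),
                by = .(gp, cell = 840L + ci + 6L * (first_card - 1L) + 60L * (sample1_value - 1L))]
      trip[[4]] <- t4
    }
  }
  tr <- data.table::rbindlist(trip)
  list(G = G,
       num = Matrix::sparseMatrix(i = tr$gp, j = tr$cell, x = as.numeric(tr$num),
                                  dims = c(G, .N_CELLS)),
       den = Matrix::sparseMatrix(i = tr$gp, j = tr$cell, x = as.numeric(tr$den),
                                  dims = c(G, .N_CELLS)))
}

.tables_from_counts <- function(num, den) {
  conds <- infoseek_conditions()
  p <- ifelse(den > 0, num / den, NA_real_)
  dim3 <- c(6, 2, 10); dimn3 <- list(conds, .TYPES, .CARD)
  dimh <- c(6, 10, 10); dimnh <- list(conds, .CARD, .CARD)
  structure(list(
    pGuess    = array(p[1:120], dim3, dimn3),
    nGuess    = array(den[1:120], dim3, dimn3),
    pChooseA  = array(p[121:240], dim3, dimn3),
    nChooseA  = array(den[121:240], dim3, dimn3),
    pGuess2   = array(p[241:840], dimh, dimnh),
    nGuess2   = array(den[241:840], dimh, dimnh),
    pSampleA  = array(p[841:1440], dimh, dimnh),
    nSampleA  = array(den[841:1440], dimh, dimnh),
    conditions = conds), class = "aggregate_tables")
}

#' Aggregate gameplay records into population cell tables
#'
#' Pools trials into the cell frequencies that the bias statistics and the
#' parametric model are defined on: per condition, trial type and first-card
#' value, the probability of guessing at Task Stage 1 (`pGuess`) and of
#' choosing row A among stage-1 guessers (`pChooseA`); and per condition and
#' card pair `(i, j)` (row A showing `i`, row B showing `j`) on AB trials,
#' the probability of guessing at Task Stage 2 (`pGuess2`) and the relative
#' probability of sampling row A over row B among stage-2 samplers
#' (`pSampleA`). Cells with no observations are `NA` (missing, not zero);
#' matching `n*` count arrays are returned alongside.
#'
#' @param dataset a gameplay dataset (see [read_dataset()] /
#'   [generate_population()]).
#' @param conditions conditions to retain (default all six).
#' @param average `"pooled"` (default; frequencies pooled over all trials,
#'   the population-level reporting convention) or `"subjects"` (per-subject
#'   cell probabilities averaged across subjects; `n*` then counts
#'   contributing subjects).
#' @return an object of class `aggregate_tables`.
#' @export
aggregate_tables <- function(dataset, conditions = infoseek_conditions(),
                             average = c("pooled", "subjects")) {
  average <- match.arg(average)
  validate_dataset(dataset, strict = FALSE)
  dataset <- dataset[dataset$condition %in% conditions, ]
  if (!nrow(dataset)) .is_err("no rows left after condition filter", "infoseek_invalid_dataset")
  if (average == "pooled") {
    cc <- .gameplay_counts(dataset)
    return(.tables_from_counts(Matrix::colSums(cc$num), Matrix::colSums(cc$den)))
  }
  ds <- dataset
  ds$gameplay <- 1L                       # collapse to one block per subject
  cc <- .gameplay_counts(ds)
  tr <- Matrix::summary(cc$den)           # (subject, cell) pairs with data
  ratio <- Matrix::sparseMatrix(i = tr$i, j = tr$j,
                                x = cc$num[cbind(tr$i, tr$j)] / tr$x,
                                dims = dim(cc$den))
  n_sub <- Matrix::colSums(cc$den > 0)
  .tables_from_counts(Matrix::colSums(ratio), n_sub)  # mean per-subject p
}

#' @export
print.aggregate_tables <- function(x, ...) {
  cat(sprintf("<aggregate_tables> %d stage-1 trials, %d stage-2 AB decisions\n",
              as.integer(sum(x$nGuess)), as.integer(sum(x$nGuess2, na.rm = TRUE))))
  invisible(x)
}

#' Cell tables implied by the greedy optimal policy
#'
#' Builds an [aggregate_tables()] object from the deterministic choice
#' probabilities of the solved dynamic-programming model, so the bias
#' statistics can be evaluated on the normative policy itself (they are all
#' exactly 0 there).
#'
#' @param conditions conditions to include.
#' @param extra_sample_cost passed to [solve_condition()].
#' @return an `aggregate_tables` object (cell counts set to 1).
#' @export
aggregate_from_policy <- function(conditions = infoseek_conditions(),
                                  extra_sample_cost = 0) {
  conds <- infoseek_conditions()
  dim3 <- c(6, 2, 10); dimn3 <- list(conds, .TYPES, .CARD)
  dimh <- c(6, 10, 10); dimnh <- list(conds, .CARD, .CARD)
  pG <- array(NA_real_, dim3, dimn3); pC <- array(NA_real_, dim3, dimn3)
  pG2 <- array(NA_real_, dimh, dimnh); pS <- array(NA_real_, dimh, dimnh)
  for (cond in conditions) {
    pol <- optimal_policy(.solved(cond, extra_sample_cost))
    pG[cond, "AA", ] <- pol$p_guess1[, "AA"]
    pG[cond, "AB", ] <- pol$p_guess1[, "AB"]
    pC[cond, "AA", ] <- pol$p_chooseA1
    pC[cond, "AB", ] <- pol$p_chooseA1
    pG2[cond, , ] <- pol$p_guess2ab
    pS[cond, , ] <- pol$p_sampleA2ab
  }
  one <- function(p) ifelse(is.na(p), 0, 1)
  structure(list(pGuess = pG, nGuess = one(pG), pChooseA = pC, nChooseA = one(pC),
                 pGuess2 = pG2, nGuess2 = one(pG2), pSampleA = pS, nSampleA = one(pS),
                 conditions = conds), class = "aggregate_tables")
}

.bias_result <- function(statistic, value, cells_used, cells_missing,
                         n = NA_integer_, level = NA_real_,
                         lower = NA_real_, upper = NA_real_, replicates = NULL) {
  structure(list(statistic = statistic, value = value, cells_used = cells_used,
                 cells_missing = cells_missing, n_gameplays = n, level = level,
                 lower = lower, upper = upper, replicates = replicates),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("<bias_result> %s = %.4f", x$statistic, x$value))
  if (!is.na(x$level))
    cat(sprintf("  [%g%% CI %.4f, %.4f; %d gameplays]",
                100 * x$level, x$lower, x$upper, x$n_gameplays))
  if (x$cells_missing > 0) cat(sprintf("  (%d empty cells omitted)", x$cells_missing))
  cat("\n")
  invisible(x)
}

.sum_cells <- function(x, na_action) {
  miss <- sum(is.na(x))
  if (miss > 0) {
    if (na_action == "error")
      .is_err("statistic undefined: empty cells present", "infoseek_missing_cells")
    if (na_action == "warn-omit")
      warning(sprintf("%d empty cell difference(s) omitted from statistic", miss),
              call. = FALSE)
    if (na_action == "impute" && miss < length(x))
      x[is.na(x)] <- mean(x, na.rm = TRUE)  # population-marginal stand-in
  }
  list(value = sum(x, na.rm = TRUE), used = sum(!is.na(x)), missing = miss)
}

#' Positive evidence approach statistic
#'
#' Signed sum of BIG-minus-SMALL differences in the stage-1 guess
#' probability: over first-card values 6--10 the BIG condition minus the
#' SMALL condition, plus over values 1--5 the SMALL minus the BIG. Positive
#' values mean subjects stop sampling sooner when the evidence favors
#' approaching the already-seen row. 0 for any policy identical across the
#' two directions (in particular the optimal policy).
#'
#' @param tables an [aggregate_tables()].
#' @param pair `"ADD"` or `"MULTIPLY"` (the SINGLE pair is not information-matched).
#' @param trial_type `"AA"` or `"AB"`.
#' @param na_action handling of empty cells: omit the cell with a warning
#'   (default), omit silently, or error.
#' @return a `bias_result`.
#' @export
positive_evidence_approach <- function(tables, pair = c("MULTIPLY", "ADD"),
                                       trial_type = c("AA", "AB"),
                                       na_action = c("warn-omit", "omit", "impute", "error")) {
  pair <- match.arg(pair); trial_type <- match.arg(trial_type)
  na_action <- match.arg(na_action)
  big <- tables$pGuess[paste0(pair, "_BIG"), trial_type, ]
  small <- tables$pGuess[paste0(pair, "_SMALL"), trial_type, ]
  d <- c((small - big)[1:5], (big - small)[6:10])
  s <- .sum_cells(d, na_action)
  .bias_result(paste0("positive_evidence_approach[", pair, ",", trial_type, "]"),
               s$value, s$used, s$missing)
}

#' Rejecting unsampled options statistic
#'
#' Sum over first-card values of the AB-minus-AA difference in the
#' probability of choosing row A among stage-1 guessers, within one
#' condition. The decision itself is identical on AA and AB trials (only the
#' declined sampling location differs), so any consistent chooser scores 0.
#'
#' @param tables an [aggregate_tables()].
#' @param condition condition code.
#' @inheritParams positive_evidence_approach
#' @return a `bias_result`.
#' @export
rejecting_unsampled <- function(tables, condition,
                                na_action = c("warn-omit", "omit", "impute", "error")) {
  .check_condition(condition)
  na_action <- match.arg(na_action)
  d <- tables$pChooseA[condition, "AB", ] - tables$pChooseA[condition, "AA", ]
  s <- .sum_cells(d, na_action)
  .bias_result(paste0("rejecting_unsampled[", condition, "]"), s$value, s$used, s$missing)
}

#' Sampling the favorite statistic
#'
#' From stage-2 AB sampling decisions: the BIG-minus-SMALL difference in the
#' relative probability of sampling row A, summed over card pairs where row A
#' holds the stronger card minus pairs where row B does. The `"strong"` band
#' uses pairs with `|i - j| >= 4`, the `"weak"` band `1 <= |i - j| <= 3`.
#' The optimal policy values the two sampling locations identically in BIG
#' and SMALL, so it scores 0 on both bands.
#'
#' @inheritParams positive_evidence_approach
#' @param band `"strong"` or `"weak"` evidence band.
#' @return a `bias_result`.
#' @export
sampling_favorite <- function(tables, pair = c("MULTIPLY", "ADD"),
                              band = c("strong", "weak"),
                              na_action = c("warn-omit", "omit", "impute", "error")) {
  pair <- match.arg(pair); band <- match.arg(band)
  na_action <- match.arg(na_action)
  D <- tables$pSampleA[paste0(pair, "_BIG"), , ] -
       tables$pSampleA[paste0(pair, "_SMALL"), , ]
  diffs <- outer(.CARD, .CARD, "-")  # i - j
  keep <- if (band == "strong") abs(diffs) >= 4 else abs(diffs) >= 1 & abs(diffs) <= 3
  d <- c(D[keep & diffs > 0], -D[keep & diffs < 0])
  s <- .sum_cells(d, na_action)
  .bias_result(paste0("sampling_favorite[", pair, ",", band, "]"),
               s$value, s$used, s$missing)
}

#' Gameplay-level bootstrap confidence interval for a statistic
#'
#' Resamples `sample_size` gameplays with replacement from the dataset,
#' recomputes the aggregate tables and the statistic on each replicate, and
#' returns the percentile interval. The resampling unit is the gameplay (a
#' two-block play of 22 trials). Internally each gameplay's cell counts are
#' precomputed once, so replicates are weighted sums.
#'
#' @param dataset a gameplay dataset.
#' @param statistic_fn function taking an `aggregate_tables` object and
#'   returning a scalar (or a `bias_result`, whose `$value` is used).
#' @param n_boot number of bootstrap replicates.
#' @param sample_size gameplays drawn per replicate (with replacement;
#'   may exceed the number available).
#' @param level confidence level.
#' @param seed optional RNG seed for reproducibility.
#' @return a `bias_result` carrying the full-sample point estimate, the
#'   percentile CI and the replicate values.
#' @export
bootstrap_ci <- function(dataset, statistic_fn, n_boot = 1000, sample_size = 10000,
                         level = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cc <- .gameplay_counts(dataset)
  eval_stat <- function(tables) {
    v <- suppressWarnings(statistic_fn(tables))
    if (inherits(v, "bias_result")) v$value else as.numeric(v)
  }
  full <- .tables_from_counts(Matrix::colSums(cc$num), Matrix::colSums(cc$den))
  point <- eval_stat(full)
  reps <- vapply(seq_len(n_boot), function(b) {
    w <- tabulate(sample.int(cc$G, sample_size, replace = TRUE), nbins = cc$G)
    eval_stat(.tables_from_counts(as.vector(Matrix::crossprod(cc$num, w)),
                                  as.vector(Matrix::crossprod(cc$den, w))))
  }, numeric(1))
  qs <- quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  .bias_result("bootstrap", point, NA_integer_, 0L, n = cc$G, level = level,
               lower = unname(qs[1]), upper = unname(qs[2]), replicates = reps)
}

#' Per-subject sampling depth relative to the optimal policy
#'
#' For every trial, the number of cards the subject sampled minus the number
#' the greedy optimal policy would sample when replayed along the same
#' revealed card sequence (expectations over cards the subject never revealed
#' use the tie-conditioned transition probabilities). Returns per
#' subject-gameplay means and, for subjects with at least two gameplays, the
#' Pearson retest correlation between gameplay 1 and gameplay 2.
#'
#' @param dataset a gameplay dataset.
#' @param extra_sample_cost subjective per-sample cost added to the optimal
#'   model (default 0; 5 recentres the population histogram near zero).
#' @param method `"replay"` (per-trial replay of the revealed sequence,
#'   default) or `"expected"` (per-state expectation, ignoring the observed
#'   continuation).
#' @return a list with `per_gameplay` (uid, gameplay, mean relative depth,
#'   n trials), `per_subject` (gameplay-1 means) and `retest_r`.
#' @export
sampling_depth <- function(dataset, extra_sample_cost = 0,
                           method = c("replay", "expected")) {
  method <- match.arg(method)
  validate_dataset(dataset, strict = FALSE)
  ds <- data.table::as.data.table(dataset)
  ds[, d_opt := NA_real_]
  for (cond in unique(ds$condition)) {
    qt <- .solved(cond, extra_sample_cost)
    es <- .expected_samples_arrays(qt)
    sel <- which(ds$condition == cond)
    sub <- ds[sel]
    i <- sub$first_card
    typ <- sub$trial_type
    if (method == "expected") {
      ds[sel, d_opt := es$e1[cbind(i, match(typ, .TYPES))]]
      next
    }
    v1 <- sub$sample1_value
    v2 <- sub$sample2_value
    r2 <- sub$sample2_row
    pol <- es$policy
    d <- numeric(nrow(sub))
    samp1 <- pol$p_guess1[cbind(i, match(typ, .TYPES))] < 1  # policy samples at stage 1
    # policy guesses immediately
    d[!samp1] <- 0
    # policy samples but subject's stage-2 card unseen: expected continuation
    no_v1 <- samp1 & is.na(v1)
    d[no_v1] <- 1 + ifelse(typ[no_v1] == "AA", es$cont1aa[i[no_v1]], es$cont1ab[i[no_v1]])
    w <- samp1 & !is.na(v1)
    # AA path: stage-2 state (i, v1); policy's stage-2 sample is a row-B card
    aa <- w & typ == "AA"
    if (any(aa)) {
      g2 <- pol$p_guess2aa[cbind(i[aa], v1[aa])] == 1
      cont <- ifelse(!is.na(v2[aa]),
                     es$e3b[cbind(i[aa], v1[aa], v2[aa])],
                     es$cont2aa[cbind(i[aa], v1[aa])])
      d[aa] <- ifelse(g2, 1, 2 + cont)
    }
    # AB path: stage-2 state (i = row-A card, v1 = row-B card)
    ab <- w & typ == "AB"
    if (any(ab)) {
      ii <- i[ab]; jj <- v1[ab]
      g2 <- pol$p_guess2ab[cbind(ii, jj)] == 1
      pA <- pol$p_sampleA2ab[cbind(ii, jj)]
      contA <- ifelse(!is.na(v2[ab]) & r2[ab] == "A",
                      es$e3b[cbind(ii, v2[ab], jj)], es$cont2abA[cbind(ii, jj)])
      contB <- ifelse(!is.na(v2[ab]) & r2[ab] == "B",
                      es$e3a[cbind(ii, jj, v2[ab])], es$cont2abB[cbind(ii, jj)])
      d[ab] <- ifelse(g2, 1, 2 + pA * contA + (1 - pA) * contB)
    }
    ds[sel, d_opt := d]
  }
  ds[, rel := (guess_stage - 1L) - d_opt]
  per_gp <- ds[, .(mean_relative = mean(rel), n_trials = .N), by = .(uid, gameplay)]
  data.table::setorder(per_gp, uid, gameplay)
  g1 <- per_gp[gameplay == 1]
  g2 <- per_gp[gameplay == 2]
  m <- merge(g1, g2, by = "uid", suffixes = c("_1", "_2"))
  retest <- if (nrow(m) >= 3) cor(m$mean_relative_1, m$mean_relative_2) else NA_real_
  list(per_gameplay = as.data.frame(per_gp),
       per_subject = as.data.frame(g1[, .(uid, mean_relative)]),
       retest_r = retest, n_retest = nrow(m))
}
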
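# Backward-induction solution of one condition.
#
# Everything is conditioned on the event that the final 4-card board is
# non-tied (tied deals are re-dealt). Win probabilities are strict-win counts
# over non-tied completions, and sampling transitions are weighted by the
# number of non-tied completions consistent with each revealed value, so the
# recursion is exactly an expectimax over completions. Guess values for the
# two rows are always computed from separately tallied integer win counts
# (never as the complement of the other row) so that mirror states in the
# BIG and SMALL directions yield bit-identical values.

#' Solve a condition by backward induction
#'
#' Computes the action value of every guess and every purchasable sample in
#' every reachable state of a condition. Guess values are
#' `60 p(win) - 50 p(lose) - costs paid so far`; sample values are the
#' transition-probability-weighted best value of the successor states, with
#' the 10/15/20-point cost schedule entering through the sunk-cost term of
#' later guesses. `extra_sample_cost` adds a subjective per-sample cost to
#' the schedule (used to model an intrinsic reluctance to sample).
#'
#' @param condition condition code (see [infoseek_conditions()]).
#' @param extra_sample_cost additional points charged per sampling action
#'   (default 0; the subjective-cost variant uses 5).
#' @return an object of class `qtable` holding per-stage arrays of guess
#'   values, sample values, win probabilities and completion counts.
#' @examples
#' qt <- solve_condition("MULTIPLY_BIG")
#' s <- trial_state("MULTIPLY_BIG", revealed_A = 2, trial_type = "AA")
#' q_guess(qt, s, "B")                 # ~34.0
#' q_sample(qt, s, "A2")               # ~28.8
#' relative_value_of_guessing(qt, s)   # ~5.2
#' @export
solve_condition <- function(condition, extra_sample_cost = 0) {
  .check_condition(condition)
  stopifnot(is.numeric(extra_sample_cost), length(extra_sample_cost) == 1L,
            extra_sample_cost >= 0)
  e <- extra_sample_cost
  W <- .winner_array(condition)
  WA <- W == 1L; WB <- W == -1L; NT <- W != 0L
  cost <- c(0, 10, 25, 45) + e * (0:3)

  qg <- function(winA, winB, nt, cost)
    list(A = 110 * winA / nt - 50 - cost, B = 110 * winB / nt - 50 - cost)
  # states with no non-tied completion (possible in SINGLE conditions) are
  # unreachable under the re-deal convention; they carry NaN values but must
  # contribute 0 to transition-weighted sums, not NaN
  z0 <- function(q, w) ifelse(w > 0, q, 0)

  # stage 3, hidden card in row B slot 2: known (a1, a2, b1)
  winA3b <- colSums(aperm(WA, c(4, 1, 2, 3)))  # sum over b2
  winB3b <- colSums(aperm(WB, c(4, 1, 2, 3)))
  nt3b   <- colSums(aperm(NT, c(4, 1, 2, 3)))
  # stage 3, hidden card in row A slot 2: known (a1, b1, b2)
  winA3a <- colSums(aperm(WA, c(2, 1, 3, 4)))
  winB3a <- colSums(aperm(WB, c(2, 1, 3, 4)))
  nt3a   <- colSums(aperm(NT, c(2, 1, 3, 4)))

  g3b <- qg(winA3b, winB3b, nt3b, cost[3])
  g3a <- qg(winA3a, winB3a, nt3a, cost[3])
  qs3 <- 15 - 3 * e  # revealing the last card always identifies the winner
  qstar3b <- pmax(g3b$A, g3b$B, qs3)
  qstar3a <- pmax(g3a$A, g3a$B, qs3)

  # stage 2, AA path: A = {a1, a2}, both B cards hidden
  winA2aa <- colSums(aperm(WA, c(3, 4, 1, 2)), dims = 2)
  winB2aa <- colSums(aperm(WB, c(3, 4, 1, 2)), dims = 2)
  nt2aa   <- colSums(aperm(NT, c(3, 4, 1, 2)), dims = 2)
  g2aa <- qg(winA2aa, winB2aa, nt2aa, cost[2])
  # sampling either B slot reveals one B card -> stage-3 b-hidden state
  qs2aa <- matrix(0, 10, 10)
  for (y in 1:10) qs2aa <- qs2aa + nt3b[, , y] * z0(qstar3b[, , y], nt3b[, , y])
  qs2aa <- qs2aa / nt2aa
  qstar2aa <- pmax(g2aa$A, g2aa$B, qs2aa)

  # stage 2, AB path: known (a1, b1), hidden a2 and b2
  winA2ab <- colSums(aperm(WA, c(2, 4, 1, 3)), dims = 2)
  winB2ab <- colSums(aperm(WB, c(2, 4, 1, 3)), dims = 2)
  nt2ab   <- colSums(aperm(NT, c(2, 4, 1, 3)), dims = 2)
  g2ab <- qg(winA2ab, winB2ab, nt2ab, cost[2])
  qs2abA <- matrix(0, 10, 10)  # sample A2, reveal x -> state (a1, x, b1)
  qs2abB <- matrix(0, 10, 10)  # sample B2, reveal y -> state (a1, b1, y)
  for (v in 1:10) {
    qs2abA <- qs2abA + nt3b[, v, ] * z0(qstar3b[, v, ], nt3b[, v, ])
    qs2abB <- qs2abB + nt3a[, , v] * z0(qstar3a[, , v], nt3a[, , v])
  }
  qs2abA <- qs2abA / nt2ab
  qs2abB <- qs2abB / nt2ab
  qstar2ab <- pmax(g2ab$A, g2ab$B, qs2abA, qs2abB)

  # stage 1: known a1 only
  winA1 <- rowSums(WA, dims = 1); winB1 <- rowSums(WB, dims = 1)
  nt1 <- rowSums(NT, dims = 1)
  g1 <- qg(winA1, winB1, nt1, cost[1])
  qs1aa <- rowSums(nt2aa * z0(qstar2aa, nt2aa)) / nt1   # reveal second A card
  qs1ab <- rowSums(nt2ab * z0(qstar2ab, nt2ab)) / nt1   # reveal first B card
  qstar1 <- cbind(AA = pmax(g1$A, g1$B, qs1aa), AB = pmax(g1$A, g1$B, qs1ab))

  structure(list(
    condition = condition, extra_sample_cost = e, cost = cost,
    s1 = list(q_guess_A = g1$A, q_guess_B = g1$B,
              q_sample = cbind(AA = qs1aa, AB = qs1ab),
              q_star = qstar1, p_win_A = winA1 / nt1, nt = nt1),
    s2aa = list(q_guess_A = g2aa$A, q_guess_B = g2aa$B, q_sample = qs2aa,
                q_star = qstar2aa, p_win_A = winA2aa / nt2aa, nt = nt2aa),
    s2ab = list(q_guess_A = g2ab$A, q_guess_B = g2ab$B,
                q_sample_A = qs2abA, q_sample_B = qs2abB,
                q_star = qstar2ab, p_win_A = winA2ab / nt2ab, nt = nt2ab),
    s3b = list(q_guess_A = g3b$A, q_guess_B = g3b$B, q_sample = qs3,
               q_star = qstar3b, p_win_A = winA3b / nt3b, nt = nt3b),
    s3a = list(q_guess_A = g3a$A, q_guess_B = g3a$B, q_sample = qs3,
               q_star = qstar3a, p_win_A = winA3a / nt3a, nt = nt3a)),
    class = "qtable")
}

#' @export
print.qtable <- function(x, ...) {
  cat(sprintf("<qtable> %s (extra sample cost %g): %d canonical states\n",
              x$condition, x$extra_sample_cost, 20L + 100L + 100L + 1000L + 1000L))
  invisible(x)
}

# locate a state's value slot in the solved arrays
.qt_lookup <- function(qtable, state) {
  if (qtable$condition != state$condition)
    .is_err("state condition does not match qtable", "infoseek_invalid_state")
  ra <- state$revealed_A; rb <- state$revealed_B
  na <- length(ra); nb <- length(rb)
  if (na == 1L && nb == 0L) list(tab = "s1", idx = ra[1L])
  else if (na == 2L && nb == 0L) list(tab = "s2aa", idx = cbind(ra[1L], ra[2L]))
  else if (na == 1L && nb == 1L) list(tab = "s2ab", idx = cbind(ra[1L], rb[1L]))
  else if (na == 2L && nb == 1L) list(tab = "s3b", idx = cbind(ra[1L], ra[2L], rb[1L]))
  else if (na == 1L && nb == 2L) list(tab = "s3a", idx = cbind(ra[1L], rb[1L], rb[2L]))
  else .is_err("no q-values for a fully revealed board (guess the winner)",
               "infoseek_invalid_state")
}

#' Action values of a solved condition
#'
#' `q_guess()` is the expected points of guessing a row now; `q_sample()` the
#' expected points of paying to reveal the card at a location;
#' `relative_value_of_guessing()` is the best guess value minus the best
#' sample value (positive when stopping is optimal).
#'
#' @param qtable a solved [solve_condition()] table.
#' @param state a [trial_state()].
#' @param row `"A"` or `"B"`.
#' @return points (net of costs already paid).
#' @export
q_guess <- function(qtable, state, row = c("A", "B")) {
  row <- match.arg(row)
  loc <- .qt_lookup(qtable, state)
  arr <- qtable[[loc$tab]][[paste0("q_guess_", row)]]
  if (loc$tab == "s1") arr[loc$idx] else arr[loc$idx]
}

#' @rdname q_guess
#' @param location a location label as in [legal_actions()] (e.g. `"A2"`).
#' @export
q_sample <- function(qtable, state, location) {
  locs <- .open_locations(state)
  if (!location %in% locs)
    .is_err(paste0("cannot sample ", location, " in this state"), "infoseek_illegal_action")
  loc <- .qt_lookup(qtable, state)
  unname(switch(loc$tab,
    s1   = qtable$s1$q_sample[loc$idx, state$trial_type],
    s2aa = qtable$s2aa$q_sample[loc$idx],
    s2ab = if (startsWith(location, "A")) qtable$s2ab$q_sample_A[loc$idx]
           else qtable$s2ab$q_sample_B[loc$idx],
    s3b  = qtable$s3b$q_sample,
    s3a  = qtable$s3a$q_sample))
}

#' @rdname q_guess
#' @export
relative_value_of_guessing <- function(qtable, state) {
  g <- max(q_guess(qtable, state, "A"), q_guess(qtable, state, "B"))
  locs <- .open_locations(state)
  if (!length(locs)) .is_err("no sampling action in this state", "infoseek_illegal_action")
  s <- max(vapply(locs, function(l) q_sample(qtable, state, l), numeric(1)))
  g - s
}

#' Greedy optimal policy tables
#'
#' Deterministic choice probabilities implied by the solved action values,
#' with ties between guessing and sampling broken toward guessing (cheaper
#' and terminates) and ties between two equally good targets split 0.5/0.5.
#' Returns, per stage-1 state, the probability of guessing and of choosing
#' row A conditional on guessing; per stage-2 AB state, the probability of
#' guessing and the relative probability of sampling row A over row B; and
#' per stage-2 AA / stage-3 state, the probability of guessing.
#'
#' @param qtable a solved [solve_condition()] table.
#' @return a list of policy arrays.
#' @export
optimal_policy <- function(qtable) {
  gmax1 <- pmax(qtable$s1$q_guess_A, qtable$s1$q_guess_B)
  p_guess1 <- cbind(AA = as.numeric(gmax1 >= qtable$s1$q_sample[, "AA"]),
                    AB = as.numeric(gmax1 >= qtable$s1$q_sample[, "AB"]))
  p_chooseA1 <- 0.5 * (sign(qtable$s1$q_guess_A - qtable$s1$q_guess_B) + 1)
  gmax2aa <- pmax(qtable$s2aa$q_guess_A, qtable$s2aa$q_guess_B)
  p_guess2aa <- (gmax2aa >= qtable$s2aa$q_sample) + 0
  gmax2ab <- pmax(qtable$s2ab$q_guess_A, qtable$s2ab$q_guess_B)
  smax2ab <- pmax(qtable$s2ab$q_sample_A, qtable$s2ab$q_sample_B)
  p_guess2ab <- (gmax2ab >= smax2ab) + 0
  p_sampleA2ab <- 0.5 * (sign(qtable$s2ab$q_sample_A - qtable$s2ab$q_sample_B) + 1)
  p_chooseA2aa <- 0.5 * (sign(qtable$s2aa$q_guess_A - qtable$s2aa$q_guess_B) + 1)
  p_chooseA2ab <- 0.5 * (sign(qtable$s2ab$q_guess_A - qtable$s2ab$q_guess_B) + 1)
  p_guess3b <- (pmax(qtable$s3b$q_guess_A, qtable$s3b$q_guess_B) >= qtable$s3b$q_sample) + 0
  p_guess3a <- (pmax(qtable$s3a$q_guess_A, qtable$s3a$q_guess_B) >= qtable$s3a$q_sample) + 0
  list(condition = qtable$condition,
       p_guess1 = p_guess1, p_chooseA1 = p_chooseA1,
       p_guess2aa = p_guess2aa, p_chooseA2aa = p_chooseA2aa,
       p_guess2ab = p_guess2ab, p_chooseA2ab = p_chooseA2ab,
       p_sampleA2ab = p_sampleA2ab,
       p_guess3b = p_guess3b, p_guess3a = p_guess3a,
       p_chooseA3b = 0.5 * (sign(qtable$s3b$q_guess_A - qtable$s3b$q_guess_B) + 1),
       p_chooseA3a = 0.5 * (sign(qtable$s3a$q_guess_A - qtable$s3a$q_guess_B) + 1))
}

# expected further samples from each state under the greedy policy,
# using the tie-conditioned transition probabilities
.expected_samples_arrays <- function(qtable) {
  pol <- optimal_policy(qtable)
  z0 <- function(q, w) ifelse(w > 0 & is.finite(q), q, 0)
  e3b <- 1 - pol$p_guess3b          # sample at stage 3 contributes 1
  e3a <- 1 - pol$p_guess3a
  nt3b <- qtable$s3b$nt; nt3a <- qtable$s3a$nt
  # stage-2 AA: sample a B card -> b-hidden stage-3 state
  cont2aa <- matrix(0, 10, 10)
  for (y in 1:10) cont2aa <- cont2aa + nt3b[, , y] * z0(e3b[, , y], nt3b[, , y])
  cont2aa <- cont2aa / qtable$s2aa$nt
  e2aa <- (1 - pol$p_guess2aa) * (1 + cont2aa)
  # stage-2 AB: policy samples its preferred row
  contA <- matrix(0, 10, 10); contB <- matrix(0, 10, 10)
  for (v in 1:10) {
    contA <- contA + nt3b[, v, ] * z0(e3b[, v, ], nt3b[, v, ])
    contB <- contB + nt3a[, , v] * z0(e3a[, , v], nt3a[, , v])
  }
  contA <- contA / qtable$s2ab$nt
  contB <- contB / qtable$s2ab$nt
  pA <- pol$p_sampleA2ab
  e2ab <- (1 - pol$p_guess2ab) * (1 + z0(pA * contA, qtable$s2ab$nt) +
                                    z0((1 - pA) * contB, qtable$s2ab$nt))
  # stage 1
  cont1aa <- rowSums(qtable$s2aa$nt * z0(e2aa, qtable$s2aa$nt)) / qtable$s1$nt
  cont1ab <- rowSums(qtable$s2ab$nt * z0(e2ab, qtable$s2ab$nt)) / qtable$s1$nt
  e1 <- cbind(AA = (1 - pol$p_guess1[, "AA"]) * (1 + cont1aa),
              AB = (1 - pol$p_guess1[, "AB"]) * (1 + cont1ab))
  list(e1 = e1, e2aa = e2aa, e2ab = e2ab, e3b = e3b, e3a = e3a,
       cont2aa = cont2aa, cont2abA = contA, cont2abB = contB,
       cont1aa = cont1aa, cont1ab = cont1ab, policy = pol)
}

#' Expected number of cards sampled by the optimal policy
#'
#' Forward pass over the enumerated game tree: expectation over the first
#' card (conditioned on a non-tied deal), the stage-1 offer location
#' (AA with probability 1/3, AB with 2/3) and all sampling transitions, of
#' the number of `SAMPLE` actions taken by the greedy optimal policy.
#'
#' @param qtable a solved [solve_condition()] table.
#' @return expected cards sampled per trial, in `[0, 3]`.
#' @export
expected_cards_optimal <- function(qtable) {
  es <- .expected_samples_arrays(qtable)
  p1 <- qtable$s1$nt / sum(qtable$s1$nt)
  sum(p1 * (es$e1[, "AA"] / 3 + es$e1[, "AB"] * 2 / 3))
}

#' @export
as.data.frame.qtable <- function(x, ...) {
  rows <- list()
  add <- function(stage, type, a1, a2, b1, b2, action, value)
    data.frame(condition = x$condition, stage = stage, trial_type = type,
               a1 = a1, a2 = a2, b1 = b1, b2 = b2, action = action, value = value)
  i <- 1:10
  g <- expand.grid(a1 = i)
  rows$s1 <- rbind(
    add("STAGE1", "AA", g$a1, NA, NA, NA, "guess_A", x$s1$q_guess_A),
    add("STAGE1", "AA", g$a1, NA, NA, NA, "guess_B", x$s1$q_guess_B),
    add("STAGE1", "AA", g$a1, NA, NA, NA, "sample_A2", x$s1$q_sample[, "AA"]),
    add("STAGE1", "AB", g$a1, NA, NA, NA, "guess_A", x$s1$q_guess_A),
    add("STAGE1", "AB", g$a1, NA, NA, NA, "guess_B", x$s1$q_guess_B),
    add("STAGE1", "AB", g$a1, NA, NA, NA, "sample_B1", x$s1$q_sample[, "AB"]))
  g2 <- expand.grid(a1 = i, a2 = i)
  rows$s2aa <- rbind(
    add("STAGE2", "AA", g2$a1, g2$a2, NA, NA, "guess_A", as.vector(x$s2aa$q_guess_A)),
    add("STAGE2", "AA", g2$a1, g2$a2, NA, NA, "guess_B", as.vector(x$s2aa$q_guess_B)),
    add("STAGE2", "AA", g2$a1, g2$a2, NA, NA, "sample_B", as.vector(x$s2aa$q_sample)))
  g2b <- expand.grid(a1 = i, b1 = i)
  rows$s2ab <- rbind(
    add("STAGE2", "AB", g2b$a1, NA, g2b$b1, NA, "guess_A", as.vector(x$s2ab$q_guess_A)),
    add("STAGE2", "AB", g2b$a1, NA, g2b$b1, NA, "guess_B", as.vector(x$s2ab$q_guess_B)),
    add("STAGE2", "AB", g2b$a1, NA, g2b$b1, NA, "sample_A2", as.vector(x$s2ab$q_sample_A)),
    add("STAGE2", "AB", g2b$a1, NA, g2b$b1, NA, "sample_B2", as.vector(x$s2ab$q_sample_B)))
  g3 <- expand.grid(a1 = i, a2 = i, b1 = i)
  rows$s3b <- rbind(
    add("STAGE3", NA, g3$a1, g3$a2, g3$b1, NA, "guess_A", as.vector(x$s3b$q_guess_A)),
    add("STAGE3", NA, g3$a1, g3$a2, g3$b1, NA, "guess_B", as.vector(x$s3b$q_guess_B)),
    add("STAGE3", NA, g3$a1, g3$a2, g3$b1, NA, "sample_B2", rep(x$s3b$q_sample, nrow(g3))))
  g3a <- expand.grid(a1 = i, b1 = i, b2 = i)
  rows$s3a <- rbind(
    add("STAGE3", NA, g3a$a1, NA, g3a$b1, g3a$b2, "guess_A", as.vector(x$s3a$q_guess_A)),
    add("STAGE3", NA, g3a$a1, NA, g3a$b1, g3a$b2, "guess_B", as.vector(x$s3a$q_guess_B)),
    add("STAGE3", NA, g3a$a1, NA, g3a$b1, g3a$b2, "sample_A2", rep(x$s3a$q_sample, nrow(g3a))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# cached solve
.solved <- function(condition, extra_sample_cost = 0) {
  key <- paste0(condition, "#", extra_sample_cost)
  if (is.null(the$qt)) the$qt <- list()
  if (is.null(the$qt[[key]])) the$qt[[key]] <- solve_condition(condition, extra_sample_cost)
  the$qt[[key]]
}
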
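#' @importFrom stats optim optimHess quantile rnorm runif sd cor median plogis setNames aggregate cov2cor
#' @importFrom utils head
NULL

# package-local cache (winner arrays, solved tables)
the <- new.env(parent = emptyenv())

.is_err <- function(msg, class) {
  stop(structure(class = c(class, "infoseek_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Task conditions
#'
#' The game is played under one of six conditions: a scoring operation
#' (`ADD`, `MULTIPLY`, `SINGLE`) crossed with an approach direction
#' (`BIG`, `SMALL`). A condition is represented as a character code such as
#' `"MULTIPLY_BIG"`.
#'
#' @return `infoseek_conditions()` returns the six condition codes.
#' @export
infoseek_conditions <- function() {
  as.vector(outer(c("ADD", "MULTIPLY", "SINGLE"), c("BIG", "SMALL"), paste, sep = "_"))
}

#' @rdname infoseek_conditions
#' @param operation one of `"ADD"`, `"MULTIPLY"`, `"SINGLE"`.
#' @param direction one of `"BIG"`, `"SMALL"`.
#' @export
condition_code <- function(operation, direction) {
  operation <- match.arg(toupper(operation), c("ADD", "MULTIPLY", "SINGLE"))
  direction <- match.arg(toupper(direction), c("BIG", "SMALL"))
  paste(operation, direction, sep = "_")
}

#' @rdname infoseek_conditions
#' @param condition a condition code.
#' @export
cond_operation <- function(condition) sub("_(BIG|SMALL)$", "", .check_condition(condition))

#' @rdname infoseek_conditions
#' @export
cond_direction <- function(condition) sub("^(ADD|MULTIPLY|SINGLE)_", "", .check_condition(condition))

.check_condition <- function(condition) {
  if (!all(condition %in% infoseek_conditions()))
    .is_err(paste0("unknown condition: ", paste(setdiff(condition, infoseek_conditions()), collapse = ", ")),
            "infoseek_invalid_condition")
  condition
}

.check_cards <- function(values) {
  values <- as.integer(values)
  if (any(is.na(values)) || any(values < 1L) || any(values > 10L))
    .is_err("card values must be integers in 1..10", "infoseek_invalid_card")
  values
}

#' Score of a row of cards
#'
#' Under `ADD` the score is the sum of the two cards, under `MULTIPLY` their
#' product, and under `SINGLE` the representative card (the larger card in a
#' `BIG` condition, the smaller in a `SMALL` condition).
#'
#' @param condition condition code.
#' @param values the two card values of the row (integers 1--10).
#' @return numeric score.
#' @examples
#' row_score("MULTIPLY_BIG", c(7, 2)) # 14
#' @export
row_score <- function(condition, values) {
  .check_condition(condition)
  values <- .check_cards(values)
  if (length(values) != 2L) .is_err("a row has exactly 2 cards", "infoseek_invalid_card")
  .score(cond_operation(condition), cond_direction(condition), values[1L], values[2L])
}

# vectorized scoring core
.score <- function(op, dir, a, b) {
  switch(op,
    ADD      = a + b,
    MULTIPLY = a * b,
    SINGLE   = if (dir == "BIG") pmax(a, b) else pmin(a, b))
}

#' Winning row of a fully revealed board
#'
#' In `BIG` conditions the row with the larger score wins; in `SMALL`
#' conditions the row with the smaller score wins. Equal scores are a tie
#' (tied deals are re-dealt in the game, and carry no probability mass in any
#' winner calculation).
#'
#' @param condition condition code.
#' @param row_a,row_b the two card values of each row.
#' @return `"A"`, `"B"` or `"TIE"`.
#' @export
winner <- function(condition, row_a, row_b) {
  sa <- row_score(condition, row_a)
  sb <- row_score(condition, row_b)
  s <- if (cond_direction(condition) == "BIG") sign(sa - sb) else sign(sb - sa)
  c("TIE", "A", "B")[match(s, c(0, 1, -1))]
}

# winner array over all 10^4 boards: +1 A wins, -1 B wins, 0 tie; cached
.winner_array <- function(condition) {
  .check_condition(condition)
  if (is.null(the$W)) the$W <- list()
  if (!is.null(the$W[[condition]])) return(the$W[[condition]])
  op <- cond_operation(condition); dir <- cond_direction(condition)
  i <- 1:10
  sA <- outer(i, i, function(a, b) .score(op, dir, a, b))  # 10x10
  d <- outer(as.vector(sA), as.vector(sA), "-")            # score A - score B
  s <- sign(d); if (dir == "SMALL") s <- -s
  W <- array(0L, c(10, 10, 10, 10))
  # d rows index (a1,a2), cols index (b1,b2)
  W[] <- as.integer(s[cbind(
    rep(rep(seq_len(100), times = 100)),
    rep(seq_len(100), each = 100))])
  the$W[[condition]] <- W
  W
}

#' Canonical trial state
#'
#' A state of one trial of the card game: the condition, the multiset of
#' revealed cards in each row, and (at Task Stage 1 only) the trial type,
#' i.e. whether the purchasable card lies on row A (`"AA"`) or row B
#' (`"AB"`). Row A is by definition the row of the first revealed card; cards
#' within a row are exchangeable, so revealed values are stored sorted. Stage
#' and sunk sampling costs are implied by the number of revealed cards
#' (costs 0 / 10 / 25 / 45 after 1--4 reveals).
#'
#' @param condition condition code.
#' @param revealed_A,revealed_B revealed card values per row (0--2 each).
#' @param trial_type `"AA"` or `"AB"`; required at stage 1, derived or
#'   irrelevant afterwards.
#' @return an object of class `trial_state`.
#' @examples
#' s <- trial_state("MULTIPLY_BIG", revealed_A = 2, trial_type = "AA")
#' win_probability(s, "B")
#' @export
trial_state <- function(condition, revealed_A = integer(), revealed_B = integer(),
                        trial_type = NULL) {
  .check_condition(condition)
  ra <- sort(.check_cards(revealed_A))
  rb <- if (length(revealed_B)) sort(.check_cards(revealed_B)) else integer()
  if (length(ra) < 1L || length(ra) > 2L || length(rb) > 2L)
    .is_err("revealed_A must hold 1-2 cards, revealed_B 0-2", "infoseek_invalid_state")
  n <- length(ra) + length(rb)
  if (n > 4L) .is_err("at most 4 cards on the board", "infoseek_invalid_state")
  stage <- c("STAGE1", "STAGE2", "STAGE3", "CHOICE")[n]
  if (stage == "STAGE1") {
    if (is.null(trial_type)) .is_err("trial_type required at stage 1", "infoseek_invalid_state")
    trial_type <- match.arg(trial_type, c("AA", "AB"))
  } else if (n == 2L) {
    trial_type <- if (length(ra) == 2L) "AA" else "AB"
  } else trial_type <- NA_character_
  structure(list(condition = condition, revealed_A = ra, revealed_B = rb,
                 stage = stage, trial_type = trial_type,
                 total_cost = c(0, 10, 25, 45)[n]),
            class = "trial_state")
}

#' @export
print.trial_state <- function(x, ...) {
  cat(sprintf("<trial_state> %s %s%s  A={%s} B={%s}  cost=%d\n",
              x$condition, x$stage,
              if (!is.na(x$trial_type)) paste0(" (", x$trial_type, ")") else "",
              paste(x$revealed_A, collapse = ","), paste(x$revealed_B, collapse = ","),
              x$total_cost))
  invisible(x)
}

# slice the winner array at a state's revealed cards -> array over hidden cards
.winner_slice <- function(state) {
  W <- .winner_array(state$condition)
  idx <- rep(list(quote(expr = )), 4)
  ra <- state$revealed_A; rb <- state$revealed_B
  if (length(ra) >= 1L) idx[[1]] <- ra[1L]
  if (length(ra) == 2L) idx[[2]] <- ra[2L]
  if (length(rb) >= 1L) idx[[3]] <- rb[1L]
  if (length(rb) == 2L) idx[[4]] <- rb[2L]
  do.call(`[`, c(list(W), idx))
}

#' Probability that a row wins
#'
#' Enumerates every equally likely completion of the hidden cards (uniform on
#' 1--10 with replacement) and returns the fraction of completions in which
#' `guess_row` strictly wins, among non-tied completions.
#'
#' @param state a [trial_state()].
#' @param guess_row `"A"` or `"B"`.
#' @return probability in `[0, 1]`.
#' @export
win_probability <- function(state, guess_row = c("A", "B")) {
  guess_row <- match.arg(guess_row)
  w <- .winner_slice(state)
  nontie <- sum(w != 0L)
  if (nontie == 0L)
    .is_err("board is tied with no hidden cards: winner undefined", "infoseek_undefined_winner")
  sum(w == if (guess_row == "A") 1L else -1L) / nontie
}

#' Actions
#'
#' An action is either `SAMPLE` at a purchasable location or a `GUESS` of a
#' row. Locations are labelled by row and slot, e.g. `"A2"` is the second card
#' of row A. At stage 1 only the single offered card can be sampled (`"A2"` on
#' AA trials, `"B1"` on AB trials); at stage 2 every remaining face-down card
#' can be; at stage 3 the last one.
#'
#' @param kind `"SAMPLE"` or `"GUESS"`.
#' @param target location (`SAMPLE`) or row `"A"`/`"B"` (`GUESS`).
#' @export
action <- function(kind = c("SAMPLE", "GUESS"), target) {
  kind <- match.arg(kind)
  structure(list(kind = kind, target = target), class = "action_spec")
}

#' @rdname action
#' @param state a [trial_state()].
#' @return `legal_actions()` returns a list of action specs.
#' @export
legal_actions <- function(state) {
  if (state$stage == "CHOICE") {
    w <- .winner_slice(state)
    if (identical(dim(w), NULL) && length(w) == 1L && w == 0L)
      .is_err("terminal tied board has no actions", "infoseek_no_actions")
  }
  guesses <- list(action("GUESS", "A"), action("GUESS", "B"))
  locs <- .open_locations(state)
  c(lapply(locs, function(l) action("SAMPLE", l)), guesses)
}

.open_locations <- function(state) {
  na <- length(state$revealed_A); nb <- length(state$revealed_B)
  if (state$stage == "STAGE1")
    return(if (state$trial_type == "AA") "A2" else "B1")
  if (state$stage == "CHOICE") return(character())
  locs <- character()
  if (na < 2L) locs <- c(locs, paste0("A", na + 1L))
  if (nb < 2L) locs <- c(locs, paste0("B", nb + 1L))
  locs
}

#' Apply an action to a state
#'
#' `SAMPLE` pays the stage cost (10/15/20 points at stages 1/2/3) and reveals
#' `drawn` at the target location, returning the successor [trial_state()].
#' `GUESS` resolves the trial: the remaining hidden cards must be supplied via
#' `hidden` (in location order, row A slots first) unless the board is already
#' fully revealed. Returns a `trial_outcome` with the chosen and winning rows
#' and the points won net of sampling costs (+60 correct / -50 incorrect).
#'
#' @param state a [trial_state()].
#' @param act an [action()].
#' @param drawn card value revealed by a `SAMPLE` action.
#' @param hidden card values of still-hidden cards for a `GUESS` action.
#' @export
apply_action <- function(state, act, drawn = NULL, hidden = NULL) {
  stopifnot(inherits(act, "action_spec"))
  if (act$kind == "SAMPLE") {
    locs <- .open_locations(state)
    if (!act$target %in% locs)
      .is_err(paste0("cannot sample ", act$target, " at ", state$stage), "infoseek_illegal_action")
    drawn <- .check_cards(drawn)
    ra <- state$revealed_A; rb <- state$revealed_B
    if (startsWith(act$target, "A")) ra <- c(ra, drawn) else rb <- c(rb, drawn)
    return(trial_state(state$condition, ra, rb))
  }
  # GUESS
  if (!act$target %in% c("A", "B")) .is_err("guess target must be A or B", "infoseek_illegal_action")
  ra <- state$revealed_A; rb <- state$revealed_B
  need <- 4L - length(ra) - length(rb)
  if (need > 0L) {
    hidden <- .check_cards(hidden)
    if (length(hidden) != need)
      .is_err(sprintf("guess needs %d hidden card value(s)", need), "infoseek_illegal_action")
    ka <- 2L - length(ra)
    ra <- c(ra, hidden[seq_len(ka)])
    rb <- c(rb, hidden[setdiff(seq_len(need), seq_len(ka))])
  }
  win <- winner(state$condition, ra, rb)
  if (win == "TIE") .is_err("tied board: re-deal", "infoseek_undefined_winner")
  pts <- (if (win == act$target) 60 else -50) - state$total_cost
  structure(list(chosen_row = act$target, winning_row = win,
                 points = pts, total_cost = state$total_cost),
            class = "trial_outcome")
}
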
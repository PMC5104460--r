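# Shared fixtures, cached across test files (solved tables are cached inside
# the package; simulated populations are cached here).

.fix <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# default parametric population playing the MULTIPLY pair
pop_multiply <- function(n, seed, ...) {
  key <- paste("popm", n, seed, paste(deparse(substitute(list(...))), collapse = ""))
  cached(key, generate_population(
    population_spec(n, conditions = c("MULTIPLY_BIG", "MULTIPLY_SMALL"), ...),
    seed = seed))
}

# homogeneous population of identical full-model agents (no heterogeneity)
pop_identical <- function(n, mean, seed,
                          conditions = c("MULTIPLY_BIG", "MULTIPLY_SMALL")) {
  spec <- population_spec(n, mean = mean, Sigma = matrix(0, 7, 7),
                          conditions = conditions)
  generate_population(spec, seed = seed)
}

default_means <- c(beta1 = 0.7, beta2 = 2.0, beta3 = 1.0, tau = 1.0,
                   beta4 = 0.045, beta5 = 0.095, beta6 = 0.057)

# ten hand-built MULTIPLY_BIG trials with known cell counts
hand_fixture <- function() {
  mk <- function(trial, type, c1, s1v = NA, s2r = NA, s2v = NA, s3r = NA,
                 s3v = NA, gs, chosen, winning) {
    cost <- c(0L, 10L, 25L, 45L)[gs]
    data.frame(uid = 1L, gameplay = 1L, block = 1L, trial = trial,
               condition = "MULTIPLY_BIG", trial_type = type, first_card = c1,
               sample1_value = s1v, sample2_row = s2r, sample2_value = s2v,
               sample3_row = s3r, sample3_value = s3v, guess_stage = gs,
               chosen_row = chosen, winning_row = winning,
               points = ifelse(chosen == winning, 60L, -50L) - cost,
               total_cost = cost, stringsAsFactors = FALSE)
  }
  rbind(
    mk(1, "AA", 5, gs = 1L, chosen = "A", winning = "A"),
    mk(2, "AA", 5, gs = 1L, chosen = "B", winning = "B"),
    mk(3, "AA", 5, s1v = 7, gs = 2L, chosen = "A", winning = "A"),
    mk(4, "AB", 2, gs = 1L, chosen = "B", winning = "B"),
    mk(5, "AB", 2, s1v = 9, gs = 2L, chosen = "B", winning = "B"),
    mk(6, "AB", 2, s1v = 9, s2r = "A", s2v = 4, gs = 3L, chosen = "A", winning = "B"),
    mk(7, "AB", 2, s1v = 9, s2r = "B", s2v = 6, gs = 3L, chosen = "B", winning = "B"),
    mk(8, "AB", 2, s1v = 9, s2r = "A", s2v = 4, s3r = "B", s3v = 6, gs = 4L,
       chosen = "B", winning = "B"),
    mk(9, "AA", 8, gs = 1L, chosen = "A", winning = "A"),
    mk(10, "AB", 8, s1v = 3, gs = 2L, chosen = "A", winning = "A"))
}

# independent enumeration oracle for win probabilities: recomputes scores
# and winners from scratch (no package internals)
oracle_win_prob <- function(condition, revealed_A, revealed_B, row) {
  op <- sub("_(BIG|SMALL)$", "", condition)
  dir <- sub("^.*_", "", condition)
  sc <- function(v1, v2) switch(op, ADD = v1 + v2, MULTIPLY = v1 * v2,
                                SINGLE = if (dir == "BIG") pmax(v1, v2) else pmin(v1, v2))
  nh_a <- 2 - length(revealed_A); nh_b <- 2 - length(revealed_B)
  grid <- do.call(expand.grid, rep(list(1:10), nh_a + nh_b))
  if (!nrow(grid)) grid <- data.frame(row.names = 1)
  wins <- ties <- 0L
  for (r in seq_len(max(nrow(grid), 1))) {
    h <- as.numeric(grid[r, ])
    a <- c(revealed_A, if (nh_a) h[seq_len(nh_a)])
    b <- c(revealed_B, if (nh_b) h[nh_a + seq_len(nh_b)])
    sa <- sc(a[1], a[2]); sb <- sc(b[1], b[2])
    w <- if (sa == sb) "TIE" else if ((sa > sb) == (dir == "BIG")) "A" else "B"
    if (w == "TIE") ties <- ties + 1L else if (w == row) wins <- wins + 1L
  }
  wins / (max(nrow(grid), 1) - ties)
}

# independent expectimax oracle: value of a state by direct recursion over
# all completions, conditioning transitions on a non-tied final board
oracle_value <- function(condition, ra, rb, cost_paid, extra = 0, n_sampled = 0) {
  op <- sub("_(BIG|SMALL)$", "", condition)
  dir <- sub("^.*_", "", condition)
  sc <- function(v1, v2) switch(op, ADD = v1 + v2, MULTIPLY = v1 * v2,
                                SINGLE = if (dir == "BIG") max(v1, v2) else min(v1, v2))
  nontie_count <- function(a, b) {
    nh_a <- 2 - length(a); nh_b <- 2 - length(b)
    grid <- do.call(expand.grid, rep(list(1:10), nh_a + nh_b))
    if (!ncol(grid)) {
      sa <- sc(a[1], a[2]); sb <- sc(b[1], b[2])
      return(as.integer(sa != sb))
    }
    n <- 0L
    for (r in seq_len(nrow(grid))) {
      h <- as.numeric(grid[r, ])
      aa <- c(a, if (nh_a) h[seq_len(nh_a)])
      bb <- c(b, if (nh_b) h[nh_a + seq_len(nh_b)])
      if (sc(aa[1], aa[2]) != sc(bb[1], bb[2])) n <- n + 1L
    }
    n
  }
  win_count <- function(a, b, row) {
    nh_a <- 2 - length(a); nh_b <- 2 - length(b)
    grid <- do.call(expand.grid, rep(list(1:10), nh_a + nh_b))
    n <- 0L
    for (r in seq_len(max(nrow(grid), 1))) {
      h <- if (ncol(grid)) as.numeric(grid[r, ]) else numeric()
      aa <- c(a, if (nh_a) h[seq_len(nh_a)])
      bb <- c(b, if (nh_b) h[nh_a + seq_len(nh_b)])
      sa <- sc(aa[1], aa[2]); sb <- sc(bb[1], bb[2])
      w <- if (sa == sb) next else if ((sa > sb) == (dir == "BIG")) "A" else "B"
      if (w == row) n <- n + 1L
    }
    n
  }
  nt <- nontie_count(ra, rb)
  pA <- win_count(ra, rb, "A") / nt
  g <- max(110 * pA - 50 - cost_paid, 110 * (1 - pA) - 50 - cost_paid)
  n_hidden <- 4 - length(ra) - length(rb)
  if (n_hidden == 0) return(g)
  next_cost <- cost_paid + c(10, 15, 20)[3 - n_hidden + 1] + extra
  vals <- g
  if (length(ra) < 2) {  # sample the remaining row-A slot
    num <- den <- 0
    for (v in 1:10) {
      w <- nontie_count(c(ra, v), rb)
      if (w > 0) {
        num <- num + w * oracle_value(condition, c(ra, v), rb, next_cost, extra)
        den <- den + w
      }
    }
    vals <- c(vals, num / den)
  }
  if (length(rb) < 2) {
    num <- den <- 0
    for (v in 1:10) {
      w <- nontie_count(ra, c(rb, v))
      if (w > 0) {
        num <- num + w * oracle_value(condition, ra, c(rb, v), next_cost, extra)
        den <- den + w
      }
    }
    vals <- c(vals, num / den)
  }
  max(vals)
}
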
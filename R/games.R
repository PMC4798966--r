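#' Proportional tit-for-tat cooperation probability
#'
#' The pTFT rule: the focal individual cooperates in the first round, and in
#' every later round cooperates with probability equal to the fraction of
#' its partners (excluding itself) that cooperated in the previous round.
#' No partner is singled out — pTFT responds to the group, not to
#' individuals — so partner choice plays no part; the strategy survives, if
#' at all, through partner fidelity feedback.
#'
#' @param prev_fraction fraction of partners that cooperated in the
#'   previous round, in \[0, 1\] (ignored in round 1).
#' @param round_index 1-based round number.
#' @return The probability of cooperating this round.
#' @examples
#' ptft_probability(0.2, 1)   # 1: starts cooperating
#' ptft_probability(0.75, 2)  # 0.75
#' @export
ptft_probability <- function(prev_fraction, round_index) {
  stopifnot(round_index >= 1)
  if (round_index == 1) return(rep(1, length(prev_fraction)))
  stopifnot(all(prev_fraction >= -1e-12), all(prev_fraction <= 1 + 1e-12))
  pmin(pmax(prev_fraction, 0), 1)
}

#' Iterated within-group public-goods game
#'
#' Plays `rounds` rounds inside each group. A cooperative act costs the
#' actor `cost` and delivers `b / (n - 1)` to each of its `n - 1` partners
#' (a linear public good divided among partners). Strategies are
#' `"ptft"` ([ptft_probability()]), `"always-cheat"` and
#' `"always-cooperate"`. pTFT randomisation uses independent per-individual
#' draws; the run is deterministic given `seed`.
#'
#' Inside any mixed group a cheater's expected payoff is at least a pTFT
#' player's every round (it harvests the same public good without ever
#' paying the cost), so pTFT can only win on the across-group margin: it
#' needs groups that persist over repeated rounds *and* vary strongly in
#' pTFT frequency, so that cooperation-sustaining groups out-earn
#' cheater-dominated ones. Those are exactly the two requirements of
#' partner fidelity feedback, and [ptft_requirements_experiment()] asserts
#' them factorially.
#'
#' @param groups list of character vectors; each vector gives the strategy
#'   of every member of one group (length >= 2).
#' @param rounds number of rounds (>= 1).
#' @param b,cost benefit delivered (split among partners) and cost paid per
#'   cooperative act; `b > cost > 0`. Defaults `b = 3`, `cost = 1` are
#'   arbitrary but conventional for public-goods demonstrations.
#' @param seed optional integer seed.
#' @return An object of class `game_result`: list with `by_strategy` (data
#'   frame of mean total payoff per strategy), `individuals` (data frame:
#'   group, strategy, payoff), and `cooperation` (matrix of per-group,
#'   per-round cooperating counts).
#' @examples
#' g <- list(rep(c("ptft", "always-cheat"), c(8, 2)),
#'           rep(c("ptft", "always-cheat"), c(2, 8)))
#' res <- iterated_group_game(g, rounds = 20, seed = 1)
#' res$by_strategy
#' @export
iterated_group_game <- function(groups, rounds, b = 3, cost = 1,
                                seed = NULL) {
  stopifnot(is.list(groups), rounds >= 1, b > 0, cost > 0)
  ok <- c("ptft", "always-cheat", "always-cooperate")
  for (g in groups) {
    if (length(g) < 2) stop("group of size 1: no partners to interact with")
    if (!all(g %in% ok))
      stop("unknown strategy; use: ", paste(ok, collapse = ", "))
  }
  .maybe_seed(seed)
  indiv <- list()
  coop_mat <- matrix(NA_real_, length(groups), rounds)
  for (gi in seq_along(groups)) {
    strat <- groups[[gi]]
    n <- length(strat)
    payoff <- numeric(n)
    prev <- rep(NA, n)   # who cooperated last round
    for (r in seq_len(rounds)) {
      if (r == 1) {
        acts <- strat != "always-cheat"
      } else {
        frac_partner <- (sum(prev) - prev) / (n - 1)
        p <- ifelse(strat == "ptft", ptft_probability(frac_partner, r),
                    ifelse(strat == "always-cooperate", 1, 0))
        acts <- runif(n) < p
      }
      n_coop_partners <- sum(acts) - acts
      payoff <- payoff + n_coop_partners * b / (n - 1) - acts * cost
      prev <- acts
      coop_mat[gi, r] <- sum(acts)
    }
    indiv[[gi]] <- data.frame(group = gi, strategy = strat, payoff = payoff)
  }
  indiv <- do.call(rbind, indiv)
  by_strategy <- aggregate(payoff ~ strategy, indiv, mean)
  structure(list(by_strategy = by_strategy, individuals = indiv,
                 cooperation = coop_mat, rounds = rounds, b = b,
                 cost = cost),
            class = "game_result")
}

#' @export
print.game_result <- function(x, ...) {
  cat("Iterated public-goods game:", nrow(x$cooperation), "group(s),",
      x$rounds, "round(s), b =", x$b, ", cost =", x$cost, "\n")
  print(x$by_strategy, row.names = FALSE)
  invisible(x)
}

#' Factorial test of the two partner-fidelity-feedback requirements
#'
#' Runs the iterated public-goods game in a 2 x 2 design crossing round
#' number (single round vs `rounds_long`) with across-group variance in
#' pTFT frequency (uniform half-and-half groups vs strongly assorted
#' groups), holding total composition fixed. pTFT should out-earn
#' always-cheat *only* in the repeated-interaction, high-variance cell —
#' repeated interactions let cooperation feed back, and across-group
#' variance lets cooperator-rich groups reap it.
#'
#' The high-variance condition uses assorted-but-mixed groups (by default
#' 8 pTFT + 2 cheaters alongside 2 pTFT + 8 cheaters): complete segregation
#' would let pTFT win trivially even in one round, which is not the claim
#' under test.
#'
#' @param rounds_long round count for the repeated-interaction level
#'   (default 20).
#' @param group_size members per group (even; default 10).
#' @param assorted_majority pTFT count in the pTFT-rich group of the
#'   high-variance condition (default 8).
#' @param b,cost payoff parameters, see [iterated_group_game()].
#' @param replicates replicate games per cell (default 30).
#' @param seed integer seed.
#' @return A data frame of class `ptft_factorial` with one row per cell:
#'   `rounds`, `variance` (`"high"`/`"low"`), mean payoffs of pTFT and
#'   cheaters, and `ptft_wins`.
#' @examples
#' ptft_requirements_experiment(replicates = 5, seed = 1)
#' @export
ptft_requirements_experiment <- function(rounds_long = 20, group_size = 10,
                                         assorted_majority = 8, b = 3,
                                         cost = 1, replicates = 30,
                                         seed = NULL) {
  stopifnot(group_size %% 2 == 0, assorted_majority > group_size / 2,
            assorted_majority < group_size)
  .maybe_seed(seed)
  comp <- function(n_ptft)
    rep(c("ptft", "always-cheat"), c(n_ptft, group_size - n_ptft))
  designs <- list(
    high = list(comp(assorted_majority), comp(group_size - assorted_majority)),
    low  = list(comp(group_size / 2), comp(group_size / 2)))
  cells <- expand.grid(rounds = c(1L, as.integer(rounds_long)),
                       variance = c("high", "low"),
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    pt <- ch <- numeric(replicates)
    for (rep_i in seq_len(replicates)) {
      res <- iterated_group_game(designs[[cells$variance[i]]],
                                 rounds = cells$rounds[i], b = b, cost = cost)
      m <- setNames(res$by_strategy$payoff, res$by_strategy$strategy)
      pt[rep_i] <- m[["ptft"]]; ch[rep_i] <- m[["always-cheat"]]
    }
    data.frame(rounds = cells$rounds[i], variance = cells$variance[i],
               ptft_payoff = mean(pt), cheater_payoff = mean(ch),
               ptft_wins = mean(pt) > mean(ch))
  })
  structure(do.call(rbind, out), class = c("ptft_factorial", "data.frame"))
}
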
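#' State of the toxin-antitoxin anti-competition model
#'
#' Cooperators carry a toxin-antitoxin gene pair: under crowding stress a
#' fraction `suicide_fraction` of them lyse, releasing toxin that kills
#' cheaters (who lack the antitoxin) while the remaining cooperators are
#' immune. Killing relieves competition — a benefit shared by all survivors,
#' cooperators and cheaters alike. Cooperators may also grow slower than
#' cheaters by a relative deficit `growth_cost`.
#'
#' @param cooperators,cheaters non-negative abundances (`C`, `D`).
#' @param suicide_fraction fraction `s` of cooperators that lyse per
#'   episode, in \[0, 1\] (default 0.1).
#' @param kill_coefficient cheaters killed per suicidal cooperator `k`
#'   (default 2).
#' @param density_threshold total population size `K` that triggers an
#'   episode (default 250).
#' @param growth_cost relative growth-rate deficit of cooperators in
#'   \[0, 1\] (cheater rate 1, cooperator rate `1 - growth_cost`); default 0.
#' @return A list of class `toxin_state`.
#' @examples
#' toxin_state(210, 40)
#' @export
toxin_state <- function(cooperators, cheaters, suicide_fraction = 0.1,
                        kill_coefficient = 2, density_threshold = 250,
                        growth_cost = 0) {
  stopifnot(cooperators >= 0, cheaters >= 0,
            suicide_fraction >= 0, suicide_fraction <= 1,
            kill_coefficient >= 0, density_threshold >= 1,
            growth_cost >= 0, growth_cost <= 1)
  structure(list(cooperators = cooperators, cheaters = cheaters,
                 suicide_fraction = suicide_fraction,
                 kill_coefficient = kill_coefficient,
                 density_threshold = density_threshold,
                 growth_cost = growth_cost),
            class = "toxin_state")
}

#' @export
print.toxin_state <- function(x, ...) {
  cat(sprintf(paste0("toxin-antitoxin state: C = %g, D = %g ",
                     "(s = %g, k = %g, K = %g, cost = %g)\n"),
              x$cooperators, x$cheaters, x$suicide_fraction,
              x$kill_coefficient, x$density_threshold, x$growth_cost))
  invisible(x)
}

#' One deterministic suicide episode
#'
#' `round(s * C)` cooperators lyse (round-half-even, which is exact at the
#' worked values) and each lysis kills up to `k` cheaters, capped at the
#' number of cheaters present: `kills = min(k * suicides, D)`. Deaths are
#' exactly suicides + kills and neither type can go negative.
#'
#' @param state a [toxin_state].
#' @return The post-episode `toxin_state`, with attributes `suicides` and
#'   `kills` recording the two death tallies.
#' @examples
#' s <- suicide_episode(toxin_state(210, 40))
#' c(s$cooperators, s$cheaters)  # 189, 0: all cheaters killed
#' s <- suicide_episode(toxin_state(50, 200))
#' c(s$cooperators, s$cheaters)  # 45, 190: cheaters lose only 5%
#' @export
suicide_episode <- function(state) {
  stopifnot(inherits(state, "toxin_state"))
  if (state$cooperators + state$cheaters < 1) stop("population is empty")
  suicides <- round(state$suicide_fraction * state$cooperators)
  kills <- min(state$kill_coefficient * suicides, state$cheaters)
  out <- state
  out$cooperators <- state$cooperators - suicides
  out$cheaters <- state$cheaters - kills
  attr(out, "suicides") <- suicides
  attr(out, "kills") <- kills
  out
}

#' Critical cooperator frequency for the suicide episode to pay off
#'
#' Across one episode, cooperators lose the relative fraction `s` while
#' cheaters lose `k * s * C / D`; cheater frequency therefore declines iff
#' the cooperator frequency exceeds `1 / (1 + k)` — independent of `s` when
#' cooperators bear no growth cost. With `growth_cost > 0` the threshold is
#' the fixed point of the full grow-to-threshold-then-lyse cycle map
#' (located numerically): growth dilutes cooperators before each episode,
#' so the critical frequency rises above `1 / (1 + k)`.
#'
#' @param s suicide fraction (> 0).
#' @param k kill coefficient (> 0; with `k = 0` cooperators can never gain
#'   and no threshold exists — an error).
#' @param growth_cost relative cooperator growth deficit in \[0, 1).
#' @param density_threshold population size at which episodes fire (only
#'   used when `growth_cost > 0`).
#' @return The critical initial cooperator frequency in (0, 1).
#' @examples
#' critical_cooperator_frequency(0.1, 2)    # 1/3
#' critical_cooperator_frequency(0.05, 2)   # still 1/3: independent of s
#' @export
critical_cooperator_frequency <- function(s, k, growth_cost = 0,
                                          density_threshold = 250) {
  stopifnot(s > 0)
  if (k <= 0)
    stop("k = 0: suicides kill nobody, cooperators can never gain in frequency")
  if (growth_cost == 0) return(1 / (1 + k))
  stopifnot(growth_cost < 1)
  K <- density_threshold
  cycle_gain <- function(p) {
    # one lysis episode at density K, then regrowth to K
    C0 <- p * K; D0 <- (1 - p) * K
    C1 <- C0 - s * C0
    D1 <- max(0, D0 - k * s * C0)
    if (D1 == 0) return(1 - p)
    f <- function(t) C1 * exp((1 - growth_cost) * t) + D1 * exp(t) - K
    tmax <- log(K / (C1 + D1)) / (1 - growth_cost) + 1
    t <- uniroot(f, c(0, tmax))$root
    C1 * exp((1 - growth_cost) * t) / K - p
  }
  uniroot(cycle_gain, c(1e-6, 1 - 1e-6))$root
}

#' Well-mixed trajectory of alternating growth and suicide episodes
#'
#' Both types grow exponentially (cheater rate 1, cooperator rate
#' `1 - growth_cost`) until total abundance reaches the density threshold
#' `K`; an episode then fires ([suicide_episode()]) and growth resumes.
#' Growth is deterministic (continuous exponential, abundances need not stay
#' integer); the episode rule rounds as specified. This is the
#' partner-choice-acting-alone regime: in a well-mixed environment
#' cooperators gain frequency only when they start above the critical
#' frequency ([critical_cooperator_frequency()]).
#'
#' @param state a [toxin_state]; if the population already meets the
#'   threshold the first episode fires immediately.
#' @param n_episodes number of episodes to simulate.
#' @return An object of class `toxin_trajectory`: a data frame with one row
#'   per episode (`episode`, `C_before`, `D_before`, `C_after`, `D_after`,
#'   `freq_before`, `freq_after`) plus a `status` attribute (`"ok"`,
#'   `"cheaters_extinct"`, `"cooperators_extinct"`, or `"stalled"` when the
#'   population can no longer reach the threshold).
#' @examples
#' tr <- well_mixed_trajectory(toxin_state(210, 40), 3)
#' tr$D_after[1]  # 0: all cheaters killed in episode 1
#' @export
well_mixed_trajectory <- function(state, n_episodes = 10) {
  stopifnot(inherits(state, "toxin_state"), n_episodes >= 1)
  C <- state$cooperators; D <- state$cheaters
  K <- state$density_threshold; g <- state$growth_cost
  if (C + D < 1) stop("population is empty")
  rows <- list(); status <- "ok"
  for (ep in seq_len(n_episodes)) {
    if (C + D < K) {
      # grow to the threshold; cooperator rate 1-g, cheater rate 1
      rC <- 1 - g
      if ((C == 0 || rC == 0) && D == 0) { status <- "stalled"; break }
      f <- function(t) C * exp(rC * t) + D * exp(t) - K
      tmax <- if (D > 0) log(K / D) + 1 else {
        if (rC == 0) { status <- "stalled"; break }
        log(K / C) / rC + 1
      }
      if (f(tmax) < 0) { status <- "stalled"; break }
      t <- uniroot(f, c(0, tmax))$root
      C <- C * exp(rC * t); D <- D * exp(t)
    }
    st <- state; st$cooperators <- C; st$cheaters <- D
    post <- suicide_episode(st)
    rows[[ep]] <- data.frame(
      episode = ep, C_before = C, D_before = D,
      C_after = post$cooperators, D_after = post$cheaters,
      freq_before = C / (C + D),
      freq_after = post$cooperators / (post$cooperators + post$cheaters))
    C <- post$cooperators; D <- post$cheaters
    if (D <= 0 && status == "ok") status <- "cheaters_extinct"
    if (C <= 0) { status <- "cooperators_extinct"; break }
  }
  structure(do.call(rbind, rows), status = status,
            class = c("toxin_trajectory", "data.frame"))
}

#' @export
print.toxin_trajectory <- function(x, ...) {
  cat("Well-mixed toxin trajectory,", nrow(x), "episode(s), status:",
      attr(x, "status"), "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# torus shift of a matrix by (dr, dc)
.shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dr) %% nr) + 1, ((seq_len(nc) - 1 - dc) %% nc) + 1,
    drop = FALSE]
}

.MOORE <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Spatial lattice variant of the toxin-antitoxin model
#'
#' Stochastic simulation on a rectangular torus whose sites are empty (0),
#' cooperator (1) or cheater (2). Per step, synchronously, every empty site
#' is colonised with probability equal to the growth-rate-weighted fraction
#' of its occupied Moore neighbours (cheater weight 1, cooperator weight
#' `1 - growth_cost`), the parent drawn proportionally to those weights.
#' Then crowding is assessed: a cooperator whose Moore neighbourhood has at
#' least `crowd_neighbors` occupied sites lyses with probability `s`,
#' killing up to `k` cheaters drawn uniformly at random from those within
#' Chebyshev distance `kill_radius`; lysing cooperators are processed
#' sequentially in random order so kills update the grid as they happen.
#' Toxin acts locally, so repeated local interactions (partner fidelity
#' feedback) join cooperator immunity (partner choice), and a clustered
#' minority of cooperators can expand where the well-mixed model says it
#' must decline.
#'
#' With `density_scope = "global"` crowding is instead triggered when total
#' occupancy reaches `global_density` of the grid and every cooperator is
#' eligible; combined with `kill_radius = Inf` and mixed placement this
#' reduces the lattice to the well-mixed threshold regime.
#'
#' @param nrow,ncol grid dimensions.
#' @param coop_frequency initial cooperator share of occupied sites.
#' @param occupancy initial fraction of occupied sites (default 0.6).
#' @param placement `"clustered"` (cooperators in one compact block) or
#'   `"mixed"` (random interspersion).
#' @param s,k suicide fraction and kill coefficient per lysis.
#' @param kill_radius Chebyshev kill radius (>= 1, may be `Inf`).
#' @param crowd_neighbors occupied Moore neighbours (out of 8) that define
#'   local crowding (default 7).
#' @param density_scope `"local"` (default) or `"global"`.
#' @param global_density occupancy fraction triggering global episodes.
#' @param growth_cost relative cooperator growth deficit.
#' @param n_steps number of synchronous update steps (default 120; the
#'   first handful of steps merely fill the lattice, transiently diluting a
#'   clustered minority — the killing-driven expansion operates on a slower
#'   timescale).
#' @param seed integer seed (the run is deterministic given the seed).
#' @return An object of class `toxin_lattice`: list with `frequency` (per
#'   step cooperator share of occupied sites, step 0 first), `counts` (data
#'   frame of per-step cooperator/cheater/empty counts), `initial_grid`,
#'   `final_grid`.
#' @examples
#' lat <- lattice_trajectory(20, 20, coop_frequency = 0.1, n_steps = 10,
#'                           seed = 1)
#' tail(lat$frequency, 1)
#' @export
lattice_trajectory <- function(nrow = 40, ncol = 40, coop_frequency = 0.02,
                               occupancy = 0.6,
                               placement = c("clustered", "mixed"),
                               s = 0.1, k = 2, kill_radius = 1,
                               crowd_neighbors = 7,
                               density_scope = c("local", "global"),
                               global_density = 0.9,
                               growth_cost = 0, n_steps = 120, seed = NULL) {
  placement <- match.arg(placement)
  density_scope <- match.arg(density_scope)
  stopifnot(kill_radius >= 1, crowd_neighbors >= 1, crowd_neighbors <= 8,
            coop_frequency >= 0, coop_frequency <= 1,
            occupancy > 0, occupancy <= 1)
  .maybe_seed(seed)
  n_sites <- nrow * ncol
  n_occ <- round(occupancy * n_sites)
  n_coop <- round(coop_frequency * n_occ)
  grid <- matrix(0L, nrow, ncol)
  if (placement == "clustered") {
    side <- ceiling(sqrt(n_coop))
    block <- as.matrix(expand.grid(r = seq_len(min(side, nrow)),
                                   c = seq_len(min(side, ncol))))
    block <- block[seq_len(min(n_coop, nrow(block))), , drop = FALSE]
    # centre the cooperator block
    block[, 1] <- ((block[, 1] + nrow %/% 2) %% nrow) + 1
    block[, 2] <- ((block[, 2] + ncol %/% 2) %% ncol) + 1
    grid[block] <- 1L
    free <- which(grid == 0L)
    grid[sample(free, n_occ - sum(grid == 1L))] <- 2L
  } else {
    idx <- sample(n_sites, n_occ)
    grid[idx] <- 2L
    grid[sample(idx, n_coop)] <- 1L
  }
  init_grid <- grid

  coop_w <- 1 - growth_cost
  freq_of <- function(g) {
    occ <- sum(g != 0L)
    if (occ == 0) NA_real_ else sum(g == 1L) / occ
  }
  counts <- function(g, step)
    data.frame(step = step, cooperators = sum(g == 1L),
               cheaters = sum(g == 2L), empty = sum(g == 0L))
  freq <- freq_of(grid)
  tally <- list(counts(grid, 0L))

  for (step in seq_len(n_steps)) {
    # --- synchronous colonisation of empty sites ---
    wc <- matrix(0, nrow, ncol); wd <- matrix(0, nrow, ncol)
    for (j in seq_len(8)) {
      nb <- .shift(grid, .MOORE[j, 1], .MOORE[j, 2])
      wc <- wc + (nb == 1L) * coop_w
      wd <- wd + (nb == 2L)
    }
    W <- wc + wd
    empt <- grid == 0L
    colonise <- empt & (matrix(runif(n_sites), nrow, ncol) < W / 8)
    if (any(colonise)) {
      pc <- wc[colonise] / W[colonise]
      grid[colonise] <- ifelse(runif(sum(colonise)) < pc, 1L, 2L)
    }
    # --- crowding-triggered suicide episodes ---
    if (density_scope == "local") {
      occ_nb <- matrix(0, nrow, ncol)
      for (j in seq_len(8))
        occ_nb <- occ_nb + (.shift(grid, .MOORE[j, 1], .MOORE[j, 2]) != 0L)
      eligible <- which(grid == 1L & occ_nb >= crowd_neighbors)
    } else {
      eligible <- if (sum(grid != 0L) >= global_density * n_sites)
        which(grid == 1L) else integer(0)
    }
    if (length(eligible)) {
      lysing <- eligible[runif(length(eligible)) < s]
      for (site in lysing[sample.int(length(lysing))]) {
        if (grid[site] != 1L) next   # may have been overwritten (it cannot
        grid[site] <- 0L             # be toxin-killed: cooperators are immune)
        r0 <- (site - 1) %% nrow + 1
        c0 <- (site - 1) %/% nrow + 1
        ch <- which(grid == 2L)
        if (!length(ch)) next
        rr <- (ch - 1) %% nrow + 1
        cc <- (ch - 1) %/% nrow + 1
        ddr <- pmin(abs(rr - r0), nrow - abs(rr - r0))
        ddc <- pmin(abs(cc - c0), ncol - abs(cc - c0))
        dist <- pmax(ddr, ddc)
        in_range <- ch[dist <= kill_radius]
        if (!length(in_range)) next
        victims <- in_range[sample.int(length(in_range),
                                       min(k, length(in_range)))]
        grid[victims] <- 0L
      }
    }
    freq <- c(freq, freq_of(grid))
    tally[[step + 1L]] <- counts(grid, step)
  }
  structure(list(frequency = freq, counts = do.call(rbind, tally),
                 initial_grid = init_grid, final_grid = grid),
            class = "toxin_lattice")
}

#' @export
print.toxin_lattice <- function(x, ...) {
  n <- length(x$frequency)
  cat("Lattice toxin run,", n - 1, "steps;",
      "cooperator frequency", signif(x$frequency[1], 3), "->",
      signif(x$frequency[n], 3), "\n")
  invisible(x)
}

#' @export
plot.toxin_lattice <- function(x, ...) {
  image(t(x$final_grid)[, rev(seq_len(nrow(x$final_grid)))],
        col = c("white", "grey20", "tomato"), axes = FALSE,
        main = "final lattice (dark = cooperator, red = cheater)", ...)
  invisible(x)
}
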
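test_that("suicide episodes reproduce the printed worked outcomes", {
  hi <- suicide_episode(toxin_state(210, 40))
  expect_equal(hi$cooperators, 189)   # 10% of 210 lyse
  expect_equal(hi$cheaters, 0)        # 42 potential kills >= 40 cheaters
  expect_equal(attr(hi, "suicides"), 21)
  expect_equal(attr(hi, "kills"), 40)
  lo <- suicide_episode(toxin_state(50, 200))
  expect_equal(lo$cooperators, 45)
  expect_equal(lo$cheaters, 190)      # cheaters lose 10 (5%) vs 10% of C
  expect_equal(attr(lo, "kills"), 10)
  none <- suicide_episode(toxin_state(80, 0))
  expect_equal(none$cooperators, 72)
  expect_equal(none$cheaters, 0)
})

test_that("episode deaths are conserved and counts never go negative", {
  set.seed(5)
  for (i in 1:50) {
    C <- sample(0:300, 1); D <- sample(0:300, 1)
    if (C + D == 0) next
    st <- toxin_state(C, D, suicide_fraction = runif(1),
                      kill_coefficient = sample(0:4, 1))
    post <- suicide_episode(st)
    expect_gte(post$cooperators, 0)
    expect_gte(post$cheaters, 0)
    expect_equal((C + D) - (post$cooperators + post$cheaters),
                 attr(post, "suicides") + attr(post, "kills"))
    expect_lte(attr(post, "kills"), D)
  }
})

test_that("analytic invasion threshold is 1/(1+k), independent of s", {
  expect_equal(critical_cooperator_frequency(0.1, 2), 1 / 3)
  expect_equal(critical_cooperator_frequency(0.05, 2), 1 / 3)
  expect_equal(critical_cooperator_frequency(0.1, 1), 1 / 2)
  expect_lt(critical_cooperator_frequency(0.1, 1000), 1e-2)
  expect_error(critical_cooperator_frequency(0.1, 0), "k = 0")
  # a growth cost raises the bar
  expect_gt(critical_cooperator_frequency(0.1, 2, growth_cost = 0.1), 1 / 3)
})

test_that("episode sweep at carrying capacity locates the analytic threshold", {
  K <- 250
  for (k in 1:3) {
    freq_gain <- vapply(1:(K - 1), function(C) {
      post <- suicide_episode(toxin_state(C, K - C, kill_coefficient = k))
      post$cooperators / (post$cooperators + post$cheaters) - C / K
    }, numeric(1))
    first_gain <- min(which(freq_gain > 0))
    expect_lte(abs(first_gain - K / (1 + k)), 1 + 1e-9)
    # above the sign change, gains persist
    expect_true(all(freq_gain[(first_gain + 5):(K - 1)] > 0))
  }
})

test_that("well-mixed trajectories follow the threshold prediction", {
  hi <- well_mixed_trajectory(toxin_state(210, 40), 4)
  expect_equal(hi$D_after[1], 0)
  expect_true(all(hi$D_after == 0))
  expect_equal(attr(hi, "status"), "cheaters_extinct")
  # below threshold (20% < 1/3) cooperators lose frequency every episode
  lo <- well_mixed_trajectory(toxin_state(50, 200), 4)
  expect_equal(lo$C_after[1], 45)
  expect_equal(lo$D_after[1], 190)
  expect_true(all(lo$freq_after < lo$freq_before))
  # a heavy growth cost sinks cooperators starting just above 1/(1+k)
  expect_gt(critical_cooperator_frequency(0.1, 2, growth_cost = 0.6), 0.4)
  burdened <- well_mixed_trajectory(
    toxin_state(100, 150, growth_cost = 0.6), 6)
  expect_lt(tail(burdened$freq_before, 1), 100 / 250)
})

test_that("clustered rare cooperators expand on the lattice", {
  gains <- vapply(1:50, function(i) {
    lat <- lattice_trajectory(coop_frequency = 0.02,
                              placement = "clustered", seed = i)
    tail(lat$frequency, 1) > lat$frequency[1]
  }, logical(1))
  expect_gte(mean(gains), 0.9)
})

test_that("well-mixed lattice conditions eliminate rare cooperators", {
  finals <- vapply(1:10, function(i) {
    lat <- lattice_trajectory(30, 30, coop_frequency = 0.02,
                              placement = "mixed", kill_radius = Inf,
                              density_scope = "global", n_steps = 60,
                              seed = i)
    tail(lat$frequency, 1)
  }, numeric(1))
  expect_true(all(finals < 0.02))
})

test_that("structured beats unstructured killing at matched parameters", {
  paired <- vapply(1:10, function(i) {
    a <- lattice_trajectory(30, 30, coop_frequency = 0.02,
                            placement = "clustered", n_steps = 60, seed = i)
    b <- lattice_trajectory(30, 30, coop_frequency = 0.02,
                            placement = "mixed", kill_radius = Inf,
                            density_scope = "global", n_steps = 60, seed = i)
    c(tail(a$frequency, 1), tail(b$frequency, 1))
  }, numeric(2))
  expect_gte(mean(paired[1, ]), mean(paired[2, ]))
})

test_that("a cheater-free lattice fills with cooperators", {
  lat <- lattice_trajectory(15, 15, coop_frequency = 1, occupancy = 0.2,
                            n_steps = 40, seed = 1)
  expect_equal(tail(lat$frequency, 1), 1)
  fin <- lat$counts[nrow(lat$counts), ]
  expect_gt(fin$cooperators, 0.8 * 15 * 15)
})
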
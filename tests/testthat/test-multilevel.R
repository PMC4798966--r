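test_that("mechanism configuration validates ranges and records annotations", {
  cfg <- mechanism_config()
  expect_false(any(cfg$enabled[c("replication_advantage", "mito_fitness",
                                 "apoptosis_rule", "organism_fecundity")]))
  cfg2 <- mechanism_config(delta = 0.5, mitophagy_rate = 0.2,
                           mitophagy_selectivity = 0.8,
                           apoptosis_rule = function(h) h)
  expect_true(all(c("replication_advantage", "mitophagy_selectivity",
                    "apoptosis_rule") %in% cfg2$annotations$mechanism))
  ann <- mechanism_annotations()
  expect_equal(ann$classification[ann$mechanism == "mitophagy_selectivity"],
               "PC")
  expect_equal(ann$classification[ann$mechanism == "apoptosis_rule"], "PFF")
  expect_equal(ann$classification[ann$mechanism == "organism_fecundity"],
               "PFF")
  expect_error(mechanism_config(segregation_bias = 1.5))
  expect_error(mechanism_config(bottleneck_size = 10000), "exceeds")
})

test_that("the neutral hierarchy drifts without systematic trend", {
  cfg <- mechanism_config(n_organisms = 10, cells_per_organism = 2,
                          mitos_per_cell = 4, copies_per_mito = 10,
                          bottleneck_size = 8)
  final_h <- vapply(1:80, function(i) {
    run <- run_multilevel(cfg, h0 = 0.4, n_generations = 4, seed = i)
    tail(run$summary$mean_h, 1)
  }, numeric(1))
  se <- sd(final_h) / sqrt(length(final_h))
  expect_lt(abs(mean(final_h) - 0.4), 3 * se)
})

test_that("unopposed replication advantage drives dysfunctional takeover", {
  cfg <- mechanism_config(delta = 1, n_organisms = 10,
                          cells_per_organism = 2, mitos_per_cell = 4,
                          bottleneck_size = 8)
  drift <- vapply(1:40, function(i) {
    run <- run_multilevel(cfg, h0 = 0.3, n_generations = 6, seed = i)
    tail(run$summary$mean_h, 1)
  }, numeric(1))
  expect_gt(mean(drift), 0.3 + 3 * sd(drift) / sqrt(length(drift)))
})

test_that("a tight bottleneck with organism selection holds heteroplasmy down", {
  fec <- function(h) 3 * (1 - h) + 0.5
  base <- list(delta = 0.5, n_organisms = 12, cells_per_organism = 2,
               mitos_per_cell = 4, copies_per_mito = 10,
               organism_fecundity = fec)
  tight <- do.call(mechanism_config, c(base, bottleneck_size = 4))
  loose <- do.call(mechanism_config, c(base, bottleneck_size = 40))
  paired <- vapply(1:40, function(i) {
    a <- run_multilevel(tight, h0 = 0.3, n_generations = 8, seed = i)
    b <- run_multilevel(loose, h0 = 0.3, n_generations = 8, seed = i)
    c(tail(a$summary$mean_h, 1), tail(b$summary$mean_h, 1))
  }, numeric(2))
  expect_lt(mean(paired[1, ]), mean(paired[2, ]))
})

test_that("stationary heteroplasmy responds monotonically to each filter", {
  run_final <- function(cfg, seeds = 1:25)
    mean(vapply(seeds, function(i)
      tail(run_multilevel(cfg, 0.3, 6, seed = i)$summary$mean_h, 1),
      numeric(1)))
  base <- list(delta = 0.5, n_organisms = 10, cells_per_organism = 2,
               mitos_per_cell = 4, bottleneck_size = 8)
  h_plain <- run_final(do.call(mechanism_config, base))
  # stronger mitophagy selectivity lowers the one-generation mean response
  # (measured before the germline bottleneck injects transmission drift)
  mbase <- list(n_organisms = 10, cells_per_organism = 2,
                mitos_per_cell = 8, copies_per_mito = 5,
                bottleneck_size = 8, mitophagy_rate = 0.4)
  one_gen <- function(sel) mean(vapply(1:100, function(i)
    run_multilevel(do.call(mechanism_config,
                           c(mbase, mitophagy_selectivity = sel)),
                   0.5, 1, seed = i)$summary$mean_h[1], numeric(1)))
  expect_lt(one_gen(1), one_gen(0) - 0.01)
  # segregation bias plus apoptosis lowers mean h
  h_seg <- run_final(do.call(mechanism_config,
    c(base, segregation_bias = 0.8, apoptosis_rule = function(h) h^2)))
  expect_lt(h_seg, h_plain)
  # a larger replication advantage raises mean h
  base_hot <- base; base_hot$delta <- 2
  h_hot <- run_final(do.call(mechanism_config, base_hot))
  expect_gt(h_hot, h_plain)
})

test_that("organism-level Price accounting satisfies the identity", {
  cfg <- mechanism_config(delta = 0.5, bottleneck_size = 4,
                          n_organisms = 10, cells_per_organism = 2,
                          mitos_per_cell = 4,
                          organism_fecundity = function(h) 3 * (1 - h) + 0.5)
  run <- run_multilevel(cfg, h0 = 0.3, n_generations = 5, seed = 99)
  for (dec in run$price) {
    if (is.null(dec) || is.na(dec$residual)) next
    expect_lt(abs(dec$residual), 1e-9)
  }
  # organism fitness covaries positively with functional frequency
  expect_true(any(vapply(run$price, function(d) d$covariance_term,
                         numeric(1)) > 0))
})

test_that("multilevel runs are reproducible from the seed", {
  cfg <- mechanism_config(delta = 0.3, bottleneck_size = 5,
                          n_organisms = 8, cells_per_organism = 2,
                          mitos_per_cell = 4)
  a <- run_multilevel(cfg, 0.3, 4, seed = 5)
  b <- run_multilevel(cfg, 0.3, 4, seed = 5)
  expect_identical(a$summary, b$summary)
  c_ <- run_multilevel(cfg, 0.3, 4, seed = 6)
  expect_false(identical(a$summary, c_$summary))
})
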
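test_that("neutral replication preserves expected heteroplasmy", {
  set.seed(1)
  h <- replicate(3000, heteroplasmy(replicate_mtdna(mt_pool(20, 20),
                                                    delta = 0, target = 80)))
  # neutral urn: E[h] stays 0.5; per-replicate sd bounded by 0.5
  expect_lt(abs(mean(h) - 0.5), 3 * sd(h) / sqrt(length(h)))
  # absorbing states
  expect_equal(heteroplasmy(replicate_mtdna(mt_pool(0, 10), 1, 40)), 1)
  expect_equal(heteroplasmy(replicate_mtdna(mt_pool(10, 0), 1, 40)), 0)
  expect_error(replicate_mtdna(mt_pool(5, 5), 0, 4), "target")
})

test_that("advantaged replication matches the exact urn recursion", {
  # oracle: propagate the full distribution of the dysfunctional count
  # through the sequential weighted draws
  urn_expected_h <- function(f0, d0, delta, target) {
    probs <- setNames(1, as.character(d0))
    total <- f0 + d0
    while (total < target) {
      nxt <- numeric(0)
      for (dn in names(probs)) {
        d <- as.numeric(dn); f <- total - d
        pd <- d * (1 + delta) / (f + d * (1 + delta))
        add <- function(key, val) {
          nxt[key] <<- (if (is.na(nxt[key])) 0 else nxt[key]) + val
        }
        add(as.character(d + 1), probs[[dn]] * pd)
        add(as.character(d), probs[[dn]] * (1 - pd))
      }
      probs <- nxt
      total <- total + 1
    }
    sum(as.numeric(names(probs)) * probs) / target
  }
  expected <- urn_expected_h(50, 50, delta = 1, target = 200)
  expect_gt(expected, 0.5)   # the advantage must raise heteroplasmy
  set.seed(2)
  sims <- replicate(4000, heteroplasmy(replicate_mtdna(mt_pool(50, 50),
                                                       delta = 1,
                                                       target = 200)))
  expect_lt(abs(mean(sims) - expected), 3 * sd(sims) / sqrt(length(sims)))
})

test_that("fitness-coupled division enriches functional mtDNA", {
  # two-type branching oracle: expected organelle counts multiply by
  # 1 + fitness(f); with pure organelles the mtDNA fractions follow
  fit <- function(f) 0.2 + 0.6 * f
  set.seed(3)
  fracs <- replicate(600, {
    cl <- divide_mitochondria(pure_mito_cell(50, 50), fit)
    tot <- colSums(cl$mitos)
    tot[["functional"]] / sum(tot)
  })
  expected <- 50 * (1 + fit(1)) / (50 * (1 + fit(1)) + 50 * (1 + fit(0)))
  expect_lt(abs(mean(fracs) - expected), 3 * sd(fracs) / sqrt(length(fracs)))
  expect_gt(mean(fracs), 0.5)
  # constant fitness leaves composition unchanged in expectation
  set.seed(4)
  fracs0 <- replicate(600, {
    cl <- divide_mitochondria(pure_mito_cell(30, 30), function(f) 0.5)
    tot <- colSums(cl$mitos)
    tot[["functional"]] / sum(tot)
  })
  expect_lt(abs(mean(fracs0) - 0.5), 3 * sd(fracs0) / sqrt(length(fracs0)))
  # identical mitochondria: composition cannot change
  cl <- divide_mitochondria(pure_mito_cell(10, 0), function(f) 1, seed = 5)
  expect_equal(heteroplasmy(cl), 0)
  # capacity is enforced
  cl <- divide_mitochondria(pure_mito_cell(10, 10), function(f) 1,
                            capacity = 12, seed = 6)
  expect_lte(nrow(cl$mitos), 12)
})

test_that("selective mitophagy purges dysfunctional organelles", {
  # survival-odds closed form for pure organelles at rate r, selectivity s:
  # functional survive with 1 - r; dysfunctional odds r/(1-r) * (1 + s)
  r <- 0.5; s <- 1
  p_dys <- (r / (1 - r) * (1 + s)) / (1 + r / (1 - r) * (1 + s))
  set.seed(7)
  counts <- replicate(2000, {
    cl <- mitophagy(pure_mito_cell(50, 50), selectivity = s, rate = r)
    tot <- colSums(cl$mitos)
    c(tot[["functional"]], tot[["dysfunctional"]])
  })
  ef <- 50 * (1 - r) * 10
  ed <- 50 * (1 - p_dys) * 10
  expect_lt(abs(mean(counts[1, ]) - ef),
            3 * sd(counts[1, ]) / sqrt(ncol(counts)))
  expect_lt(abs(mean(counts[2, ]) - ed),
            3 * sd(counts[2, ]) / sqrt(ncol(counts)))
  # post-mitophagy heteroplasmy drops below 0.5
  expect_lt(mean(counts[2, ] / (counts[1, ] + counts[2, ])), 0.5)
  # zero selectivity is unbiased turnover: expected h unchanged
  set.seed(8)
  h0 <- replicate(2000, heteroplasmy(mitophagy(pure_mito_cell(40, 40),
                                               selectivity = 0, rate = 0.3)))
  expect_lt(abs(mean(h0, na.rm = TRUE) - 0.5),
            3 * sd(h0, na.rm = TRUE) / sqrt(length(h0)))
  # all-functional cells cannot change composition
  expect_equal(heteroplasmy(mitophagy(pure_mito_cell(20, 0), 1, 0.4,
                                      seed = 9)), 0)
})

test_that("asymmetric segregation splits heteroplasmy as the bias dictates", {
  # bias 1: favored daughter deterministically gets every functional mito
  dg <- asymmetric_inheritance(pure_mito_cell(6, 6), bias = 1, seed = 10)
  expect_equal(heteroplasmy(dg$favored), 0)
  expect_equal(heteroplasmy(dg$other), 1)
  # molecules conserved by the partition
  expect_equal(sum(dg$favored$mitos) + sum(dg$other$mitos), 120)
  # bias 0.5: expected counts in favored daughter are 0.75/0.25 splits
  set.seed(11)
  counts <- replicate(2000, {
    dd <- asymmetric_inheritance(pure_mito_cell(20, 20), bias = 0.5)
    tot <- colSums(dd$favored$mitos)
    c(tot[["functional"]], tot[["dysfunctional"]])
  })
  expect_lt(abs(mean(counts[1, ]) - 20 * 0.75 * 10),
            3 * sd(counts[1, ]) / sqrt(ncol(counts)))
  expect_lt(abs(mean(counts[2, ]) - 20 * 0.25 * 10),
            3 * sd(counts[2, ]) / sqrt(ncol(counts)))
  # bias 0: symmetric in expectation
  set.seed(12)
  diffs <- replicate(2000, {
    dd <- asymmetric_inheritance(pure_mito_cell(20, 20), bias = 0)
    sum(dd$favored$mitos[, 1]) - sum(dd$other$mitos[, 1])
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("apoptosis removes high-heteroplasmy cells as the rule dictates", {
  cells <- lapply(c(0.2, 0.5, 0.9), function(h)
    cell_state(rbind(c(10 * (1 - h), 10 * h))))
  surv <- apoptosis_filter(cells, function(h) as.numeric(h > 0.6), seed = 1)
  expect_equal(sort(heteroplasmy(surv)), c(0.2, 0.5))
  # rule == 0 is the identity
  expect_length(apoptosis_filter(cells, function(h) 0), 3)
  # logistic rule: survivor mean h matches the importance-weighted form
  rule <- function(h) 1 / (1 + exp(-8 * (h - 0.5)))
  hs <- rep(seq(0, 1, by = 0.05), each = 500)
  big <- lapply(hs, function(h) cell_state(rbind(c(20 - 20 * h, 20 * h))))
  set.seed(13)
  surv_h <- heteroplasmy(apoptosis_filter(big, rule))
  w <- 1 - rule(hs)
  expected <- sum(hs * w) / sum(w)
  expect_lt(abs(mean(surv_h) - expected),
            3 * sd(surv_h) / sqrt(length(surv_h)))
})

test_that("bottleneck variance follows the hypergeometric law", {
  pool <- mt_pool(5000, 5000)
  M <- 10000
  tr <- germline_transmission(pool, 10, 20000, seed = 14)
  v_exp <- 0.5 * 0.5 / 10 * (M - 10) / (M - 1)
  v_obs <- var(tr$founder_h)
  se <- v_exp * sqrt(2 / (20000 - 1))
  expect_lt(abs(v_obs - v_exp), 3 * se)
  # degenerate bottlenecks
  all_of_it <- germline_transmission(mt_pool(30, 10), 40, 50, seed = 15)
  expect_true(all(all_of_it$founder_h == 0.25))
  single <- germline_transmission(mt_pool(500, 500), 1, 200, seed = 16)
  expect_true(all(single$founder_h %in% c(0, 1)))
  expect_error(germline_transmission(mt_pool(5, 5), 11, 2), "exceeds")
})

test_that("selective import biases founder draws toward functional mtDNA", {
  set.seed(17)
  unbiased <- germline_transmission(mt_pool(500, 500), 10, 4000)
  biased <- germline_transmission(mt_pool(500, 500), 10, 4000,
                                  import_bias = 2)
  expect_lt(mean(biased$founder_h) + 3 * sd(biased$founder_h) / sqrt(4000),
            mean(unbiased$founder_h))
  # conservation: a founder draw has exactly the bottleneck size
  expect_true(all(rowSums(biased$founders) == 10))
})

test_that("amplification after the bottleneck reaches the adult copy number", {
  tr <- germline_transmission(mt_pool(100, 100), 5, 50, adult_size = 80,
                              delta = 0.5, seed = 18)
  expect_true(all(rowSums(tr$adults) == 80))
  # replication advantage raises mean adult h above mean founder h
  expect_gt(mean(tr$adults[, "dysfunctional"] / 80), mean(tr$founder_h) - 0.02)
})
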
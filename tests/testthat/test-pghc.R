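test_that("one-pass classification matches the rule-table oracle", {
  set.seed(31)
  for (i in 1:100) {
    st <- random_stats(n_pairs = sample(10:60, 1), seed = i)
    th <- thresholds(runif(1, 0, 2), runif(1), runif(1, 0.01, 1))
    part <- classify_once(st, th)
    oracle <- classify_oracle(st, th)
    expect_setequal(part$apgs, oracle$APG)
    expect_setequal(part$qpgs, oracle$QPG)
    expect_setequal(part$upgs, oracle$UPG)
    # conservation and disjointness
    all_ids <- c(part$apgs, part$qpgs, part$upgs)
    expect_identical(sort(all_ids), sort(st$pair_id))
  }
})

test_that("vacuous and unreachable thresholds hit the partition extremes", {
  st <- random_stats(30, seed = 2)
  all_in <- classify_once(st, thresholds(0, 0, 1))
  expect_length(all_in$apgs, 30)
  none <- classify_once(st, thresholds(max(st$mi_bits) + 1, 1, 1e-12))
  expect_length(none$apgs, 0)
  expect_length(none$qpgs, 0)
  expect_length(none$upgs, 30)
})

test_that("classification is idempotent at its own thresholds", {
  st <- random_stats(40, seed = 3)
  th <- thresholds(0.8, 0.5, 0.2)
  p1 <- classify_once(st, th)
  p2 <- classify_once(st, p1$thresholds_used)
  expect_identical(p1$apgs, p2$apgs)
  expect_identical(p1$qpgs, p2$qpgs)
  expect_identical(p1$upgs, p2$upgs)
})

test_that("lowering thresholds never shrinks the authentic group", {
  set.seed(32)
  st <- random_stats(60, seed = 4)
  for (i in 1:30) {
    mi <- runif(1, 0, 2); cc <- runif(1); p <- runif(1, 0.05, 1)
    hi <- classify_once(st, thresholds(mi, cc, p))
    lo <- classify_once(st, thresholds(mi * runif(1), cc * runif(1), p))
    expect_true(all(hi$apgs %in% lo$apgs))
  }
})

test_that("threshold iteration lands in the band and is deterministic", {
  st <- random_stats(276, seed = 5)
  st$p_value <- runif(276, 0, 0.08)  # most pairs significant at 0.05
  p1 <- pghc_iterate(st, target_fraction = c(0.25, 0.35))
  p2 <- pghc_iterate(st, target_fraction = c(0.25, 0.35))
  frac <- length(p1$apgs) / 276
  expect_identical(p1$status, "converged")
  expect_gte(frac, 0.25); expect_lte(frac, 0.35)
  # re-running is bit-identical
  expect_identical(p1$apgs, p2$apgs)
  expect_identical(p1$thresholds_used, p2$thresholds_used)
  expect_identical(p1$history, p2$history)
  # conservation at every recorded iteration
  with(p1$history, expect_true(all(apgs + qpgs + upgs == 276L)))
})

test_that("iteration respects a fixed point already inside the band", {
  st <- random_stats(100, seed = 6)
  st$p_value <- rep(0.01, 100)  # significance never binds here
  cent <- centroids(st)
  base <- classify_once(st, thresholds(cent$mi, min(1, cent$cor)))
  frac <- length(base$apgs) / 100
  part <- pghc_iterate(st, target_fraction = c(frac - 0.01, frac + 0.01))
  expect_identical(part$iterations, 0L)
  expect_equal(part$thresholds_used$mi_th, cent$mi)
})

test_that("a saturating band drives thresholds to the floor", {
  st <- random_stats(50, seed = 7)
  part <- pghc_iterate(st,
                       init = thresholds(0.5, 0.3, 1,
                                         delta_mi = 0.02,
                                         delta_cc = 0.02),
                       target_fraction = c(0.999, 1))
  expect_identical(part$status, "converged")
  expect_length(part$apgs, 50)
  expect_lte(part$thresholds_used$mi_th, 0.5)
})

test_that("iteration always terminates, even on impossible narrow bands", {
  st <- random_stats(20, seed = 8)
  # a band between attainable fractions forces a cycle, not a hang
  expect_warning(part <- pghc_iterate(st, target_fraction = c(0.401, 0.42),
                                      max_iter = 500),
                 "did not reach")
  expect_true(part$status %in% c("cycle", "cap", "exhausted", "boundary"))
  expect_identical(sort(c(part$apgs, part$qpgs, part$upgs)),
                   sort(st$pair_id))
})

test_that("questionable-pair ranking equals a comparison-sort oracle", {
  expect_identical(rank_qpgs(random_stats(10), character(0)),
                   character(0))
  set.seed(33)
  for (i in 1:100) {
    st <- random_stats(n_pairs = sample(5:40, 1), seed = 100 + i)
    ids <- sample(st$pair_id, sample(seq_len(nrow(st)), 1))
    got <- rank_qpgs(st, ids)
    sub <- st[st$pair_id %in% ids, ]
    # independent oracle: order by the documented key
    key <- order(-sub$am, sub$p_value, sub$pair_id)
    expect_identical(got, sub$pair_id[key])
  }
  # ties on am break by p, then id
  st <- random_stats(4, seed = 9)
  st$am <- c(0.9, 0.5, 0.9, 0.9)
  st$p_value <- c(0.2, 0.1, 0.2, 0.05)
  expect_identical(rank_qpgs(st),
                   c(st$pair_id[4], st$pair_id[1], st$pair_id[3],
                     st$pair_id[2]))
  expect_error(rank_qpgs(st, "NOPE|PAIR"), "not in statistics")
})

test_that("the P-value ladder returns the smallest sufficient rung", {
  st <- random_stats(120, seed = 10)
  st$p_value <- c(runif(72, 0, 0.05), runif(48, 0.5, 1))  # 60% below 0.05
  expect_equal(adapt_p_threshold(st, 0.4), 0.05)

  # only 10 of 120 significant: must climb above 0.05
  st$p_value <- c(runif(10, 0, 0.05), runif(110, 0.3, 1))
  expect_gt(adapt_p_threshold(st, 0.4), 0.05)

  # uniform p-values: the first rung with rung >= target fraction
  st$p_value <- seq(0, 1, length.out = 120)
  expect_equal(adapt_p_threshold(st, 0.4), 0.4)
  expect_equal(adapt_p_threshold(st, 0.95), 1)
})
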
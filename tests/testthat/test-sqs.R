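test_that("Good's coverage handles no-singleton, all-singleton and mixed bins", {
  expect_equal(goods_u(c(A = 5, B = 3, C = 2)), 1)
  expect_equal(goods_u(c(A = 1, B = 1)), 0)
  expect_equal(goods_u(c(A = 3, B = 1)), 0.75)
  expect_error(goods_u(numeric(0)), "empty bin")
})

test_that("a quorum of 1 with full coverage requires every genus", {
  counts <- c(A = 5, B = 3, C = 2)
  sq <- sqs_richness(counts, q = 1, trials = 20, seed = 1)
  expect_true(all(sq$richness == 3))
  expect_equal(sq$S_mean, 3)
})

test_that("an unreachable quorum (q > u) is an insufficient-coverage error", {
  expect_error(sqs_richness(c(A = 1, B = 1, C = 2), q = 0.8, seed = 1),
               "insufficient coverage")
})

test_that("trial-mean richness matches the exhaustive-ordering expectation", {
  # hand-checkable case: with counts {5,3,2}, q = 0.5, u = 1, the walk stops
  # at the first genus iff it is A (share 0.5, probability 5/10), else at the
  # second; expectation 1.5
  expect_equal(sqs_expected_richness(c(5, 3, 2), 0.5), 1.5)
  sq <- sqs_richness(c(A = 5, B = 3, C = 2), q = 0.5, trials = 4000, seed = 2)
  se <- sd(sq$richness) / sqrt(4000)
  expect_lt(abs(sq$S_mean - 1.5), 2 * se + 1e-9)

  # a second multiset with partial coverage (one singleton)
  counts <- c(A = 4, B = 2, C = 1, D = 1)
  ex <- sqs_expected_richness(counts, 0.55)
  sq2 <- sqs_richness(counts, q = 0.55, trials = 4000, seed = 3)
  se2 <- sd(sq2$richness) / sqrt(4000)
  expect_lt(abs(sq2$S_mean - ex), 3 * se2 + 1e-9)
})

test_that("per-trial richness never exceeds raw richness and grows with the quorum", {
  set.seed(4)
  counts <- table(sample(letters[1:8], 60, replace = TRUE, prob = 8:1))
  counts <- stats::setNames(as.numeric(counts), names(counts))
  sq <- sqs_richness(counts, q = 0.6, trials = 200, seed = 5)
  expect_true(all(sq$richness <= length(counts)))

  means <- vapply(c(0.2, 0.4, 0.6, 0.8),
                  function(q) sqs_richness(counts, q = q, trials = 400,
                                           seed = 6)$S_mean,
                  numeric(1))
  expect_true(all(diff(means) > -0.2)) # non-decreasing in expectation
  # at a vanishing quorum a single genus suffices
  expect_equal(sqs_richness(counts, q = 1e-6, trials = 50, seed = 7)$S_mean, 1)
})

test_that("three-timer counts match the hand-counted incidence example", {
  # A in bins {1,2,3}, B in {1,3}, C in {2}
  m <- matrix(FALSE, 3, 12, dimnames = list(c("A", "B", "C"), NULL))
  m["A", 1:3] <- TRUE
  m["B", c(1, 3)] <- TRUE
  m["C", 2] <- TRUE
  ctr <- three_timer_counts(m, 2)
  expect_equal(ctr[c("t3", "pt", "t2_bottom", "t2_top")],
               list(t3 = 1L, pt = 1L, t2_bottom = 1L, t2_top = 1L))
  expect_equal(ctr$P_s, 0.5)

  full <- matrix(TRUE, 5, 12)
  ctr2 <- three_timer_counts(full, 5)
  expect_equal(ctr2$pt, 0L)
  expect_equal(ctr2$P_s, 1)

  # an empty middle bin has no three-timers; every through-ranger is a
  # part-timer, so the sampling statistic collapses to zero
  hole <- full
  hole[, 6] <- FALSE
  ctr3 <- three_timer_counts(hole, 6)
  expect_equal(ctr3$t3, 0L)
  expect_equal(ctr3$P_s, 0)

  expect_error(three_timer_counts(full, 1), "edge")
  expect_error(three_timer_counts(full, 12), "edge")
})

test_that("three-timer count inequalities hold on random incidence matrices", {
  set.seed(8)
  for (i in 1:25) {
    m <- matrix(runif(40 * 12) < 0.5, 40, 12)
    j <- sample(2:11, 1)
    ctr <- three_timer_counts(m, j)
    expect_lte(ctr$t3, ctr$t2_bottom)
    expect_lte(ctr$t3, ctr$t2_top)
    if (!is.na(ctr$P_s)) expect_true(ctr$P_s >= 0 && ctr$P_s <= 1)
  }
})

test_that("turnover rates: range-through limit is zero, ratios give log rates, edges flag", {
  full <- matrix(TRUE, 6, 12)
  tr <- turnover_rates(full, 6)
  expect_equal(tr$lambda, 0)
  expect_equal(tr$mu, 0)

  # four two-timers die out, four background three-timers persist:
  # t2_bottom/t3 = 8/4 with perfect neighbour sampling, so mu = log 2
  m <- matrix(FALSE, 8, 12)
  m[1:4, 4:5] <- TRUE   # present in i-1 and i (i = 5), gone by i+1
  m[5:8, 3:8] <- TRUE   # background genera keeping neighbour P_s = 1
  ctr <- three_timer_counts(m, 5)
  expect_equal(ctr$t2_bottom, 8L)
  expect_equal(ctr$t3, 4L)
  tr2 <- turnover_rates(m, 5)
  expect_equal(tr2$mu, log(2))

  first <- turnover_rates(full, 2)
  expect_true(is.na(first$lambda))
  expect_match(paste(first$flags, collapse = " "), "older neighbour")
})

test_that("diversity_table flags thin bins and single-period data gets no rates", {
  occ <- as_genus_occurrences(data.frame(
    genus = rep(c("Aa", "Bb", "Cc", "Dd"), 8),
    host_class = "Bivalvia",
    max_ma = rep(100, 32), min_ma = rep(100, 32)
  ))
  dt <- diversity_table(occ, q = 0.6, trials = 20, seed = 1)
  expect_s3_class(dt, "diversity_table")
  expect_equal(nrow(dt), 12L)
  cret <- dt[dt$period == "Cretaceous", ]
  expect_false(is.na(cret$S_mean))
  expect_true(all(is.na(dt$lambda_3t)))
  expect_true(all(is.na(dt$mu_3t)))
  expect_true(all(is.na(dt$S_mean[dt$period != "Cretaceous"])))
})

test_that("doubling every genus's occurrence count leaves subsampled richness unchanged", {
  counts <- c(A = 6, B = 4, C = 3, D = 2, E = 2)
  s1 <- sqs_richness(counts, q = 0.6, trials = 3000, seed = 11)
  s2 <- sqs_richness(counts * 2, q = 0.6, trials = 3000, seed = 12)
  se <- sqrt(sd(s1$richness)^2 + sd(s2$richness)^2) / sqrt(3000)
  expect_lt(abs(s1$S_mean - s2$S_mean), 3 * se + 0.02)
})
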
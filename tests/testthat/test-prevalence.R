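eligible_records <- function(k, n, era = "Cenozoic", age = 10) {
  as_parasitism_records(data.frame(
    record_id = paste0("r", seq_along(k)),
    host_taxon = "sp", host_phylum = "Mollusca", host_class = "Bivalvia",
    parasite_phylum = "unknown", certainty = 1L,
    n_specimens = n, n_infested = k,
    best_age_ma = age,
    period = assign_interval(age)$period,
    era = assign_interval(age)$era,
    reference_id = "ref", stringsAsFactors = FALSE
  ))
}

test_that("prevalence is the exact infested fraction, including 0 and 1", {
  pv <- occurrence_prevalence(eligible_records(k = c(5, 0, 10), n = c(50, 10, 10)))
  expect_equal(pv$p, c(0.10, 0, 1))
  expect_error(
    occurrence_prevalence(eligible_records(k = c(5, NA), n = c(50, NA))),
    "ineligible"
  )
})

test_that("per-Myr rates reproduce the worked-example era rates at 2 decimals", {
  expect_equal(round(per_myr_rate(481, 289), 2), 1.66)
  expect_equal(round(per_myr_rate(492, 185), 2), 2.66)
  expect_equal(round(per_myr_rate(451, 66), 2), 6.83)
  expect_equal(round(per_myr_rate(117, 66), 2), 1.77)
  expect_equal(per_myr_rate(0, 66), 0)
  expect_error(per_myr_rate(10, 0), "positive")
})

test_that("bootstrap median CI is degenerate for constant data and reproducible", {
  ci <- bootstrap_median_ci(rep(0.1, 20), B = 200, seed = 5)
  expect_equal(as.numeric(ci), c(0.1, 0.1))

  x <- c(0.02, 0.08, 0.05, 0.11, 0.01, 0.3, 0.07)
  a <- bootstrap_median_ci(x, B = 500, seed = 42)
  b <- bootstrap_median_ci(x, B = 500, seed = 42)
  expect_identical(a, b)
  expect_true(a[["ci_low"]] <= median(x) && median(x) <= a[["ci_high"]])

  expect_error(bootstrap_median_ci(numeric(0)), "nonempty")
  expect_error(bootstrap_median_ci(x, B = 0), "at least 1")
})

test_that("Mann-Whitney U: exact small-sample p, symmetry, and complementarity", {
  # enumeration oracle: all 6 rank arrangements of sizes (2,2); both x-values
  # below both y-values is one of 6, two-sided doubles it
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$p, 1 / 3)
  expect_equal(mw$method, "exact")

  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(3:15, 1))
    y <- rnorm(sample(3:15, 1))
    a <- mann_whitney_u(x, y)
    b <- mann_whitney_u(y, x)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    expect_equal(a$U + b$U, length(x) * length(y))
  }
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("exact and normal-approximation branches agree within 0.02 on sizes 9-12", {
  set.seed(31)
  for (i in 1:30) {
    x <- rnorm(sample(9:12, 1))
    y <- rnorm(sample(9:12, 1))
    ex <- mann_whitney_u(x, y, method = "exact")
    no <- mann_whitney_u(x, y, method = "normal")
    expect_lt(abs(ex$p - no$p), 0.02)
  }
  expect_error(mann_whitney_u(c(1, 1, 2), c(2, 3), method = "exact"), "ties")
})

test_that("era summary reports medians, CIs, per-Myr rates and pairwise tests", {
  recs <- rbind(
    eligible_records(k = c(2, 5, 8), n = rep(100, 3), age = 300),
    eligible_records(k = c(1, 3, 9, 12), n = rep(100, 4), age = 150),
    eligible_records(k = c(10, 11), n = rep(100, 2), age = 10)
  )
  pv <- occurrence_prevalence(recs)
  es <- era_summary_table(pv, B = 300, seed = 7)
  s <- es$summary

  expect_equal(s$era, c("Paleozoic", "Mesozoic", "Cenozoic"))
  expect_equal(s$median_p, c(0.05, 0.06, 0.105))
  expect_equal(s$n_values, c(3L, 4L, 2L))
  expect_equal(s$obs_per_myr, c(3 / 289, 4 / 185, 2 / 66))
  expect_true(all(s$ci_low <= s$median_p & s$median_p <= s$ci_high))
  expect_equal(nrow(es$pairwise), 3L)

  # median is invariant to the order of values
  perm <- pv[sample(nrow(pv)), ]
  es2 <- era_summary_table(perm, B = 300, seed = 7)
  expect_equal(es2$summary$median_p, s$median_p)

  # an era with no values yields a flagged row, not an error
  pv_no_cen <- pv[pv$era != "Cenozoic", ]
  es3 <- era_summary_table(pv_no_cen, B = 300, seed = 7)
  expect_equal(es3$summary$flag[3], "no values")
  expect_true(is.na(es3$summary$median_p[3]))
})
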
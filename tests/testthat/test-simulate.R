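test_that("zero extinction carries every genus to the youngest bin; zero turnover is constant", {
  p0 <- sim_params(n0 = 40, mu_myr = 0, lambda_myr = 0,
                   diversity_profile = NULL)
  r <- simulate_taxon_history(p0, seed = 1)
  expect_true(all(r$last_bin == 12L))
  expect_equal(attr(r, "richness"), rep(40, 12))

  expect_warning(empty <- simulate_taxon_history(sim_params(n0 = 0), seed = 1),
                 "empty starting pool")
  expect_equal(nrow(empty), 0L)
})

test_that("final richness matches the branching-process mean within 3 SE over 200 replicates", {
  p <- sim_params(n0 = 60, lambda_myr = 0.004, mu_myr = 0.004,
                  diversity_profile = NULL, env_sd = 0.2)
  finals <- vapply(1:200, function(s) {
    attr(simulate_taxon_history(p, seed = s), "richness")[12]
  }, numeric(1))
  expected <- attr(simulate_taxon_history(p, seed = 1), "expected_richness")[12]
  se <- sd(finals) / sqrt(200)
  expect_lt(abs(mean(finals) - expected), 3 * se)
})

test_that("profile-driven histories track the configured diversity trajectory", {
  p <- sim_params(n0 = 150, env_sd = 0)
  r <- simulate_taxon_history(p, seed = 3)
  rich <- attr(r, "richness")
  prof <- attr(r, "expected_richness")
  # correlated shape, several-fold dynamic range, Quaternary above Cambrian
  expect_gt(cor(rich, prof), 0.9)
  expect_gt(max(rich) / min(rich), 2)
})

test_that("sampling respects ranges, bins and the intensity limits", {
  p <- sim_params(n0 = 30, sampling_intensity = 3)
  r <- simulate_taxon_history(p, seed = 2)
  occ <- simulate_sampling(r, p, seed = 2)
  expect_s3_class(occ, "genus_occurrences")
  expect_false(any(occ$age_ambiguous))
  ts <- load_timescale()
  bin <- match(occ$period, ts$name)
  g <- match(occ$genus, r$genus)
  expect_true(all(bin >= r$first_bin[g] & bin <= r$last_bin[g]))

  none <- simulate_sampling(r, sim_params(sampling_intensity = 0), seed = 2)
  expect_equal(nrow(none), 0L)
})

test_that("fixed seeds give identical outputs and do not disturb the caller's RNG", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  b1 <- scenario_bundle("neutral", "tiny", seed = 4)
  after <- runif(1)
  expect_identical(before, after)
  b2 <- scenario_bundle("neutral", "tiny", seed = 4)
  expect_identical(b1$parasitism, b2$parasitism)
  expect_identical(b1$occurrences, b2$occurrences)
})

test_that("with no diversity link the pooled prevalence sits at the link intercept", {
  p <- sim_params(b = 0, sigma_h = 0, n_analytical = 600, n_category4 = 0,
                  n_eligible = 500,
                  occ_weights = stats::setNames(rep(1, 12), load_timescale()$name))
  par <- simulate_parasitism(NULL, p, seed = 5)
  el <- select_prevalence_eligible(filter_analytical(par), 10)
  pooled <- sum(el$n_infested) / sum(el$n_specimens)
  n_tot <- sum(el$n_specimens)
  se <- sqrt(0.06 * 0.94 / n_tot)
  expect_lt(abs(pooled - plogis(qlogis(0.06))), 4 * se)
})

test_that("a positive richness link makes observed per-bin prevalence track true richness", {
  b <- scenario_bundle("amplification", "paper", seed = 6)
  pv <- occurrence_prevalence(select_prevalence_eligible(
    filter_analytical(b$parasitism), 10))
  per_bin <- tapply(pv$k, pv$period, sum) / tapply(pv$n, pv$period, sum)
  rich <- b$truth$richness[match(names(per_bin), b$truth$period)]
  expect_gt(cor(per_bin, rich, use = "complete.obs"), 0.5)
  # and the recorded truth exposes the generating prevalence law
  expect_true(all(b$truth$pi > 0 & b$truth$pi < 1))
})

test_that("scenario bundles have the preset row counts exactly and validate cleanly", {
  b <- emulate_published_database(seed = 7)
  expect_equal(nrow(b$parasitism), 2118L)
  a <- filter_analytical(b$parasitism)
  expect_equal(nrow(a), 1424L)
  expect_equal(as.vector(table(factor(a$era,
    c("Paleozoic", "Mesozoic", "Cenozoic")))), c(481L, 492L, 451L))
  el <- select_prevalence_eligible(a, 10)
  expect_equal(nrow(el), 373L)
  expect_equal(as.vector(table(factor(el$era,
    c("Paleozoic", "Mesozoic", "Cenozoic")))), c(112L, 144L, 117L))
  # emitted tables pass the package's own validation with zero errors
  expect_equal(nrow(attr(b$parasitism, "validation")), 0L)
  expect_equal(nrow(attr(b$occurrences, "validation")), 0L)

  expect_error(scenario_bundle("upside-down", "tiny"), "arg")
})

test_that("bundle files round-trip through the readers", {
  dir <- withr::local_tempdir()
  b <- scenario_bundle("neutral", "tiny", seed = 8, dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("parasitism.csv", "occurrences.csv", "truth.json")))))
  rec <- read_parasitism_table(file.path(dir, "parasitism.csv"))
  expect_equal(nrow(rec), nrow(b$parasitism))
  expect_equal(nrow(attr(rec, "validation")), 0L)
  occ <- read_occurrence_table(file.path(dir, "occurrences.csv"))
  expect_equal(nrow(occ), nrow(b$occurrences))
})
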
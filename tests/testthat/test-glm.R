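test_that("intercept-only fits reproduce closed forms to 1e-8", {
  # Poisson: intercept = log of the (weighted) mean
  f1 <- fit_parasitism_glm(y ~ 1, data.frame(y = c(1, 2, 3)), "poisson")
  expect_equal(unname(coef(f1)), log(2), tolerance = 1e-8)

  f2 <- fit_parasitism_glm(y ~ 1, data.frame(y = c(0, 4)), "poisson",
                           weights = c(1, 3))
  expect_equal(unname(coef(f2)), log(3), tolerance = 1e-8)

  # binomial: intercept = empirical logit
  f3 <- fit_parasitism_glm(cbind(k, n - k) ~ 1,
                           data.frame(k = 30, n = 100, extra = 1), "binomial")
  expect_equal(unname(coef(f3)), qlogis(0.3), tolerance = 1e-8)
})

test_that("coefficients are invariant to weight scale; raw-weight SEs shrink as expected", {
  set.seed(21)
  d <- data.frame(y = rpois(40, 5), x = rnorm(40))
  w <- runif(40, 0.5, 3)
  a <- fit_parasitism_glm(y ~ x, d, "poisson", weights = w,
                          normalize_weights = FALSE)
  b <- fit_parasitism_glm(y ~ x, d, "poisson", weights = 2 * w,
                          normalize_weights = FALSE)
  expect_equal(coef(a), coef(b), tolerance = 1e-8)
  se_a <- sqrt(diag(vcov(a, "model")))
  se_b <- sqrt(diag(vcov(b, "model")))
  expect_equal(se_a / se_b, rep(sqrt(2), 2), tolerance = 1e-8,
               ignore_attr = TRUE)

  # normalized weights make the fit invariant to scale entirely
  a2 <- fit_parasitism_glm(y ~ x, d, "poisson", weights = w)
  b2 <- fit_parasitism_glm(y ~ x, d, "poisson", weights = 2 * w)
  expect_equal(coef(a2), coef(b2), tolerance = 1e-10)
  expect_equal(vcov(a2, "model"), vcov(b2, "model"), tolerance = 1e-8)
})

test_that("deviance is non-increasing as predictors are added", {
  set.seed(22)
  d <- data.frame(y = rpois(30, 4), x1 = rnorm(30), x2 = rnorm(30))
  d0 <- fit_parasitism_glm(y ~ 1, d, "poisson")$fit$deviance
  d1 <- fit_parasitism_glm(y ~ x1, d, "poisson")$fit$deviance
  d2 <- fit_parasitism_glm(y ~ x1 + x2, d, "poisson")$fit$deviance
  expect_lte(d1, d0 + 1e-10)
  expect_lte(d2, d1 + 1e-10)
})

test_that("Wald summary applies the documented significance codes", {
  expect_equal(sig_code(c(1, 0.089, 0.03, 0.002, 0.0002)),
               c("", "#", "*", "**", "***"))
  # z = 1.7 is marginal at the p < 0.10 convention
  expect_equal(round(2 * pnorm(-1.7), 3), 0.089)

  set.seed(23)
  d <- data.frame(y = rpois(50, 6), x = rnorm(50))
  tab <- wald_summary(fit_parasitism_glm(y ~ x, d, "poisson"))
  expect_named(tab, c("term", "estimate", "se", "z", "p", "code"))
  expect_equal(tab$z, tab$estimate / tab$se)
  expect_equal(tab$p, 2 * pnorm(-abs(tab$z)))
})

test_that("a single-period prevalence design is reported as rank-deficient", {
  pv <- data.frame(record_id = 1:25, p = 0.1, n = rep(50, 25), k = rep(5, 25),
                   era = "Mesozoic", period = "Jurassic",
                   best_age_ma = runif(25, 145, 201),
                   host_phylum = "Mollusca", host_class = "Bivalvia")
  divtab <- data.frame(period = "Jurassic", midpoint_ma = 173.15,
                       S_mean = 50, lambda_3t = 0.2, mu_3t = 0.3)
  expect_warning(fit <- prevalence_model(pv, divtab), "rank-deficient")
  expect_false(fit$converged)
  expect_true(fit$rank_deficient)
})

test_that("too few usable rows or periods refuse to fit with a clear message", {
  divtab <- data.frame(period = c("Jurassic", "Cretaceous"),
                       midpoint_ma = c(173.15, 105.5),
                       S_mean = c(50, 60), lambda_3t = c(0.2, 0.1),
                       mu_3t = c(0.3, 0.2))
  recs <- data.frame(period = rep("Jurassic", 10), n_specimens = 50)
  expect_error(occurrence_model(recs, divtab), "at least 6")

  pv <- data.frame(record_id = 1:5, p = 0.1, n = 50, k = 5,
                   era = "Mesozoic", period = "Jurassic",
                   best_age_ma = 170, host_phylum = "x", host_class = "x")
  expect_error(prevalence_model(pv, divtab), "at least 20")
})

test_that("the amplification/dilution classifier follows the documented rule", {
  tab <- function(sS, pS, sL = 0.1, pL = 0.5, sM = -0.1, pM = 0.5) {
    data.frame(term = c("(Intercept)", "S_mean", "lambda_3t", "mu_3t", "age"),
               estimate = c(1, sS, sL, sM, 0),
               se = 1, z = 1,
               p = c(0.5, pS, pL, pM, 0.9),
               code = "", stringsAsFactors = FALSE)
  }
  expect_equal(classify_support(tab(0.003, 1e-4))$call, "amplification")
  expect_equal(classify_support(tab(-0.02, 1e-4))$call, "dilution")
  expect_equal(classify_support(tab(0.001, 0.8))$call, "unclear")
  # positive origination with negative extinction, one significant
  expect_equal(classify_support(tab(0.001, 0.8, sL = 1, pL = 0.01))$call,
               "amplification")
  # significantly positive extinction coefficient implies dilution
  expect_equal(classify_support(tab(0.001, 0.8, sM = 3, pM = 0.01))$call,
               "dilution")
  # marginal-only S_mean gives a flagged marginal call
  m <- classify_support(tab(-0.02, 0.07))
  expect_equal(m$call, "dilution")
  expect_true(m$marginal)
  expect_true(all(classify_support(tab(0.003, 1e-4))$mechanism$term != "(Intercept)"))
})
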
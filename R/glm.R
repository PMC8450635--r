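# Weighted Poisson / binomial GLMs relating parasitism to diversity indices,
# Wald summaries with significance codes, and the amplification/dilution
# classifier.

#' Fit a weighted Poisson or binomial GLM
#'
#' The workhorse behind [occurrence_model()] and [prevalence_model()]. Fits by
#' iteratively reweighted least squares (via [stats::glm()]) to relative
#' tolerance 1e-10 within 100 iterations. `log10(specimens)` enters as an
#' analytic (precision) weight; by default weights are rescaled to mean 1,
#' which leaves the coefficients exactly unchanged (weight-scale invariance)
#' while keeping the nominal information at the actual sample size. Set
#' `normalize_weights = FALSE` for raw prior weights (then doubling all
#' weights halves squared standard errors).
#'
#' @param formula Model formula. For a binomial fit the response may be a
#'   two-column matrix `cbind(k, n - k)`.
#' @param data Data frame of model rows; rows with missing variables are
#'   dropped and their count recorded.
#' @param family `"poisson"` (log link) or `"binomial"` (logit link).
#' @param weights Optional numeric vector of positive weights (one per row of
#'   `data`), or `NULL` for an unweighted fit.
#' @param normalize_weights Rescale weights to mean 1 (default `TRUE`).
#' @return An object of class `parasite_glm` wrapping the [stats::glm] fit,
#'   with elements `fit`, `family`, `weighted`, `n_rows`, `n_dropped`,
#'   `converged`, and the weight vector used.
#' @seealso [wald_summary()], [classify_support()]
#' @export
fit_parasitism_glm <- function(formula, data, family = c("poisson", "binomial"),
                               weights = NULL, normalize_weights = TRUE) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data))
  if (!is.null(weights) && length(weights) != nrow(data)) {
    stop("`weights` must have one value per row of `data`", call. = FALSE)
  }
  vars <- all.vars(formula)
  use <- stats::complete.cases(data[, intersect(vars, names(data)), drop = FALSE])
  if (!is.null(weights)) use <- use & !is.na(weights) & is.finite(weights)
  n_dropped <- sum(!use)
  data <- data[use, , drop = FALSE]
  w <- if (is.null(weights)) NULL else weights[use]
  if (!is.null(w) && any(w <= 0)) {
    stop("weights must be positive", call. = FALSE)
  }
  if (!is.null(w) && normalize_weights) w <- w / mean(w)

  fam <- if (family == "poisson") stats::poisson("log") else stats::binomial("logit")
  env <- list2env(list(.paleoprev_w = w), parent = environment(formula))
  environment(formula) <- env
  fit <- suppressWarnings(stats::glm(
    formula, data = data, family = fam,
    weights = .paleoprev_w,
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  ))
  p <- length(stats::coef(fit))
  if (nrow(data) < p) {
    stop("too few rows (", nrow(data), ") for ", p, " coefficients",
         call. = FALSE)
  }
  rank_deficient <- fit$rank < p || anyNA(stats::coef(fit))
  if (rank_deficient) {
    warning("rank-deficient design: some coefficients are not estimable",
            call. = FALSE)
  }
  out <- list(fit = fit, family = family, weighted = !is.null(w),
              weights = w, normalize_weights = normalize_weights,
              n_rows = nrow(data), n_dropped = n_dropped,
              converged = fit$converged && !rank_deficient,
              rank_deficient = rank_deficient)
  class(out) <- "parasite_glm"
  out
}

#' @export
coef.parasite_glm <- function(object, ...) stats::coef(object$fit)

#' @export
predict.parasite_glm <- function(object, ...) stats::predict(object$fit, ...)

#' @export
residuals.parasite_glm <- function(object, ...) stats::residuals(object$fit, ...)

#' Covariance matrix of a fitted parasitism GLM
#'
#' @param object A `parasite_glm`.
#' @param type `"model"` for the model-based (inverse Fisher information)
#'   covariance with dispersion fixed at 1, or `"robust"` for the
#'   heteroscedasticity-consistent sandwich estimator (HC0), which stays
#'   calibrated when analytic weights are correlated with sample size.
#' @param ... Unused.
#' @export
vcov.parasite_glm <- function(object, type = c("model", "robust"), ...) {
  type <- match.arg(type)
  if (type == "model") {
    s <- summary(object$fit, dispersion = 1)
    s$cov.scaled
  } else {
    sandwich::vcovHC(object$fit, type = "HC3")
  }
}

#' Significance codes used in coefficient tables
#'
#' `#` for p < 0.10 (marginal), `*` < 0.05, `**` < 0.01, `***` < 0.001.
#' @param p Numeric vector of p-values.
#' @return Character vector of codes (empty string for p >= 0.10).
#' @export
sig_code <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
      labels = c("***", "**", "*", "#", ""), right = FALSE) |> as.character()
}

#' Wald coefficient table with significance codes
#'
#' `z = beta / SE`, two-sided normal p-values, coded `#` (p < 0.10, marginal),
#' `*` (< 0.05), `**` (< 0.01), `***` (< 0.001).
#'
#' @param fit A `parasite_glm` (must have converged).
#' @param vcov_type `"model"` or `"robust"`; see [vcov.parasite_glm()].
#' @return Data frame with `term`, `estimate`, `se`, `z`, `p`, `code`.
#' @export
wald_summary <- function(fit, vcov_type = c("model", "robust")) {
  stopifnot(inherits(fit, "parasite_glm"))
  vcov_type <- match.arg(vcov_type)
  if (!fit$fit$converged) stop("fit did not converge", call. = FALSE)
  b <- stats::coef(fit$fit)
  V <- vcov(fit, type = vcov_type)
  se <- sqrt(diag(V))
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(term = names(b), estimate = unname(b), se = unname(se),
             z = unname(z), p = unname(p), code = sig_code(p),
             stringsAsFactors = FALSE)
}

#' @export
print.parasite_glm <- function(x, ...) {
  cat("Weighted", x$family, "GLM",
      if (x$weighted) "(log10-specimen weights)" else "(unweighted)", "\n")
  cat("rows:", x$n_rows,
      if (x$n_dropped) paste0("(", x$n_dropped, " dropped: missing values)"),
      "\n")
  print(stats::coef(x$fit))
  invisible(x)
}

#' @export
summary.parasite_glm <- function(object, vcov_type = "model", ...) {
  tab <- wald_summary(object, vcov_type = vcov_type)
  cat(if (object$weighted) "Weighted " else "Unweighted ", object$family,
      " GLM — Wald summary (", vcov_type, " covariance)\n", sep = "")
  tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 3)
  tab$z <- round(tab$z, 2)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat("residual deviance:", signif(object$fit$deviance, 5),
      "on", object$fit$df.residual, "df\n")
  invisible(tab)
}

#' Per-period occurrence model
#'
#' Poisson (log link) GLM of the number of analytical (certainty 1-3)
#' parasitized host occurrences per geologic period against the period-level
#' SQS diversity indices (`S_mean`, `lambda_3t`, `mu_3t`) and the period
#' midpoint age, weighted by log10 of the total reported specimens per period
#' when sample sizes are available (otherwise unweighted, annotated like the
#' `#` footnote convention for inadequately sampled groups). Periods with any
#' missing predictor are dropped and recorded.
#'
#' @param records Analytical `parasitism_records` (after
#'   [filter_analytical()]).
#' @param divtab A `diversity_table` for the matching host group.
#' @param weighted Use log10 specimen-total weights when available (default
#'   `TRUE`).
#' @return A `parasite_glm` with extra fields `model_frame` and
#'   `dropped_periods`.
#' @export
occurrence_model <- function(records, divtab, weighted = TRUE) {
  stopifnot(is.data.frame(records), is.data.frame(divtab))
  counts <- table(factor(records$period, levels = divtab$period))
  spec_tot <- tapply(records$n_specimens, factor(records$period, levels = divtab$period),
                     function(x) sum(x, na.rm = TRUE))
  spec_tot[is.na(spec_tot)] <- 0
  mf <- data.frame(period = divtab$period,
                   count = as.numeric(counts),
                   S_mean = divtab$S_mean,
                   lambda_3t = divtab$lambda_3t,
                   mu_3t = divtab$mu_3t,
                   age = divtab$midpoint_ma,
                   specimens = as.numeric(spec_tot),
                   stringsAsFactors = FALSE)
  complete <- stats::complete.cases(mf[, c("S_mean", "lambda_3t", "mu_3t", "age")])
  dropped <- mf$period[!complete]
  n_complete <- sum(complete)
  if (n_complete < 6) {
    stop("only ", n_complete,
         " periods with complete predictors; at least 6 required", call. = FALSE)
  }
  w <- NULL
  if (weighted) {
    cand <- log10(mf$specimens)
    if (all(is.finite(cand[complete])) && all(cand[complete] > 0)) {
      w <- cand
    } else {
      weighted <- FALSE
    }
  }
  fit <- fit_parasitism_glm(count ~ S_mean + lambda_3t + mu_3t + age,
                            data = mf, family = "poisson", weights = w)
  fit$model_frame <- mf
  fit$dropped_periods <- dropped
  fit$weighted <- weighted
  fit
}

#' Per-occurrence prevalence model
#'
#' Binomial (logit link) GLM of infested vs uninfested specimens per eligible
#' occurrence against the host group's period-level SQS diversity indices and
#' the record's best age estimate, weighted by log10 of the record's specimen
#' count. Records falling in periods with missing predictors are dropped and
#' counted. By default the Wald covariance reported by
#' [wald_summary()]/[classify_support()] for this model is the sandwich
#' (robust) estimator: the analytic weights are correlated with sample size,
#' under which the model-based covariance is anticonservative.
#'
#' @param prevalence Data frame from [occurrence_prevalence()] on eligible
#'   records.
#' @param divtab A `diversity_table` for the matching host group.
#' @param min_records Minimum usable records (default 20).
#' @return A `parasite_glm` with extra fields `model_frame` and
#'   `default_vcov = "robust"`.
#' @export
prevalence_model <- function(prevalence, divtab, min_records = 20) {
  stopifnot(is.data.frame(prevalence), is.data.frame(divtab))
  idx <- match(prevalence$period, divtab$period)
  mf <- data.frame(k = prevalence$k,
                   n = prevalence$n,
                   S_mean = divtab$S_mean[idx],
                   lambda_3t = divtab$lambda_3t[idx],
                   mu_3t = divtab$mu_3t[idx],
                   age = prevalence$best_age_ma,
                   stringsAsFactors = FALSE)
  complete <- stats::complete.cases(mf)
  if (sum(complete) < min_records) {
    stop("only ", sum(complete), " usable prevalence records; at least ",
         min_records, " required", call. = FALSE)
  }
  w <- log10(mf$n)
  fit <- fit_parasitism_glm(cbind(k, n - k) ~ S_mean + lambda_3t + mu_3t + age,
                            data = mf, family = "binomial", weights = w)
  fit$model_frame <- mf
  fit$default_vcov <- "robust"
  fit
}

#' Classify a coefficient table as amplification, dilution, or unclear
#'
#' Documented default rule applied to a Wald coefficient table over the terms
#' `S_mean`, `lambda_3t`, `mu_3t`:
#' * amplification — the `S_mean` coefficient is significant (p < `alpha`)
#'   and positive, or the origination coefficient is positive and the
#'   extinction coefficient negative with at least one of the two significant;
#' * dilution — `S_mean` significant and negative, or `mu_3t` significant and
#'   positive;
#' * unclear — no term reaches p < 0.10.
#' Calls reached only through marginal terms (0.05 <= p < 0.10) are flagged
#' `marginal`. The mechanism notes list every term with p < 0.10 and its sign.
#'
#' @param x A `parasite_glm` or a Wald table from [wald_summary()].
#' @param alpha Significance threshold (default 0.05); p < 0.10 counts as
#'   marginal.
#' @param group Optional host-group label carried into the result.
#' @param vcov_type Covariance used when `x` is a fit; defaults to the fit's
#'   `default_vcov` or `"model"`.
#' @return Object of class `hypothesis_call`: list with `group`, `call`,
#'   `marginal`, `mechanism` (data frame of signed significant terms), and the
#'   full `table`.
#' @export
classify_support <- function(x, alpha = 0.05, group = "all", vcov_type = NULL) {
  tab <- if (inherits(x, "parasite_glm")) {
    wald_summary(x, vcov_type = vcov_type %||% x$default_vcov %||% "model")
  } else x
  stopifnot(all(c("term", "estimate", "p") %in% names(tab)))
  get <- function(term) {
    i <- match(term, tab$term)
    if (is.na(i)) list(est = NA_real_, p = NA_real_)
    else list(est = tab$estimate[i], p = tab$p[i])
  }
  S <- get("S_mean"); L <- get("lambda_3t"); M <- get("mu_3t")
  sig <- function(t, a = alpha) !is.na(t$p) && t$p < a
  marg <- function(t) !is.na(t$p) && t$p < 0.1

  call <- "unclear"; marginal <- FALSE
  if (sig(S) && S$est > 0) {
    call <- "amplification"
  } else if (!is.na(L$est) && !is.na(M$est) && L$est > 0 && M$est < 0 &&
             (sig(L) || sig(M))) {
    call <- "amplification"
  } else if (sig(S) && S$est < 0) {
    call <- "dilution"
  } else if (sig(M) && M$est > 0) {
    call <- "dilution"
  } else if (marg(S)) {
    call <- if (S$est > 0) "amplification" else "dilution"
    marginal <- TRUE
  } else if (marg(M) && M$est > 0) {
    call <- "dilution"; marginal <- TRUE
  }
  terms <- tab[!is.na(tab$p) & tab$p < 0.1 & tab$term != "(Intercept)", ,
               drop = FALSE]
  mech <- data.frame(term = terms$term,
                     sign = ifelse(terms$estimate > 0, "+", "-"),
                     p = terms$p, code = sig_code(terms$p),
                     stringsAsFactors = FALSE)
  out <- list(group = group, call = call, marginal = marginal,
              mechanism = mech, table = tab, alpha = alpha)
  class(out) <- "hypothesis_call"
  out
}

#' @export
print.hypothesis_call <- function(x, ...) {
  cat(x$group, ": ", x$call,
      if (x$marginal) " (marginal)", "\n", sep = "")
  if (nrow(x$mechanism)) {
    cat("mechanism: ",
        paste0("(", x$mechanism$sign, ") ", x$mechanism$term,
               x$mechanism$code, collapse = "; "), "\n", sep = "")
  } else {
    cat("mechanism: no significant relationships\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
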
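# Prevalence statistics: per-occurrence prevalence, per-Myr rates, bootstrap
# confidence intervals for medians, Mann-Whitney comparisons, era summaries.

#' Per-occurrence parasite prevalence
#'
#' Prevalence is the proportion of individuals in a sample bearing evidence of
#' parasitism, `p = n_infested / n_specimens`, computed for every record of an
#' eligible set (see [select_prevalence_eligible()]). Values are kept at full
#' precision; rounding happens only in printed summaries.
#'
#' @param records A `parasitism_records` data frame in which every row has
#'   `n_specimens` and `n_infested` present.
#' @return A data frame with `record_id`, `p`, `n`, `k`, `era`, `period`,
#'   `best_age_ma`, `host_phylum`, `host_class`.
#' @export
occurrence_prevalence <- function(records) {
  stopifnot(is.data.frame(records))
  if (anyNA(records$n_specimens) || anyNA(records$n_infested)) {
    stop("records with missing specimen counts are ineligible for prevalence",
         call. = FALSE)
  }
  if (any(records$n_infested > records$n_specimens)) {
    stop("n_infested exceeds n_specimens", call. = FALSE)
  }
  data.frame(record_id = records$record_id,
             p = records$n_infested / records$n_specimens,
             n = records$n_specimens,
             k = records$n_infested,
             era = records$era,
             period = records$period,
             best_age_ma = records$best_age_ma,
             host_phylum = records$host_phylum,
             host_class = records$host_class,
             stringsAsFactors = FALSE)
}

#' Occurrences per million years
#'
#' @param count Number of occurrences (or observations).
#' @param duration_myr Interval duration in Myr, > 0.
#' @return `count / duration_myr` (full precision; summaries round to 2 dp).
#' @examples
#' round(per_myr_rate(481, 289), 2) # 1.66
#' @export
per_myr_rate <- function(count, duration_myr) {
  if (any(duration_myr <= 0)) stop("duration must be positive", call. = FALSE)
  count / duration_myr
}

#' Percentile bootstrap confidence interval for a median
#'
#' Draws `B` resamples with replacement, takes the median of each, and returns
#' the percentile interval at the requested level. Deterministic for a fixed
#' `seed` (the caller's RNG state is untouched when a seed is given).
#'
#' @param values Nonempty numeric vector.
#' @param B Number of bootstrap replicates (default 10000).
#' @param level Confidence level, default 0.95.
#' @param seed Optional integer seed.
#' @return Named numeric vector `c(ci_low, ci_high)` with attributes `B`,
#'   `level`, `median` (the sample median).
#' @export
bootstrap_median_ci <- function(values, B = 10000, level = 0.95, seed = NULL) {
  if (!length(values) || anyNA(values)) {
    stop("`values` must be nonempty with no missing values", call. = FALSE)
  }
  if (B < 1) stop("`B` must be at least 1", call. = FALSE)
  run <- function() {
    n <- length(values)
    meds <- vapply(seq_len(B),
                   function(i) stats::median(values[sample.int(n, n, replace = TRUE)]),
                   numeric(1))
    alpha <- (1 - level) / 2
    stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE, type = 7)
  }
  ci <- if (is.null(seed)) run() else withr_seed(seed, run())
  out <- c(ci_low = ci[1], ci_high = ci[2])
  attr(out, "B") <- B
  attr(out, "level") <- level
  attr(out, "median") <- stats::median(values)
  out
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Mann-Whitney U test (two-sided)
#'
#' Computes the U statistic from rank sums. For small samples
#' (`min(n1, n2) <= 8`) without ties the two-sided p-value is exact, from the
#' null distribution of U; otherwise a tie-corrected normal approximation
#' with continuity correction is used.
#'
#' @param x,y Nonempty numeric vectors.
#' @param method `"auto"` (exact for small samples without ties, otherwise
#'   the normal approximation), `"exact"`, or `"normal"`.
#' @return List with `U` (statistic for `x`), `p` (two-sided), and `method`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p # exactly 1/3
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("both samples must be nonempty", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (method == "exact" && has_ties) {
    stop("exact method is unavailable with ties", call. = FALSE)
  }
  use_exact <- method == "exact" ||
    (method == "auto" && min(n1, n2) <= 8 && !has_ties)
  if (use_exact) {
    # exact: null distribution of U for samples without ties
    p_low <- stats::pwilcox(U, n1, n2)
    p_high <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      cc <- if (U == mu) 0 else 0.5 * sign(U - mu)
      z <- (U - mu - cc) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal-tie-corrected"
  }
  list(U = U, p = p, method = method)
}

#' Era-level prevalence summary
#'
#' One row per era: number of prevalence values, median prevalence,
#' percentile-bootstrap 95% confidence interval, and the number of prevalence
#' observations per Myr of era duration (pinned denominators, see
#' [load_timescale()]). Eras with no values get a flagged row with `NA`
#' statistics. All pairwise two-sided Mann-Whitney comparisons between eras
#' are included in the `pairwise` component.
#'
#' @param prevalence Data frame from [occurrence_prevalence()].
#' @param B Bootstrap replicates for the CI (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed passed to [bootstrap_median_ci()].
#' @return An object of class `era_summary`: list with `summary` and
#'   `pairwise` data frames.
#' @export
era_summary_table <- function(prevalence, B = 10000, level = 0.95, seed = NULL) {
  eras <- .eras$name
  rows <- lapply(seq_along(eras), function(i) {
    e <- eras[i]
    v <- prevalence$p[prevalence$era == e]
    if (!length(v)) {
      return(data.frame(era = e, n_values = 0L, median_p = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        obs_per_myr = 0, flag = "no values",
                        stringsAsFactors = FALSE))
    }
    ci <- bootstrap_median_ci(v, B = B, level = level,
                              seed = if (is.null(seed)) NULL else seed + i)
    data.frame(era = e, n_values = length(v),
               median_p = stats::median(v),
               ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
               obs_per_myr = per_myr_rate(length(v), era_duration(e)),
               flag = "", stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)

  pairs <- utils::combn(eras, 2)
  pw <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    va <- prevalence$p[prevalence$era == a]
    vb <- prevalence$p[prevalence$era == b]
    if (!length(va) || !length(vb)) {
      return(data.frame(era_a = a, era_b = b, U = NA_real_, p = NA_real_,
                        method = "undefined", stringsAsFactors = FALSE))
    }
    mw <- mann_whitney_u(va, vb)
    data.frame(era_a = a, era_b = b, U = mw$U, p = mw$p, method = mw$method,
               stringsAsFactors = FALSE)
  })
  out <- list(summary = summary, pairwise = do.call(rbind, pw),
              B = B, level = level, seed = seed)
  class(out) <- "era_summary"
  out
}

#' @export
print.era_summary <- function(x, ...) {
  cat("Era-level parasite prevalence summary\n")
  s <- x$summary
  s$median_p <- round(s$median_p, 2)
  s$ci_low <- round(s$ci_low, 2)
  s$ci_high <- round(s$ci_high, 2)
  s$obs_per_myr <- round(s$obs_per_myr, 2)
  print(s, row.names = FALSE)
  cat("\nPairwise Mann-Whitney (two-sided):\n")
  pw <- x$pairwise
  pw$p <- signif(pw$p, 3)
  print(pw, row.names = FALSE)
  invisible(x)
}

#' @export
plot.era_summary <- function(x, ...) {
  s <- x$summary[!is.na(x$summary$median_p), ]
  bp <- graphics::barplot(s$median_p, names.arg = s$era,
                          ylab = "median prevalence",
                          ylim = c(0, max(s$ci_high, na.rm = TRUE) * 1.2), ...)
  graphics::arrows(bp, s$ci_low, bp, s$ci_high, angle = 90, code = 3,
                   length = 0.06)
  invisible(x)
}
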
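# Shareholder quorum subsampling (coverage-standardized richness) and
# three-timer turnover rates from period-binned genus occurrence data.

#' Good's coverage estimate
#'
#' `u = 1 - singletons / N`: the estimated fraction of the underlying
#' occurrence-frequency distribution represented by the sampled genera, where
#' singletons are genera with exactly one occurrence in the bin.
#'
#' @param counts Named integer vector of per-genus occurrence counts (N >= 1).
#' @return Coverage in \[0, 1\].
#' @examples
#' goods_u(c(A = 3, B = 1)) # 0.75
#' @export
goods_u <- function(counts) {
  if (!length(counts) || sum(counts) < 1) stop("empty bin", call. = FALSE)
  1 - sum(counts == 1) / sum(counts)
}

#' Shareholder quorum subsampled richness for one bin
#'
#' Each trial shuffles the bin's occurrence list and walks it; the first time
#' a genus is encountered its coverage-corrected frequency share `u * f_t`
#' (with `f_t = n_t / N` and `u` Good's coverage) is added to the running
#' coverage and the genus is counted. The walk stops as soon as the running
#' coverage reaches the quorum `q`, counting the genus that crosses it. The
#' subsampled richness is the mean count over trials.
#'
#' @param counts Named vector of per-genus occurrence counts.
#' @param q Coverage quorum in (0, 1\]; default 0.6.
#' @param trials Number of shuffles; default 50.
#' @param seed Optional integer seed (caller RNG state preserved).
#' @param exclude_dominant If `TRUE`, the single most common genus is excluded
#'   from the coverage accounting (a variant correction; default off).
#' @return List with `S_mean`, `richness` (per-trial counts), `u`, `q`.
#'   Errors if the quorum exceeds the bin's coverage (`q > u`), in which case
#'   the bin cannot be standardized at that quorum.
#' @export
sqs_richness <- function(counts, q = 0.6, trials = 50, seed = NULL,
                         exclude_dominant = FALSE) {
  stopifnot(q > 0, q <= 1, trials >= 1)
  if (!length(counts) || sum(counts) < 1) stop("empty bin", call. = FALSE)
  u <- goods_u(counts)
  if (q > u + 1e-12) {
    stop("insufficient coverage: quorum ", q, " exceeds Good's u = ",
         signif(u, 3), call. = FALSE)
  }
  N <- sum(counts)
  f <- counts / N
  share <- u * f
  if (exclude_dominant && length(counts) > 1) {
    dom <- which.max(counts)
    # dominant genus contributes occurrences but no coverage; rescale the
    # remaining shares so the attainable total is still u
    share[dom] <- 0
    share <- share / sum(share) * u
  }
  occ <- rep(seq_along(counts), counts) # occurrence list as genus indices
  run <- function() {
    vapply(seq_len(trials), function(t) {
      perm <- sample(occ)
      first <- !duplicated(perm)
      cum <- cumsum(share[perm[first]])
      hit <- which(cum >= q - 1e-12)
      if (length(hit)) hit[1] else length(cum)
    }, numeric(1))
  }
  rich <- if (is.null(seed)) run() else withr_seed(seed, run())
  list(S_mean = mean(rich), richness = rich, u = u, q = q)
}

#' Three-timer and part-timer counts for an interior bin
#'
#' Given a genus-by-period incidence (presence/absence) matrix, counts for bin
#' `i`: `t3` genera present in bins i-1, i, i+1; `pt` present in i-1 and i+1
#' but not i; `t2_bottom` present in i-1 and i; `t2_top` present in i and
#' i+1; and the sampling statistic `P_s = t3 / (t3 + pt)` (NA when undefined).
#'
#' @param presence Logical or 0/1 matrix, genera in rows, bins in columns
#'   ordered old to young.
#' @param i Interior bin index (`1 < i < ncol(presence)`).
#' @return List `t3`, `pt`, `t2_bottom`, `t2_top`, `P_s`.
#' @export
three_timer_counts <- function(presence, i) {
  presence <- presence > 0
  nb <- ncol(presence)
  if (i <= 1 || i >= nb) {
    stop("three-timer counts are undefined for edge bins", call. = FALSE)
  }
  a <- presence[, i - 1]; b <- presence[, i]; c <- presence[, i + 1]
  t3 <- sum(a & b & c)
  pt <- sum(a & !b & c)
  t2b <- sum(a & b)
  t2t <- sum(b & c)
  P_s <- if (t3 + pt > 0) t3 / (t3 + pt) else NA_real_
  list(t3 = t3, pt = pt, t2_bottom = t2b, t2_top = t2t, P_s = P_s)
}

#' Three-timer origination and extinction rates for an interior bin
#'
#' Sampling-corrected per-bin rates:
#' extinction `mu_i = log(t2_bottom_i / t3_i) + log(P_s at bin i+1)` and
#' origination `lambda_i = log(t2_top_i / t3_i) + log(P_s at bin i-1)`,
#' where the `P_s` correction uses the three-timer sampling statistic of the
#' neighbouring bin on the side the ratio looks toward. Rates are per bin by
#' default (dimensionless); set `per_myr` with a bin duration to normalize.
#' Negative values (sampling noise) are reported as-is with a flag.
#'
#' @param presence Incidence matrix as in [three_timer_counts()].
#' @param i Bin index with both neighbours interior enough for the needed
#'   `P_s` values (`2 < i < ncol - 1` for both rates; one-sided values are
#'   returned with the other flagged `NA`).
#' @param duration_myr Optional bin duration; when given, rates are divided
#'   by it.
#' @return List `lambda`, `mu` (NA when undefined) and `flags` (character).
#' @export
turnover_rates <- function(presence, i, duration_myr = NULL) {
  nb <- ncol(presence)
  ctr <- three_timer_counts(presence, i)
  flags <- character(0)
  lambda <- mu <- NA_real_
  if (ctr$t3 > 0) {
    if (i + 1 < nb) {
      ps_up <- three_timer_counts(presence, i + 1)$P_s
      if (!is.na(ps_up) && ps_up > 0) {
        mu <- log(ctr$t2_bottom / ctr$t3) + log(ps_up)
      } else flags <- c(flags, "P_s undefined at bin i+1")
    } else flags <- c(flags, "no younger neighbour for mu")
    if (i - 1 > 1) {
      ps_dn <- three_timer_counts(presence, i - 1)$P_s
      if (!is.na(ps_dn) && ps_dn > 0) {
        lambda <- log(ctr$t2_top / ctr$t3) + log(ps_dn)
      } else flags <- c(flags, "P_s undefined at bin i-1")
    } else flags <- c(flags, "no older neighbour for lambda")
  } else {
    flags <- c(flags, "t3 = 0")
  }
  if (!is.null(duration_myr)) {
    lambda <- lambda / duration_myr
    mu <- mu / duration_myr
  }
  if (!is.na(lambda) && lambda < 0) flags <- c(flags, "negative lambda")
  if (!is.na(mu) && mu < 0) flags <- c(flags, "negative mu")
  list(lambda = lambda, mu = mu, flags = flags)
}

#' Period-level diversity table from genus occurrences
#'
#' Bins genus occurrences by period (age-ambiguous occurrences excluded),
#' computes per-period SQS mean sampled richness at the given quorum and the
#' three-timer origination and extinction rates, and reports the underlying
#' counts and flags. Bins with fewer than `min_genera` genera or
#' `min_occurrences` occurrences, or whose Good's coverage falls below the
#' quorum, yield missing richness cells with a logged reason.
#'
#' @param occurrences A `genus_occurrences` data frame.
#' @param q Sampling quorum (default 0.6).
#' @param trials SQS trials per bin (default 50).
#' @param seed Integer seed for the subsampling (required for
#'   reproducibility).
#' @param host_class Optional class name; restricts the table to that class.
#' @param min_genera,min_occurrences Minimum bin sizes (defaults 2 and 10).
#' @param per_myr Normalize 3T rates by period duration (default `FALSE`,
#'   matching dimensionless per-bin rates).
#' @param exclude_dominant Passed to [sqs_richness()].
#' @return A data frame of class `diversity_table`: one row per period with
#'   `period`, `midpoint_ma`, `S_mean`, `lambda_3t`, `mu_3t`, `N_occ`,
#'   `n_genera`, `u`, `t3`, `pt`, `t2_bottom`, `t2_top`, `P_s`, `flags`.
#' @export
diversity_table <- function(occurrences, q = 0.6, trials = 50, seed = 1,
                            host_class = NULL, min_genera = 2,
                            min_occurrences = 10, per_myr = FALSE,
                            exclude_dominant = FALSE) {
  stopifnot(is.data.frame(occurrences))
  occ <- occurrences[!occurrences$age_ambiguous & !is.na(occurrences$period), ,
                     drop = FALSE]
  if (!is.null(host_class)) {
    occ <- occ[!is.na(occ$host_class) & occ$host_class %in% host_class, ,
               drop = FALSE]
  }
  periods <- .periods$name
  nb <- length(periods)
  genera <- sort(unique(occ$genus))
  presence <- matrix(FALSE, nrow = length(genera), ncol = nb,
                     dimnames = list(genera, periods))
  if (nrow(occ)) {
    idx <- cbind(match(occ$genus, genera), period_index(occ$period))
    presence[idx] <- TRUE
  }

  rows <- lapply(seq_len(nb), function(i) {
    p <- periods[i]
    sub <- occ[occ$period == p, , drop = FALSE]
    counts <- table(sub$genus)
    N <- sum(counts)
    flags <- character(0)
    S_mean <- u <- NA_real_
    if (N == 0) {
      flags <- c(flags, "empty bin")
    } else {
      u <- goods_u(as.numeric(counts))
      if (length(counts) < min_genera || N < min_occurrences) {
        flags <- c(flags, "below minimum bin size")
      } else if (q > u + 1e-12) {
        flags <- c(flags, "insufficient coverage (q > u)")
      } else {
        sq <- sqs_richness(stats::setNames(as.numeric(counts), names(counts)),
                           q = q, trials = trials,
                           seed = seed + i, exclude_dominant = exclude_dominant)
        S_mean <- sq$S_mean
      }
    }
    lambda <- mu <- NA_real_
    t3 <- pt <- t2b <- t2t <- NA_real_
    P_s <- NA_real_
    if (i > 1 && i < nb) {
      ctr <- three_timer_counts(presence, i)
      t3 <- ctr$t3; pt <- ctr$pt; t2b <- ctr$t2_bottom; t2t <- ctr$t2_top
      P_s <- ctr$P_s
      dur <- if (per_myr) .periods$max_ma[i] - .periods$min_ma[i] else NULL
      tr <- turnover_rates(presence, i, duration_myr = dur)
      lambda <- tr$lambda; mu <- tr$mu
      flags <- c(flags, tr$flags)
    } else {
      flags <- c(flags, "edge bin: no 3T rates")
    }
    data.frame(period = p,
               midpoint_ma = (.periods$max_ma[i] + .periods$min_ma[i]) / 2,
               S_mean = S_mean, lambda_3t = lambda, mu_3t = mu,
               N_occ = N, n_genera = length(counts), u = u,
               t3 = t3, pt = pt, t2_bottom = t2b, t2_top = t2t, P_s = P_s,
               flags = paste(flags, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(q = q, trials = trials, seed = seed,
                              host_class = host_class,
                              min_genera = min_genera,
                              min_occurrences = min_occurrences,
                              per_myr = per_myr,
                              exclude_dominant = exclude_dominant)
  class(out) <- c("diversity_table", "data.frame")
  out
}

#' @export
plot.diversity_table <- function(x, ...) {
  ok <- !is.na(x$S_mean)
  graphics::plot(x$midpoint_ma[ok], x$S_mean[ok], type = "b",
                 xlim = rev(range(x$midpoint_ma)),
                 xlab = "age (Ma)", ylab = "SQS mean sampled diversity", ...)
  invisible(x)
}
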
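# Phanerozoic timescale (ICS 2020 boundaries, Carboniferous undivided) and
# period/era binning helpers.

.periods <- data.frame(
  name = c("Cambrian", "Ordovician", "Silurian", "Devonian", "Carboniferous",
           "Permian", "Triassic", "Jurassic", "Cretaceous", "Paleogene",
           "Neogene", "Quaternary"),
  max_ma = c(541, 485.4, 443.8, 419.2, 358.9, 298.9, 251.902, 201.3, 145,
             66, 23.03, 2.58),
  min_ma = c(485.4, 443.8, 419.2, 358.9, 298.9, 251.902, 201.3, 145, 66,
             23.03, 2.58, 0),
  era = c(rep("Paleozoic", 6), rep("Mesozoic", 3), rep("Cenozoic", 3)),
  stringsAsFactors = FALSE
)

.eras <- data.frame(
  name = c("Paleozoic", "Mesozoic", "Cenozoic"),
  max_ma = c(541, 251.902, 66),
  min_ma = c(251.902, 66, 0),
  # durations for per-Myr rates are pinned to the conventional rounded values
  # (289, 185, 66 Myr) so that reported era rates are reproducible to 2 dp
  duration_myr = c(289, 185, 66),
  stringsAsFactors = FALSE
)

#' Phanerozoic timescale
#'
#' Returns the period- and era-level geologic timescale used throughout the
#' package: the 12 Phanerozoic periods (ICS 2020 boundaries, with the
#' Carboniferous kept undivided, matching period-level binning of Paleobiology
#' Database exports) and the 3 eras. Periods tile the interval 541--0 Ma with
#' no gaps; era durations used as per-Myr rate denominators are pinned to the
#' conventional rounded values (Paleozoic 289, Mesozoic 185, Cenozoic 66 Myr).
#'
#' @param level `"period"` (default), `"era"`, or `"both"`.
#' @return A data frame with columns `name`, `level`, `max_ma`, `min_ma`,
#'   `midpoint_ma`, and for periods `era`, for eras `duration_myr`. With
#'   `level = "both"` a list with components `periods` and `eras`.
#' @examples
#' load_timescale()
#' load_timescale("era")$duration_myr
#' @export
load_timescale <- function(level = c("period", "era", "both")) {
  level <- match.arg(level)
  p <- .periods
  p$level <- "period"
  p$midpoint_ma <- (p$max_ma + p$min_ma) / 2
  p <- p[, c("name", "level", "max_ma", "min_ma", "midpoint_ma", "era")]
  e <- .eras
  e$level <- "era"
  e$midpoint_ma <- (e$max_ma + e$min_ma) / 2
  e <- e[, c("name", "level", "max_ma", "min_ma", "midpoint_ma", "duration_myr")]
  switch(level, period = p, era = e, both = list(periods = p, eras = e))
}

#' Assign a point age to its geologic period and era
#'
#' Ages exactly on a period boundary are assigned to the younger period (the
#' one whose older bound equals the age); 541 Ma itself falls in the Cambrian.
#'
#' @param age_ma Numeric vector of ages in Ma, each in \[0, 541\].
#' @return A data frame with one row per age: `age_ma`, `period`, `era`.
#' @examples
#' assign_interval(c(100, 300))
#' @export
assign_interval <- function(age_ma) {
  if (!is.numeric(age_ma) || anyNA(age_ma)) {
    stop("`age_ma` must be numeric with no missing values", call. = FALSE)
  }
  if (any(age_ma < 0 | age_ma > 541)) {
    bad <- age_ma[age_ma < 0 | age_ma > 541]
    stop("age(s) outside the Phanerozoic (0-541 Ma): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  # youngest period whose older bound covers the age => boundary ages go young
  idx <- vapply(age_ma, function(a) max(which(.periods$max_ma >= a)), 1L)
  data.frame(age_ma = age_ma,
             period = .periods$name[idx],
             era = .periods$era[idx],
             stringsAsFactors = FALSE)
}

# duration (Myr) of the pinned per-Myr denominator for an era name
era_duration <- function(era) {
  i <- match(era, .eras$name)
  if (anyNA(i)) stop("unknown era: ", paste(era[is.na(i)], collapse = ", "),
                     call. = FALSE)
  .eras$duration_myr[i]
}

period_index <- function(period) {
  i <- match(period, .periods$name)
  if (anyNA(i)) stop("unknown period: ", paste(period[is.na(i)], collapse = ", "),
                     call. = FALSE)
  i
}
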
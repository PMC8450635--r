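# Readers and record filters for the two input tables: the species-level
# parasitism database and PBDB-style genus occurrence exports.

.parasitism_cols <- c("record_id", "host_taxon", "host_phylum", "host_class",
                      "parasite_phylum", "certainty", "n_specimens",
                      "n_infested", "best_age_ma", "period", "era",
                      "reference_id")

#' Read and validate a parasitism occurrence table
#'
#' Reads a delimited table with one row per species-level host occurrence
#' showing evidence of parasitism. Mandatory columns: `record_id`,
#' `host_taxon`, `host_phylum`, `host_class`, `parasite_phylum`, `certainty`
#' (1--4), `n_specimens`, `n_infested` (either may be empty when a sample
#' size was not reported), `best_age_ma`, `period`, `era`, `reference_id`.
#'
#' Row-level validation rejects rows with `n_infested > n_specimens`,
#' certainty outside 1--4, ages outside the Phanerozoic, or a stated
#' period/era inconsistent with `best_age_ma`. Rows with missing
#' `n_specimens` are retained (they still count as occurrences) but flagged
#' ineligible for prevalence. The validation report is attached as
#' `attr(x, "validation")`.
#'
#' @param path Path to a CSV (or `sep`-delimited) file.
#' @param sep Field separator, default `","`.
#' @return A data frame of typed records, class `parasitism_records`, with a
#'   logical column `prevalence_possible` and a `validation` attribute listing
#'   rejected rows and reasons.
#' @seealso [filter_analytical()], [select_prevalence_eligible()]
#' @export
read_parasitism_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  missing_cols <- setdiff(.parasitism_cols, names(raw))
  if (length(missing_cols)) {
    stop("parasitism table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_parasitism_records(raw[, .parasitism_cols])
}

#' Validate an in-memory parasitism table
#'
#' Applies the same row-level validation as [read_parasitism_table()] to a
#' data frame already in the documented schema.
#'
#' @param df Data frame with the parasitism schema columns.
#' @return A `parasitism_records` data frame; rejected rows are dropped and
#'   listed in the `validation` attribute.
#' @export
as_parasitism_records <- function(df) {
  df$certainty <- as.integer(df$certainty)
  df$n_specimens <- suppressWarnings(as.numeric(df$n_specimens))
  df$n_infested <- suppressWarnings(as.numeric(df$n_infested))
  df$best_age_ma <- as.numeric(df$best_age_ma)

  problems <- character(nrow(df))
  flag <- function(bad, msg) {
    bad[is.na(bad)] <- FALSE
    problems[bad] <<- ifelse(nzchar(problems[bad]),
                             paste(problems[bad], msg, sep = "; "), msg)
  }
  flag(!(df$certainty %in% 1:4), "certainty not in 1-4")
  flag(!is.na(df$n_infested) & is.na(df$n_specimens),
       "n_infested reported without n_specimens")
  flag(!is.na(df$n_infested) & !is.na(df$n_specimens) &
         df$n_infested > df$n_specimens, "n_infested > n_specimens")
  flag(!is.na(df$n_specimens) & df$n_specimens < 0, "negative n_specimens")
  flag(!is.na(df$n_infested) & df$n_infested < 0, "negative n_infested")
  out_of_range <- is.na(df$best_age_ma) | df$best_age_ma < 0 | df$best_age_ma > 541
  flag(out_of_range, "best_age_ma outside 0-541 Ma")

  ok_age <- !out_of_range
  if (any(ok_age)) {
    binned <- assign_interval(df$best_age_ma[ok_age])
    mism <- (df$period[ok_age] != binned$period) | (df$era[ok_age] != binned$era)
    idx <- which(ok_age)[mism]
    if (length(idx)) {
      problems[idx] <- ifelse(nzchar(problems[idx]),
                              paste(problems[idx],
                                    "period/era inconsistent with best_age_ma",
                                    sep = "; "),
                              "period/era inconsistent with best_age_ma")
    }
  }

  bad <- nzchar(problems)
  report <- data.frame(row = which(bad),
                       record_id = df$record_id[bad],
                       problem = problems[bad],
                       stringsAsFactors = FALSE)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out$prevalence_possible <- !is.na(out$n_specimens) & !is.na(out$n_infested)
  class(out) <- c("parasitism_records", "data.frame")
  attr(out, "validation") <- report
  out
}

#' Restrict records to unambiguous parasitism (certainty 1--3)
#'
#' Certainty category 4 marks interactions that could be parasitism but are
#' also consistent with other interpretations; they are excluded from all
#' analyses. Idempotent.
#'
#' @param records A `parasitism_records` data frame.
#' @return The retained records; the number removed is attached as
#'   `attr(x, "n_removed")` and reported via `message()`.
#' @export
filter_analytical <- function(records) {
  stopifnot(is.data.frame(records), "certainty" %in% names(records))
  keep <- records$certainty %in% 1:3
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  removed <- sum(!keep)
  if (nrow(out) == 0L) {
    warning("no records remain after excluding certainty category 4",
            call. = FALSE)
  }
  attr(out, "n_removed") <- removed
  attr(out, "validation") <- attr(records, "validation")
  class(out) <- c("parasitism_records", "data.frame")
  out
}

#' Select records eligible for prevalence calculation
#'
#' Prevalence is only computed for occurrences whose reported sample size is
#' at least `min_n` fossil remains (default 10; 20 is the robustness setting)
#' and whose infested count is present.
#'
#' @param records A `parasitism_records` data frame (normally after
#'   [filter_analytical()]).
#' @param min_n Minimum number of specimens, inclusive; default 10.
#' @return The eligible subset, class preserved.
#' @export
select_prevalence_eligible <- function(records, min_n = 10) {
  stopifnot(is.data.frame(records), min_n >= 1)
  keep <- !is.na(records$n_specimens) & !is.na(records$n_infested) &
    records$n_specimens >= min_n
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_n") <- min_n
  class(out) <- c("parasitism_records", "data.frame")
  out
}

#' Read a PBDB-style genus occurrence export
#'
#' Expects columns `genus`, `class` (host class), `collection_no`, `max_ma`,
#' `min_ma`, `reference_no`; extra columns are ignored. Each occurrence is
#' assigned to a geologic period when its age range lies within a single
#' period; ranges that span a period boundary are flagged `age_ambiguous` and
#' excluded from period bins by downstream functions. Rows with an empty genus
#' or unparseable/inverted ages are rejected and listed in the `validation`
#' attribute.
#'
#' @param path Path to a CSV file.
#' @param sep Field separator, default `","`.
#' @return A data frame of class `genus_occurrences` with columns `genus`,
#'   `host_class`, `collection_id`, `max_ma`, `min_ma`, `reference_id`,
#'   `period` (NA when ambiguous), `age_ambiguous`.
#' @export
read_occurrence_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  need <- c("genus", "max_ma", "min_ma")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("occurrence table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(
    genus = as.character(raw$genus),
    host_class = if ("class" %in% names(raw)) as.character(raw$class) else NA_character_,
    collection_id = if ("collection_no" %in% names(raw)) raw$collection_no else seq_len(nrow(raw)),
    max_ma = suppressWarnings(as.numeric(raw$max_ma)),
    min_ma = suppressWarnings(as.numeric(raw$min_ma)),
    reference_id = if ("reference_no" %in% names(raw)) raw$reference_no else NA,
    stringsAsFactors = FALSE
  )
  as_genus_occurrences(df)
}

#' @rdname read_occurrence_table
#' @param df Data frame with at least `genus`, `max_ma`, `min_ma`.
#' @export
as_genus_occurrences <- function(df) {
  if (is.null(df$host_class)) df$host_class <- NA_character_
  problems <- character(nrow(df))
  bad_genus <- is.na(df$genus) | !nzchar(trimws(df$genus))
  bad_age <- is.na(df$max_ma) | is.na(df$min_ma) | df$max_ma < df$min_ma |
    df$min_ma < 0 | df$max_ma > 541
  problems[bad_genus] <- "empty genus"
  problems[bad_age] <- ifelse(nzchar(problems[bad_age]),
                              paste(problems[bad_age], "bad age range", sep = "; "),
                              "bad age range")
  bad <- nzchar(problems)
  report <- data.frame(row = which(bad), problem = problems[bad],
                       stringsAsFactors = FALSE)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL

  # ambiguous iff a period boundary lies strictly inside (min_ma, max_ma);
  # otherwise bin by midpoint (boundary midpoints resolve to the younger bin)
  inner_bounds <- .periods$min_ma[.periods$min_ma > 0]
  out$age_ambiguous <- vapply(seq_len(nrow(out)), function(i) {
    any(inner_bounds > out$min_ma[i] & inner_bounds < out$max_ma[i])
  }, logical(1))
  out$period <- rep(NA_character_, nrow(out))
  if (any(!out$age_ambiguous)) {
    mids <- (out$max_ma[!out$age_ambiguous] + out$min_ma[!out$age_ambiguous]) / 2
    out$period[!out$age_ambiguous] <- assign_interval(mids)$period
  }
  class(out) <- c("genus_occurrences", "data.frame")
  attr(out, "validation") <- report
  out
}
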
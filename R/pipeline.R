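# Config-driven end-to-end pipeline: filter -> prevalence/era stats -> SQS/3T
# -> GLMs -> hypothesis calls, with reconciled stage counts and metadata.

#' Pipeline run configuration
#'
#' @param parasitism Path to a parasitism CSV, or a `parasitism_records`
#'   data frame.
#' @param occurrences Path to a PBDB-style occurrence CSV, or a
#'   `genus_occurrences` data frame.
#' @param out_dir Output directory; `NULL` for no file output.
#' @param min_n Prevalence sample-size threshold (default 10).
#' @param certainty_max Highest certainty category retained (default 3).
#' @param quorum,trials SQS settings (defaults 0.6, 50).
#' @param bootstrap_B Bootstrap replicates for era CIs (default 10000).
#' @param seed Integer master seed; per-stage substreams derive from it.
#' @param host_groups Optional named list of host-class subsets for per-group
#'   models, e.g. `list(Bivalvia = "Bivalvia")`; the pooled analysis always
#'   runs.
#' @return List of class `run_config`.
#' @export
run_config <- function(parasitism, occurrences, out_dir = NULL,
                       min_n = 10, certainty_max = 3, quorum = 0.6,
                       trials = 50, bootstrap_B = 10000, seed = 1,
                       host_groups = NULL) {
  for (p in list(parasitism, occurrences)) {
    if (is.character(p) && !file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full parasitism-versus-diversity analysis
#'
#' Executes the whole chain: record validation and certainty filtering,
#' prevalence selection and era summary statistics, SQS diversity and
#' three-timer rates per period (pooled and per host group), the per-period
#' occurrence GLM and per-occurrence prevalence GLM, and
#' amplification/dilution hypothesis calls. When `out_dir` is set, writes
#' `era_summary.csv`, `pairwise_tests.csv`, `diversity_table.csv`,
#' `occurrence_glm.csv`, `prevalence_glm.csv`, `hypothesis_calls.csv`,
#' `run_log.txt` and `metadata.json` (numeric outputs unrounded; rounding is
#' presentation-only).
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_result` with components `records`,
#'   `analytical`, `eligible`, `prevalence`, `era_summary`, `diversity`,
#'   `occurrence_fit`, `prevalence_fit`, `calls`, `composition`, `log`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  records <- stage("read", {
    if (is.character(config$parasitism)) {
      read_parasitism_table(config$parasitism)
    } else config$parasitism
  })
  occurrences <- stage("read", {
    if (is.character(config$occurrences)) {
      read_occurrence_table(config$occurrences)
    } else config$occurrences
  })
  say("input: ", nrow(records), " parasitism records, ",
      nrow(occurrences), " genus occurrences")

  analytical <- stage("filter", filter_analytical(records))
  say("certainty filter: ", nrow(analytical), " retained, ",
      attr(analytical, "n_removed"), " category-4 removed (",
      nrow(analytical) + attr(analytical, "n_removed"), " in)")

  eligible <- stage("prevalence",
                    select_prevalence_eligible(analytical, min_n = config$min_n))
  prevalence <- stage("prevalence", occurrence_prevalence(eligible))
  say("prevalence-eligible (n >= ", config$min_n, "): ", nrow(eligible),
      " occurrences, ", sum(eligible$n_specimens), " specimens")

  era_sum <- stage("era_stats",
                   era_summary_table(prevalence, B = config$bootstrap_B,
                                     seed = config$seed + 11L))

  divtab <- stage("sqs", diversity_table(occurrences, q = config$quorum,
                                         trials = config$trials,
                                         seed = config$seed + 23L))
  say("diversity table: ", sum(!is.na(divtab$S_mean)), "/", nrow(divtab),
      " periods with SQS richness")

  occ_fit <- stage("glm", occurrence_model(analytical, divtab))
  prev_fit <- stage("glm", prevalence_model(prevalence, divtab))
  calls <- list(
    occurrence = classify_support(occ_fit, group = "all (occurrence)"),
    prevalence = classify_support(prev_fit, group = "all (prevalence)")
  )
  say("hypothesis calls: occurrence=", calls$occurrence$call,
      ", prevalence=", calls$prevalence$call)

  group_results <- list()
  for (g in names(config$host_groups)) {
    group_results[[g]] <- tryCatch({
      dg <- diversity_table(occurrences, q = config$quorum,
                            trials = config$trials,
                            seed = config$seed + 23L,
                            host_class = config$host_groups[[g]])
      sub <- analytical[analytical$host_class %in% config$host_groups[[g]], ,
                        drop = FALSE]
      fg <- occurrence_model(sub, dg)
      classify_support(fg, group = g)
    }, error = function(e) {
      say("host group ", g, " skipped: ", conditionMessage(e))
      NULL
    })
  }

  composition <- list(
    host_phylum = round(100 * prop.table(table(analytical$host_phylum)), 1),
    parasite_phylum = round(100 * prop.table(table(analytical$parasite_phylum)), 1)
  )

  result <- list(records = records, analytical = analytical,
                 eligible = eligible, prevalence = prevalence,
                 era_summary = era_sum, diversity = divtab,
                 occurrence_fit = occ_fit, prevalence_fit = prev_fit,
                 calls = calls, group_calls = group_results,
                 composition = composition, config = config,
                 log = log_lines)
  class(result) <- "pipeline_result"

  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(era_sum$summary, file.path(od, "era_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(era_sum$pairwise, file.path(od, "pairwise_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(divtab),
                     file.path(od, "diversity_table.csv"), row.names = FALSE)
    utils::write.csv(wald_summary(occ_fit),
                     file.path(od, "occurrence_glm.csv"), row.names = FALSE)
    utils::write.csv(wald_summary(prev_fit, vcov_type = "robust"),
                     file.path(od, "prevalence_glm.csv"), row.names = FALSE)
    call_rows <- do.call(rbind, lapply(c(calls, group_results), function(cl) {
      if (is.null(cl)) return(NULL)
      data.frame(group = cl$group, call = cl$call, marginal = cl$marginal,
                 mechanism = paste0("(", cl$mechanism$sign, ") ",
                                    cl$mechanism$term, collapse = "; "),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(call_rows, file.path(od, "hypothesis_calls.csv"),
                     row.names = FALSE)
    writeLines(log_lines, file.path(od, "run_log.txt"))
    meta <- list(seed = config$seed, min_n = config$min_n,
                 quorum = config$quorum, trials = config$trials,
                 bootstrap_B = config$bootstrap_B,
                 r_version = as.character(getRversion()),
                 package_version = as.character(utils::packageVersion("paleoprev")),
                 timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(meta, file.path(od, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("paleoprev pipeline result\n")
  cat("  records:", nrow(x$records), "| analytical:", nrow(x$analytical),
      "| prevalence-eligible:", nrow(x$eligible), "\n")
  print(x$era_summary)
  cat("\n")
  print(x$calls$occurrence)
  print(x$calls$prevalence)
  invisible(x)
}
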
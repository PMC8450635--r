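# Independent oracles used by the unit and acceptance tests.

# Exact expected SQS richness by exhaustive enumeration of genus
# first-encounter orderings. In a uniform shuffle of the occurrence
# multiset, the first-encounter order of genera is successive sampling
# without replacement proportional to occurrence counts; the subsampled
# richness depends only on that order, so the expectation is a sum over all
# k! orderings. Independent of the trial-based implementation.
sqs_expected_richness <- function(counts, q) {
  counts <- as.numeric(counts)
  u <- 1 - sum(counts == 1) / sum(counts)
  share <- u * counts / sum(counts)
  res <- 0
  rec <- function(remaining, cum, prob, depth) {
    tot <- sum(counts[remaining])
    for (g in remaining) {
      p <- prob * counts[g] / tot
      c2 <- cum + share[g]
      if (c2 >= q - 1e-12) {
        res <<- res + p * depth
      } else {
        rec(setdiff(remaining, g), c2, p, depth + 1)
      }
    }
  }
  rec(seq_along(counts), 0, 1, 1)
  res
}

# genus x period presence matrix from a genus_occurrences table
presence_from_occurrences <- function(occ) {
  periods <- load_timescale()$name
  occ <- occ[!occ$age_ambiguous & !is.na(occ$period), , drop = FALSE]
  genera <- sort(unique(occ$genus))
  m <- matrix(FALSE, length(genera), length(periods),
              dimnames = list(genera, periods))
  m[cbind(match(occ$genus, genera), match(occ$period, periods))] <- TRUE
  m
}

# small well-formed parasitism table for IO tests
make_parasitism_csv <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      record_id = c("r1", "r2", "r3"),
      host_taxon = c("Chamelea gallina", "Arthroacantha carpenteri", "Galathea sp."),
      host_phylum = c("Mollusca", "Echinodermata", "Arthropoda"),
      host_class = c("Bivalvia", "Crinoidea", "Malacostraca"),
      parasite_phylum = c("Platyhelminthes", "Mollusca", "Arthropoda"),
      certainty = c(1L, 2L, 4L),
      n_specimens = c(50, NA, 12),
      n_infested = c(5, NA, 3),
      best_age_ma = c(0.01, 390, 100),
      period = c("Quaternary", "Devonian", "Cretaceous"),
      era = c("Cenozoic", "Paleozoic", "Mesozoic"),
      reference_id = c("ref1", "ref2", "ref3"),
      stringsAsFactors = FALSE
    )
  }
  utils::write.csv(rows, path, row.names = FALSE)
  rows
}
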
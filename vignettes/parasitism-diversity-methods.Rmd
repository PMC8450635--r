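---
title: "Methods: parasitism, prevalence and host diversity across the Phanerozoic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parasitism, prevalence and host diversity across the Phanerozoic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoprev)
```

## The scientific question

Marine animals have hosted parasites since at least the Cambrian. Two
opposing expectations link parasitism to host biodiversity: under
*amplification*, richer host faunas accumulate more parasite–host
interactions, so both the number of parasitism occurrences and the
within-sample prevalence of infestation rise with diversity; under
*dilution*, diverse communities depress transmission, so prevalence falls as
richness rises. `paleoprev` implements a period-level, occurrence-based test
of these hypotheses against the marine fossil record: it summarises a
compiled database of trace-based parasitism observations, estimates
coverage-standardized host diversity from genus occurrence data, and relates
the two with specimen-weighted generalized linear models whose signed,
significant coefficients are classified as supporting amplification or
dilution.

## Time binning

All analyses use the 12 Phanerozoic periods (ICS 2020 boundaries, 541–0 Ma)
with the Carboniferous kept undivided, matching the period-level binning of
Paleobiology Database exports, nested in the three eras. Era durations used
as per-Myr rate denominators are pinned to the conventional rounded values —
Paleozoic 289, Mesozoic 185, Cenozoic 66 Myr — so that reported rates such
as 481/289 = 1.66 Myr⁻¹ reproduce exactly at two decimals.

Point ages on a period boundary are assigned to the *younger* period, a
deterministic tie-break. For genus occurrences dated by an age *range*, the
range is ambiguous if a period boundary lies strictly inside it; ambiguous
occurrences are excluded from period bins (and counted), because period-level
incidence needs a unique bin and the source data give no basis for
apportioning. A range that merely touches a boundary at its endpoint (e.g.
70–66 Ma) is binned by its midpoint.

## Record filters

The parasitism table carries a per-record certainty category, 1–3 grading
increasingly indirect evidence that a trace records true parasitism and 4
marking interactions equally consistent with other readings. Category 4 is
excluded from every analysis. Prevalence — the infested fraction k/n of a
sampled population — is computed only for records reporting at least
`min_n = 10` specimens (20 as a robustness setting), because small samples
make k/n uninformative; records without sample sizes still count as
occurrences. These two data requirements are why occurrence counts and
prevalence are treated as separate indices throughout.

## Prevalence statistics

Per-era summaries report the median prevalence with a percentile bootstrap
95% confidence interval (B = 10 000 resamples of the median; B and the
percentile method are package choices, recorded in output metadata together
with the seed) and the number of prevalence observations per Myr. Pairwise
era comparisons use the two-sided Mann–Whitney U test: exact p-values from
the null U distribution when the smaller sample has at most 8 values and
there are no ties, otherwise a tie-corrected normal approximation *with*
continuity correction. The continuity correction was adopted after measuring
the two branches against each other: on tie-free samples of 9–12 values the
corrected approximation stays within 0.007 of the exact p, while the
uncorrected version drifts to ~0.03.

## Coverage-standardized diversity (SQS)

Raw richness per bin confounds diversity with sampling effort. The package
standardizes by *coverage*: for one bin with per-genus occurrence counts
n_t summing to N, Good's u = 1 − singletons/N estimates the fraction of the
occurrence-frequency distribution that sampled genera represent. Each
subsampling trial shuffles the bin's occurrence list and walks it, adding
the coverage-corrected share u·f_t (f_t = n_t/N) when a genus is first
encountered; the walk stops as soon as accumulated coverage reaches the
quorum q, counting the genus that crosses it. Mean richness over trials is
the subsampled diversity S̄. Defaults are q = 0.6 and 50 trials; the seed is
mandatory. Bins whose coverage falls below the quorum, or with fewer than 2
genera or 10 occurrences, yield flagged missing cells rather than numbers.
A dominant-genus exclusion exists as an off-by-default flag;
publication-level corrections are out of scope. These baseline choices keep
the estimator exactly testable: for bins of ≤ 8 occurrences the trial mean
is checked against an exhaustive enumeration of genus first-encounter
orderings.

Turnover uses three-timer counts on the genus × period incidence matrix:
t3 (present in bins i−1, i, i+1), pt (present in i−1 and i+1 but not i),
two-timers t2 on each side, and the sampling statistic P_s = t3/(t3+pt).
Rates for bin i are

* extinction μᵢ = log(t2_bottom/t3) + log(P_s at bin i+1)
* origination λᵢ = log(t2_top/t3) + log(P_s at bin i−1)

with per-bin P_s (the correction is taken from the neighbour the ratio looks
toward). Rates are per bin, i.e. dimensionless, matching the coefficient
scales of period-level regressions; a per-Myr normalization sits behind a
flag. Edge bins and undefined P_s propagate as flagged missing cells, so
with 12 periods at most 8 interior periods carry complete predictor rows.
Negative rates (sampling noise) are reported as-is with a flag.

## The weighted GLMs

Two models relate parasitism to the diversity indices:

* **Occurrence model** — Poisson, log link: analytical occurrence count per
  period ~ S̄ + λ + μ + period midpoint age, weighted by log10 of the
  period's total reported specimens (unweighted with an annotation when
  sample sizes are unavailable, mirroring the `#` convention for
  inadequately sampled host groups).
* **Prevalence model** — binomial, logit link: (k infested, n−k) per
  eligible occurrence ~ period-level S̄ + λ + μ + the record's best age,
  weighted by log10(n).

Fitting is IRLS (`stats::glm`) to relative tolerance 1e-10; predictors enter
unstandardized; rows with any missing predictor are dropped and logged;
inference is Wald z with the usual significance codes (# p<0.10 marginal,
\* <0.05, \*\* <0.01, \*\*\* <0.001) and no multiple-testing correction.

Two inference details are deliberate package choices. First, log10 specimen
counts are *analytic* weights — they encode relative reliability, not
replicated observations — so they are rescaled to mean 1 by default. The
rescaling leaves coefficients exactly unchanged (weight-scale invariance)
but stops the likelihood from claiming more Fisher information than the
data contain, which with raw weights of typical magnitude 1.5–3.5 would
inflate every Wald z by roughly the square root of the mean weight. The raw
prior-weight behaviour (doubling all weights halves squared SEs) is
available via `normalize_weights = FALSE`. Second, the record-level
prevalence model defaults to a heteroscedasticity-consistent sandwich
covariance (HC3): per-occurrence prevalence is overdispersed relative to
the binomial and the information is concentrated in records from sparsely
sampled periods and in very large samples, under which the model-based
covariance is badly anticonservative (simulated null rejection ~27% with
HC0-style corrections and worse with none, ~5–7% with HC3). The
model-based covariance remains available and is the default for the
12-period occurrence model, where no sandwich asymptotics apply.

## The amplification/dilution classifier

The default, configurable rule applied to a coefficient table:
amplification when S̄ is significantly positive, or when λ is positive and
μ negative with at least one significant; dilution when S̄ is significantly
negative or μ significantly positive; unclear when no term reaches p < 0.10.
Calls reached only through marginal terms are flagged. Mechanism notes
always list every signed term with p < 0.10, so a call can be audited
against its table. The rule is explicit because published summaries of this
kind mix diversity-, origination- and extinction-based arguments; the
default reproduces the unambiguous combinations.

## The synthetic-data generator

The generator exists so every stage can be validated against known truth
without any external download; its defaults are the package's reference
study conditions.

* **Taxon histories.** A discrete-bin branching process: a genus in bin i
  survives into bin i+1 with probability exp(−μ·dᵢ); survivors spawn
  Poisson-distributed new genera entering bin i+1. Per-bin origination
  expectations are solved from the branching-mean recursion so that expected
  standing richness follows a fixed Phanerozoic-like profile (≈4× dynamic
  range: early-Paleozoic rise, end-Permian trough, Meso-Cenozoic radiation)
  multiplied by lognormal environmental noise (sd 0.35 on the log scale).
  The profile matters: with unstructured noise alone many simulated
  histories are nearly flat, which leaves nothing for a recovery experiment
  to recover and is also unlike the strongly structured Phanerozoic record.
  A flat-rate mode (`diversity_profile = NULL`) retains the plain branching
  process; under it the expected three-timer extinction estimate for bin i
  is exactly μ·dᵢ, the analytic oracle used in testing.
* **Sampling.** Genus-bin occurrence counts are negative binomial (mean 3,
  size 1.5 by default; Poisson in the high-sampling limit), with point ages
  uniform inside the bin. This yields per-bin coverage u ≈ 0.9, comfortably
  above the 0.6 quorum.
* **Parasitism records.** Specimens per prevalence-eligible occurrence are
  lognormal (median ≈ 30, sdlog 2.1, capped at 30 000), chosen to match both
  the reported-sample-size skew and a mean of ≈ 266 specimens per eligible
  occurrence; infested counts are binomial with per-occurrence prevalence
  logit(π) = intercept + slope·(centred true richness) + era shift +
  heterogeneity (sd 1 on the logit scale, giving the observed 0–1 range and
  a mean well above the median, as in real compilations). About 30% of
  non-eligible rows report a small (<10) sample size, mirroring the fact
  that only about a quarter of compiled observations report usable sample
  sizes.
* **The published-database emulation** pins the row-count marginals to the
  published values — 2118 rows; 1424 analytical split 481/492/451 across
  eras; 112/144/117 prevalence-eligible — and sets era prevalence levels
  calibrated (a one-time Monte-Carlo root-find, frozen in code) so the
  median *observed* k/n per era reproduces the published 5%/4%/10% in
  expectation. The observed median of ~112 values still carries a
  seed-to-seed sd of ~0.6–1 percentage points; that scatter is a property
  of the statistic, not the generator. Within-era period allocation follows
  the published density peaks (Devonian, Jurassic, Neogene).
* **Scenario bundles** (`neutral`, `amplification`, `dilution`) instead pin
  only grand totals and allocate records across periods in a single
  multinomial with weights exp(count-link · centred richness) — exactly the
  allocation a Poisson log-link count model describes, so the neutral
  scenario is a true null for the occurrence model. Scenario slopes
  (prevalence logit ±0.03 per centred genus; count link 0.005) were sized by
  a design-stage power analysis and frozen: with only ~8 periods carrying
  complete predictors and S̄ strongly collinear with the turnover rates and
  age (R² up to ~0.98 across seeds), reliable sign recovery requires
  link-scale effects of ~3 SD, not the ~0.5 SD that would suffice in an
  orthogonal design. This is a real property of period-level Phanerozoic
  regressions worth knowing when interpreting fitted tables.

What passing tests on these simulations do *not* show: the generator has no
taphonomic overprint, no spatial or environmental structure, no correlation
between sample size and prevalence (the published n ≥ 20 robustness medians
are lower than the n ≥ 10 ones, implying such a correlation in real data),
and parasite identity is a label, not a process. Results on real compilations
inherit all of those complications.

## What is, and is not, reproduced

Deterministic quantities reproduce the published worked examples exactly:
era occurrence rates 1.66/2.66/6.83 Myr⁻¹, prevalence-observation rates
0.39/0.78/1.77 Myr⁻¹, and the 2118/1424/373 record-count structure. Era
prevalence medians reproduce in expectation (5/4/10%) with the sampling
scatter noted above. Published GLM coefficient tables and Mann–Whitney
p-values are *not* reproducible from this package alone: they depend on the
unpublished full compilation and on dated Paleobiology Database snapshots.
The package's evidence that the model stage is correct is therefore
simulation-based: closed-form fits to 1e-8, null rejection rates at the
nominal α, and ≥90% sign recovery on the signal scenarios.

## Numerical and degenerate-input choices

Quorum comparisons use a 1e-12 tolerance so accumulated floating-point
coverage exactly at q stops the walk. Empty bins, unreachable quorums, edge
bins, rank-deficient designs (e.g. all prevalence records in one period) and
non-convergent fits all surface as flagged cells, warnings, or errors —
never silent numbers. Bootstrap and subsampling seeds are explicit
arguments; seeded helpers restore the caller's RNG state. Problem sizes in
the test-suite simulations (100 seeds per scenario at the ~2100-row scale,
200 replicates for turnover consistency, 1000 datasets for bootstrap
coverage) were chosen to bound Monte-Carlo error well below the tolerances
they check.
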
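# paleoprev

Parasitism occurrence and prevalence versus host diversity across the
Phanerozoic.

`paleoprev` is an R package for palaeobiologists studying how marine
parasite–host interactions relate to host biodiversity over geologic time.
It takes two inputs — a compiled table of species-level host occurrences
bearing parasitic traces (with confidence categories and, where reported,
specimens examined/infested) and a Paleobiology-Database-style genus
occurrence export — and produces:

* **prevalence statistics**: per-occurrence prevalence p = k/n for records
  with n ≥ 10 specimens, era medians with percentile-bootstrap 95% CIs,
  two-sided Mann–Whitney era comparisons, and per-Myr observation rates;
* **coverage-standardized diversity**: shareholder quorum subsampling (SQS,
  quorum 0.6, 50 trials) of genus occurrences per period — mean sampled
  richness S̄ — plus three-timer (3T) origination and extinction rates
  λᵢ = log(t2_top/t3) + log(P_s,ᵢ₋₁), μᵢ = log(t2_bottom/t3) + log(P_s,ᵢ₊₁),
  with P_s = 3t/(3t + pt);
* **weighted GLMs**: a Poisson (log link) model of occurrence counts per
  period and a binomial (logit link) model of per-occurrence prevalence,
  both on S̄, λ, μ and age, weighted by log10 specimen counts, with Wald
  tables (codes `#` p<0.10, `*` <0.05, `**` <0.01, `***` <0.001) and an
  explicit classifier of each fit as supporting **amplification** (parasitism
  rises with host diversity) or **dilution** (prevalence falls as diversity
  rises);
* **synthetic data with known truth**: a branching-process fossil-record
  generator and parasitism-database emulator, so the whole chain is testable
  offline, including an emulation of the published database's marginals
  (2118 records, 1424 unambiguous, 373 prevalence-eligible).

## Worked example

```r
library(paleoprev)

# emulation of the compiled database at its published marginals
bundle <- emulate_published_database(seed = 1)
res <- run_analysis(run_config(parasitism  = bundle$parasitism,
                               occurrences = bundle$occurrences,
                               bootstrap_B = 10000, seed = 1))
res$era_summary
#> Era-level parasite prevalence summary
#>        era n_values median_p ci_low ci_high obs_per_myr flag
#>  Paleozoic      112     0.06   0.03    0.08        0.39
#>   Mesozoic      144     0.05   0.04    0.06        0.78
#>   Cenozoic      117     0.09   0.06    0.10        1.77
#>
#> Pairwise Mann-Whitney (two-sided):
#>      era_a    era_b      U        p               method
#>  Paleozoic Mesozoic 8039.5 0.967000 normal-tie-corrected
#>  Paleozoic Cenozoic 4797.0 0.000430 normal-tie-corrected
#>   Mesozoic Cenozoic 6112.0 0.000128 normal-tie-corrected
```

Prevalence observations accumulate at 0.39, 0.78 and 1.77 per Myr across the
three eras (1.66, 2.66 and 6.83 Myr⁻¹ for occurrence counts), and the
Cenozoic median prevalence sits significantly above the two earlier eras —
the temporal pattern the emulation is built to carry. On a synthetic
*amplification* scenario, where the generator links both occurrence
intensity and prevalence to true standing richness, the occurrence GLM
recovers the positive diversity effect:

```r
b <- scenario_bundle("amplification", "paper", seed = 42)
analytical <- filter_analytical(b$parasitism)
divtab <- diversity_table(b$occurrences, q = 0.6, trials = 50, seed = 42)
fit <- occurrence_model(analytical, divtab)
summary(fit)
#> Unweighted poisson GLM — Wald summary (model covariance)
#>         term   estimate      se     z        p code
#>  (Intercept) -0.4326000 1.18000 -0.37 7.14e-01
#>       S_mean  0.0104400 0.00261  4.00 6.35e-05  ***
#>    lambda_3t  1.2710000 0.60800  2.09 3.67e-02    *
#>        mu_3t -0.3327000 0.97900 -0.34 7.34e-01
#>          age  0.0002555 0.00161  0.16 8.74e-01
#> residual deviance: 12.056 on 3 df
classify_support(fit)
#> all: amplification
#> mechanism: (+) S_mean***; (+) lambda_3t*
```

The positive, highly significant `S_mean` coefficient (occurrences multiply
by exp(0.0104) ≈ 1.01 per sampled genus) drives the amplification call; this
fit fell back to unweighted because one usable period reported no sample
sizes, mirroring the annotation convention for inadequately sampled groups.

## Input formats

* **Parasitism CSV** (one row per species-level host occurrence):
  `record_id, host_taxon, host_phylum, host_class, parasite_phylum,
  certainty (1–4), n_specimens, n_infested, best_age_ma, period, era,
  reference_id`. Rows failing validation (k > n, ages outside 0–541 Ma,
  period/era inconsistent with the age) are rejected and listed in the
  attached validation report; rows without sample sizes are kept as
  occurrences but are ineligible for prevalence.
* **Occurrence CSV** (PBDB export style): `genus, class, collection_no,
  max_ma, min_ma, reference_no`; extra columns ignored. Ranges spanning a
  period boundary are flagged age-ambiguous and excluded from bins.

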
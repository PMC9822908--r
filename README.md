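# alsSubtypes

Molecular subtype discovery and classification for bulk postmortem-cortex
RNA-seq with locus-specific transposable-element (TE) features.

ALS cortex transcriptomes stratify into three recurrent expression programs —
a glial-activation program (**ALS-Glia**), an oxidative-stress / synaptic
program (**ALS-Ox**), and a transcriptional-dysregulation program with
elevated TE expression (**ALS-TD**) — that differ in clinical course, most
notably survival. `alsSubtypes` implements the full workflow for discovering
and using such subtypes:

- **TE features** — parsing/validation of locus IDs of the form
  `chrom|start|end|subfamily:family:superfamily|score|strand`, the score ≥ 99
  retention filter, the nonzero-in-all-samples rule, and gene+TE matrix
  assembly.
- **Normalization** — median-of-ratios size factors; a closed-form
  negative-binomial variance stabilizing transformation under the dispersion
  trend α(μ) = a0 + a1/μ; MAD-based variable-feature selection (top 10,000 by
  default); linear covariate adjustment (RIN, site, platform); reference
  z-scoring with a −4 clip for control samples.
- **Differential expression** — a deliberately simple NB Wald GLM
  (IRLS, fixed trend dispersion, BH correction) used for XIST/UTY-based sex
  calling and sex-gene removal before clustering.
- **Consensus nsNMF subtyping** — non-smooth NMF (X ≈ W·S·H,
  S = (1−θ)I + (θ/k)J) with multiplicative KL updates, cophenetic-correlation
  rank estimation over ranks 2–6 (50 runs each), 10-replicate consensus labels
  with an 11th-run tiebreaker, entropy feature scores, and top-1000-per-cohort
  feature union.
- **Co-expression** — topological-overlap modules (soft power 13, minimum
  size 25), module eigengenes, eigengene–trait correlation, one-vs-rest
  subtype dummy regression, hypergeometric over-representation, and
  weight-thresholded network edge export (0.05).
- **Bootstrap classification** — per-sample subtype scores (mean predictor
  expression minus mean expression of the full classification feature list),
  1000 bootstrap resamples of the predictor sets, pure calls at >50% pass
  fraction, hybrid states at >40% for a second subtype, and hexagonal
  coordinates where pure vertices, hybrid vertices and the origin have exact
  geometric meaning.
- **Clinical endpoints** — patient consensus labels with the Discordant rule,
  Kaplan–Meier product-limit curves, omnibus and pairwise log-rank tests,
  ANOVA, chi-square independence, and cross-study label agreement.
- **Synthetic cohorts** — a seeded generator producing NB counts with three
  subtype programs (proportions 3 : 1.4 : 1), TE-like features, a platform
  batch, sex-dependent genes, hybrid samples, and subtype-dependent
  exponential survival (medians 28 / 36 / 42 months), so the whole pipeline
  is testable without patient data.

The methods vignette (`vignettes/methods.Rmd`) documents the model choices,
including the one deliberate deviation: classification thresholds are
calibrated against the out-of-subtype score distribution
(`build_null(method = "reference")`) because the literal per-sample
self-resampling null is not a calibrated test; the literal construction
remains available as `build_null(method = "resample")`.

## Worked example

```r
library(alsSubtypes)

# 1. Simulate a cohort: 150 cortex samples, 2700 genes + 300 TE loci
cohort <- generate_cohort(cohort_config(seed = 1))

# 2. TE retention filter (score >= 99, nonzero in every sample)
tes  <- cohort$counts[cohort$counts$feature_kind == "TE", ]
kept <- filter_te_features(tes)

# 3. Remove sex-dependent genes, normalize, select variable features
drop   <- remove_sex_features(cohort$counts)
counts <- cohort$counts[!rownames(cohort$counts$values) %in% drop, ]
vst    <- vst_transform(counts$values, size_factors(counts$values))
X      <- vst$values[select_mad_features(vst, 1000), ]
X      <- X - min(0, min(X))

# 4. Consensus nsNMF subtyping (10 replicates, rank 3)
cons <- consensus_subtypes(X, k = 3, n_runs = 10, max_iter = 500, seed = 1)
adjusted_rand_index(cons$labels, cohort$true_sample_labels)

# 5. Survival by subtype
clin <- generate_clinical(cohort, seed = 11)
logrank_test(clin$duration_months, clin$event, clin$subtype)
```

Output (printed by the code above):

```
SyntheticCohort: 150 samples / 71 patients, 2700 genes + 300 TEs
Glia   Ox   TD
  24   75   51
TE filter: 243 of 300 loci retained
sex-dependent features removed: 285
ConsensusResult: k = 3, cophenetic rho = 0.9576, 150 samples
ARI vs simulated truth: 0.930
omnibus log-rank: chi2 = 5.22 (df 2), p = 0.0736
```

Reading these numbers: 243 of 300 simulated TE loci clear the score/nonzero
filter; the sex contrast removes the 50 planted sex genes plus genes that are
sex-confounded by chance at 71 patients (the published procedure tests sex
without subtype covariates, and at this cohort size sex and subtype are
measurably correlated); consensus clustering recovers the three planted
programs almost perfectly (ARI 0.93, cophenetic ρ 0.96); and at only 71
patients the 28/36/42-month survival separation is not yet significant
(p = 0.07) — the acceptance tests demonstrate median recovery and p < 0.01 at
500 patients per group. A full end-to-end run, including classification and
clinical statistics, is `run_pipeline(pipeline_config(simcohort =
cohort_config(seed = 1)), "out")` or, from the shell,
`inst/scripts/als-subtypes run-all --out out --seed 1`.

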
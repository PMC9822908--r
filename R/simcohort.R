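SUBTYPE_NAMES <- c("Ox", "TD", "Glia")

#' Synthetic cohort configuration
#'
#' Defaults state the world the pipeline assumes: 150 cortex samples over
#' 3000 features (2700 genes + 300 TE loci), three expression programs in
#' proportions 3 : 1.4 : 1 (Ox : TD : Glia), program effect 1.5 log2 units
#' over 150 genes per program, negative-binomial counts with dispersion 0.2
#' (variance mu + 0.2 mu^2), a two-platform batch effect, sex-dependent genes
#' (including XIST/UTY markers), and one to three cortex samples per patient.
#'
#' @param n_samples,n_genes,n_te,n_subtypes cohort dimensions.
#' @param subtype_proportions simplex vector over subtypes (sums to 1).
#' @param program_size genes per subtype program (disjoint across subtypes).
#' @param program_log2fc program effect size in log2 units.
#' @param baseline_mean_log_range interval for natural-log baseline gene
#'   means.
#' @param te_mean_log_range interval for natural-log baseline TE means (kept
#'   high enough that a useful fraction of loci is nonzero in every sample).
#' @param dispersion NB dispersion alpha; variance = mu + alpha mu^2.
#' @param batch_frac fraction of samples on the second sequencing platform.
#' @param batch_log2fc platform shift applied to a random 10\% gene subset.
#' @param n_sex_genes number of sex-dependent genes (+/- 2 log2fc by sex),
#'   two of which are the XIST / UTY markers.
#' @param te_skew_frac fraction of TE loci with subtype-skewed expression.
#' @param te_skew_log2fc effect size of the TE subtype skew.
#' @param hybrid_frac fraction of samples expressing two programs at half
#'   strength; default 0.1, the approximate hybrid incidence seen in
#'   score-based classification of ALS cortex (24 of 244 classified samples).
#' @param samples_per_patient probability vector over 1, 2, 3 samples.
#' @param seed RNG seed.
#' @return `CohortConfig` list.
#' @export
cohort_config <- function(n_samples = 150, n_genes = 2700, n_te = 300,
                          n_subtypes = 3,
                          subtype_proportions = c(3, 1.4, 1) / 5.4,
                          program_size = 150, program_log2fc = 1.5,
                          baseline_mean_log_range = c(log(5), log(500)),
                          te_mean_log_range = c(log(20), log(200)),
                          dispersion = 0.2, batch_frac = 0.4,
                          batch_log2fc = 1, n_sex_genes = 50,
                          te_skew_frac = 0.5, te_skew_log2fc = 1,
                          hybrid_frac = 0.1, samples_per_patient = c(0.25, 0.35, 0.4),
                          seed = 1) {
  cfg <- list(n_samples = n_samples, n_genes = n_genes, n_te = n_te,
              n_subtypes = n_subtypes,
              subtype_proportions = subtype_proportions,
              program_size = program_size, program_log2fc = program_log2fc,
              baseline_mean_log_range = baseline_mean_log_range,
              te_mean_log_range = te_mean_log_range,
              dispersion = dispersion, batch_frac = batch_frac,
              batch_log2fc = batch_log2fc, n_sex_genes = n_sex_genes,
              te_skew_frac = te_skew_frac, te_skew_log2fc = te_skew_log2fc,
              hybrid_frac = hybrid_frac,
              samples_per_patient = samples_per_patient, seed = seed)
  validate_cohort_config(cfg)
  structure(cfg, class = "CohortConfig")
}

validate_cohort_config <- function(cfg) {
  counts <- c("n_samples", "n_genes", "n_te", "n_subtypes", "program_size")
  for (nm in counts)
    if (cfg[[nm]] < 0 || (nm != "n_te" && cfg[[nm]] <= 0))
      stop("configuration error: ", nm, " must be positive")
  if (cfg$n_subtypes < 2)
    stop("configuration error: n_subtypes must be >= 2")
  if (abs(sum(cfg$subtype_proportions) - 1) > 1e-12)
    stop("configuration error: subtype_proportions must sum to 1")
  if (length(cfg$subtype_proportions) != cfg$n_subtypes)
    stop("configuration error: one proportion per subtype required")
  if (cfg$program_size * cfg$n_subtypes > cfg$n_genes)
    stop("configuration error: program_size x n_subtypes exceeds n_genes")
  if (cfg$program_size * cfg$n_subtypes + cfg$n_sex_genes > cfg$n_genes)
    stop("configuration error: programs plus sex genes exceed n_genes")
  if (cfg$dispersion < 0) stop("configuration error: dispersion must be >= 0")
  if (cfg$batch_frac < 0 || cfg$batch_frac > 1 ||
      cfg$hybrid_frac < 0 || cfg$hybrid_frac > 1)
    stop("configuration error: fractions must lie in [0, 1]")
  if (abs(sum(cfg$samples_per_patient) - 1) > 1e-8)
    stop("configuration error: samples_per_patient must sum to 1")
  invisible(cfg)
}

rnb <- function(n, mu, alpha) {
  if (alpha <= 1e-12) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / alpha, mu = mu)
}

random_te_ids <- function(n_te) {
  if (n_te == 0) return(character(0))
  subfam <- c("AluSz", "AluY", "L1PA4", "L1MB7", "MLT1B", "MIRb", "L2a",
              "MER41B", "THE1C", "HERVK9-int")
  fam <- c(AluSz = "Alu", AluY = "Alu", L1PA4 = "L1", L1MB7 = "L1",
           MLT1B = "ERVL-MaLR", MIRb = "MIR", L2a = "L2", MER41B = "ERV1",
           THE1C = "ERVL-MaLR", `HERVK9-int` = "ERVK")
  sup <- c(Alu = "SINE", L1 = "LINE", `ERVL-MaLR` = "LTR", MIR = "SINE",
           L2 = "LINE", ERV1 = "LTR", ERVK = "LTR")
  repeat {
    chrom <- sample(paste0("chr", c(1:22, "X")), n_te, replace = TRUE)
    start <- sample.int(2e8, n_te, replace = TRUE)
    len <- sample(80:6000, n_te, replace = TRUE)
    sf <- sample(subfam, n_te, replace = TRUE)
    # scores: most loci confidently aligned (>= 99), a tail below the cutoff
    score <- ifelse(stats::runif(n_te) < 0.85,
                    sample(99:1000, n_te, replace = TRUE),
                    sample(0:98, n_te, replace = TRUE))
    strand <- sample(c("+", "-"), n_te, replace = TRUE)
    ids <- paste(chrom, start, start + len,
                 paste(sf, fam[sf], sup[fam[sf]], sep = ":"),
                 score, strand, sep = "|")
    if (!anyDuplicated(ids)) return(ids)
  }
}

#' Generate a synthetic ALS-like cohort
#'
#' Counts are drawn NB(mean = baseline x 2^(program + batch + sex + TE-skew
#' effects), dispersion alpha), with each subtype's program genes up-shifted
#' only in that subtype's samples; hybrid samples apply two programs at half
#' the configured log2 effect. Patients carry the subtype; their 1-3 cortex
#' samples inherit it. Deterministic given `config$seed`.
#'
#' @param config a `CohortConfig`.
#' @return `SyntheticCohort`: list with `counts` (`CountMatrix` including
#'   sample metadata: patient, platform, RIN, site, sex),
#'   `true_sample_labels`, `true_patient_labels`, `hybrid_flags`,
#'   `hybrid_pairs` (two-column matrix of program pairs for hybrid samples),
#'   `truth_programs` (subtype -> gene IDs), `sex_genes`, `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    k <- config$n_subtypes
    subtype_names <- if (k == 3) SUBTYPE_NAMES else paste0("S", seq_len(k))
    # patients until sample slots are filled
    pat_sizes <- integer(0)
    while (sum(pat_sizes) < config$n_samples)
      pat_sizes <- c(pat_sizes, sample(1:3, 1, prob = config$samples_per_patient))
    overshoot <- sum(pat_sizes) - config$n_samples
    if (overshoot > 0)
      pat_sizes[length(pat_sizes)] <- pat_sizes[length(pat_sizes)] - overshoot
    pat_sizes <- pat_sizes[pat_sizes > 0]
    n_pat <- length(pat_sizes)
    patient_ids <- sprintf("P%03d", seq_len(n_pat))
    pat_subtype <- sample(subtype_names, n_pat, replace = TRUE,
                          prob = config$subtype_proportions)
    sample_patient <- rep(patient_ids, pat_sizes)
    sample_subtype <- rep(pat_subtype, pat_sizes)
    n <- length(sample_patient)
    sample_ids <- sprintf("S%03d", seq_len(n))

    gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
    te_ids <- random_te_ids(config$n_te)
    # program gene sets: disjoint blocks at the top of the gene list
    programs <- lapply(seq_len(k), function(s)
      gene_ids[((s - 1) * config$program_size + 1):(s * config$program_size)])
    names(programs) <- subtype_names
    # sex genes drawn from non-program genes; first two act as XIST / UTY
    non_prog <- setdiff(gene_ids, unlist(programs))
    sex_genes <- character(0)
    if (config$n_sex_genes > 0) {
      sex_genes <- sample(non_prog, config$n_sex_genes)
      gene_ids[match(sex_genes[1:min(2, length(sex_genes))], gene_ids)] <-
        c("XIST", "UTY")[1:min(2, length(sex_genes))]
      sex_genes[1:min(2, length(sex_genes))] <-
        c("XIST", "UTY")[1:min(2, length(sex_genes))]
      for (s in seq_len(k)) names(programs[[s]]) <- NULL
    }

    # per-sample covariates
    platform <- ifelse(stats::runif(n) < config$batch_frac, "NovaSeq", "HiSeq")
    rin <- stats::runif(n, 5, 9)
    site <- sample(c("siteA", "siteB", "siteC"), n, replace = TRUE)
    pat_sex <- sample(c("female", "male"), n_pat, replace = TRUE)
    sex <- rep(pat_sex, pat_sizes)

    # hybrid samples: two distinct programs at half strength
    hybrid <- stats::runif(n) < config$hybrid_frac
    hybrid_pairs <- matrix(NA_character_, n, 2)
    for (j in which(hybrid)) {
      second <- sample(setdiff(subtype_names, sample_subtype[j]), 1)
      hybrid_pairs[j, ] <- c(sample_subtype[j], second)
    }

    # log2 effect matrix, features x samples
    all_ids <- c(gene_ids, te_ids)
    nfeat <- length(all_ids)
    log_mu_base <- c(stats::runif(config$n_genes,
                                  config$baseline_mean_log_range[1],
                                  config$baseline_mean_log_range[2]),
                     stats::runif(config$n_te,
                                  config$te_mean_log_range[1],
                                  config$te_mean_log_range[2]))
    effect <- matrix(0, nfeat, n, dimnames = list(all_ids, sample_ids))
    for (s in subtype_names) {
      rows <- match(programs[[s]], all_ids)
      pure_cols <- which(sample_subtype == s & !hybrid)
      effect[rows, pure_cols] <- effect[rows, pure_cols] + config$program_log2fc
      half_cols <- which(hybrid & (hybrid_pairs[, 1] == s | hybrid_pairs[, 2] == s))
      effect[rows, half_cols] <- effect[rows, half_cols] + config$program_log2fc / 2
    }
    # batch effect on a random 10% gene subset
    if (config$batch_frac > 0 && config$batch_log2fc != 0) {
      batch_genes <- sample(config$n_genes, max(1, round(config$n_genes * 0.1)))
      effect[batch_genes, platform == "NovaSeq"] <-
        effect[batch_genes, platform == "NovaSeq"] + config$batch_log2fc
    }
    # sex effects: +/- 2 log2fc; XIST up in females, UTY up in males
    if (length(sex_genes) > 0) {
      sex_dir <- stats::setNames(sample(c(-2, 2), length(sex_genes),
                                        replace = TRUE), sex_genes)
      if ("XIST" %in% sex_genes) sex_dir["XIST"] <- 4
      if ("UTY" %in% sex_genes) sex_dir["UTY"] <- -4
      fem <- sex == "female"
      rows <- match(sex_genes, all_ids)
      effect[rows, fem] <- effect[rows, fem] + sex_dir
    }
    # TE subtype skew
    if (config$n_te > 0 && config$te_skew_frac > 0) {
      n_skew <- round(config$n_te * config$te_skew_frac)
      if (n_skew > 0) {
        skew_rows <- config$n_genes + sample(config$n_te, n_skew)
        skew_sub <- sample(subtype_names, n_skew, replace = TRUE)
        for (i in seq_len(n_skew)) {
          cols <- sample_subtype == skew_sub[i]
          effect[skew_rows[i], cols] <- effect[skew_rows[i], cols] +
            config$te_skew_log2fc
        }
      }
    }

    mu <- exp(log_mu_base) * 2^effect
    counts <- matrix(rnb(length(mu), as.vector(mu), config$dispersion),
                     nfeat, n, dimnames = list(all_ids, sample_ids))
    meta <- data.frame(sample = sample_ids, patient = sample_patient,
                       platform = platform, rin = rin, site = site, sex = sex,
                       stringsAsFactors = FALSE)
    cm <- count_matrix(counts,
                       feature_kind = rep(c("gene", "TE"),
                                          c(config$n_genes, config$n_te)),
                       sample_metadata = meta)
    structure(list(counts = cm,
                   true_sample_labels = stats::setNames(sample_subtype, sample_ids),
                   true_patient_labels = stats::setNames(pat_subtype, patient_ids),
                   hybrid_flags = stats::setNames(hybrid, sample_ids),
                   hybrid_pairs = hybrid_pairs,
                   truth_programs = programs,
                   sex_genes = sex_genes,
                   config = config),
              class = "SyntheticCohort")
  })
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d samples / %d patients, %d genes + %d TEs\n",
              ncol(x$counts$values), length(x$true_patient_labels),
              sum(x$counts$feature_kind == "gene"),
              sum(x$counts$feature_kind == "TE")))
  print(table(x$true_sample_labels))
  invisible(x)
}

#' Generate subtype-dependent clinical endpoints for a synthetic cohort
#'
#' Disease duration is exponential with the subtype's configured median
#' (defaults 28 / 36 / 42 months for Glia / Ox / TD), onset age normal around
#' the subtype mean, age at death = onset + duration / 12, and a fraction of
#' patients is censored at a uniform fraction of their drawn duration.
#' Deterministic given `seed`.
#'
#' @param cohort a `SyntheticCohort`.
#' @param median_survival_by_subtype named months per subtype.
#' @param onset_mean_by_subtype named years per subtype.
#' @param onset_sd SD of onset age in years, default 10.
#' @param censor_frac proportion of patients censored, in \[0, 1\].
#' @param ftld_prob probability of FTLD comorbidity, default 0.15.
#' @param seed RNG seed.
#' @return `ClinicalTable` data.frame: `patient`, `subtype`, `onset_age`,
#'   `age_death`, `duration_months`, `event`, `onset_site`, `ftld`.
#' @export
generate_clinical <- function(cohort,
                              median_survival_by_subtype = c(Glia = 28, Ox = 36, TD = 42),
                              onset_mean_by_subtype = c(Glia = 63.2, Ox = 60.4, TD = 62),
                              onset_sd = 10, censor_frac = 0,
                              ftld_prob = 0.15, seed = 1) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  labs <- cohort$true_patient_labels
  if (!all(unique(labs) %in% names(median_survival_by_subtype)) ||
      !all(unique(labs) %in% names(onset_mean_by_subtype)))
    stop("every patient subtype must appear in the parameter maps")
  if (any(median_survival_by_subtype <= 0))
    stop("configuration error: medians must be positive")
  if (censor_frac < 0 || censor_frac > 1)
    stop("configuration error: censor_frac must lie in [0, 1]")
  with_seed(seed, {
    n <- length(labs)
    rate <- log(2) / median_survival_by_subtype[labs]
    duration <- stats::rexp(n, rate = rate)
    onset <- stats::rnorm(n, mean = onset_mean_by_subtype[labs], sd = onset_sd)
    censored <- seq_len(n) %in% sample(n, round(censor_frac * n))
    duration[censored] <- duration[censored] * stats::runif(sum(censored))
    site <- sample(c("bulbar", "limb", "other"), n, replace = TRUE,
                   prob = c(0.3, 0.6, 0.1))
    out <- data.frame(patient = names(labs), subtype = unname(labs),
                      onset_age = onset,
                      age_death = onset + duration / 12,
                      duration_months = duration,
                      event = !censored,
                      onset_site = site,
                      ftld = stats::runif(n) < ftld_prob,
                      stringsAsFactors = FALSE)
    class(out) <- c("ClinicalTable", "data.frame")
    out
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Counts as TSV (and optionally a MatrixMarket triplet), sample metadata and
#' clinical table as CSV, configuration as JSON.
#'
#' @param cohort `SyntheticCohort`.
#' @param dir output directory (created if needed).
#' @param clinical optional `ClinicalTable`.
#' @param mtx also write counts as MatrixMarket triplet.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, clinical = NULL, mtx = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts_tsv(cohort$counts, file.path(dir, "counts.tsv"))
  utils::write.csv(cohort$counts$sample_metadata,
                   file.path(dir, "sample_metadata.csv"), row.names = FALSE)
  truth <- data.frame(sample = names(cohort$true_sample_labels),
                      subtype = unname(cohort$true_sample_labels),
                      hybrid = unname(cohort$hybrid_flags))
  utils::write.csv(truth, file.path(dir, "truth_labels.csv"), row.names = FALSE)
  if (!is.null(clinical))
    utils::write.csv(clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  if (mtx) {
    Matrix::writeMM(Matrix::Matrix(cohort$counts$values, sparse = TRUE),
                    file.path(dir, "counts.mtx"))
    writeLines(rownames(cohort$counts$values), file.path(dir, "features.txt"))
    writeLines(colnames(cohort$counts$values), file.path(dir, "samples.txt"))
  }
  invisible(dir)
}
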
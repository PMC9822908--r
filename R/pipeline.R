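#' Pipeline configuration with published stage defaults
#'
#' @param simcohort optional `CohortConfig`; when supplied the cohort is
#'   generated rather than read from files.
#' @param counts_path,metadata_path,clinical_path input files (TSV counts,
#'   CSV metadata/clinical) used when no `simcohort` block is given.
#' @param te_min_score TE alignment-score filter, default 99.
#' @param mad_top MAD features kept for clustering, default 10000 (capped at
#'   the feature count).
#' @param rank factorization rank, default 3.
#' @param rank_candidates ranks scanned during estimation, default 2:6.
#' @param rank_runs runs per candidate rank, default 50.
#' @param consensus_runs consensus replicates, default 10.
#' @param nmf_iter nsNMF update sweeps, default 500 (the published listing
#'   says 200, but with theta = 0.5 smoothing the multiplicative updates are
#'   frequently pre-convergence at 200 sweeps on cohorts of 60-150 samples;
#'   reference implementations iterate to stationarity with much higher caps).
#' @param theta nsNMF smoothing, default 0.5.
#' @param top_features per-cohort feature-score cut, default 1000.
#' @param soft_power,min_module_size co-expression parameters (13, 25).
#' @param n_null_sets resampled predictor sets, default 100.
#' @param n_boot bootstrap iterations, default 1000.
#' @param pure_frac,hybrid_frac classification call fractions (0.5, 0.4).
#' @param weight_rule threshold weighting rule, see [build_null()].
#' @param platform_column metadata column used for cohort splitting.
#' @param estimate_rank_stage run the rank-estimation scan (slow; default
#'   FALSE — the rank default is the production choice).
#' @param seed global seed; per-stage seeds are derived at fixed offsets.
#' @return `PipelineConfig` list.
#' @export
pipeline_config <- function(simcohort = NULL, counts_path = NULL,
                            metadata_path = NULL, clinical_path = NULL,
                            te_min_score = 99, mad_top = 10000, rank = 3,
                            rank_candidates = 2:6, rank_runs = 50,
                            consensus_runs = 10, nmf_iter = 500, theta = 0.5,
                            top_features = 1000, soft_power = 13,
                            min_module_size = 25, n_null_sets = 100,
                            n_boot = 1000, pure_frac = 0.5, hybrid_frac = 0.4,
                            weight_rule = "proportion",
                            platform_column = "platform",
                            estimate_rank_stage = FALSE, seed = 1) {
  structure(as.list(environment()), class = "PipelineConfig")
}

match_clusters_by_centroid <- function(X, labels_a, labels_b, samples_a,
                                       samples_b, k) {
  # relabel cohort-b clusters to best match cohort-a via centroid correlation
  cent <- function(labels, samples) vapply(seq_len(k), function(c0) {
    cols <- samples[labels == c0]
    if (length(cols) == 0) return(rep(NA_real_, nrow(X)))
    rowMeans(X[, cols, drop = FALSE])
  }, numeric(nrow(X)))
  ca <- cent(labels_a, samples_a); cb <- cent(labels_b, samples_b)
  cors <- suppressWarnings(stats::cor(ca, cb))
  cors[!is.finite(cors)] <- -1
  perms <- all_permutations(k)
  best <- perms[which.max(apply(perms, 1, function(p)
    sum(cors[cbind(seq_len(k), p)]))), ]
  map <- integer(k); map[best] <- seq_len(k)
  map
}

#' Run the end-to-end subtyping pipeline
#'
#' Stages, in order: TE score/nonzero filtering, gene + TE assembly, sex-gene
#' removal, size factors, VST, MAD feature selection, per-platform nsNMF
#' consensus subtyping (cluster labels aligned across platforms by centroid
#' correlation), feature scores and top-feature union, co-expression modules
#' and eigengenes with subtype association, covariate adjustment (RIN, site,
#' platform), eigengene-derived predictor sets, bootstrap classification, and
#' (when a clinical table is available) patient consensus labels with
#' Kaplan-Meier / log-rank, ANOVA and chi-square endpoint statistics. Every
#' stage artifact is written under `out_dir` together with a JSON manifest of
#' parameters and seeds.
#'
#' @param config a `PipelineConfig`.
#' @param out_dir output directory.
#' @param clinical optional `ClinicalTable` (overrides `clinical_path`; for a
#'   simulated cohort one is generated unless `clinical = NA`).
#' @return results bundle (list), invisibly writes artifacts.
#' @export
run_pipeline <- function(config, out_dir, clinical = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[pipeline] ", sprintf(...))
  bundle <- list(config = config)

  # --- input acquisition -----------------------------------------------------
  if (!is.null(config$simcohort)) {
    log_stage("generating synthetic cohort (seed %d)", config$simcohort$seed)
    cohort <- generate_cohort(config$simcohort)
    counts <- cohort$counts
    bundle$cohort <- cohort
    if (is.null(clinical))
      clinical <- generate_clinical(cohort, seed = config$seed + 11L)
    if (length(clinical) == 1 && is.na(clinical)) clinical <- NULL
  } else {
    if (is.null(config$counts_path)) stop("no inputs: need simcohort or counts_path")
    meta <- if (!is.null(config$metadata_path))
      utils::read.csv(config$metadata_path, stringsAsFactors = FALSE)
    counts <- read_counts_tsv(config$counts_path, sample_metadata = meta)
    if (is.null(clinical) && !is.null(config$clinical_path))
      clinical <- utils::read.csv(config$clinical_path, stringsAsFactors = FALSE)
  }

  # --- TE filter + assembly --------------------------------------------------
  is_te <- counts$feature_kind == "TE"
  if (any(is_te)) {
    tes <- filter_te_features(counts[is_te, ], min_score = config$te_min_score)
    log_stage("TE filter: %d of %d loci retained", nrow(tes$values), sum(is_te))
    counts <- assemble_feature_matrix(counts[!is_te, ], tes)
  }

  # --- sex-gene removal ------------------------------------------------------
  drop_sex <- tryCatch(remove_sex_features(counts),
                       error = function(e) {
                         log_stage("sex-gene removal skipped: %s", conditionMessage(e))
                         character(0)
                       })
  log_stage("removing %d sex-dependent feature(s)", length(drop_sex))
  counts_clust <- counts[!rownames(counts$values) %in% drop_sex, ]
  bundle$sex_features_removed <- drop_sex

  # --- normalization + feature selection ------------------------------------
  sf <- size_factors(counts_clust$values)
  vst <- vst_transform(counts_clust$values, sf)
  n_top <- min(config$mad_top, nrow(vst$values))
  mad_features <- select_mad_features(vst, n_top = n_top)
  X <- vst$values[mad_features, , drop = FALSE]
  X <- X - min(0, min(X))  # shift-to-nonnegative for NMF
  bundle$size_factors <- sf
  bundle$mad_features <- mad_features

  # --- per-platform consensus clustering ------------------------------------
  meta <- counts_clust$sample_metadata
  platform <- if (!is.null(meta) && config$platform_column %in% names(meta))
    as.character(meta[[config$platform_column]]) else rep("all", ncol(X))
  platforms <- unique(platform)
  k <- config$rank
  if (config$estimate_rank_stage) {
    log_stage("rank estimation over ranks %s", paste(config$rank_candidates,
                                                     collapse = ","))
    bundle$rank_estimation <- estimate_rank(X, ranks = config$rank_candidates,
                                            n_runs = config$rank_runs,
                                            theta = config$theta,
                                            max_iter = config$nmf_iter,
                                            seed = config$seed + 100L)
  }
  consensus <- list()
  labels <- stats::setNames(integer(ncol(X)), colnames(X))
  for (i in seq_along(platforms)) {
    pf <- platforms[i]
    cols <- platform == pf
    log_stage("consensus nsNMF on %s cohort (%d samples)", pf, sum(cols))
    cr <- consensus_subtypes(X[, cols, drop = FALSE], k = k,
                             n_runs = config$consensus_runs,
                             theta = config$theta,
                             max_iter = config$nmf_iter,
                             seed = config$seed + 200L + i)
    consensus[[pf]] <- cr
    lab <- cr$labels
    if (i > 1) {  # align to the first platform's cluster identities
      map <- match_clusters_by_centroid(X, consensus[[platforms[1]]]$labels,
                                        lab, colnames(X)[platform == platforms[1]],
                                        colnames(X)[cols], k)
      lab <- stats::setNames(map[lab], names(lab))
    }
    labels[names(lab)] <- lab
  }
  subtype_names <- paste0("S", seq_len(k))
  sample_labels <- stats::setNames(subtype_names[labels], names(labels))
  bundle$consensus <- consensus
  bundle$sample_labels <- sample_labels

  # --- feature scores + union ------------------------------------------------
  score_tables <- lapply(consensus, function(cr) feature_scores(cr$fits))
  union_features <- select_top_features(score_tables,
                                        n_top = min(config$top_features,
                                                    nrow(X)))
  log_stage("feature union: %d features", length(union_features))
  bundle$feature_scores <- score_tables
  bundle$union_features <- union_features

  # --- modules + eigengenes --------------------------------------------------
  Xu <- vst$values[union_features, , drop = FALSE]
  modules <- tryCatch(detect_modules(Xu, soft_power = config$soft_power,
                                     min_size = config$min_module_size),
                      error = function(e) NULL)
  if (is.null(modules)) {
    log_stage("module detection failed; predictors fall back to per-subtype top features")
  }
  eigengenes <- NULL; assoc <- NULL
  if (!is.null(modules)) {
    mods <- setdiff(unique(modules$labels), "gray")
    if (length(mods) >= 1) {
      eigengenes <- vapply(mods, function(mm)
        module_eigengene(Xu, names(modules$labels)[modules$labels == mm]),
        numeric(ncol(Xu)))
      traits <- NULL
      if (!is.null(clinical) && !is.null(meta)) {
        idx <- match(meta$patient, clinical$patient)
        traits <- data.frame(onset_age = clinical$onset_age[idx],
                             age_death = clinical$age_death[idx],
                             duration_months = clinical$duration_months[idx])
      }
      assoc <- eigengene_association(eigengenes, traits = traits,
                                     subtypes = sample_labels[colnames(Xu)])
    }
  }
  bundle$modules <- modules
  bundle$eigengenes <- eigengenes
  bundle$associations <- assoc

  # --- covariate adjustment --------------------------------------------------
  adj <- vst
  if (!is.null(meta)) {
    covs <- meta[, intersect(c("rin", "site", "platform"), names(meta)),
                 drop = FALSE]
    if (ncol(covs) > 0) {
      complete <- stats::complete.cases(covs)
      if (!all(complete))
        log_stage("excluding %d sample(s) with missing covariates", sum(!complete))
      adj <- tryCatch(
        adjust_covariates(
          new_transformed(vst$values[, complete, drop = FALSE], vst$transform),
          covs[complete, , drop = FALSE]),
        error = function(e) {
          log_stage("covariate adjustment skipped: %s", conditionMessage(e))
          vst
        })
    }
  }

  # --- predictor sets + bootstrap classification -----------------------------
  sets <- NULL
  if (!is.null(assoc) && !is.null(assoc$subtypes)) {
    sets <- list()
    for (s in subtype_names) {
      tab <- assoc$subtypes[assoc$subtypes$subtype == s, ]
      tab <- tab[order(-tab$beta), ]
      best <- tab$eigengene[1]
      members <- names(modules$labels)[modules$labels == best]
      if (length(members) >= 2 && tab$beta[1] > 0) sets[[s]] <- members
    }
    if (length(sets) < k) sets <- NULL
  }
  if (is.null(sets)) {
    # fallback: per-subtype top differential features among the union
    sets <- lapply(subtype_names, function(s) {
      in_s <- sample_labels[colnames(adj$values)] == s
      delta <- rowMeans(adj$values[union_features, in_s, drop = FALSE]) -
        rowMeans(adj$values[union_features, !in_s, drop = FALSE])
      union_features[order(-delta)[seq_len(min(50, length(delta)))]]
    })
    names(sets) <- subtype_names
  }
  psets <- predictor_sets(sets, union_features)
  null <- build_null(adj, psets, method = "reference",
                     reference_labels = sample_labels[colnames(adj$values)],
                     seed = config$seed + 300L)
  classification <- bootstrap_classify(adj, psets, null, n_boot = config$n_boot,
                                       pure_frac = config$pure_frac,
                                       hybrid_frac = config$hybrid_frac,
                                       seed = config$seed + 400L)
  bundle$predictor_sets <- psets
  bundle$null <- null
  bundle$classification <- classification

  # --- clinical stage --------------------------------------------------------
  if (!is.null(clinical) && !is.null(meta)) {
    pat_labels <- vapply(split(sample_labels, meta$patient[match(names(sample_labels),
                                                                 meta$sample)]),
                         patient_consensus_label, character(1))
    cl <- clinical[match(names(pat_labels), clinical$patient), ]
    cl$consensus_label <- unname(pat_labels)
    keep <- cl$consensus_label != "Discordant" &
      !is.na(cl$onset_age) & !is.na(cl$duration_months)
    surv <- cl[keep, ]
    km <- lapply(split(seq_len(nrow(surv)), surv$consensus_label), function(ix)
      kaplan_meier(surv$duration_months[ix], surv$event[ix]))
    lr <- if (length(unique(surv$consensus_label)) >= 2 && any(surv$event))
      logrank_test(surv$duration_months, surv$event, surv$consensus_label) else NULL
    tests <- tryCatch(group_tests(values = cl$onset_age[keep],
                                  labels = cl$consensus_label[keep],
                                  contingency = table(cl$consensus_label[keep],
                                                      cl$ftld[keep])),
                      error = function(e) NULL)
    bundle$patient_labels <- pat_labels
    bundle$clinical <- list(table = cl, km = km, logrank = lr, tests = tests,
                            n_survival = sum(keep))
  } else {
    log_stage("clinical stage skipped: no clinical table available")
  }

  # --- artifacts + manifest --------------------------------------------------
  utils::write.csv(data.frame(sample = names(sample_labels),
                              label = unname(sample_labels),
                              tiebreaker_used = unlist(lapply(platforms, function(pf)
                                consensus[[pf]]$tiebreaker_used))[
                                  order(unlist(lapply(platforms, function(pf)
                                    match(names(consensus[[pf]]$labels),
                                          names(sample_labels)))))]),
                   file.path(out_dir, "sample_labels.csv"), row.names = FALSE)
  utils::write.csv(classification, file.path(out_dir, "classification.csv"),
                   row.names = FALSE)
  writeLines(union_features, file.path(out_dir, "union_features.txt"))
  if (!is.null(bundle$patient_labels))
    utils::write.csv(data.frame(patient = names(bundle$patient_labels),
                                label = unname(bundle$patient_labels)),
                     file.path(out_dir, "patient_labels.csv"), row.names = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("alsSubtypes")),
                   seed = config$seed,
                   stage_seed_offsets = c(rank = 100, consensus = 200,
                                          null = 300, bootstrap = 400,
                                          clinical_sim = 11),
                   parameters = unclass(config)[!vapply(config, is.list, logical(1))])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(bundle)
}
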
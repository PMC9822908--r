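#' Bundle per-subtype predictor feature sets
#'
#' Predictor sets are typically the member features of each subtype's
#' eigengene module; `all_features` is the full classification feature list
#' (the role played by the 1681-feature union) against which scores are
#' centered.
#'
#' @param sets named list (one element per subtype) of feature ID vectors,
#'   each of length >= 2.
#' @param all_features character vector containing every predictor feature.
#' @return `PredictorSets` list.
#' @export
predictor_sets <- function(sets, all_features) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  for (nm in names(sets)) {
    if (length(sets[[nm]]) < 2)
      stop("predictor set '", nm, "' needs >= 2 features")
    if (!all(sets[[nm]] %in% all_features))
      stop("predictor set '", nm, "' contains features outside all_features")
  }
  structure(list(sets = sets, all_features = unique(all_features)),
            class = "PredictorSets")
}

#' Per-sample subtype score
#'
#' Mean expression over the subtype's predictor features minus mean expression
#' over the full classification feature list, per sample, on the
#' covariate-adjusted normalized scale.
#'
#' @param expr `TransformedMatrix` or matrix (features x samples); a single
#'   column (plain named vector) is also accepted.
#' @param predictors predictor feature IDs (nonempty, subset of
#'   `all_features`).
#' @param all_features full classification feature list.
#' @return numeric score per sample.
#' @export
subtype_score <- function(expr, predictors, all_features) {
  m <- if (inherits(expr, "TransformedMatrix")) expr$values else expr
  if (is.null(dim(m))) m <- cbind(sample = m)
  if (length(predictors) == 0) stop("empty predictor set")
  if (!all(predictors %in% all_features))
    stop("predictors must be a subset of all_features")
  if (!all(all_features %in% rownames(m)))
    stop("all_features must be present in the expression matrix")
  colMeans(m[predictors, , drop = FALSE]) -
    colMeans(m[all_features, , drop = FALSE])
}

# Constants for the 15% upper-trimmed normal null estimators: the trimmed
# median sits at z = -0.1890 and MAD(residuals) * 1.4826 equals 0.8463 sigma
# (computed once by large-sample Monte Carlo of the truncated normal).
TRIM_FRACTION <- 0.15
TRIM_MEDIAN_Z <- 0.1890
TRIM_MAD_FACTOR <- 0.8463

#' Build the score null and per-sample classification thresholds
#'
#' Two constructions are provided.
#'
#' `method = "resample"` (the per-sample expected-score null): for each
#' subtype, `n_sets` predictor sets of the original size are sampled with
#' replacement from that subtype's eigengene features and scored per sample;
#' the per-sample cutoff is the 95th percentile of those scores (a 5\% cutoff
#' for the expected subtype score) and the final threshold multiplies the
#' cutoff by a proportion weight: `weight_rule = "proportion"` uses
#' w_s = p_s, `weight_rule = "balanced"` uses w_s = k p_s (w = 1 at equal
#' proportions, i.e. thresholds equal to the unweighted cutoffs). Because
#' these null sets are resamples of the same features that the bootstrap
#' later resamples, the construction is self-referential: it measures each
#' sample's own expected score rather than an off-subtype baseline, and the
#' resulting calls are sensitive to the predictor sets' baseline expression
#' offsets. It is retained as the literal published construction.
#'
#' `method = "reference"` (the default used by the pipeline) requires
#' `reference_labels` (the consensus clustering labels): expression is
#' centered per subtype on the out-of-subtype reference mean, scores are
#' computed for all samples, and each subtype's threshold is an upper
#' confidence bound of the off-subtype score distribution. The bound is
#' estimated robustly: the top 15\% of each off-group is trimmed (genuine
#' hybrid samples carry real partial signal in that tail), and the trimmed
#' median and MAD are de-biased to consistent normal-null estimates; the
#' threshold is max over off-groups of mu_hat + qnorm(conf) sigma_hat. This
#' keeps false subtype calls at ~(1 - conf) while leaving half-strength
#' hybrid expression detectable.
#'
#' @param expr `TransformedMatrix` or matrix (features x samples).
#' @param psets `PredictorSets`.
#' @param n_sets resampled predictor sets per subtype (resample method),
#'   default 100.
#' @param proportions named per-subtype cohort fractions (simplex; names must
#'   match `psets`). Required for the resample method.
#' @param seed RNG seed.
#' @param weight_rule "proportion" (default) or "balanced"; resample method
#'   only.
#' @param method "reference" or "resample".
#' @param reference_labels per-sample subtype labels (reference method).
#' @param conf confidence level of the reference bound, default 0.995.
#' @return `ScoreNull`: list with `thresholds` (samples x subtypes),
#'   `method`, and per-method detail (`null_scores`, `cutoffs`, `weights` for
#'   resample; `centering`, `scores`, `bounds` for reference).
#' @export
build_null <- function(expr, psets, n_sets = 100, proportions = NULL, seed = 1,
                       weight_rule = c("proportion", "balanced"),
                       method = c("resample", "reference"),
                       reference_labels = NULL, conf = 0.995) {
  weight_rule <- match.arg(weight_rule)
  method <- match.arg(method)
  stopifnot(inherits(psets, "PredictorSets"))
  m <- if (inherits(expr, "TransformedMatrix")) expr$values else as.matrix(expr)
  subtypes <- names(psets$sets)
  k <- length(subtypes)
  if (method == "reference") {
    if (is.null(reference_labels))
      stop("reference method requires reference_labels")
    labels <- as.character(reference_labels)
    if (length(labels) != ncol(m))
      stop("reference_labels must have one entry per sample")
    if (!all(subtypes %in% labels))
      stop("every subtype needs at least one reference-labeled sample")
    centering <- lapply(subtypes, function(s)
      rowMeans(m[, labels != s, drop = FALSE]))
    names(centering) <- subtypes
    scores <- vapply(subtypes, function(s) {
      ms <- m - centering[[s]]
      colMeans(ms[psets$sets[[s]], , drop = FALSE]) -
        colMeans(ms[psets$all_features, , drop = FALSE])
    }, numeric(ncol(m)))
    bounds <- vapply(subtypes, function(s) {
      offs <- setdiff(subtypes, s)
      trimmed <- lapply(offs, function(s2) {
        x <- sort(scores[labels == s2, s])
        x[seq_len(max(3L, floor(length(x) * (1 - TRIM_FRACTION))))]
      })
      meds <- vapply(trimmed, stats::median, numeric(1))
      resid <- unlist(lapply(seq_along(trimmed), function(i)
        trimmed[[i]] - meds[i]))
      sigma <- 1.4826 * stats::median(abs(resid)) / TRIM_MAD_FACTOR
      mu <- max(meds) + TRIM_MEDIAN_Z * sigma
      mu + stats::qnorm(conf) * sigma
    }, numeric(1))
    thresholds <- matrix(bounds, ncol(m), k, byrow = TRUE,
                         dimnames = list(colnames(m), subtypes))
    return(structure(list(thresholds = thresholds, method = "reference",
                          centering = centering, scores = scores,
                          bounds = bounds, conf = conf),
                     class = "ScoreNull"))
  }
  if (is.null(proportions)) stop("resample method requires proportions")
  if (is.null(names(proportions))) names(proportions) <- subtypes
  if (!setequal(names(proportions), subtypes))
    stop("proportions must be named by subtype")
  if (abs(sum(proportions) - 1) > 1e-8 || any(proportions < 0))
    stop("proportions must lie on the simplex")
  all_mean <- colMeans(m[psets$all_features, , drop = FALSE])
  null_scores <- with_seed(seed, {
    lapply(subtypes, function(s) {
      feats <- psets$sets[[s]]
      sc <- vapply(seq_len(n_sets), function(t) {
        idx <- sample(feats, length(feats), replace = TRUE)
        colMeans(m[idx, , drop = FALSE]) - all_mean
      }, numeric(ncol(m)))
      if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1)
      sc
    })
  })
  names(null_scores) <- subtypes
  cutoffs <- vapply(null_scores, function(sc)
    apply(sc, 1, stats::quantile, probs = 0.95, names = FALSE),
    numeric(ncol(m)))
  if (is.null(dim(cutoffs)))
    cutoffs <- matrix(cutoffs, ncol = k, dimnames = list(NULL, subtypes))
  rownames(cutoffs) <- colnames(m)
  w <- switch(weight_rule,
              proportion = proportions[subtypes],
              balanced = k * proportions[subtypes])
  thresholds <- sweep(cutoffs, 2, as.numeric(w), "*")
  structure(list(null_scores = null_scores, cutoffs = cutoffs,
                 weights = stats::setNames(as.numeric(w), subtypes),
                 thresholds = thresholds, n_sets = n_sets,
                 weight_rule = weight_rule, method = "resample"),
            class = "ScoreNull")
}

#' Bootstrap subtype classification with hybrid states
#'
#' For `n_boot` iterations, each subtype's predictor set is resampled with
#' replacement, subtype scores are computed for every sample, and passes
#' against the per-sample thresholds from [build_null()] are tallied. A sample
#' is labeled with the subtype whose pass fraction exceeds `pure_frac`
#' (> 50\%); if a second subtype's fraction also exceeds `hybrid_frac`
#' (> 40\%) the sample is a hybrid of the two; samples passing nothing above
#' `pure_frac` are "unclassified". When two subtypes both exceed `pure_frac`,
#' the higher fraction is primary and the other is the hybrid partner.
#'
#' Hexagonal coordinates place each sample at the pass-fraction-weighted sum
#' of three unit vectors at 90, 210 and 330 degrees (one per subtype, in
#' predictor-set order): a sample passing one subtype in every iteration sits
#' on that subtype's vertex, one passing two subtypes in every iteration sits
#' on the shared hybrid vertex, and one passing all three sits at the origin.
#'
#' @param expr `TransformedMatrix` or matrix (features x samples).
#' @param psets `PredictorSets` used to build `null`.
#' @param null `ScoreNull` from [build_null()].
#' @param n_boot bootstrap iterations, default 1000.
#' @param pure_frac primary-label pass fraction, default 0.5.
#' @param hybrid_frac secondary-label pass fraction, default 0.4 (must be
#'   below `pure_frac`).
#' @param seed RNG seed.
#' @return `ClassificationResult` data.frame: `sample`, one `f_<subtype>`
#'   column per subtype, `label`, `primary`, `secondary`, `x`, `y`; attribute
#'   `n_boot`.
#' @export
bootstrap_classify <- function(expr, psets, null, n_boot = 1000,
                               pure_frac = 0.5, hybrid_frac = 0.4, seed = 1) {
  stopifnot(inherits(psets, "PredictorSets"), inherits(null, "ScoreNull"))
  if (pure_frac <= hybrid_frac)
    stop("pure_frac must exceed hybrid_frac")
  m <- if (inherits(expr, "TransformedMatrix")) expr$values else as.matrix(expr)
  subtypes <- names(psets$sets)
  k <- length(subtypes)
  nsamp <- ncol(m)
  passes <- matrix(0, nsamp, k, dimnames = list(colnames(m), subtypes))
  with_seed(seed, {
    for (s in subtypes) {
      # reference nulls score on the out-of-subtype centered scale
      ms <- if (!is.null(null$centering)) m - null$centering[[s]] else m
      all_mean <- colMeans(ms[psets$all_features, , drop = FALSE])
      feats <- psets$sets[[s]]
      nf <- length(feats)
      thr <- null$thresholds[, s]
      sub <- ms[feats, , drop = FALSE]
      # weight matrix of resample counts: one row per bootstrap iteration
      W <- t(vapply(seq_len(n_boot), function(b)
        tabulate(sample.int(nf, nf, replace = TRUE), nbins = nf),
        integer(nf))) / nf
      sc <- W %*% sub  # n_boot x samples score component
      sc <- sweep(sc, 2, all_mean)
      passes[, s] <- colSums(sc > rep(thr, each = n_boot))
    }
  })
  f <- passes / n_boot
  label <- character(nsamp); primary <- rep(NA_character_, nsamp)
  secondary <- rep(NA_character_, nsamp)
  for (j in seq_len(nsamp)) {
    fj <- f[j, ]
    if (max(fj) <= pure_frac) {
      label[j] <- "unclassified"
      next
    }
    top <- which.max(fj)
    primary[j] <- subtypes[top]
    rest <- fj[-top]
    if (max(rest) > hybrid_frac) {
      second <- names(rest)[which.max(rest)]
      secondary[j] <- second
      label[j] <- paste(subtypes[top], second, sep = "-")
    } else {
      label[j] <- subtypes[top]
    }
  }
  angles <- c(90, 210, 330)[seq_len(k)] * pi / 180
  x <- as.numeric(f %*% cos(angles))
  y <- as.numeric(f %*% sin(angles))
  out <- data.frame(sample = colnames(m) %||% paste0("sample", seq_len(nsamp)),
                    f, label = label, primary = primary, secondary = secondary,
                    x = x, y = y, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out)[1 + seq_len(k)] <- paste0("f_", subtypes)
  rownames(out) <- NULL
  attr(out, "n_boot") <- n_boot
  class(out) <- c("ClassificationResult", "data.frame")
  out
}
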
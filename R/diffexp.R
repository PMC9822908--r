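#' Specify a differential-expression design
#'
#' @param group factor (or character) of interest, one entry per sample.
#' @param contrast length-2 character vector `c(numerator, denominator)`:
#'   log2 fold changes are numerator over denominator, with the denominator
#'   used as the reference level.
#' @param covariates optional data.frame of nuisance covariates per sample
#'   (e.g. platform, RIN, site); categoricals are one-hot encoded.
#' @return a `DesignSpec` list.
#' @export
design_spec <- function(group, contrast, covariates = NULL) {
  group <- as.character(group)
  stopifnot(length(contrast) == 2L)
  if (!all(contrast %in% group))
    stop("contrast levels must be present in the group factor")
  if (contrast[1] == contrast[2]) stop("contrast levels must differ")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(group))
      stop("covariates must have one row per sample")
  }
  structure(list(group = group, contrast = contrast, covariates = covariates),
            class = "DesignSpec")
}

build_design_matrix <- function(design) {
  lev <- unique(design$group)
  # reference level = contrast denominator; remaining levels alphabetical
  lev <- c(design$contrast[2], sort(setdiff(lev, design$contrast[2])))
  df <- data.frame(.group = factor(design$group, levels = lev))
  if (!is.null(design$covariates)) df <- cbind(df, design$covariates)
  X <- stats::model.matrix(~ ., data = df)
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  list(X = X, test_coef = paste0(".group", design$contrast[1]))
}

#' Negative-binomial Wald differential expression
#'
#' A deliberately simple NB engine: per feature, a log-link NB GLM with offset
#' log(size factor), dispersion held fixed at the method-of-moments trend
#' value alpha(mu) = a0 + a1/mu evaluated at the feature's normalized mean,
#' fit by iteratively reweighted least squares (deviance tolerance 1e-8, at
#' most 50 iterations). Wald z = beta / SE from the unscaled information
#' matrix, two-tailed p, Benjamini-Hochberg adjustment across converged
#' features. No fold-change shrinkage, no outlier refitting, no independent
#' filtering.
#'
#' @param counts `CountMatrix` or matrix.
#' @param design a `DesignSpec`.
#' @param factors `SizeFactors` (computed from `counts` if missing).
#' @return `DEResult` data.frame: `feature`, `log2fc`, `se`, `stat`, `pvalue`,
#'   `padj`, `dispersion`, `converged`.
#' @export
nb_wald_test <- function(counts, design, factors = NULL) {
  m <- if (inherits(counts, "CountMatrix")) counts$values else as.matrix(counts)
  stopifnot(inherits(design, "DesignSpec"))
  if (is.null(factors)) factors <- size_factors(m)
  sf <- as.numeric(factors)
  if (length(sf) != ncol(m)) stop("size factors do not match sample count")
  q <- sweep(m, 2, sf, "/")
  trend <- fit_dispersion_trend(q)
  mu <- rowMeans(q)
  alpha <- if (trend$a0 > 0) pmax(trend$a0 + trend$a1 / pmax(mu, 1e-8), 1e-8) else
    rep(1e-8, nrow(m))
  dm <- build_design_matrix(design)
  X <- dm$X
  off <- log(sf)
  n <- nrow(m)
  out <- data.frame(feature = rownames(m),
                    log2fc = NA_real_, se = NA_real_, stat = NA_real_,
                    pvalue = NA_real_, padj = NA_real_,
                    dispersion = alpha, converged = FALSE,
                    stringsAsFactors = FALSE)
  ci <- match(dm$test_coef, colnames(X))
  if (is.na(ci)) stop("internal error: test coefficient not in design matrix")
  for (i in seq_len(n)) {
    y <- m[i, ]
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(
        X, y, offset = off,
        family = MASS::negative.binomial(theta = 1 / alpha[i]),
        control = stats::glm.control(epsilon = 1e-8, maxit = 50))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    beta <- fit$coefficients[ci]
    # information matrix from the IRLS weights (dispersion fixed at 1)
    XtWX <- crossprod(X * fit$weights, X)
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(cov)) next
    se <- sqrt(cov[ci, ci])
    if (!is.finite(se) || se <= 0) next
    z <- beta / se
    out$log2fc[i] <- beta / log(2)
    out$se[i] <- se / log(2)
    out$stat[i] <- z
    out$pvalue[i] <- 2 * stats::pnorm(-abs(z))
    out$converged[i] <- TRUE
  }
  out$padj <- bh_adjust(out$pvalue)
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Call sample sex from XIST/UTY and list sex-dependent features for removal
#'
#' Sex is called female iff normalized XIST exceeds normalized UTY (ties are
#' excluded with a warning); a `sex` column in the sample metadata, or the
#' `sex` argument, overrides the expression-based call. Features with a
#' BH-adjusted sex-contrast p-value at or below `alpha` (NB Wald test, male as
#' reference level) are returned for removal prior to clustering.
#'
#' @param counts `CountMatrix`.
#' @param sex optional explicit per-sample sex ("female"/"male").
#' @param xist_id,uty_id feature IDs of the sex marker transcripts.
#' @param alpha BH threshold, default 0.05.
#' @return character vector of feature IDs to drop (may be empty).
#' @export
remove_sex_features <- function(counts, sex = NULL, xist_id = "XIST",
                                uty_id = "UTY", alpha = 0.05) {
  stopifnot(inherits(counts, "CountMatrix"))
  m <- counts$values
  sf <- size_factors(m)
  if (is.null(sex) && !is.null(counts$sample_metadata) &&
      "sex" %in% names(counts$sample_metadata))
    sex <- as.character(counts$sample_metadata$sex)
  if (is.null(sex)) {
    if (!all(c(xist_id, uty_id) %in% rownames(m)))
      stop("XIST/UTY rows absent and no sex column supplied")
    xist <- m[xist_id, ] / as.numeric(sf)
    uty <- m[uty_id, ] / as.numeric(sf)
    sex <- ifelse(xist > uty, "female", ifelse(xist < uty, "male", NA))
    if (anyNA(sex)) {
      warning(sum(is.na(sex)), " sample(s) with XIST = UTY excluded from the sex contrast")
    }
  }
  keep <- !is.na(sex)
  sex <- sex[keep]
  if (length(unique(sex)) < 2) {
    warning("all samples are one sex; no sex-dependent features removed")
    return(character(0))
  }
  sub <- counts[, keep]
  res <- nb_wald_test(sub, design_spec(sex, contrast = c("female", "male")),
                      factors = size_factors(sub$values))
  res$feature[!is.na(res$padj) & res$padj <= alpha]
}

#' Write a differential-expression result table as TSV
#'
#' Columns: feature, log2fc, se, stat, pvalue, padj, dispersion, converged.
#'
#' @param x a `DEResult`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(x, path) {
  stopifnot(inherits(x, "DEResult"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
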
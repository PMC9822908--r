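#' Median-of-ratios size factors
#'
#' Library-size normalization against a geometric-mean pseudo-reference:
#' factor_j = median over all-nonzero features i of x_ij / geomean_i(x_i.).
#' Features with any zero count are excluded from the reference.
#'
#' @param counts `CountMatrix` or plain nonnegative matrix.
#' @return `SizeFactors`: a named positive numeric vector with attributes
#'   `reference` (description) and `n_reference_features`.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "CountMatrix")) counts$values else as.matrix(counts)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stop("no feature has nonzero counts in all samples; ",
         "consider adding a pseudocount upstream")
  geo <- exp(rowMeans(log(m[ref, , drop = FALSE])))
  sf <- apply(m[ref, , drop = FALSE] / geo, 2, stats::median)
  structure(stats::setNames(sf, colnames(m)),
            reference = "geometric mean over features nonzero in all samples",
            n_reference_features = sum(ref),
            class = "SizeFactors")
}

# per-gene method-of-moments dispersions on normalized counts, fitted to the
# parametric trend alpha(mu) = a0 + a1/mu by least squares on the positive
# raw estimates. a1 is clamped at 0 (a negative trend slope has no meaning in
# the closed-form transform); a0 <= 0 signals the caller to fall back.
fit_dispersion_trend <- function(q) {
  mu <- rowMeans(q)
  v <- apply(q, 1, stats::var)
  raw <- (v - mu) / mu^2
  ok <- is.finite(raw) & raw > 0 & mu > 0
  if (sum(ok) < 2)
    return(list(a0 = -1, a1 = 0, n_used = sum(ok)))
  fit <- stats::lm.fit(cbind(1, 1 / mu[ok]), raw[ok])
  a0 <- fit$coefficients[1]; a1 <- fit$coefficients[2]
  if (!is.finite(a1) || a1 < 0) {
    a1 <- 0
    a0 <- mean(raw[ok])
  }
  list(a0 = unname(a0), a1 = unname(a1), n_used = sum(ok))
}

new_transformed <- function(values, transform, params = list()) {
  structure(list(values = values, transform = transform, params = params),
            class = "TransformedMatrix")
}

#' @export
print.TransformedMatrix <- function(x, ...) {
  cat(sprintf("TransformedMatrix (%s): %d features x %d samples\n",
              x$transform, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Variance stabilizing transformation for negative-binomial counts
#'
#' Normalized counts q = x / factor are mapped through the closed-form
#' transform for the dispersion trend alpha(mu) = a0 + a1/mu:
#'   y = log2((1 + a1 + 2 a0 q + 2 sqrt(a0 q (1 + a1 + a0 q))) / (4 a0)),
#' which is strictly increasing in q and has log2 slope 1 for q >> 1/a0, so
#' large counts behave like log2 while small-count variance is flattened.
#' If the fitted a0 is not positive the data carry no usable overdispersion
#' signal and the transform falls back to log2(q + 1) with a warning.
#'
#' @param counts `CountMatrix` or matrix.
#' @param factors `SizeFactors` from [size_factors()] (computed if missing).
#' @return `TransformedMatrix` with tag `"vst"` (or `"log2norm"` on fallback)
#'   and fitted `a0`, `a1` in `$params`.
#' @export
vst_transform <- function(counts, factors = NULL) {
  m <- if (inherits(counts, "CountMatrix")) counts$values else as.matrix(counts)
  if (is.null(factors)) factors <- size_factors(m)
  q <- sweep(m, 2, as.numeric(factors), "/")
  tr <- fit_dispersion_trend(q)
  if (tr$a0 <= 0) {
    warning("fitted dispersion trend intercept a0 <= 0; falling back to log2(q + 1)")
    return(new_transformed(log2(q + 1), "log2norm",
                           list(size_factors = as.numeric(factors))))
  }
  a0 <- tr$a0; a1 <- tr$a1
  y <- log2((1 + a1 + 2 * a0 * q + 2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
  new_transformed(y, "vst",
                  list(a0 = a0, a1 = a1, size_factors = as.numeric(factors)))
}

#' Select the most variable features by median absolute deviation
#'
#' Features are ranked by MAD of the transformed values (consistency constant
#' omitted; it is rank-invariant), descending, ties broken by feature ID in
#' lexicographic order.
#'
#' @param matrix `TransformedMatrix` or plain matrix with rownames.
#' @param n_top number of features to keep, default 10000.
#' @return character vector of feature IDs, highest MAD first.
#' @export
select_mad_features <- function(matrix, n_top = 10000) {
  m <- if (inherits(matrix, "TransformedMatrix")) matrix$values else as.matrix(matrix)
  if (n_top > nrow(m)) stop("n_top exceeds the number of features")
  med <- apply(m, 1, stats::median)
  mad <- apply(abs(m - med), 1, stats::median)
  ord <- order(-mad, rownames(m), method = "radix")
  rownames(m)[ord[seq_len(n_top)]]
}

#' Remove technical covariate effects by linear residualization
#'
#' Per feature, a least-squares fit on the supplied covariates (categoricals
#' one-hot encoded against the alphabetically first reference level); the
#' returned values are intercept + residuals, i.e. the covariate effects are
#' subtracted on the transformed scale. Single-level categorical columns are
#' dropped with a warning; a rank-deficient design is an error naming the
#' aliased columns.
#'
#' @param matrix `TransformedMatrix` or matrix (features x samples).
#' @param covariates data.frame with one row per sample (e.g. RIN, site,
#'   platform), in sample order. No missing values allowed.
#' @return `TransformedMatrix` tagged `"covariate-adjusted"`.
#' @export
adjust_covariates <- function(matrix, covariates) {
  m <- if (inherits(matrix, "TransformedMatrix")) matrix$values else as.matrix(matrix)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != ncol(m))
    stop("covariates must have one row per sample")
  if (anyNA(covariates))
    stop("covariates contain missing values; exclude those samples upstream")
  keep <- vapply(covariates, function(col) {
    !(is.character(col) || is.factor(col)) || length(unique(col)) > 1
  }, logical(1))
  if (!all(keep)) {
    warning("dropping single-level covariate column(s): ",
            paste(names(covariates)[!keep], collapse = ", "))
    covariates <- covariates[, keep, drop = FALSE]
  }
  X <- stats::model.matrix(~ ., data = covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  fit <- stats::lm.fit(X, t(m))
  coefs <- fit$coefficients
  resid <- fit$residuals
  if (is.null(dim(coefs))) {  # single-feature input
    coefs <- matrix(coefs, ncol = 1)
    resid <- matrix(resid, ncol = 1)
  }
  adjusted <- t(resid) + matrix(coefs[1, ], nrow(m), ncol(m))
  dimnames(adjusted) <- dimnames(m)
  new_transformed(adjusted, "covariate-adjusted",
                  list(covariates = names(covariates)))
}

#' Z-score against a reference sample set, clipping non-reference scores
#'
#' Per feature, z = (x - mean_ref) / sd_ref using only `reference_samples` to
#' define mean and standard deviation; z-scores of non-reference samples below
#' `clip_floor` are raised to `clip_floor` (the heatmap rule for control
#' samples). Features with zero reference SD are emitted as all-zero with a
#' warning.
#'
#' @param matrix `TransformedMatrix` or matrix.
#' @param reference_samples sample IDs (or logical/integer index) defining the
#'   reference distribution.
#' @param clip_floor lower clip for non-reference z-scores, default -4.
#' @return `TransformedMatrix` tagged `"zscore"`.
#' @export
zscore_reference_clip <- function(matrix, reference_samples, clip_floor = -4) {
  m <- if (inherits(matrix, "TransformedMatrix")) matrix$values else as.matrix(matrix)
  if (is.character(reference_samples)) {
    if (!all(reference_samples %in% colnames(m)))
      stop("unknown reference sample IDs")
    ref_idx <- colnames(m) %in% reference_samples
  } else {
    ref_idx <- seq_len(ncol(m)) %in% seq_len(ncol(m))[reference_samples]
  }
  if (!any(ref_idx)) stop("reference sample set is empty")
  mu <- rowMeans(m[, ref_idx, drop = FALSE])
  sd <- apply(m[, ref_idx, drop = FALSE], 1, stats::sd)
  z <- (m - mu) / sd
  bad <- !is.finite(sd) | sd == 0
  if (any(bad)) {
    warning(sum(bad), " feature(s) with zero reference SD emitted as all-zero")
    z[bad, ] <- 0
  }
  z[, !ref_idx] <- pmax(z[, !ref_idx, drop = FALSE], clip_floor)
  new_transformed(z, "zscore",
                  list(clip_floor = clip_floor, n_reference = sum(ref_idx)))
}

#' Write a transformed matrix as TSV with a JSON parameter sidecar
#'
#' The sidecar (`<path>.params.json`) records the transform tag and fitted
#' parameters (a0, a1, size factors) for reproducibility.
#'
#' @param x a `TransformedMatrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_transformed <- function(x, path) {
  stopifnot(inherits(x, "TransformedMatrix"))
  df <- data.frame(feature = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(list(transform = x$transform), x$params),
                       paste0(path, ".params.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
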
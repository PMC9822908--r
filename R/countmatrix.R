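#' Construct a CountMatrix
#'
#' The pipeline's universal input: a nonnegative integer feature-by-sample
#' count matrix with a feature kind ("gene" or "TE") per row and an optional
#' sample metadata table. Feature kind defaults to "TE" for any row name that
#' parses as a locus-specific transposable-element ID (see [parse_te_id()]),
#' "gene" otherwise.
#'
#' @param values integer matrix, features x samples, with unique row and
#'   column names.
#' @param feature_kind optional character vector ("gene"/"TE") per feature.
#' @param sample_metadata optional data.frame keyed by sample ID (rownames or a
#'   `sample` column); reordered to match `colnames(values)`.
#' @return an object of class `CountMatrix`: a list with elements `values`,
#'   `feature_kind`, `sample_metadata`.
#' @export
count_matrix <- function(values, feature_kind = NULL, sample_metadata = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if ((is.null(rownames(values)) && nrow(values) > 0) ||
      (is.null(colnames(values)) && ncol(values) > 0))
    stop("count matrix must have feature (row) and sample (column) names")
  if (anyDuplicated(rownames(values))) stop("duplicate feature IDs")
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs")
  if (any(values < 0)) stop("counts must be nonnegative")
  if (any(abs(values - round(values)) > 1e-8))
    stop("counts must be integers")
  storage.mode(values) <- "double"  # keeps large counts safe; values stay integral
  if (is.null(feature_kind)) {
    feature_kind <- ifelse(is_te_id(rownames(values)), "TE", "gene")
  } else {
    if (length(feature_kind) != nrow(values))
      stop("feature_kind length must equal the number of features")
    if (!all(feature_kind %in% c("gene", "TE")))
      stop("feature_kind entries must be 'gene' or 'TE'")
  }
  if (!is.null(sample_metadata)) {
    sample_metadata <- as.data.frame(sample_metadata)
    key <- if ("sample" %in% names(sample_metadata)) sample_metadata$sample else
      rownames(sample_metadata)
    if (!all(colnames(values) %in% key))
      stop("sample_metadata missing entries for some samples")
    sample_metadata <- sample_metadata[match(colnames(values), key), , drop = FALSE]
    rownames(sample_metadata) <- colnames(values)
  }
  structure(list(values = values,
                 feature_kind = stats::setNames(feature_kind, rownames(values)),
                 sample_metadata = sample_metadata),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

#' @export
dimnames.CountMatrix <- function(x) dimnames(x$values)

#' Subset a CountMatrix by features and/or samples
#' @param x a `CountMatrix`.
#' @param i,j feature / sample indices (any form `[` accepts).
#' @param ... ignored.
#' @export
`[.CountMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  count_matrix(x$values[i, j, drop = FALSE],
               feature_kind = unname(x$feature_kind[i]),
               sample_metadata = if (!is.null(x$sample_metadata))
                 x$sample_metadata[j, , drop = FALSE])
}

#' @export
print.CountMatrix <- function(x, ...) {
  kinds <- table(x$feature_kind)
  cat(sprintf("CountMatrix: %d features (%s) x %d samples\n",
              nrow(x$values),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "),
              ncol(x$values)))
  invisible(x)
}

#' Read counts from a TSV file
#'
#' Expects a header row of sample IDs and a first column of feature IDs
#' (column name arbitrary). Comma-separated files are accepted via `sep`.
#'
#' @param path file path.
#' @param sep field separator, default tab.
#' @param sample_metadata optional metadata data.frame passed through.
#' @return a `CountMatrix`.
#' @export
read_counts_tsv <- function(path, sep = "\t", sample_metadata = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  count_matrix(m, sample_metadata = sample_metadata)
}

#' Write counts to a TSV file
#' @param x a `CountMatrix`.
#' @param path file path.
#' @param id_column name for the feature ID column.
#' @export
write_counts_tsv <- function(x, path, id_column = "feature") {
  df <- data.frame(rownames(x$values), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read counts from a MatrixMarket triplet
#'
#' @param mtx_path MatrixMarket file; `features_path`, `samples_path` are
#'   newline-delimited name files (row and column order respectively).
#' @param features_path,samples_path sidecar name files.
#' @return a `CountMatrix`.
#' @export
read_counts_mtx <- function(mtx_path, features_path, samples_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  rownames(m) <- readLines(features_path)
  colnames(m) <- readLines(samples_path)
  count_matrix(m)
}
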
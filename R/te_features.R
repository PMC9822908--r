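#' Parse a locus-specific transposable-element feature ID
#'
#' Locus-level TE features are named
#' `chrom|start|end|subfamily:family:superfamily|score|strand`, e.g.
#' `"chr5 | 760200 | 760576 | MLT1B:ERVL-MaLR:LTR | 277 | +"`. Whitespace
#' around pipes is tolerated (figure-style and compact dialects are both
#' valid). Coordinates are treated as opaque 1-based labels; the score is the
#' quantifier's alignment-quality score used by the `>= 99` retention filter.
#'
#' @param id a single TE feature ID string.
#' @return an object of class `TELocus` with fields `chrom`, `start`, `end`,
#'   `subfamily`, `family`, `superfamily`, `score`, `strand`.
#' @export
parse_te_id <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  parts <- trimws(strsplit(id, "|", fixed = TRUE)[[1]])
  if (length(parts) != 6L)
    stop(sprintf("TE ID must have 6 pipe-delimited fields, got %d: '%s'",
                 length(parts), id))
  as_pos <- function(x, field) {
    if (!grepl("^[0-9]+$", x))
      stop(sprintf("TE ID field '%s' is not a nonnegative integer: '%s'", field, x))
    as.integer(x)
  }
  start <- as_pos(parts[2], "start")
  end <- as_pos(parts[3], "end")
  if (start >= end)
    stop(sprintf("TE ID start (%d) must be < end (%d)", start, end))
  tax <- strsplit(parts[4], ":", fixed = TRUE)[[1]]
  if (length(tax) != 3L || any(!nzchar(tax)))
    stop(sprintf("TE ID taxonomy field must be subfamily:family:superfamily: '%s'",
                 parts[4]))
  score <- as_pos(parts[5], "score")
  if (!parts[6] %in% c("+", "-"))
    stop(sprintf("TE ID strand must be '+' or '-': '%s'", parts[6]))
  structure(list(chrom = parts[1], start = start, end = end,
                 subfamily = tax[1], family = tax[2], superfamily = tax[3],
                 score = score, strand = parts[6]),
            class = "TELocus")
}

#' Format a TELocus back into its canonical ID
#' @param locus a `TELocus`.
#' @param spaced use the figure-caption dialect with spaces around pipes.
#' @return character ID.
#' @export
format_te_id <- function(locus, spaced = FALSE) {
  stopifnot(inherits(locus, "TELocus"))
  sep <- if (spaced) " | " else "|"
  paste(locus$chrom, locus$start, locus$end,
        paste(locus$subfamily, locus$family, locus$superfamily, sep = ":"),
        locus$score, locus$strand, sep = sep)
}

#' @export
print.TELocus <- function(x, ...) {
  cat("TELocus:", format_te_id(x, spaced = TRUE), "\n")
  invisible(x)
}

#' Test whether strings parse as TE locus IDs
#' @param ids character vector.
#' @return logical vector.
#' @export
is_te_id <- function(ids) {
  vapply(ids, function(id) {
    # cheap prefilter before attempting a full parse
    if (!grepl("|", id, fixed = TRUE)) return(FALSE)
    !inherits(tryCatch(parse_te_id(id), error = function(e) e), "error")
  }, logical(1), USE.NAMES = FALSE)
}

#' Filter locus-specific TE features
#'
#' Retains TEs with alignment-quality score at or above `min_score`
#' (default 99, the threshold restricting false-positive loci with few
#' uniquely mapping reads to ~1\%) and, when `require_nonzero_all` is set, at
#' least one count in every sample. Feature order is preserved and the filter
#' is idempotent.
#'
#' @param te_counts `CountMatrix` whose feature IDs all parse as TE loci.
#' @param min_score minimum score, default 99.
#' @param require_nonzero_all require count >= 1 in every sample (default TRUE).
#' @return filtered `CountMatrix` (warns if empty).
#' @export
filter_te_features <- function(te_counts, min_score = 99,
                               require_nonzero_all = TRUE) {
  stopifnot(inherits(te_counts, "CountMatrix"))
  ids <- rownames(te_counts$values)
  loci <- lapply(ids, parse_te_id)  # errors if any ID is not a TE locus
  scores <- vapply(loci, `[[`, numeric(1), "score")
  keep <- scores >= min_score
  if (require_nonzero_all)
    keep <- keep & apply(te_counts$values >= 1, 1, all)
  if (!any(keep)) warning("no TE features pass the filter")
  te_counts[keep, ]
}

#' Row-stack gene and TE count matrices over a shared sample set
#'
#' Samples are aligned by ID to the gene table's order. When `zero_fill` is
#' set, samples present in the gene table but absent from the TE table get TE
#' counts of 0 (the treatment applied to TE loci missing from a cohort);
#' otherwise any sample-set mismatch is an error.
#'
#' @param genes,tes `CountMatrix` objects.
#' @param zero_fill zero-fill TE counts for samples missing from `tes`.
#' @return combined `CountMatrix` with per-row `feature_kind` from the source.
#' @export
assemble_feature_matrix <- function(genes, tes, zero_fill = FALSE) {
  stopifnot(inherits(genes, "CountMatrix"), inherits(tes, "CountMatrix"))
  gsamp <- colnames(genes$values)
  tsamp <- colnames(tes$values)
  if (!setequal(gsamp, tsamp)) {
    if (!zero_fill || length(setdiff(tsamp, gsamp)) > 0)
      stop("sample ID sets differ between gene and TE tables ",
           "(set zero_fill = TRUE to zero-fill TEs for missing samples)")
    extra <- setdiff(gsamp, tsamp)
    fill <- matrix(0, nrow(tes$values), length(extra),
                   dimnames = list(rownames(tes$values), extra))
    tes <- count_matrix(cbind(tes$values, fill),
                        feature_kind = unname(tes$feature_kind))
  }
  tev <- tes$values[, gsamp, drop = FALSE]
  if (any(rownames(genes$values) %in% rownames(tev)))
    stop("duplicate feature IDs across gene and TE inputs")
  count_matrix(rbind(genes$values, tev),
               feature_kind = c(unname(genes$feature_kind), unname(tes$feature_kind)),
               sample_metadata = genes$sample_metadata)
}
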
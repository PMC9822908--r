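MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow", "tan",
                   "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
                   "lightgreen", "lightyellow", "royalblue", "darkred",
                   "darkgreen", "darkturquoise", "darkgrey", "orange",
                   "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
                   "paleturquoise", "violet", "darkolivegreen", "darkmagenta",
                   "gold", "navy", "maroon")

#' Detect co-expression modules from topological overlap
#'
#' A simplified weighted co-expression workflow: unsigned adjacency
#' a_ij = |cor(x_i, x_j)|^soft_power, topological overlap
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' k = connectivity (row sums, self excluded), average-linkage clustering of
#' 1 - TOM, and a static cut chosen by scanning heights 0.99 down to 0.50 in
#' steps of 0.01 and keeping the greatest height that yields at least two
#' clusters of size >= `min_size`. Clusters below `min_size` (or everything,
#' if no height qualifies) are labeled "gray"; qualifying modules get color
#' names by decreasing size. Constant features are excluded with a warning
#' (undefined correlation) and labeled gray.
#'
#' @param matrix `TransformedMatrix` or matrix (features x samples).
#' @param soft_power adjacency exponent, default 13 (scale-free-topology
#'   choice; a config input here, not re-estimated).
#' @param min_size minimum module size, default 25.
#' @return `ModuleSet`: list with `labels` (named color per feature), `TOM`,
#'   `soft_power`, `min_size`, `cut_height`.
#' @export
detect_modules <- function(matrix, soft_power = 13, min_size = 25) {
  m <- if (inherits(matrix, "TransformedMatrix")) matrix$values else as.matrix(matrix)
  if (nrow(m) < 2 * min_size)
    stop("need at least 2 * min_size features")
  sds <- apply(m, 1, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const))
    warning(sum(const), " constant feature(s) excluded from module detection")
  ids <- rownames(m) %||% paste0("feature", seq_len(nrow(m)))
  labels <- stats::setNames(rep("gray", nrow(m)), ids)
  work <- m[!const, , drop = FALSE]
  A <- abs(stats::cor(t(work)))^soft_power
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A
  kmin <- outer(k, k, pmin)
  TOM <- (L + A) / (kmin + 1 - A)
  diag(TOM) <- 1
  TOM <- pmin(pmax(TOM, 0), 1)
  dimnames(TOM) <- list(rownames(work), rownames(work))
  hc <- stats::hclust(stats::as.dist(1 - TOM), method = "average")
  cut_height <- NA_real_
  assign <- NULL
  for (h in seq(0.99, 0.50, by = -0.01)) {
    ct <- stats::cutree(hc, h = h)
    big <- sum(table(ct) >= min_size)
    if (big >= 2) {
      cut_height <- h
      assign <- ct
      break
    }
  }
  if (!is.null(assign)) {
    sizes <- table(assign)
    keep <- names(sizes)[sizes >= min_size]
    ord <- keep[order(-sizes[keep])]
    for (i in seq_along(ord)) {
      col <- if (i <= length(MODULE_COLORS)) MODULE_COLORS[i] else
        paste0("module", i)
      labels[rownames(work)[assign == as.integer(ord[i])]] <- col
    }
  }
  structure(list(labels = labels, TOM = TOM, soft_power = soft_power,
                 min_size = min_size, cut_height = cut_height),
            class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("ModuleSet: %d features, %d module(s) + gray (cut height %s)\n",
              length(x$labels), sum(names(tab) != "gray"),
              format(x$cut_height)))
  print(tab)
  invisible(x)
}

#' Module eigengene
#'
#' First right singular vector of the feature-standardized member submatrix
#' (the module's first principal component across samples), sign-oriented so
#' that its mean correlation with member features is nonnegative, and returned
#' standardized to mean 0, SD 1.
#'
#' @param matrix `TransformedMatrix` or matrix (features x samples).
#' @param members feature IDs (or row indices) of the module.
#' @return numeric eigengene vector, one entry per sample.
#' @export
module_eigengene <- function(matrix, members) {
  m <- if (inherits(matrix, "TransformedMatrix")) matrix$values else as.matrix(matrix)
  sub <- m[members, , drop = FALSE]
  if (nrow(sub) < 1) stop("empty member set")
  sds <- apply(sub, 1, stats::sd)
  if (all(sds == 0)) stop("all module members are constant")
  if (any(sds == 0)) sub <- sub[sds > 0, , drop = FALSE]
  Z <- (sub - rowMeans(sub)) / apply(sub, 1, stats::sd)
  e <- svd(Z, nu = 0, nv = 1)$v[, 1]
  cors <- suppressWarnings(stats::cor(e, t(Z)))
  if (mean(cors, na.rm = TRUE) < 0) e <- -e
  e <- (e - mean(e)) / stats::sd(e)
  stats::setNames(e, colnames(m))
}

#' Eigengene-trait and eigengene-subtype association
#'
#' Per eigengene x numeric trait: Pearson correlation on pairwise-complete
#' observations with a two-tailed p from the t-distribution on n - 2 df. Per
#' eigengene x subtype: one-vs-rest dummy regression (the indicated subtype
#' coded 1, the rest 0), whose slope equals the in-subtype minus out-subtype
#' mean eigengene difference; a positive beta denotes subtype upregulation.
#' Subtype p-values are Bonferroni-adjusted across all eigengene x subtype
#' cells.
#'
#' @param eigengenes matrix samples x eigengenes (or a named list of vectors).
#' @param traits data.frame of numeric traits per sample (NAs allowed).
#' @param subtypes factor/character subtype label per sample (optional).
#' @return list with data.frames `traits` (`eigengene`, `trait`, `r`, `p`,
#'   `n`) and `subtypes` (`eigengene`, `subtype`, `beta`, `p`, `p_bonferroni`).
#' @export
eigengene_association <- function(eigengenes, traits = NULL, subtypes = NULL) {
  if (is.list(eigengenes) && !is.data.frame(eigengenes))
    eigengenes <- do.call(cbind, eigengenes)
  E <- as.matrix(eigengenes)
  trait_tab <- NULL
  if (!is.null(traits)) {
    traits <- as.data.frame(traits)
    rows <- list()
    for (ei in colnames(E)) for (tr in names(traits)) {
      x <- E[, ei]; y <- as.numeric(traits[[tr]])
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n < 3) {
        rows[[length(rows) + 1]] <- data.frame(eigengene = ei, trait = tr,
                                               r = NA_real_, p = NA_real_, n = n)
        next
      }
      r <- stats::cor(x[ok], y[ok])
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
      rows[[length(rows) + 1]] <- data.frame(eigengene = ei, trait = tr,
                                             r = r, p = p, n = n)
    }
    trait_tab <- do.call(rbind, rows)
  }
  subtype_tab <- NULL
  if (!is.null(subtypes)) {
    subtypes <- as.character(subtypes)
    levs <- sort(unique(subtypes))
    rows <- list()
    for (ei in colnames(E)) for (s in levs) {
      y <- E[, ei]
      in_s <- subtypes == s
      n1 <- sum(in_s); n0 <- sum(!in_s); n <- n1 + n0
      beta <- mean(y[in_s]) - mean(y[!in_s])
      # two-level dummy regression: slope t equals the pooled two-sample t
      ss <- sum((y[in_s] - mean(y[in_s]))^2) + sum((y[!in_s] - mean(y[!in_s]))^2)
      se <- sqrt(ss / (n - 2) * (1 / n1 + 1 / n0))
      p <- if (se == 0) {
        if (beta == 0) 1 else 0
      } else 2 * stats::pt(-abs(beta / se), df = n - 2)
      rows[[length(rows) + 1]] <- data.frame(eigengene = ei, subtype = s,
                                             beta = beta, p = p)
    }
    subtype_tab <- do.call(rbind, rows)
    subtype_tab$p_bonferroni <- pmin(1, subtype_tab$p * nrow(subtype_tab))
  }
  list(traits = trait_tab, subtypes = subtype_tab)
}

#' Hypergeometric over-representation analysis
#'
#' One-tailed hypergeometric (equivalently one-tailed Fisher exact) upper-tail
#' p-value per gene set, with BH or Bonferroni correction across sets. Gene
#' sets are intersected with the universe; the query must be a subset of the
#' universe.
#'
#' @param query character vector of hit genes.
#' @param gene_sets named list of character vectors.
#' @param universe character vector of all assayable genes.
#' @param correction "BH" (default) or "Bonferroni".
#' @return data.frame: `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `p_adjusted`.
#' @export
enrich_hypergeometric <- function(query, gene_sets, universe,
                                  correction = c("BH", "Bonferroni")) {
  correction <- match.arg(correction)
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  N <- length(universe); nq <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(unique(gene_sets[[nm]]), universe)
    ov <- length(intersect(query, gs))
    p <- stats::phyper(ov - 1, length(gs), N - length(gs), nq,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(gs),
               query_size = nq, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (correction == "BH") bh_adjust(out$p) else
    pmin(1, out$p * nrow(out))
  out
}

#' Export a thresholded undirected edge list
#'
#' Upper-triangle entries of a symmetric weight matrix (TOM or adjacency)
#' meeting the threshold become edges; isolated nodes are dropped implicitly.
#'
#' @param weights symmetric numeric matrix.
#' @param weight_threshold minimum edge weight, default 0.05.
#' @return data.frame `from`, `to`, `weight` with from < to positionally.
#' @export
export_network_edges <- function(weights, weight_threshold = 0.05) {
  w <- as.matrix(weights)
  if (!isSymmetric(unname(w), tol = 1e-8)) stop("weight matrix must be symmetric")
  ids <- rownames(w) %||% as.character(seq_len(nrow(w)))
  idx <- which(upper.tri(w) & w >= weight_threshold, arr.ind = TRUE)
  data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
             weight = w[idx], stringsAsFactors = FALSE)
}
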
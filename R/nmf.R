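#' Non-smooth non-negative matrix factorization (nsNMF)
#'
#' Factorizes a nonnegative matrix as X ~ W S H where the smoothing matrix
#' S = (1 - theta) I + (theta / k) J interpolates between plain KL-NMF
#' (theta = 0) and fully smoothed factors (theta = 1), inducing sparseness in
#' W and H. Multiplicative Kullback-Leibler updates are used, with the
#' W-update treating S H as the effective coefficient matrix and the H-update
#' treating W S as the effective basis, so each half-step inherits the
#' monotone-descent guarantee of KL-NMF. Initialization is uniform random
#' from `seed`.
#'
#' @param X nonnegative numeric matrix (features x samples) or
#'   `TransformedMatrix`. Negative entries are an error; shift upstream.
#' @param k factorization rank (>= 2, < min(dim(X))).
#' @param theta smoothing parameter in \[0, 1\], default 0.5.
#' @param max_iter multiplicative update sweeps, default 200.
#' @param seed RNG seed for initialization.
#' @param eps numerical floor guarding divisions, default 1e-16.
#' @return `NMFFit`: list with `W`, `H`, `S`, `k`, `theta`, `seed`,
#'   `objective_trace` (KL divergence at initialization followed by one value
#'   per sweep; non-increasing).
#' @export
nsnmf_factorize <- function(X, k, theta = 0.5, max_iter = 200, seed = 1,
                            eps = 1e-16) {
  if (inherits(X, "TransformedMatrix")) X <- X$values
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be elementwise nonnegative (shift upstream)")
  if (k < 2) stop("rank k must be >= 2")
  if (k >= min(dim(X))) stop("rank k must be smaller than both dimensions of X")
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  n <- nrow(X); p <- ncol(X)
  S <- (1 - theta) * diag(k) + (theta / k) * matrix(1, k, k)
  scale0 <- sqrt(mean(X) / k)
  init <- with_seed(seed, list(W = matrix(stats::runif(n * k), n, k) * scale0,
                               H = matrix(stats::runif(k * p), k, p) * scale0))
  W <- init$W; H <- init$H
  kl <- function(A, B) {
    B <- pmax(B, eps)
    pos <- A > 0
    sum(A[pos] * log(A[pos] / B[pos])) - sum(A) + sum(B)
  }
  kl0 <- kl(X, W %*% S %*% H)  # divergence at initialization
  trace <- numeric(max_iter)
  for (it in seq_len(max_iter)) {
    # H-update with effective basis W S
    Weff <- W %*% S
    R <- X / pmax(Weff %*% H, eps)
    H <- H * (crossprod(Weff, R) / pmax(colSums(Weff), eps))
    # W-update with effective coefficients S H
    Heff <- S %*% H
    R <- X / pmax(W %*% Heff, eps)
    W <- W * (R %*% t(Heff)) / rep(pmax(rowSums(Heff), eps), each = n)
    trace[it] <- kl(X, W %*% S %*% H)
  }
  structure(list(W = W, H = H, S = S, k = k, theta = theta, seed = seed,
                 objective_trace = c(kl0, trace)),
            class = "NMFFit")
}

#' @export
print.NMFFit <- function(x, ...) {
  cat(sprintf("NMFFit: rank %d, theta %.2f, %d x %d, final KL %.4g\n",
              x$k, x$theta, nrow(x$W), ncol(x$H),
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

# hard sample labels: argmax coefficient row per sample
nmf_labels <- function(fit) apply(fit$H, 2, which.max)

# best permutation of `labels`' cluster indices maximizing agreement with ref;
# returns the relabeling map as an attribute: new_label = map[old_label]
match_partition <- function(ref, labels, k) {
  tab <- matrix(0, k, k)
  for (i in seq_along(ref)) tab[ref[i], labels[i]] <- tab[ref[i], labels[i]] + 1
  perms <- all_permutations(k)
  best <- perms[which.max(apply(perms, 1, function(p)
    sum(tab[cbind(seq_len(k), p)]))), ]
  # best[j] = cluster of `labels` matched to ref cluster j; invert to relabel
  map <- integer(k); map[best] <- seq_len(k)
  structure(map[labels], map = map)
}

consensus_from_labels <- function(label_matrix) {
  # label_matrix: runs x samples
  p <- ncol(label_matrix)
  C <- matrix(0, p, p)
  for (r in seq_len(nrow(label_matrix))) {
    lab <- label_matrix[r, ]
    C <- C + outer(lab, lab, "==")
  }
  C <- C / nrow(label_matrix)
  diag(C) <- 1
  C
}

cophenetic_rho <- function(C) {
  d <- stats::as.dist(1 - C)
  hc <- stats::hclust(d, method = "average")
  coph <- stats::cophenetic(hc)
  if (stats::sd(d) == 0 || stats::sd(coph) == 0) {
    # perfectly stable (or degenerate) consensus: treat as full agreement
    return(1)
  }
  stats::cor(d, coph)
}

#' Rank estimation by cophenetic correlation of the consensus matrix
#'
#' For each candidate rank, `n_runs` seeded nsNMF fits are computed; per-run
#' hard labels (argmax of H) define a co-clustering consensus matrix C, and
#' the cophenetic correlation rho compares (1 - C) with the cophenetic
#' distances of its average-linkage dendrogram. Stable ranks give rho near 1.
#'
#' @param X nonnegative matrix or `TransformedMatrix`.
#' @param ranks integer vector of candidate ranks, default 2:6.
#' @param n_runs fits per rank, default 50.
#' @param theta,max_iter,seed passed to [nsnmf_factorize()]; run r uses
#'   seed + r.
#' @return named list (one per rank) of `ConsensusResult` objects with
#'   elements `C`, `rho`, `labels` (majority after matching), `run_labels`.
#' @export
estimate_rank <- function(X, ranks = 2:6, n_runs = 50, theta = 0.5,
                          max_iter = 200, seed = 1) {
  if (inherits(X, "TransformedMatrix")) X <- X$values
  out <- lapply(ranks, function(k) {
    labs <- t(vapply(seq_len(n_runs), function(r)
      nmf_labels(nsnmf_factorize(X, k, theta = theta, max_iter = max_iter,
                                 seed = seed + r)),
      integer(ncol(X))))
    matched <- labs
    for (r in seq_len(n_runs)[-1])
      matched[r, ] <- match_partition(matched[1, ], labs[r, ], k)
    C <- consensus_from_labels(matched)
    dimnames(C) <- list(colnames(X), colnames(X))
    maj <- apply(matched, 2, function(v) as.integer(names(which.max(table(v)))))
    structure(list(C = C, rho = cophenetic_rho(C), k = k,
                   labels = stats::setNames(maj, colnames(X)),
                   run_labels = matched),
              class = "ConsensusResult")
  })
  names(out) <- paste0("k", ranks)
  out
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("ConsensusResult: k = %d, cophenetic rho = %.4f, %d samples\n",
              x$k, x$rho, ncol(x$C)))
  invisible(x)
}

#' Replicate-consensus subtype assignment with an 11th-run tiebreaker
#'
#' Runs `n_runs` (default 10) seeded nsNMF fits; each run's factors are
#' matched to run 1 by maximum-agreement bipartite assignment on label
#' overlap, and every sample receives the label holding a simple majority
#' (> n_runs / 2) of matched votes. For samples without a majority an
#' additional seeded run is computed and plurality over the enlarged vote set
#' decides; any remaining tie goes to the label with the highest mean matched
#' H coefficient across runs. `tiebreaker_used` records which samples needed
#' the extra run.
#'
#' @param X nonnegative matrix or `TransformedMatrix`.
#' @param k rank, default 3.
#' @param n_runs consensus replicates, default 10.
#' @param theta,max_iter,seed as in [nsnmf_factorize()]; run r uses seed + r.
#' @return `ConsensusResult` with `C`, `rho`, `labels`, `run_labels`,
#'   `tiebreaker_used`, and `fits` (the replicate `NMFFit`s).
#' @export
consensus_subtypes <- function(X, k = 3, n_runs = 10, theta = 0.5,
                               max_iter = 200, seed = 1) {
  if (inherits(X, "TransformedMatrix")) X <- X$values
  p <- ncol(X)
  fits <- lapply(seq_len(n_runs), function(r)
    nsnmf_factorize(X, k, theta = theta, max_iter = max_iter, seed = seed + r))
  labs <- t(vapply(fits, nmf_labels, integer(p)))
  matched <- labs
  perm_of_run <- vector("list", n_runs)
  perm_of_run[[1]] <- seq_len(k)
  for (r in seq_len(n_runs)[-1]) {
    rel <- match_partition(matched[1, ], labs[r, ], k)
    matched[r, ] <- rel
    perm_of_run[[r]] <- attr(rel, "map")  # new_label = map[old_label]
  }
  # mean matched H coefficient per label x sample, for tie-breaking
  meanH <- matrix(0, k, p)
  for (r in seq_len(n_runs)) {
    Hm <- matrix(0, k, p)
    Hm[perm_of_run[[r]], ] <- fits[[r]]$H
    meanH <- meanH + Hm / n_runs
  }
  votes <- apply(matched, 2, function(v) tabulate(v, nbins = k))
  labels <- integer(p)
  tiebreaker <- logical(p)
  need_extra <- which(apply(votes, 2, max) <= n_runs / 2)
  extra_matched <- NULL
  if (length(need_extra)) {
    extra <- nsnmf_factorize(X, k, theta = theta, max_iter = max_iter,
                             seed = seed + n_runs + 1)
    extra_matched <- match_partition(matched[1, ], nmf_labels(extra), k)
  }
  for (j in seq_len(p)) {
    v <- votes[, j]
    if (max(v) > n_runs / 2) {
      labels[j] <- which.max(v)
    } else {
      tiebreaker[j] <- TRUE
      v[extra_matched[j]] <- v[extra_matched[j]] + 1
      top <- which(v == max(v))
      labels[j] <- if (length(top) == 1) top else top[which.max(meanH[top, j])]
    }
  }
  C <- consensus_from_labels(matched)
  dimnames(C) <- list(colnames(X), colnames(X))
  structure(list(C = C, rho = cophenetic_rho(C), k = k,
                 labels = stats::setNames(labels, colnames(X)),
                 run_labels = matched, tiebreaker_used = tiebreaker,
                 fits = fits),
            class = "ConsensusResult")
}

#' Entropy-based NMF feature scores
#'
#' For feature i with basis loadings W\[i, \], p(i, q) = W(i, q) / sum_q W(i, q)
#' and score(i) = 1 + (1 / log2 k) * sum_q p(i, q) log2 p(i, q) (0 log 0 = 0):
#' 1 for a feature loading on a single factor, 0 for uniform loadings. Given a
#' list of replicate fits, per-replicate scores are averaged.
#'
#' @param fit an `NMFFit` or a list of them (replicates over the same
#'   features).
#' @return `FeatureScoreTable` data.frame: `feature`, `score` (mean across
#'   replicates), `rank` (1 = most factor-specific), `all_zero` flag, plus a
#'   `replicates` attribute holding the per-replicate score matrix.
#' @export
feature_scores <- function(fit) {
  fits <- if (inherits(fit, "NMFFit")) list(fit) else fit
  stopifnot(all(vapply(fits, inherits, logical(1), "NMFFit")))
  k <- fits[[1]]$k
  score_one <- function(f) {
    W <- f$W
    rs <- rowSums(W)
    p <- W / ifelse(rs > 0, rs, 1)
    plogp <- ifelse(p > 0, p * log2(p), 0)
    s <- 1 + rowSums(plogp) / log2(k)
    s[rs == 0] <- 0
    s
  }
  mat <- vapply(fits, score_one, numeric(nrow(fits[[1]]$W)))
  mean_score <- rowMeans(mat)
  feat <- rownames(fits[[1]]$W) %||% paste0("feature", seq_along(mean_score))
  out <- data.frame(feature = feat, score = mean_score,
                    rank = rank(-mean_score, ties.method = "first"),
                    all_zero = rowSums(vapply(fits, function(f) rowSums(f$W),
                                              numeric(nrow(mat)))) == 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "replicates") <- mat
  class(out) <- c("FeatureScoreTable", "data.frame")
  out
}

#' Union of top-scoring features across cohorts
#'
#' Takes the `n_top` highest mean-score features from each cohort's score
#' table and returns the duplicate-free union (first cohort's order first,
#' then novel features of later cohorts in their order).
#'
#' @param score_tables a `FeatureScoreTable` or list of them (one per cohort).
#' @param n_top per-cohort cut, default 1000. If a table is smaller, all of
#'   its features are taken with a warning.
#' @return character vector of feature IDs.
#' @export
select_top_features <- function(score_tables, n_top = 1000) {
  if (inherits(score_tables, "FeatureScoreTable"))
    score_tables <- list(score_tables)
  stopifnot(length(score_tables) >= 1)
  tops <- lapply(score_tables, function(tab) {
    ord <- order(-tab$score, tab$feature, method = "radix")
    if (n_top > nrow(tab)) {
      warning("n_top exceeds table size; taking all ", nrow(tab), " features")
      tab$feature[ord]
    } else tab$feature[ord[seq_len(n_top)]]
  })
  unique(unlist(tops, use.names = FALSE))
}

#' Serialize an NMF fit as W/H TSV files plus a JSON sidecar
#'
#' Writes `<prefix>_W.tsv`, `<prefix>_H.tsv` and `<prefix>.json` (rank, theta,
#' seed, final objective).
#'
#' @param fit an `NMFFit`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_nmf_fit <- function(fit, prefix) {
  stopifnot(inherits(fit, "NMFFit"))
  wtab <- data.frame(feature = rownames(fit$W) %||% seq_len(nrow(fit$W)), fit$W,
                     check.names = FALSE)
  utils::write.table(wtab, paste0(prefix, "_W.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  htab <- data.frame(factor = seq_len(nrow(fit$H)), fit$H, check.names = FALSE)
  utils::write.table(htab, paste0(prefix, "_H.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(k = fit$k, theta = fit$theta, seed = fit$seed,
                            objective = fit$objective_trace[length(fit$objective_trace)]),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
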
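#' Patient consensus subtype label from per-sample labels
#'
#' A single characterized sample gives its label directly; multiple samples
#' give the label holding a strict majority; patients whose cortex samples
#' split with no majority are labeled "Discordant".
#'
#' @param sample_labels character vector of subtype labels for one patient's
#'   samples.
#' @return single character label.
#' @export
patient_consensus_label <- function(sample_labels) {
  sample_labels <- as.character(sample_labels)
  if (length(sample_labels) < 1) stop("at least one sample label required")
  if (length(sample_labels) == 1) return(sample_labels)
  tab <- table(sample_labels)
  if (max(tab) > length(sample_labels) / 2) return(names(which.max(tab)))
  "Discordant"
}

#' Kaplan-Meier product-limit estimate
#'
#' @param durations nonnegative event/censoring times (months).
#' @param events logical (or 0/1): TRUE = event observed, FALSE = censored.
#' @return `SurvivalCurve`: list with `table` (data.frame `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, rows at event times only) and `median`
#'   (smallest time with S(t) <= 0.5, NA if S never reaches 0.5).
#' @export
kaplan_meier <- function(durations, events = rep(TRUE, length(durations))) {
  if (length(durations) == 0) stop("empty input")
  if (any(durations < 0)) stop("durations must be nonnegative")
  events <- as.logical(events)
  times <- sort(unique(durations[events]))
  s <- 1
  rows <- lapply(times, function(t) {
    n_risk <- sum(durations >= t)
    n_event <- sum(durations == t & events)
    n_censor <- sum(durations == t & !events)
    s <<- s * (1 - n_event / n_risk)
    data.frame(time = t, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, survival = s)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = numeric(0), n_risk = integer(0), n_event = integer(0),
               n_censor = integer(0), survival = numeric(0))
  med <- if (nrow(tab) && any(tab$survival <= 0.5))
    min(tab$time[tab$survival <= 0.5]) else NA_real_
  structure(list(table = tab, median = med, n = length(durations),
                 n_events = sum(events)),
            class = "SurvivalCurve")
}

#' @export
print.SurvivalCurve <- function(x, ...) {
  cat(sprintf("SurvivalCurve: %d subjects, %d events, median %s\n",
              x$n, x$n_events,
              if (is.na(x$median)) "undefined" else format(x$median)))
  invisible(x)
}

logrank_two_or_more <- function(durations, events, group) {
  levs <- sort(unique(group))
  k <- length(levs)
  times <- sort(unique(durations[events]))
  OE <- stats::setNames(numeric(k), levs)
  V <- matrix(0, k, k, dimnames = list(levs, levs))
  for (t in times) {
    at_risk <- durations >= t
    n <- sum(at_risk)
    d <- sum(durations == t & events)
    if (n <= 1 || d == 0) {
      if (d > 0) for (g in levs)
        OE[g] <- OE[g] + sum(durations == t & events & group == g) -
          d * sum(at_risk & group == g) / n
      next
    }
    nj <- vapply(levs, function(g) sum(at_risk & group == g), numeric(1))
    dj <- vapply(levs, function(g) sum(durations == t & events & group == g),
                 numeric(1))
    OE <- OE + dj - d * nj / n
    hyper <- d * (n - d) / (n - 1)
    V <- V + hyper * (diag(nj / n, k) - outer(nj / n, nj / n))
  }
  v_red <- V[-k, -k, drop = FALSE]
  oe_red <- OE[-k]
  stat <- tryCatch(as.numeric(t(oe_red) %*% solve(v_red) %*% oe_red),
                   error = function(e)
                     as.numeric(t(oe_red) %*% MASS::ginv(v_red) %*% oe_red))
  if (!is.finite(stat) || stat < 0) stat <- 0
  df <- k - 1
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE),
       observed_minus_expected = OE)
}

#' Log-rank test across survival groups
#'
#' Standard log-rank chi-square on k - 1 degrees of freedom using the full
#' observed-minus-expected vector and its hypergeometric variance-covariance.
#' `mode = "omnibus"` tests all groups jointly; `mode = "pairwise"` returns a
#' row per group pair.
#'
#' @param durations,events as in [kaplan_meier()].
#' @param group group label per subject (>= 2 nonempty groups; at least one
#'   event overall).
#' @param mode "omnibus" (default) or "pairwise".
#' @return for omnibus: list with `statistic`, `df`, `p`; for pairwise: a
#'   data.frame `group1`, `group2`, `statistic`, `p`.
#' @export
logrank_test <- function(durations, events, group,
                         mode = c("omnibus", "pairwise")) {
  mode <- match.arg(mode)
  group <- as.character(group)
  events <- as.logical(events)
  levs <- sort(unique(group))
  if (length(levs) < 2) stop("need at least two groups")
  if (any(table(factor(group, levels = levs)) == 0)) stop("empty group")
  if (!any(events)) stop("need at least one event")
  if (mode == "omnibus")
    return(logrank_two_or_more(durations, events, group))
  pairs <- utils::combn(levs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    sel <- group %in% c(g1, g2)
    res <- logrank_two_or_more(durations[sel], events[sel], group[sel])
    data.frame(group1 = g1, group2 = g2, statistic = res$statistic, p = res$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-way ANOVA and chi-square test of independence for clinical endpoints
#'
#' @param values numeric endpoint per patient (e.g. onset age), used with
#'   `labels` for the one-way ANOVA; NAs dropped pairwise. Every group needs
#'   >= 2 values.
#' @param labels group label per patient.
#' @param contingency optional label x flag count table (matrix or table) for
#'   the Pearson chi-square of independence (no continuity correction); all
#'   expected cell counts must be positive.
#' @return list with `anova` (`F`, `df1`, `df2`, `p`) and, when a table is
#'   supplied, `chisq` (`statistic`, `df`, `p`, `expected`).
#' @export
group_tests <- function(values = NULL, labels = NULL, contingency = NULL) {
  out <- list()
  if (!is.null(values)) {
    ok <- !is.na(values) & !is.na(labels)
    values <- values[ok]; labels <- as.character(labels)[ok]
    groups <- split(values, labels)
    if (length(groups) < 2) stop("ANOVA needs at least two groups")
    if (any(vapply(groups, length, integer(1)) < 2))
      stop("every group needs at least two values for ANOVA")
    n <- length(values); k <- length(groups)
    grand <- mean(values)
    ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                      numeric(1)))
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
    df1 <- k - 1; df2 <- n - k
    if (ssw == 0) {
      fstat <- if (ssb == 0) 0 else Inf
    } else fstat <- (ssb / df1) / (ssw / df2)
    p <- if (ssb == 0) 1 else stats::pf(fstat, df1, df2, lower.tail = FALSE)
    out$anova <- list(F = fstat, df1 = df1, df2 = df2, p = p)
  }
  if (!is.null(contingency)) {
    tab <- as.matrix(contingency)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected <= 0)) stop("all expected cell counts must be positive")
    stat <- sum((tab - expected)^2 / expected)
    df <- (nrow(tab) - 1) * (ncol(tab) - 1)
    out$chisq <- list(statistic = stat, df = df,
                      p = stats::pchisq(stat, df, lower.tail = FALSE),
                      expected = expected)
  }
  out
}

#' Label agreement between two classifications
#'
#' @param labels_a,labels_b named label vectors over the same sample IDs (any
#'   order; matched by name when names are present, by position otherwise).
#' @return list with `fraction` (proportion of equal labels), `n_agree`, `n`,
#'   and the full cross-tabulation `table`.
#' @export
label_agreement <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    common <- intersect(names(labels_a), names(labels_b))
    if (length(common) == 0) stop("disjoint sample ID sets")
    labels_a <- labels_a[common]; labels_b <- labels_b[common]
  } else if (length(labels_a) != length(labels_b)) {
    stop("unnamed label vectors must have equal length")
  }
  agree <- sum(labels_a == labels_b)
  list(fraction = agree / length(labels_a), n_agree = agree,
       n = length(labels_a), table = table(labels_a, labels_b))
}
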
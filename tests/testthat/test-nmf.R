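test_that("nsNMF objective is non-increasing across seeds and shapes", {
  set.seed(9)
  for (i in 1:20) {
    X <- matrix(runif(30 * 12, 0, 5), 30, 12)
    fit <- nsnmf_factorize(X, k = sample(2:4, 1), theta = runif(1),
                           max_iter = 60, seed = i)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * pmax(1, abs(tr[-length(tr)]))))
  }
})

test_that("theta = 0 matches a reference KL-NMF trajectory from identical init", {
  set.seed(2)
  X <- matrix(runif(40 * 15, 0, 4), 40, 15)
  fit <- nsnmf_factorize(X, k = 3, theta = 0, max_iter = 50, seed = 42)
  ref <- oracle_kl_nmf(X, k = 3, max_iter = 50, seed = 42)
  expect_equal(fit$objective_trace, ref$objective_trace,
               tolerance = 1e-9)
  expect_equal(fit$W, ref$W, tolerance = 1e-8)
})

test_that("a planted W.S.H factorization is recovered to small relative KL", {
  set.seed(33)
  k <- 3; theta <- 0.5
  W0 <- matrix(runif(60 * k), 60, k)
  H0 <- matrix(runif(k * 30), k, 30)
  S <- (1 - theta) * diag(k) + theta / k * matrix(1, k, k)
  X <- W0 %*% S %*% H0
  fit <- nsnmf_factorize(X, k = k, theta = theta, max_iter = 500, seed = 4)
  tr <- fit$objective_trace
  expect_lte(tr[length(tr)], 1e-3 * tr[1])
})

test_that("input validation rejects negative entries and bad ranks", {
  X <- matrix(1, 10, 5)
  expect_error(nsnmf_factorize(X - 2, 3), "nonnegative")
  expect_error(nsnmf_factorize(X, 1), ">= 2")
  expect_error(nsnmf_factorize(X, 5), "smaller")
  expect_error(nsnmf_factorize(X, 3, theta = 1.5), "theta")
})

test_that("consensus matrices are well-formed and rho = 1 when runs agree", {
  set.seed(6)
  X <- matrix(runif(30 * 14), 30, 14)
  colnames(X) <- paste0("s", 1:14)
  re <- estimate_rank(X, ranks = 2:3, n_runs = 4, max_iter = 30, seed = 3)
  for (cr in re) {
    expect_true(isSymmetric(unname(cr$C)))
    expect_equal(unname(diag(cr$C)), rep(1, 14))
    expect_true(all(cr$C >= 0 & cr$C <= 1))
    expect_true(cr$rho >= -1 && cr$rho <= 1)
  }
  # identical partitions across runs -> binary C, rho 1
  labs <- matrix(rep(c(1, 1, 2, 2, 3, 3), 5), 5, 6, byrow = TRUE)
  C <- alsSubtypes:::consensus_from_labels(labs)
  expect_true(all(C %in% c(0, 1)))
  expect_equal(alsSubtypes:::cophenetic_rho(C), 1)
})

test_that("majority, tiebreaker and permutation alignment behave as specified", {
  # run-permutation invariance: H row-permutations give identical labels
  set.seed(11)
  H1 <- matrix(runif(3 * 10), 3, 10)
  l1 <- apply(H1, 2, which.max)
  perm <- c(3, 1, 2)
  l2 <- apply(H1[perm, ], 2, which.max)     # relabeled clustering
  matched <- alsSubtypes:::match_partition(l1, l2, 3)
  expect_equal(as.integer(matched), l1)

  # majority vote without tiebreak: 6 of 10 runs agree
  co <- small_cohort()
  drop <- suppressWarnings(remove_sex_features(co$counts))
  cc <- co$counts[!rownames(co$counts$values) %in% drop, ]
  v <- vst_transform(cc$values, size_factors(cc$values))
  X <- v$values[select_mad_features(v, 300), ]
  X <- X - min(0, min(X))
  cr <- consensus_subtypes(X, k = 3, n_runs = 6, max_iter = 300, seed = 5)
  votes <- apply(cr$run_labels, 2, function(v) max(tabulate(v, 3)))
  expect_true(all(cr$tiebreaker_used == (votes <= 3)))
  # labels with a strict majority equal the top vote
  maj <- votes > 3
  top <- apply(cr$run_labels[, maj, drop = FALSE], 2,
               function(v) which.max(tabulate(v, 3)))
  expect_equal(unname(cr$labels[maj]), unname(top))
})

test_that("feature scores hit the closed forms and are permutation-invariant", {
  mk_fit <- function(W) structure(list(W = W, H = matrix(1, ncol(W), 2), k = ncol(W)),
                                  class = "NMFFit")
  W <- rbind(c(1, 0, 0), c(1, 1, 1) / 3, c(0.5, 0.5, 0), c(0, 0, 0))
  rownames(W) <- paste0("f", 1:4)
  fs <- feature_scores(mk_fit(W))
  expect_equal(fs$score[1], 1)
  expect_equal(fs$score[2], 0, tolerance = 1e-12)
  expect_equal(fs$score[3], 1 - 1 / log2(3), tolerance = 1e-12)
  expect_equal(fs$score[4], 0)
  expect_true(fs$all_zero[4])

  set.seed(18)
  Wr <- matrix(runif(50 * 4), 50, 4)
  f_orig <- feature_scores(mk_fit(Wr))$score
  f_perm <- feature_scores(mk_fit(Wr[, c(3, 1, 4, 2)]))$score
  expect_equal(f_orig, f_perm, tolerance = 1e-12)

  # replicate averaging
  fits <- list(mk_fit(W), mk_fit(W[, c(2, 3, 1)]))
  expect_equal(feature_scores(fits)$score, fs$score, tolerance = 1e-12)
})

test_that("top-feature union sizes follow the overlap structure", {
  mk_tab <- function(feats, scores) {
    structure(data.frame(feature = feats, score = scores,
                         rank = rank(-scores, ties.method = "first"),
                         all_zero = FALSE),
              class = c("FeatureScoreTable", "data.frame"))
  }
  n <- 1200
  pool <- sprintf("g%04d", 1:(2 * n))
  # cohorts sharing exactly 319 of their top-1000
  shared <- pool[1:319]
  a_only <- pool[320:1000]
  b_only <- pool[1001:1681]
  tab_a <- mk_tab(c(shared, a_only, pool[1682:1800]),
                  c(rep(1, 1000), rep(0.1, 119)))
  tab_b <- mk_tab(c(shared, b_only, pool[1801:1900]),
                  c(rep(1, 1000), rep(0.1, 100)))
  u <- select_top_features(list(tab_a, tab_b), n_top = 1000)
  expect_length(u, 1681)

  expect_length(select_top_features(list(tab_a, tab_a), 1000), 1000)
  disj <- select_top_features(list(mk_tab(pool[1:50], runif(50)),
                                   mk_tab(pool[51:100], runif(50))), 50)
  expect_length(disj, 100)
  expect_warning(select_top_features(mk_tab(pool[1:10], runif(10)), 20),
                 "taking all")
})
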
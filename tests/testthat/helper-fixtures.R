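# Shared fixtures and independent oracles. Fixtures are generated in code and
# cached per test run; oracles deliberately re-derive quantities by brute
# force, independently of the package's implementation paths.

fixture_env <- new.env(parent = emptyenv())

# small cohort reused by several module tests
small_cohort <- function() {
  if (is.null(fixture_env$small)) {
    fixture_env$small <- generate_cohort(cohort_config(
      n_samples = 60, n_genes = 600, n_te = 60, program_size = 60,
      n_sex_genes = 10, hybrid_frac = 0, seed = 101))
  }
  fixture_env$small
}

random_count_matrix <- function(nfeat, nsamp, seed = 1, mu = 50, size = 5) {
  set.seed(seed)
  m <- matrix(rnbinom(nfeat * nsamp, mu = mu, size = size), nfeat, nsamp,
              dimnames = list(sprintf("g%03d", seq_len(nfeat)),
                              sprintf("s%02d", seq_len(nsamp))))
  m
}

# --- oracles ----------------------------------------------------------------

# brute-force median-of-ratios
oracle_size_factors <- function(m) {
  ref <- apply(m, 1, function(x) all(x > 0))
  geo <- exp(rowMeans(log(m[ref, , drop = FALSE])))
  apply(m[ref, , drop = FALSE], 2, function(x) median(x / geo))
}

# step-up BH oracle
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# plain multiplicative KL-NMF with identical initialization scheme
oracle_kl_nmf <- function(X, k, max_iter, seed) {
  n <- nrow(X); p <- ncol(X)
  scale0 <- sqrt(mean(X) / k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  W <- matrix(runif(n * k), n, k) * scale0
  H <- matrix(runif(k * p), k, p) * scale0
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  eps <- 1e-16
  obj <- numeric(max_iter)
  kl <- function(A, B) {
    B <- pmax(B, eps); pos <- A > 0
    sum(A[pos] * log(A[pos] / B[pos])) - sum(A) + sum(B)
  }
  kl0 <- kl(X, W %*% H)
  for (it in seq_len(max_iter)) {
    WH <- pmax(W %*% H, eps)
    H <- H * (t(W) %*% (X / WH)) / pmax(colSums(W), eps)
    WH <- pmax(W %*% H, eps)
    W <- W * ((X / WH) %*% t(H)) / rep(pmax(rowSums(H), eps), each = n)
    obj[it] <- kl(X, W %*% H)
  }
  list(W = W, H = H, objective_trace = c(kl0, obj))
}

# direct observed-minus-expected two-group log-rank
oracle_logrank2 <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  times <- sort(unique(time[event]))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group == g[1])
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & group == g[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O - E)^2 / V
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

random_te_locus <- function() {
  sub <- c("AluY", "L1PA2", "MLT1B", "MIRb", "HERVK9-int")
  fam <- c("Alu", "L1", "ERVL-MaLR", "MIR", "ERVK")
  s <- sample(5, 1)
  start <- sample.int(1e8, 1)
  structure(list(chrom = paste0("chr", sample(c(1:22, "X", "Y"), 1)),
                 start = start, end = start + sample(50:5000, 1),
                 subfamily = sub[s], family = fam[s],
                 superfamily = sample(c("SINE", "LINE", "LTR"), 1),
                 score = sample(0:1000, 1),
                 strand = sample(c("+", "-"), 1)),
            class = "TELocus")
}
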
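test_that("size factors match forced cases and the brute-force oracle", {
  m <- random_count_matrix(30, 2, seed = 5) + 1
  m[, 2] <- m[, 1]
  expect_equal(unname(as.numeric(size_factors(m))), c(1, 1))

  m2 <- cbind(a = m[, 1], b = 2 * m[, 1])
  expect_equal(unname(as.numeric(size_factors(m2))), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  m3 <- random_count_matrix(50, 6, seed = 9)
  expect_equal(unname(as.numeric(size_factors(m3))),
               unname(oracle_size_factors(m3)), tolerance = 1e-12)

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2,
                                   dimnames = list(c("a", "b"), c("x", "y")))),
               "pseudocount")
})

test_that("size factors are scale-equivariant in a single sample", {
  m <- random_count_matrix(80, 5, seed = 21) + 1
  sf <- as.numeric(size_factors(m))
  m2 <- m
  m2[, 3] <- m2[, 3] * 4
  sf2 <- as.numeric(size_factors(m2))
  # geometric mean reference shifts by 4^(1/5); all factors rescale accordingly
  expect_equal(sf2[3] / sf[3] * (sf2[1] / sf[1])^-1, 4, tolerance = 1e-10)
})

test_that("vst is monotone, leaves constants constant, and flattens variance", {
  m <- random_count_matrix(400, 20, seed = 2, mu = 100)
  m[1, ] <- 50  # constant feature
  sf <- size_factors(m)
  v <- vst_transform(m, sf)
  expect_equal(v$transform, "vst")
  expect_gt(v$params$a0, 0)
  # constant gene with equal factors stays constant
  m_eq <- m
  v_eq <- vst_transform(m_eq, structure(rep(1, 20), class = "SizeFactors"))
  expect_equal(var(v_eq$values[1, ]), 0)
  # monotone within a sample: ordering of q implies ordering of y
  q <- sweep(m, 2, as.numeric(sf), "/")
  ord_q <- order(q[, 1]); ord_y <- order(v$values[, 1])
  expect_equal(ord_q, ord_y)

  # stabilization: NB genes spanning means 10..1e4, alpha = 0.2
  set.seed(4)
  mus <- 10^runif(2000, 1, 4)
  raw <- t(vapply(mus, function(mu) rnbinom(100, mu = mu, size = 5),
                  numeric(100)))
  rownames(raw) <- paste0("g", seq_len(nrow(raw)))
  colnames(raw) <- paste0("s", seq_len(ncol(raw)))
  vs <- vst_transform(raw, structure(rep(1, 100), class = "SizeFactors"))
  bins <- cut(log10(mus), 5)
  var_ratio <- function(x) {
    bv <- tapply(seq_along(mus), bins, function(ix) mean(apply(x[ix, ], 1, var)))
    max(bv) / min(bv)
  }
  expect_lte(var_ratio(vs$values), 3)
  expect_gt(var_ratio(raw), 30)
})

test_that("vst approaches log2 slope 1 for large counts", {
  m <- random_count_matrix(200, 10, seed = 6, mu = 200)
  v <- vst_transform(m)
  a0 <- v$params$a0; a1 <- v$params$a1
  q <- 1e4 / a0
  y <- function(q) log2((1 + a1 + 2 * a0 * q + 2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
  expect_equal(y(2 * q) - y(q), 1, tolerance = 1e-3)
})

test_that("MAD selection reproduces a brute-force sort with documented ties", {
  set.seed(8)
  m <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(sprintf("f%02d", 20:1), paste0("s", 1:10)))
  m[3, ] <- 7  # constant feature, MAD 0
  sel <- select_mad_features(m, 20)
  mads <- apply(m, 1, function(x) median(abs(x - median(x))))
  ord <- order(-mads, rownames(m), method = "radix")
  expect_identical(sel, rownames(m)[ord])
  expect_identical(sel[20], rownames(m)[3])   # constant never outranks varying
  expect_error(select_mad_features(m, 21), "exceeds")
})

test_that("covariate adjustment removes linear effects and handles degeneracy", {
  set.seed(12)
  n <- 200
  rin <- runif(n, 5, 9)
  site <- sample(c("a", "b", "c"), n, replace = TRUE)
  expr <- rbind(f1 = 2 * rin + rnorm(n, sd = 0.5),
                f2 = rnorm(n))
  colnames(expr) <- paste0("s", seq_len(n))
  adj <- adjust_covariates(expr, data.frame(rin = rin, site = site))
  expect_lt(abs(cor(adj$values["f1", ], rin)), 0.05)

  # covariates orthogonal to expression (balanced within rin groups):
  # zero fitted effect, output equals input
  cov0 <- data.frame(rin = rep(c(4, 6), each = 4))
  ortho <- rbind(f = rep(c(1, 2), 4))
  colnames(ortho) <- paste0("s", 1:8)
  expect_equal(adjust_covariates(ortho, cov0)$values, ortho, tolerance = 1e-10)

  # single-level factor dropped with warning, not an error
  expect_warning(adjust_covariates(expr, data.frame(rin = rin,
                                                    site = rep("a", n))),
                 "single-level")
  # rank-deficient design errors and names the aliased column
  expect_error(adjust_covariates(expr, data.frame(rin = rin, rin2 = rin)),
               "rank-deficient")
})

test_that("reference z-scoring centers, scales and clips", {
  set.seed(30)
  m <- matrix(rnorm(50 * 12, mean = 5), 50, 12,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:12)))
  refs <- paste0("s", 1:8)
  z <- zscore_reference_clip(m, refs, clip_floor = -4)
  expect_equal(rowMeans(z$values[, refs]), rep(0, 50), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(z$values[, refs], 1, sd), rep(1, 50), tolerance = 1e-12,
               ignore_attr = TRUE)

  # a non-reference value 7 SD below the reference mean is emitted as -4
  m2 <- m
  m2[1, "s12"] <- mean(m[1, refs]) - 7 * sd(m[1, refs])
  z2 <- zscore_reference_clip(m2, refs)
  expect_equal(z2$values[1, "s12"], -4)
  # reference samples are never clipped: their z equals the plain z-score
  z_manual <- (m - rowMeans(m[, refs])) /
    apply(m[, refs], 1, sd)
  expect_equal(z$values[, refs], z_manual[, refs], tolerance = 1e-12)

  m4 <- m
  m4[2, ] <- 3
  expect_warning(z4 <- zscore_reference_clip(m4, refs), "zero reference SD")
  expect_equal(unname(z4$values[2, ]), rep(0, 12))
})
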
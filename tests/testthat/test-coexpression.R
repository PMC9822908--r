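make_block_data <- function(n_block = 2, block_size = 40, n_noise = 20,
                            n_samples = 60, r = 0.8, seed = 1) {
  set.seed(seed)
  blocks <- lapply(seq_len(n_block), function(b) {
    f <- rnorm(n_samples)
    t(vapply(seq_len(block_size), function(i)
      sqrt(r) * f + sqrt(1 - r) * rnorm(n_samples), numeric(n_samples)))
  })
  m <- rbind(do.call(rbind, blocks),
             matrix(rnorm(n_noise * n_samples), n_noise, n_samples))
  dimnames(m) <- list(sprintf("f%03d", seq_len(nrow(m))),
                      sprintf("s%02d", seq_len(n_samples)))
  list(m = m, truth = rep(c(seq_len(n_block), 0),
                          c(rep(block_size, n_block), n_noise)))
}

test_that("planted correlation blocks are recovered as modules", {
  d <- make_block_data(seed = 42)
  ms <- detect_modules(d$m, soft_power = 13, min_size = 25)
  mods <- setdiff(unique(ms$labels), "gray")
  expect_length(mods, 2)
  in_block <- d$truth > 0
  expect_gte(adjusted_rand_index(ms$labels[in_block], d$truth[in_block]), 0.95)
  # TOM well-formed
  expect_true(isSymmetric(unname(ms$TOM)))
  expect_true(all(ms$TOM >= 0 & ms$TOM <= 1))
  expect_equal(unname(diag(ms$TOM)), rep(1, nrow(ms$TOM)))
})

test_that("independent features yield no modules and near-zero TOM", {
  set.seed(3)
  m <- matrix(rnorm(60 * 80), 60, 80,
              dimnames = list(sprintf("f%02d", 1:60), sprintf("s%02d", 1:80)))
  ms <- detect_modules(m, min_size = 25)
  expect_true(all(ms$labels == "gray"))
  off <- ms$TOM[upper.tri(ms$TOM)]
  expect_lt(max(off), 0.05)

  m[1, ] <- 5
  expect_warning(detect_modules(m, min_size = 25), "constant")
  expect_error(detect_modules(m[1:10, ], min_size = 25), "min_size")
})

test_that("module eigengenes match identities and the SVD oracle", {
  set.seed(8)
  m <- matrix(rnorm(30 * 25, mean = 3), 30, 25,
              dimnames = list(paste0("f", 1:30), paste0("s", 1:25)))
  # single-gene module: the standardized gene itself
  e1 <- module_eigengene(m, "f1")
  expect_equal(unname(e1), unname(scale(m[1, ])[, 1]), tolerance = 1e-10)

  # two perfectly correlated genes
  m2 <- m
  m2["f2", ] <- 2 * m2["f1", ] + 3
  e2 <- module_eigengene(m2, c("f1", "f2"))
  expect_equal(abs(cor(e2, m2["f1", ])), 1, tolerance = 1e-10)

  # 30-gene random module equals brute-force first right singular vector
  Z <- t(scale(t(m)))
  sv <- svd(Z)$v[, 1]
  if (mean(cor(sv, t(Z))) < 0) sv <- -sv
  sv <- (sv - mean(sv)) / sd(sv)
  expect_equal(unname(module_eigengene(m, rownames(m))), sv, tolerance = 1e-8)

  # orientation rule: mean member correlation nonnegative
  expect_gte(mean(cor(module_eigengene(m, paste0("f", 1:10)),
                      t(m[1:10, ]))), 0)
  expect_error(module_eigengene(rbind(c = rep(1, 5)), "c"), "constant")
})

test_that("eigengene associations match closed-form regression oracles", {
  set.seed(19)
  n <- 80
  e <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("gold", "navy")))
  traits <- data.frame(onset = rnorm(n), death = e[, 1] * 2 + rnorm(n))
  traits$onset[c(3, 10)] <- NA
  subs <- sample(c("Glia", "Ox", "TD"), n, replace = TRUE)
  assoc <- eigengene_association(e, traits, subs)

  for (i in seq_len(nrow(assoc$traits))) {
    row <- assoc$traits[i, ]
    x <- e[, row$eigengene]; y <- traits[[row$trait]]
    ok <- !is.na(x) & !is.na(y)
    ct <- cor.test(x[ok], y[ok])
    expect_equal(row$r, unname(ct$estimate), tolerance = 1e-10)
    expect_equal(row$p, ct$p.value, tolerance = 1e-10)
  }
  for (i in seq_len(nrow(assoc$subtypes))) {
    row <- assoc$subtypes[i, ]
    dummy <- as.numeric(subs == row$subtype)
    fit <- summary(lm(e[, row$eigengene] ~ dummy))$coefficients
    expect_equal(row$beta, fit["dummy", "Estimate"], tolerance = 1e-10)
    expect_equal(row$p, fit["dummy", "Pr(>|t|)"], tolerance = 1e-10)
  }
  expect_equal(assoc$subtypes$p_bonferroni,
               pmin(1, assoc$subtypes$p * nrow(assoc$subtypes)))

  # sign convention: upregulated-in-A eigengene has beta_A > 0, others < 0
  eA <- matrix(as.numeric(subs == "Glia"), n, 1, dimnames = list(NULL, "m"))
  aA <- eigengene_association(eA, subtypes = subs)$subtypes
  expect_gt(aA$beta[aA$subtype == "Glia"], 0)
  expect_lt(max(aA$beta[aA$subtype != "Glia"]), 0)

  # constant eigengene across subtypes: all betas 0
  e0 <- matrix(1, n, 1, dimnames = list(NULL, "flat"))
  a0 <- eigengene_association(e0, subtypes = subs)$subtypes
  expect_equal(a0$beta, rep(0, 3))
})

test_that("hypergeometric enrichment equals Fisher's exact test", {
  universe <- sprintf("g%04d", 1:1000)
  query <- universe[1:10]
  gs <- list(hit = c(universe[1:8], universe[101:192]),
             miss = universe[500:599])
  res <- enrich_hypergeometric(query, gs, universe)
  f <- fisher.test(matrix(c(8, 2, 92, 898), 2, 2), alternative = "greater")
  expect_equal(res$p[res$set == "hit"], f$p.value, tolerance = 1e-12)

  # saturation and disjoint cases
  sat <- enrich_hypergeometric(universe, gs, universe)
  expect_equal(sat$p, rep(1, 2))
  dis <- enrich_hypergeometric(universe[900:950],
                               list(s = universe[1:100]), universe)
  expect_equal(dis$p, 1)

  bon <- enrich_hypergeometric(query, gs, universe, correction = "Bonferroni")
  expect_equal(bon$p_adjusted, pmin(1, bon$p * 2))
  expect_error(enrich_hypergeometric(c("zzz"), gs, universe), "subset")
  expect_error(enrich_hypergeometric(query, gs, character(0)), "empty")
})

test_that("edge export equals a brute-force threshold filter", {
  w <- matrix(c(1, .2, .04, .5,
                .2, 1, .06, .01,
                .04, .06, 1, .3,
                .5, .01, .3, 1), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  e <- export_network_edges(w, 0.05)
  manual <- data.frame()
  for (i in 1:3) for (j in (i + 1):4)
    if (w[i, j] >= 0.05)
      manual <- rbind(manual, data.frame(from = letters[i], to = letters[j],
                                         weight = w[i, j]))
  expect_equal(e[order(e$from, e$to), ], manual[order(manual$from, manual$to), ],
               ignore_attr = TRUE)
  expect_equal(nrow(export_network_edges(w * 0 + diag(4), 0.05)), 0)
  expect_error(export_network_edges(matrix(1:4, 2, 2)), "symmetric")
})
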
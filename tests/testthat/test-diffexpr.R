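test_that("TMM factors are 1 for identical libraries and flag zero samples", {
  m <- matrix(rep(c(10, 100, 1000, 50), 4), 4, 4,
              dimnames = list(NULL, paste0("S", 1:4)))
  expect_equal(unname(compute_tmm_factors(m)), rep(1, 4), tolerance = 1e-12)

  m[, 2] <- 0
  expect_error(compute_tmm_factors(m), "S2")
})

test_that("TMM factors match a from-scratch trimmed-mean oracle", {
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(rnbinom(400 * 4, mu = exp(runif(400, log(20), log(2000))),
                        size = 5), 400, 4)
    colnames(m) <- paste0("S", 1:4)
    # composition shift: sample 2 has 10% of features 8-fold up
    m[1:40, 2] <- m[1:40, 2] * 8
    expect_equal(unname(compute_tmm_factors(m)), unname(tmm_oracle(m)),
                 tolerance = 1e-10)
  }
})

test_that("TMM factors are invariant to global library scaling", {
  set.seed(3)
  m <- matrix(rnbinom(200 * 5, mu = 100, size = 5), 200, 5,
              dimnames = list(NULL, paste0("S", 1:5)))
  f1 <- compute_tmm_factors(m)
  f2 <- compute_tmm_factors(m * 7)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("log-CPM matches its closed form and is finite at zero counts", {
  m <- matrix(c(1e6, 0), 1, 2, dimnames = list("G1", c("A", "B")))
  lc <- normalize_logcpm(matrix(1e6, 1, 1, dimnames = list("G1", "A")),
                         factors = 1)
  expect_equal(lc[1, 1], log2(1e6 + 0.5), tolerance = 1e-12)

  m2 <- matrix(c(0, 10, 5, 100), 2, 2,
               dimnames = list(c("G1", "G2"), c("A", "B")))
  lc2 <- normalize_logcpm(m2, c(1, 1))
  expect_true(all(is.finite(lc2)))
  expect_error(normalize_logcpm(m2, 1), "ncol")
})

test_that("doubling one library leaves its normalized log-CPM unchanged", {
  set.seed(8)
  m <- matrix(rnbinom(300 * 4, mu = 200, size = 5), 300, 4,
              dimnames = list(NULL, paste0("S", 1:4)))
  # the plain trimmed mean is exactly invariant here; precision weights are
  # scale-sensitive per library, so this invariance is checked unweighted
  lc1 <- normalize_logcpm(m, compute_tmm_factors(m, weighted = FALSE))
  m2 <- m
  m2[, 3] <- m2[, 3] * 2
  lc2 <- normalize_logcpm(m2, compute_tmm_factors(m2, weighted = FALSE))
  expect_equal(lc1[, 3], lc2[, 3], tolerance = 1e-6)
})

test_that("permuting samples permutes log-CPM columns identically", {
  set.seed(9)
  m <- matrix(rnbinom(100 * 4, mu = 100, size = 5), 100, 4,
              dimnames = list(NULL, paste0("S", 1:4)))
  f <- compute_tmm_factors(m)
  perm <- c(3, 1, 4, 2)
  expect_equal(normalize_logcpm(m[, perm], f[perm]),
               normalize_logcpm(m, f)[, perm])
})

test_that("BH adjustment matches hand computation and handles edge cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("BH monotonicity and fdr >= p hold on random vectors", {
  set.seed(21)
  for (i in 1:20) {
    p <- runif(50)^2
    fdr <- bh_adjust(p)
    expect_true(all(fdr >= p))
    o <- order(p)
    expect_true(all(diff(fdr[o]) >= -1e-15))
  }
})

test_that("row-wise paired Wilcoxon matches stats::wilcox.test", {
  set.seed(4)
  d <- matrix(rnorm(20 * 15), 20, 15) + rep(c(0, 0.8), each = 10)
  p_pkg <- paired_wilcoxon_p(d)
  p_ref <- apply(d, 1, function(x) {
    wilcox.test(x, exact = FALSE, correct = TRUE)$p.value
  })
  expect_equal(unname(p_pkg), unname(p_ref), tolerance = 1e-12)
  # constant (all-zero-difference) feature
  expect_equal(unname(paired_wilcoxon_p(matrix(0, 1, 15))), 1)
})

test_that("test_differential flags planted effects with correct direction", {
  tc <- tiny_counts(n_feat = 60, n_pairs = 20, log2fc = 2, n_de = 10,
                    seed = 13)
  tab <- test_differential(tc$counts, tc$metadata)
  expect_equal(tab$direction[1:10], rep("up", 10))
  expect_true(all(tab$fdr >= tab$pvalue - 1e-15))
  expect_error(test_differential(tc$counts[, 1:4], tc$metadata[1:4, ]),
               "3 pairs")
})

test_that("a strong but small fold change fails the |log2FC| > 1 gate", {
  tc <- tiny_counts(n_feat = 200, n_pairs = 60, log2fc = 0.5, n_de = 20,
                    seed = 17)
  tab <- test_differential(tc$counts, tc$metadata)
  planted <- tab[1:20, ]
  expect_true(any(planted$pvalue < 1e-6))
  expect_true(all(planted$direction == "none"))
  expect_true(all(abs(planted$log2fc) < 1))
})

test_that("stability selection reduces to single-pass DE at rounds = 1", {
  tc <- tiny_counts(n_feat = 80, n_pairs = 12, log2fc = 2, n_de = 10,
                    seed = 19)
  tab <- test_differential(tc$counts, tc$metadata)
  sel <- stability_select(tc$counts, tc$metadata, rounds = 1, fraction = 1,
                          seed = 5)
  expect_setequal(sel$stable, tab$feature_id[tab$direction != "none"])
})

test_that("the stability intersection shrinks monotonically with rounds", {
  tc <- tiny_counts(n_feat = 100, n_pairs = 15, log2fc = 1.5, n_de = 15,
                    seed = 23)
  sel <- stability_select(tc$counts, tc$metadata, rounds = 12, seed = 31)
  inter <- Reduce(intersect, sel$per_round, accumulate = TRUE)
  for (k in 2:length(inter)) {
    expect_true(all(inter[[k]] %in% inter[[k - 1]]))
  }
})

test_that("stability selection guards degenerate subsamples", {
  tc <- tiny_counts(n_feat = 10, n_pairs = 3, seed = 1)
  expect_error(stability_select(tc$counts, tc$metadata, rounds = 2,
                                fraction = 0.5),
               "3-pair")
  expect_error(stability_select(tc$counts, tc$metadata, rounds = 0), "rounds")
})

test_that("missing-value filtering applies the per-class rules", {
  m <- matrix(1, 4, 9)
  m[1, 1:4] <- NA   # 4/9 > 1/3 missing
  m[2, 1:3] <- NA   # 3/9 = 1/3, kept for RNA-Seq; > 2 missing for miRNA
  m[3, 1:2] <- NA
  expect_equal(nrow(filter_missing(m, "mrna")), 3L)
  expect_equal(nrow(filter_missing(m, "mirna")), 2L)
})
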
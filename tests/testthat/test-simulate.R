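test_that("invalid simulation configs fail naming the offending field", {
  expect_error(sim_config(n_pairs = 0), "n_pairs")
  expect_error(sim_config(planted_log2fc = 0.5), "planted_log2fc")
  expect_error(sim_config(triplet_strength = 1.2), "triplet_strength")
  expect_error(sim_config(n_triplets = 80, n_de_mrna = 70, n_de_lncrna = 90),
               "n_triplets")
  expect_error(sim_config(n_de_mrna = 1000), "n_de_mrna")
  expect_error(sim_config(baseline_mean_range = c(10, 5)),
               "baseline_mean_range")
})

test_that("identical seeds give byte-identical datasets and files", {
  cfg <- sim_config(n_pairs = 10, n_mrna = 40, n_lncrna = 20, n_mirna = 15,
                    n_de_mrna = 10, n_de_lncrna = 6, n_de_mirna = 4,
                    n_triplets = 4, mrnas_per_module = 2, seed = 42)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_dataset(d1, dir1)
  write_dataset(d2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})

test_that("datasets round-trip through write/read", {
  cfg <- sim_config(n_pairs = 8, n_mrna = 30, n_lncrna = 12, n_mirna = 10,
                    n_de_mrna = 8, n_de_lncrna = 4, n_de_mirna = 3,
                    n_triplets = 3, mrnas_per_module = 2, seed = 5)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$counts, ds$counts)
  expect_equal(back$metadata, ds$metadata)
  expect_equal(back$edges, ds$edges)
  expect_equal(back$targets_mrna, ds$targets_mrna)
  expect_equal(back$targets_lncrna, ds$targets_lncrna)
  expect_equal(back$truth$de_features, ds$truth$de_features)
  expect_equal(back$truth$triplets, ds$truth$triplets)
  expect_equal(back$truth$modules, ds$truth$modules)
})

test_that("ground truth lists exactly n_triplets planted triplets, all DE", {
  cfg <- sim_config(n_pairs = 8, n_mrna = 60, n_lncrna = 20, n_mirna = 15,
                    n_de_mrna = 20, n_de_lncrna = 8, n_de_mirna = 6,
                    n_triplets = 7, mrnas_per_module = 3, seed = 2)
  ds <- generate_dataset(cfg)
  tr <- ds$truth$triplets
  expect_equal(nrow(tr), 7L)
  de <- ds$truth$de_features$feature_id
  expect_true(all(unlist(tr) %in% de))
  # expected module grouping = union of triplet partners per miRNA
  for (m in ds$truth$modules) {
    expect_setequal(m$mrna_ids, tr$mrna_id[tr$mirna_id == m$mirna_id])
    expect_setequal(m$lncrna_ids,
                    unique(tr$lncrna_id[tr$mirna_id == m$mirna_id]))
  }
})

test_that("without planted signal, empirical |log2FC| concentrates near 0", {
  cfg <- sim_config(n_pairs = 100, n_mrna = 300, n_lncrna = 10, n_mirna = 10,
                    n_de_mrna = 0, n_de_lncrna = 0, n_de_mirna = 0,
                    n_triplets = 0, planted_log2fc = 0, seed = 1)
  ds <- generate_dataset(cfg)
  lc <- normalize_logcpm(ds$counts$mrna, compute_tmm_factors(ds$counts$mrna))
  tumor <- ds$metadata$condition == "tumor"
  lfc <- rowMeans(lc[, tumor]) - rowMeans(lc[, !tumor])
  expect_lt(median(abs(lfc)), 0.1)
  expect_lt(max(abs(lfc)), 1)
})

test_that("planted triplets show the ceRNA correlation sign pattern", {
  cfg <- sim_config(n_pairs = 100, triplet_strength = 0.7, seed = 7)
  ds <- generate_dataset(cfg)
  norm <- lapply(ds$counts,
                 function(m) normalize_logcpm(m, compute_tmm_factors(m)))
  expr <- do.call(rbind, norm)
  tr <- ds$truth$triplets
  ok <- mapply(function(g, m, l) {
    cor(expr[m, ], expr[g, ]) < 0 &&
      cor(expr[m, ], expr[l, ]) < 0 &&
      cor(expr[g, ], expr[l, ]) > 0
  }, tr$mrna_id, tr$mirna_id, tr$lncrna_id)
  expect_gte(mean(ok), 0.95)
})

test_that("an empty dataset writes valid empty files", {
  cfg <- sim_config(n_pairs = 5, n_mrna = 10, n_lncrna = 5, n_mirna = 5,
                    n_de_mrna = 0, n_de_lncrna = 0, n_de_mirna = 0,
                    n_triplets = 0, planted_log2fc = 0, n_decoy_targets = 0,
                    seed = 3)
  ds <- generate_dataset(cfg)
  empty <- ds
  for (cls in names(empty$counts)) {
    empty$counts[[cls]] <- empty$counts[[cls]][integer(), , drop = FALSE]
  }
  dir <- withr::local_tempdir()
  expect_no_error(write_dataset(empty, dir))
  back <- suppressWarnings(read_dataset(dir))   # empty target tables warn
  expect_equal(nrow(back$counts$mrna), 0L)
  expect_equal(nrow(back$truth$triplets), 0L)
})
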
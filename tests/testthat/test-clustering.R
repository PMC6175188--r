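test_that("window pair counts follow the inclusive same-chromosome definition", {
  expect_equal(pairwise_window_counts("chr1", c(100L, 300L, 10000L), 101, 500), 1)
  expect_equal(pairwise_window_counts("chr1", c(100L, 150L), 101, 500), 0)
  expect_equal(pairwise_window_counts(c("chr1", "chr2"), c(100L, 300L), 101, 500), 0)
  # inclusive bounds on both ends
  expect_equal(pairwise_window_counts("chr1", c(100L, 201L), 101, 500), 1)
  expect_equal(pairwise_window_counts("chr1", c(100L, 600L), 101, 500), 1)
  expect_equal(pairwise_window_counts("chr1", c(100L, 601L), 101, 500), 0)
  # duplicated positions collapse; distance 0 never counts
  expect_equal(pairwise_window_counts("chr1", c(100L, 100L), 1, 500), 0)
  expect_error(pairwise_window_counts("chr1", 100L, 0, 10), "lo_bp")
})

test_that("window pair counts equal the all-pairs double loop", {
  set.seed(61)
  for (rep in 1:6) {
    n <- sample(50:200, 1)
    chrom <- sample(c("chr1", "chr2", "chr3"), n, replace = TRUE)
    pos <- sample.int(50000, n, replace = TRUE)
    for (w in list(c(1, 100), c(101, 500), c(1001, 5000))) {
      expect_equal(pairwise_window_counts(chrom, pos, w[1], w[2]),
                   pair_count_oracle(chrom, pos, w[1], w[2]))
    }
  }
})

test_that("within-pair permutation test flags planted hotspots and is calibrated", {
  # candidates identical to background: every permutation reproduces the
  # observed statistic, so p = 1 in every window
  bg <- data.frame(chrom = "chr1", pos = sort(sample.int(1e6, 300)))
  res <- within_pair_cluster_test(bg, bg, n_perm = 50, seed = 3)
  expect_true(all(res$p_perm == 1))
  expect_true(all(res$fold_change[res$perm_mean > 0] == 1))

  # strongly clustered candidates against a uniform background
  set.seed(71)
  d <- generate_twin_dataset(generator_config(
    n_loci = 10000, n_mosaic = 150, mosaic_cell_fraction = 1,
    hotspots = list(n_hotspots = 5, span_bp = 5000, fraction_in_hotspots = 0.8),
    seed = 71))
  cand <- d$truth[d$truth$is_mosaic, c("chrom", "pos")]
  res2 <- within_pair_cluster_test(cand, d$truth[, c("chrom", "pos")],
                                   n_perm = 500, seed = 8)
  expect_lte(min(res2$p_perm), 0.01)
  expect_true(all(res2$p_perm >= 1 / 501))

  expect_error(within_pair_cluster_test(bg, bg[1:10, ]), "fewer loci")
  notin <- data.frame(chrom = "chr9", pos = 1L)
  expect_error(within_pair_cluster_test(notin, bg), "subset")
})

test_that("permutation p-values are invariant to relabeling and translation", {
  set.seed(81)
  bg <- data.frame(chrom = rep(c("chr1", "chr2"), each = 400),
                   pos = c(sort(sample.int(5e5, 400)), sort(sample.int(5e5, 400))))
  cand <- bg[sample.int(800, 60), ]
  r1 <- within_pair_cluster_test(cand, bg, n_perm = 100, seed = 5)
  relabel <- function(df) transform(df, chrom = ifelse(chrom == "chr1", "alpha", "beta"))
  r2 <- within_pair_cluster_test(relabel(cand), relabel(bg), n_perm = 100, seed = 5)
  expect_equal(r1$p_perm, r2$p_perm)
  expect_equal(r1$observed, r2$observed)
  shift <- function(df) transform(df, pos = pos + ifelse(chrom == "chr1", 10000L, 250L))
  r3 <- within_pair_cluster_test(shift(cand), shift(bg), n_perm = 100, seed = 5)
  expect_equal(r1$p_perm, r3$p_perm)
  # determinism under a fixed seed
  r4 <- within_pair_cluster_test(cand, bg, n_perm = 100, seed = 5)
  expect_identical(r1, r4)
})

test_that("permutation p-values are calibrated under the uniform null", {
  set.seed(91)
  window <- data.frame(lo_bp = 1001L, hi_bp = 5000L)
  hits <- 0L
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    bg <- data.frame(chrom = "chr1", pos = sample.int(1e6, 2000))
    cand <- bg[sample.int(2000, 200), ]
    res <- within_pair_cluster_test(cand, bg, windows = window,
                                    n_perm = 199, seed = s)
    if (res$p_perm <= 0.05) hits <- hits + 1L
  }
  # 99% binomial band around 0.05 (discrete ties make the test conservative)
  expect_lte(hits, qbinom(0.995, n_seeds, 0.05))
})

test_that("between-pair test counts pair-1 loci with a pair-2 neighbor", {
  c1 <- data.frame(chrom = "chr1", pos = c(1000L, 5000L, 9000L))
  c2 <- data.frame(chrom = c("chr1", "chr1", "chr2"), pos = c(1200L, 20000L, 5100L))
  bg2 <- rbind(c2, data.frame(chrom = "chr1", pos = seq(30000L, 80000L, by = 500L)))
  res <- between_pair_cluster_test(c1, c2, bg2,
                                   windows = data.frame(lo_bp = 101L, hi_bp = 500L),
                                   n_perm = 20, seed = 2)
  expect_equal(res$observed, 1L)  # only 1000 has a neighbor (1200, d = 200)

  # empty pair-2 candidates: observed 0, fold change undefined
  res0 <- between_pair_cluster_test(c1, c2[0, ], bg2,
                                    windows = data.frame(lo_bp = 101L, hi_bp = 500L),
                                    n_perm = 20, seed = 2)
  expect_equal(res0$observed, 0L)
  expect_true(is.na(res0$fold_change))
  expect_equal(res0$p_perm, 1)

  # identical positions are distance 0 and excluded by lo_bp >= 1
  resid <- between_pair_cluster_test(c1, c1, rbind(c1, bg2),
                                     windows = data.frame(lo_bp = 1L, hi_bp = 100L),
                                     n_perm = 20, seed = 2)
  expect_equal(resid$observed, 0L)
})

test_that("co-located hotspots across pairs yield small between-pair p-values", {
  centers <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(1e6L, 5e6L, 2e6L))
  mk <- function(seed) generate_twin_dataset(generator_config(
    n_loci = 8000, n_mosaic = 120, mosaic_cell_fraction = 1,
    hotspots = list(n_hotspots = 3, span_bp = 4000, fraction_in_hotspots = 0.8),
    hotspot_centers = centers, seed = seed))
  d1 <- mk(111); d2 <- mk(222)
  res <- between_pair_cluster_test(
    d1$truth[d1$truth$is_mosaic, c("chrom", "pos")],
    d2$truth[d2$truth$is_mosaic, c("chrom", "pos")],
    d2$truth[, c("chrom", "pos")],
    n_perm = 300, seed = 4)
  expect_lte(min(res$p_perm), 0.01)
})
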
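test_that("the generator is reproducible and honors its ground-truth contract", {
  cfg <- generator_config(n_loci = 3000, n_mosaic = 60, mosaic_cell_fraction = 0.4,
                          seed = 13)
  d1 <- generate_twin_dataset(cfg)
  d2 <- generate_twin_dataset(cfg)
  expect_identical(lapply(d1$tracks, as.data.frame), lapply(d2$tracks, as.data.frame))
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$annotations, d2$annotations)

  tr <- d1$truth
  expect_equal(sum(tr$is_mosaic), 60)
  # non-mosaic loci have identical true fractions; mosaic loci differ by f/2
  expect_true(all(tr$f_a[!tr$is_mosaic] == tr$f_b[!tr$is_mosaic]))
  expect_equal(abs(tr$f_a[tr$is_mosaic] - tr$f_b[tr$is_mosaic]),
               rep(0.2, 60))
  # the mutated twin is the one whose fraction moved off the germline value
  germ_f <- unname(c(hom_ref = 0, het = 0.5, hom_alt = 1)[tr$germline[tr$is_mosaic]])
  moved_a <- tr$f_a[tr$is_mosaic] != germ_f
  expect_equal(ifelse(moved_a, "a", "b"), tr$mutated_twin[tr$is_mosaic])
  # loci are unique and inside the include regions
  expect_false(anyDuplicated(paste(tr$chrom, tr$pos)) > 0)
  expect_true(all(positions_in_regions(tr$chrom, tr$pos, d1$include)))
  # counts sum to depth and genotype calls are canonical
  a_hi <- d1$tracks$a_hi
  expect_true(all(a_hi$ref_count + a_hi$alt_count >= 1))
  expect_true(all(a_hi$genotype %in% c("hom_ref", "het", "hom_alt")))
})

test_that("null datasets contain no mosaic loci", {
  d <- generate_null_dataset(generator_config(n_loci = 1000, n_mosaic = 50, seed = 2))
  expect_equal(sum(d$truth$is_mosaic), 0)
  expect_true(all(d$truth$f_a == d$truth$f_b))
})

test_that("hotspots hold their quota of mosaics and infeasible spans error", {
  cfg <- generator_config(
    n_loci = 4000, n_mosaic = 100, mosaic_cell_fraction = 1,
    hotspots = list(n_hotspots = 4, span_bp = 8000, fraction_in_hotspots = 0.5),
    seed = 17)
  d <- generate_twin_dataset(cfg)
  tr <- d$truth
  expect_equal(sum(!is.na(tr$hotspot_id)), 50)
  expect_true(all(tr$is_mosaic[!is.na(tr$hotspot_id)]))
  # members of one hotspot span at most span_bp
  for (h in unique(na.omit(tr$hotspot_id))) {
    member_pos <- tr$pos[!is.na(tr$hotspot_id) & tr$hotspot_id == h]
    member_chrom <- tr$chrom[!is.na(tr$hotspot_id) & tr$hotspot_id == h]
    expect_equal(length(unique(member_chrom)), 1)
    expect_lte(diff(range(member_pos)), 8000)
  }
  expect_error(generate_twin_dataset(generator_config(
    n_loci = 500, n_mosaic = 100, mosaic_cell_fraction = 1,
    hotspots = list(n_hotspots = 1, span_bp = 50, fraction_in_hotspots = 1),
    seed = 18)), "hotspot")
})

test_that("detect recovers strong planted mosaics with high recall and matching excess", {
  recalls <- numeric(10); pvals <- numeric(10)
  for (s in 1:10) {
    d <- generate_twin_dataset(generator_config(
      n_loci = 100000, n_mosaic = 200, mosaic_cell_fraction = 1,
      depth_model = "fixed", seed = 600 + s))
    j <- join_tracks(d$tracks$a_hi, d$tracks$b_hi, d$tracks$a_lo, d$tracks$b_lo)
    cs <- detect(j)
    found <- locus_key(cs$sites$chrom, cs$sites$pos, cs$sites$ref, cs$sites$alt)
    recalls[s] <- mean(d$truth$key[d$truth$is_mosaic] %in% found)
    pvals[s] <- matching_test(cs$n_match, cs$n_total)$p_value
  }
  expect_gte(median(recalls), 0.90)
  expect_lt(median(pvals), 1e-6)
})

test_that("null matching fraction averages 50% across generator seeds", {
  match_tot <- 0L; all_tot <- 0L
  for (s in 1:20) {
    d <- generate_null_dataset(generator_config(n_loci = 30000,
                                                depth_model = "fixed",
                                                seed = 700 + s))
    j <- join_tracks(d$tracks$a_hi, d$tracks$b_hi, d$tracks$a_lo, d$tracks$b_lo)
    cs <- detect(j)
    match_tot <- match_tot + cs$n_match
    all_tot <- all_tot + cs$n_total
  }
  # the clear-call + dual-threshold chain admits only ~1e-4 of null het
  # loci, so the pooled candidate count is small but the symmetry holds
  frac <- match_tot / all_tot
  se <- sqrt(0.25 / all_tot)
  expect_gte(all_tot, 10)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("null threshold exceedance at het loci matches the exact rate", {
  flagged <- 0L; n_het <- 0L
  for (s in 1:4) {
    d <- generate_null_dataset(generator_config(n_loci = 40000,
                                                depth_model = "fixed",
                                                seed = 800 + s))
    j <- join_tracks(d$tracks$a_hi, d$tracks$b_hi, d$tracks$a_lo, d$tracks$b_lo)
    het_keys <- d$truth$key[d$truth$germline == "het"]
    het <- j[locus_key(j$chrom, j$pos, j$ref, j$alt) %in% het_keys, ]
    pass <- abs(het$ard_hi) > 0.25 & abs(het$ard_lo) > 0.25
    flagged <- flagged + sum(pass)
    n_het <- n_het + nrow(het)
  }
  p_hat <- flagged / n_het
  p_exact <- exact_fp_rate(40, 13, 0.25)
  se <- sqrt(p_exact * (1 - p_exact) / n_het)
  expect_lt(abs(p_hat - p_exact), 3 * se)
})

test_that("a category multiplier of 3 ranks that category's FDR lowest", {
  mult <- setNames(rep(1, 14), names(default_category_probs()))
  mult["regulatory"] <- 3
  wins <- 0L
  for (s in 1:10) {
    d <- generate_twin_dataset(generator_config(
      n_loci = 20000, n_mosaic = 200, mosaic_cell_fraction = 1,
      category_multipliers = mult, seed = 900 + s))
    j <- join_tracks(d$tracks$a_hi, d$tracks$b_hi, d$tracks$a_lo, d$tracks$b_lo)
    cs <- detect(j)
    pre <- clear_call_filter(drop_double_homref(j))
    cand <- locus_key(cs$sites$chrom, cs$sites$pos, cs$sites$ref, cs$sites$alt)
    back <- locus_key(pre$chrom, pre$pos, pre$ref, pre$alt)
    enr <- category_enrichment(cand, back, d$annotations)
    if (enr$category[which.min(enr$q_fdr)] == "regulatory") wins <- wins + 1L
  }
  expect_gte(wins, 9)
})

test_that("datasets round-trip through their plain-text files", {
  d <- generate_twin_dataset(generator_config(n_loci = 500, n_mosaic = 10, seed = 23))
  dir <- withr::local_tempdir()
  paths <- write_dataset(d, dir)
  back <- read_counts_from_tsv(paths[["a_hi"]], individual_id = "a",
                               platform = "high_depth")
  expect_equal(as.data.frame(back), as.data.frame(d$tracks$a_hi))
  inc <- read_regions_bed(paths[["include"]])
  expect_true(all(positions_in_regions(d$truth$chrom, d$truth$pos, inc)))
  ann <- read_annotations_tsv(paths[["annotations"]])
  expect_setequal(paste(ann$key, ann$category),
                  paste(d$annotations$key, d$annotations$category))
})
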
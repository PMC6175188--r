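test_that("allelic ratio is the alternative-read fraction", {
  expect_equal(allelic_ratio(40, 0), 0)
  expect_equal(allelic_ratio(20, 20), 0.5)
  expect_equal(allelic_ratio(28, 12), 0.30)
  expect_error(allelic_ratio(0, 0), "zero total depth")
  expect_error(allelic_ratio(-1, 5), "non-negative")
})

test_that("ARD is the signed antisymmetric ratio difference", {
  expect_equal(ard(0.5, 0.5), 0)
  expect_equal(ard(1, 0), 1)
  expect_equal(ard(0.30, 0.62), -0.32)
  set.seed(11)
  a <- runif(200); b <- runif(200)
  expect_equal(ard(a, b), -ard(b, a))
  expect_true(all(abs(ard(a, b)) <= 1))
  expect_error(ard(1.2, 0.5), "\\[0, 1\\]")
})

test_that("clear-call filter requires one twin near the same canonical on both platforms", {
  p <- filter_params()
  # twin A clear at 0.5 on both platforms -> kept
  j1 <- joint_from_ratios(0.49, 0.30, 0.51, 0.28)
  expect_equal(nrow(clear_call_filter(j1, p)), 1)
  # neither twin near any canonical -> dropped
  j2 <- joint_from_ratios(0.20, 0.30, 0.22, 0.35)
  expect_equal(nrow(clear_call_filter(j2, p)), 0)
  # twin A near different canonicals across platforms (0.04 vs 0.52) does not
  # count; twin B not clear either -> dropped
  j3 <- joint_from_ratios(0.04, 0.30, 0.52, 0.35)
  expect_equal(nrow(clear_call_filter(j3, p)), 0)
  # ... but kept when twin B is clear
  j4 <- joint_from_ratios(0.04, 0.52, 0.52, 0.49)
  expect_equal(nrow(clear_call_filter(j4, p)), 1)
  # just outside tolerance on one platform -> not clear
  j5 <- joint_from_ratios(0.44, 0.30, 0.51, 0.30)
  expect_equal(nrow(clear_call_filter(j5, p)), 0)
})

test_that("threshold filter is strict on both platforms' |ARD|", {
  p <- filter_params(ard_threshold = 0.25)
  j <- joint_from_ratios(
    r_a_hi = c(0.80, 0.80, 0.80), r_b_hi = c(0.50, 0.50, 0.50),
    r_a_lo = c(0.76, 0.75, 0.24), r_b_lo = c(0.50, 0.50, 0.50))
  # ard_hi = 0.30 throughout; ard_lo = 0.26, 0.25, -0.26
  kept <- threshold_filter(j, p)
  expect_equal(sort(kept$ard_lo), c(-0.26, 0.26))
})

test_that("matching classification follows the ARD sign product", {
  j <- joint_from_ratios(
    r_a_hi = c(0.80, 0.80, 0.50), r_b_hi = c(0.50, 0.50, 0.50),
    r_a_lo = c(0.76, 0.24, 0.76), r_b_lo = c(0.50, 0.50, 0.50))
  m <- classify_matching(j)
  expect_equal(m$matching, c("matching", "nonmatching", "undefined"))
})

test_that("double hom-ref loci are dropped using genotypes, else alt counts", {
  zero <- list(ref = 30, alt = 0)
  some <- list(ref = 27, alt = 3)
  het <- list(ref = 15, alt = 15)
  # both twins hom_ref by genotype, no alt reads -> dropped
  j1 <- mk_joint(100L, zero, zero, zero, zero,
                 gt = list(a_hi = "hom_ref", a_lo = "hom_ref",
                           b_hi = "hom_ref", b_lo = "hom_ref"))
  expect_equal(nrow(drop_double_homref(j1)), 0)
  # twin A het on the high-depth platform -> kept
  j2 <- mk_joint(100L, het, zero, zero, zero,
                 gt = list(a_hi = "het", a_lo = "hom_ref",
                           b_hi = "hom_ref", b_lo = "hom_ref"))
  expect_equal(nrow(drop_double_homref(j2)), 1)
  # genotypes missing: twin B has 3 alt reads on the low platform -> kept
  j3 <- mk_joint(100L, zero, zero, zero, some)
  expect_equal(nrow(drop_double_homref(j3)), 1)
  # genotypes missing and no alt evidence anywhere -> dropped
  j4 <- mk_joint(100L, zero, zero, zero, zero)
  expect_equal(nrow(drop_double_homref(j4)), 0)
})

test_that("detect applies the chain in order with non-increasing stage counts", {
  d <- generate_twin_dataset(generator_config(n_loci = 4000, n_mosaic = 40,
                                              mosaic_cell_fraction = 1, seed = 21))
  j <- join_tracks(d$tracks$a_hi, d$tracks$b_hi, d$tracks$a_lo, d$tracks$b_lo)
  cs <- detect(j, include = d$include, exclude = d$exclude)
  expect_true(all(diff(cs$stage_counts) <= 0))
  expect_equal(cs$n_match + cs$n_nonmatch, cs$n_total)
  expect_equal(cs$n_total, nrow(cs$sites))

  # determinism: identical inputs give identical candidate sets
  cs2 <- detect(j, include = d$include, exclude = d$exclude)
  expect_identical(cs$sites, cs2$sites)
  expect_identical(cs$stage_counts, cs2$stage_counts)
})

test_that("every candidate satisfies all filter predicates on independent re-check", {
  d <- generate_twin_dataset(generator_config(n_loci = 6000, n_mosaic = 60,
                                              mosaic_cell_fraction = 0.8, seed = 31))
  j <- join_tracks(d$tracks$a_hi, d$tracks$b_hi, d$tracks$a_lo, d$tracks$b_lo)
  p <- filter_params()
  cs <- detect(j, p, include = d$include, exclude = d$exclude)
  s <- cs$sites
  for (i in seq_len(nrow(s))) {
    expect_true(positions_in_regions(s$chrom[i], s$pos[i], d$include))
    clear_a <- any(vapply(p$canonical_ratios, function(cc)
      abs(s$r_a_hi[i] - cc) < 0.05 && abs(s$r_a_lo[i] - cc) < 0.05, logical(1)))
    clear_b <- any(vapply(p$canonical_ratios, function(cc)
      abs(s$r_b_hi[i] - cc) < 0.05 && abs(s$r_b_lo[i] - cc) < 0.05, logical(1)))
    expect_true(clear_a || clear_b)
    expect_true(abs(s$ard_hi[i]) > 0.25 && abs(s$ard_lo[i]) > 0.25)
    expect_false((s$gt_a_hi[i] == "hom_ref" && s$gt_a_lo[i] == "hom_ref") &&
                 (s$gt_b_hi[i] == "hom_ref" && s$gt_b_lo[i] == "hom_ref"))
  }
})

test_that("matching fraction on null data is consistent with 50%", {
  # few null loci survive the full chain, so pool several generator seeds
  n_match <- 0L; n_total <- 0L
  for (s in 1:4) {
    d <- generate_null_dataset(generator_config(n_loci = 40000,
                                                depth_model = "fixed",
                                                seed = 40 + s))
    j <- join_tracks(d$tracks$a_hi, d$tracks$b_hi, d$tracks$a_lo, d$tracks$b_lo)
    cs <- detect(j)
    n_match <- n_match + cs$n_match
    n_total <- n_total + cs$n_total
  }
  expect_gt(n_total, 0)
  mt <- matching_test(n_match, n_total)
  expect_true(mt$ci_low <= 0.5 && 0.5 <= mt$ci_high)
})
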
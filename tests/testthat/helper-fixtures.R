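# compact builders for tracks and joint sites used across the suite

mk_track <- function(pos, ref_count, alt_count, chrom = "chr1",
                     ref = "A", alt = "G", genotype = "missing",
                     id = NA_character_, platform = NA_character_) {
  sample_track(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                          ref_count = ref_count, alt_count = alt_count,
                          genotype = genotype, stringsAsFactors = FALSE),
               individual_id = id, platform = platform)
}

# joint sites at shared loci from four (ref, alt) count pairs; each of
# a_hi, b_hi, a_lo, b_lo is a list(ref = vector, alt = vector)
mk_joint <- function(pos, a_hi, b_hi, a_lo, b_lo, chrom = "chr1",
                     gt = list()) {
  g <- function(nm) if (!is.null(gt[[nm]])) gt[[nm]] else "missing"
  join_tracks(
    mk_track(pos, a_hi$ref, a_hi$alt, chrom = chrom, genotype = g("a_hi")),
    mk_track(pos, b_hi$ref, b_hi$alt, chrom = chrom, genotype = g("b_hi")),
    mk_track(pos, a_lo$ref, a_lo$alt, chrom = chrom, genotype = g("a_lo")),
    mk_track(pos, b_lo$ref, b_lo$alt, chrom = chrom, genotype = g("b_lo")))
}

# joint sites with prescribed ratios at depth `depth` (counts rounded, so use
# ratios representable at that depth)
joint_from_ratios <- function(r_a_hi, r_b_hi, r_a_lo, r_b_lo,
                              depth_hi = 100, depth_lo = 100,
                              pos = seq_along(r_a_hi) * 1000L, gt = list()) {
  cnt <- function(r, d) list(ref = round(d * (1 - r)), alt = round(d * r))
  mk_joint(pos,
           a_hi = cnt(r_a_hi, depth_hi), b_hi = cnt(r_b_hi, depth_hi),
           a_lo = cnt(r_a_lo, depth_lo), b_lo = cnt(r_b_lo, depth_lo),
           gt = gt)
}

write_test_vcf <- function(path, extra_records = character()) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/1:28,12\t0/0:40,0",
    "chr1\t200\t.\tC\tT\t50\tPASS\t.\tGT:AD\t1/1:0,35\t0/1:20,20",
    "chr1\t300\t.\tG\tA,T\t50\tPASS\t.\tGT:AD\t1/2:10,5,5\t0/1:12,8,0",
    "chr1\t400\t.\tA\tAG\t50\tPASS\t.\tGT:AD\t0/1:15,5\t0/1:18,2",
    "chr1\t500\t.\tT\tC\t50\tPASS\t.\tGT:AD\t./.:.\t0/1:9,11",
    extra_records)
  writeLines(lines, path)
  path
}

# exact two-sided binomial p at p0 = 0.5 by direct tail summation
binom_two_sided_oracle <- function(k, n) {
  lo <- sum(dbinom(0:k, n, 0.5))
  hi <- sum(dbinom(k:n, n, 0.5))
  min(1, 2 * min(lo, hi))
}

# hypergeometric upper-tail oracle for a 2x2 enrichment table
hyper_tail_oracle <- function(k_cand, n_cand, k_rest, n_rest) {
  white <- k_cand + k_rest
  sum(dhyper(k_cand:min(white, n_cand), white,
             n_cand + n_rest - white, n_cand))
}

# all-pairs double-loop oracle for window pair counts
pair_count_oracle <- function(chrom, pos, lo_bp, hi_bp) {
  df <- unique(data.frame(chrom = chrom, pos = pos))
  cnt <- 0L
  n <- nrow(df)
  if (n < 2) return(0L)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (df$chrom[i] != df$chrom[j]) next
    d <- abs(df$pos[i] - df$pos[j])
    if (d >= lo_bp && d <= hi_bp) cnt <- cnt + 1L
  }
  cnt
}
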
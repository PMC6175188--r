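#' Default genomic distance windows for hotspot testing
#'
#' Inclusive base-pair windows partitioning distances from 101 bp to
#' 10,000 bp: 101-500, 501-1000, 1001-5000, 5001-10000.
#'
#' @return Data frame with columns `lo_bp`, `hi_bp`.
#' @export
distance_windows <- function() {
  data.frame(lo_bp = c(101L, 501L, 1001L, 5001L),
             hi_bp = c(500L, 1000L, 5000L, 10000L))
}

check_window <- function(lo_bp, hi_bp) {
  if (lo_bp < 1 || lo_bp > hi_bp)
    stop("distance window must satisfy 1 <= lo_bp <= hi_bp")
}

# loci as data.frame(chrom, pos); deduplicated per chromosome, split + sorted
split_positions <- function(loci) {
  stopifnot(all(c("chrom", "pos") %in% names(loci)))
  lapply(split(as.integer(loci$pos), as.character(loci$chrom)),
         function(p) sort(unique(p)))
}

count_pairs_sorted <- function(p, lo_bp, hi_bp) {
  # p sorted unique; unordered pairs (i < j) with pos_j - pos_i in [lo, hi]
  if (length(p) < 2) return(0L)
  hi_idx <- findInterval(p + hi_bp, p)
  lo_idx <- findInterval(p + lo_bp - 1L, p)
  as.integer(sum(hi_idx - lo_idx))
}

#' Count locus pairs within a genomic distance window
#'
#' Unordered same-chromosome pairs whose distance `|p1 - p2|` lies in the
#' inclusive window `[lo_bp, hi_bp]`. Identical positions (distance 0) are
#' never counted; positions are deduplicated per chromosome.
#'
#' @param chrom,pos parallel vectors of chromosome names and 1-based
#'   positions.
#' @param lo_bp,hi_bp inclusive window bounds, `1 <= lo_bp <= hi_bp`.
#' @return Integer pair count.
#' @export
pairwise_window_counts <- function(chrom, pos, lo_bp, hi_bp) {
  check_window(lo_bp, hi_bp)
  by_chrom <- split_positions(data.frame(chrom = chrom, pos = pos))
  sum(vapply(by_chrom, count_pairs_sorted, integer(1),
             lo_bp = lo_bp, hi_bp = hi_bp))
}

perm_test_table <- function(observed, perm_counts, windows, n_perm) {
  perm_mean <- colMeans(perm_counts)
  p_perm <- vapply(seq_along(observed), function(w)
    (1 + sum(perm_counts[, w] >= observed[w])) / (n_perm + 1), numeric(1))
  data.frame(lo_bp = windows$lo_bp, hi_bp = windows$hi_bp,
             observed = observed, perm_mean = perm_mean,
             fold_change = ifelse(perm_mean > 0, observed / perm_mean, NA_real_),
             p_perm = p_perm, n_perm = n_perm)
}

#' Permutation test for clustering of candidate loci within a twin pair
#'
#' Tests whether candidate loci sit closer together than expected for a
#' random draw from the background (reference) locus set. Each permutation
#' samples `nrow(candidates)` loci without replacement from the background
#' and counts same-chromosome pairs per distance window; the one-sided
#' p-value is the add-one estimator
#' `(1 + #\{permuted count >= observed\}) / (n_perm + 1)`.
#'
#' @param candidates,background data frames with columns `chrom`, `pos`;
#'   candidates must be a subset of the background.
#' @param windows data frame of inclusive windows (`lo_bp`, `hi_bp`);
#'   default [distance_windows()].
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return Data frame with one row per window: `lo_bp`, `hi_bp`, `observed`,
#'   `perm_mean`, `fold_change` (`NA` when the permuted mean is 0), `p_perm`,
#'   `n_perm`.
#' @export
within_pair_cluster_test <- function(candidates, background,
                                     windows = distance_windows(),
                                     n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  if (nrow(background) < nrow(candidates))
    stop("background has fewer loci than the candidate set")
  key_c <- paste(candidates$chrom, candidates$pos)
  key_b <- paste(background$chrom, background$pos)
  if (!all(key_c %in% key_b))
    stop("candidates must be a subset of the background locus set")
  for (w in seq_len(nrow(windows))) check_window(windows$lo_bp[w], windows$hi_bp[w])

  observed <- vapply(seq_len(nrow(windows)), function(w)
    pairwise_window_counts(candidates$chrom, candidates$pos,
                           windows$lo_bp[w], windows$hi_bp[w]), integer(1))
  set.seed(seed)
  n_cand <- nrow(candidates)
  perm_counts <- matrix(0L, n_perm, nrow(windows))
  for (i in seq_len(n_perm)) {
    idx <- sample.int(nrow(background), n_cand)
    perm <- background[idx, c("chrom", "pos")]
    perm_counts[i, ] <- vapply(seq_len(nrow(windows)), function(w)
      pairwise_window_counts(perm$chrom, perm$pos,
                             windows$lo_bp[w], windows$hi_bp[w]), integer(1))
  }
  perm_test_table(observed, perm_counts, windows, n_perm)
}

count_with_neighbor <- function(loci1, by_chrom2, lo_bp, hi_bp) {
  total <- 0L
  by_chrom1 <- split_positions(loci1)
  for (chr in names(by_chrom1)) {
    p2 <- by_chrom2[[chr]]
    if (is.null(p2)) next
    p1 <- by_chrom1[[chr]]
    right <- findInterval(p1 + hi_bp, p2) - findInterval(p1 + lo_bp - 1L, p2)
    left <- findInterval(p1 - lo_bp, p2) - findInterval(p1 - hi_bp - 1L, p2)
    total <- total + sum(right + left > 0)
  }
  as.integer(total)
}

#' Permutation test for co-location of candidate loci between twin pairs
#'
#' The statistic is the number of pair-1 candidate loci having at least one
#' pair-2 candidate at a same-chromosome distance inside the window. The
#' null distribution resamples the pair-2 candidates from the pair-2
#' background (and optionally pair 1 from its own background as well).
#'
#' @param candidates_1,candidates_2 data frames with columns `chrom`, `pos`.
#' @param background_2 background locus set for pair 2 (superset of
#'   `candidates_2`).
#' @param background_1 optional background for pair 1, used when
#'   `resample = "both"`.
#' @param resample `"second"` (default) resamples only pair 2; `"both"`
#'   resamples both candidate sets.
#' @inheritParams within_pair_cluster_test
#' @return As [within_pair_cluster_test()].
#' @export
between_pair_cluster_test <- function(candidates_1, candidates_2, background_2,
                                      windows = distance_windows(),
                                      n_perm = 1000, seed = 1,
                                      resample = c("second", "both"),
                                      background_1 = NULL) {
  resample <- match.arg(resample)
  stopifnot(n_perm >= 1)
  if (nrow(background_2) < nrow(candidates_2))
    stop("background_2 has fewer loci than candidates_2")
  if (!all(paste(candidates_2$chrom, candidates_2$pos) %in%
           paste(background_2$chrom, background_2$pos)))
    stop("candidates_2 must be a subset of background_2")
  if (resample == "both") {
    if (is.null(background_1)) stop("resample = 'both' needs background_1")
    if (nrow(background_1) < nrow(candidates_1))
      stop("background_1 has fewer loci than candidates_1")
  }
  for (w in seq_len(nrow(windows))) check_window(windows$lo_bp[w], windows$hi_bp[w])

  observed <- vapply(seq_len(nrow(windows)), function(w)
    count_with_neighbor(candidates_1, split_positions(candidates_2),
                        windows$lo_bp[w], windows$hi_bp[w]), integer(1))
  set.seed(seed)
  perm_counts <- matrix(0L, n_perm, nrow(windows))
  for (i in seq_len(n_perm)) {
    c2 <- background_2[sample.int(nrow(background_2), nrow(candidates_2)),
                       c("chrom", "pos")]
    c1 <- if (resample == "both")
      background_1[sample.int(nrow(background_1), nrow(candidates_1)),
                   c("chrom", "pos")]
    else candidates_1
    by2 <- split_positions(c2)
    perm_counts[i, ] <- vapply(seq_len(nrow(windows)), function(w)
      count_with_neighbor(c1, by2, windows$lo_bp[w], windows$hi_bp[w]),
      integer(1))
  }
  perm_test_table(observed, perm_counts, windows, n_perm)
}

#' Write a cluster-test table as TSV
#'
#' @param result data frame from [within_pair_cluster_test()] or
#'   [between_pair_cluster_test()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(pkg_header(), con)
  utils::write.table(result, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
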
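#' Allelic ratio of a locus
#'
#' The fraction of alternative reads among all reads at a locus:
#' `alt / (ref + alt)`. A pure-reference locus scores 0, a balanced
#' heterozygote 0.5, a pure-alternative locus 1; mosaic loci fall in
#' between.
#'
#' @param ref_count,alt_count non-negative read counts (vectorised).
#' @return Numeric vector of ratios in `[0, 1]`.
#' @export
allelic_ratio <- function(ref_count, alt_count) {
  if (any(ref_count < 0 | alt_count < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  total <- ref_count + alt_count
  if (any(total == 0, na.rm = TRUE))
    stop("allelic ratio undefined at zero total depth; filter such loci first")
  alt_count / total
}

#' Allelic-ratio difference between co-twins
#'
#' Signed difference `r_a - r_b` with a fixed twin ordering; a value in
#' `[-1, 1]` where 0 means no between-twin difference.
#'
#' @param r_a,r_b allelic ratios in `[0, 1]` (vectorised).
#' @return Numeric vector in `[-1, 1]`.
#' @export
ard <- function(r_a, r_b) {
  if (any(r_a < 0 | r_a > 1 | r_b < 0 | r_b > 1, na.rm = TRUE))
    stop("allelic ratios must lie in [0, 1]")
  r_a - r_b
}

#' Filter parameters for the candidate chain
#'
#' @param ard_threshold minimum absolute allelic-ratio difference required on
#'   *both* platforms (strict `>`); default 0.25.
#' @param clear_call_tolerance a twin is a "clear call" when its ratio is
#'   within this distance (strict `<`) of the same canonical genotype value
#'   on both platforms; default 0.05.
#' @param canonical_ratios canonical genotype ratios; default `c(0, 0.5, 1)`.
#' @return A `filter_params` list.
#' @export
filter_params <- function(ard_threshold = 0.25, clear_call_tolerance = 0.05,
                          canonical_ratios = c(0, 0.5, 1)) {
  stopifnot(ard_threshold >= 0, ard_threshold <= 1,
            clear_call_tolerance >= 0, clear_call_tolerance < 0.25)
  structure(list(ard_threshold = ard_threshold,
                 clear_call_tolerance = clear_call_tolerance,
                 canonical_ratios = canonical_ratios),
            class = "filter_params")
}

#' Restrict joint sites to inclusion regions and away from exclusion regions
#'
#' @param sites a `joint_sites` data frame from [join_tracks()].
#' @param include,exclude `GRanges` region sets (or `NULL` to skip the
#'   respective restriction), e.g. GIAB-style high-confidence regions and
#'   RepeatMasker-style repeats.
#' @return The filtered `joint_sites`.
#' @export
filter_regions <- function(sites, include = NULL, exclude = NULL) {
  keep <- rep(TRUE, nrow(sites))
  if (!is.null(include))
    keep <- keep & positions_in_regions(sites$chrom, sites$pos, include)
  if (!is.null(exclude))
    keep <- keep & !positions_in_regions(sites$chrom, sites$pos, exclude)
  sites[keep, , drop = FALSE]
}

# per-twin hom-ref evidence: a track with a genotype call contributes
# genotype == hom_ref; a track without one contributes alt_count == 0
twin_is_homref <- function(sites, twin) {
  gt_hi <- sites[[paste0("gt_", twin, "_hi")]]
  gt_lo <- sites[[paste0("gt_", twin, "_lo")]]
  alt_hi <- sites[[paste0("alt_", twin, "_hi")]]
  alt_lo <- sites[[paste0("alt_", twin, "_lo")]]
  hr_hi <- ifelse(gt_hi != "missing", gt_hi == "hom_ref", alt_hi == 0)
  hr_lo <- ifelse(gt_lo != "missing", gt_lo == "hom_ref", alt_lo == 0)
  hr_hi & hr_lo
}

#' Drop loci where both co-twins are homozygous reference
#'
#' Such loci carry no detectable between-twin difference by definition. A
#' twin counts as homozygous reference when every one of its tracks says so:
#' by genotype call where one is present, by `alt_count == 0` otherwise.
#'
#' @inheritParams filter_regions
#' @return The filtered `joint_sites`.
#' @export
drop_double_homref <- function(sites) {
  drop <- twin_is_homref(sites, "a") & twin_is_homref(sites, "b")
  sites[!drop, , drop = FALSE]
}

clear_twin <- function(sites, twin, params) {
  r_hi <- sites[[paste0("r_", twin, "_hi")]]
  r_lo <- sites[[paste0("r_", twin, "_lo")]]
  clear <- rep(FALSE, nrow(sites))
  for (canon in params$canonical_ratios)
    clear <- clear | (abs(r_hi - canon) < params$clear_call_tolerance &
                      abs(r_lo - canon) < params$clear_call_tolerance)
  clear
}

#' Keep loci where at least one co-twin is clearly not mosaic
#'
#' A co-twin is "clear" when its allelic ratio lies within
#' `clear_call_tolerance` of the *same* canonical value (0, 0.5 or 1) on
#' both platforms. Conditioning a candidate mosaic on the other twin being
#' clear anchors the between-twin difference to a real genotype state.
#'
#' @inheritParams filter_regions
#' @param params a [filter_params()].
#' @return The filtered `joint_sites`.
#' @export
clear_call_filter <- function(sites, params = filter_params()) {
  keep <- clear_twin(sites, "a", params) | clear_twin(sites, "b", params)
  sites[keep, , drop = FALSE]
}

#' Keep loci exceeding the ARD threshold on both platforms
#'
#' Strict inequality: `|ard_hi| > t` and `|ard_lo| > t`.
#'
#' @inheritParams clear_call_filter
#' @return The filtered `joint_sites`.
#' @export
threshold_filter <- function(sites, params = filter_params()) {
  t <- params$ard_threshold
  keep <- abs(sites$ard_hi) > t & abs(sites$ard_lo) > t
  sites[keep, , drop = FALSE]
}

#' Classify candidate loci by cross-platform sign agreement
#'
#' A locus is *matching* when the allelic-ratio difference has the same sign
#' on both platforms (`ard_hi * ard_lo > 0`), *nonmatching* on opposite
#' signs, and *undefined* when either ARD is exactly zero (excluded from
#' both tallies).
#'
#' @inheritParams filter_regions
#' @return `sites` with an added `matching` column
#'   (`"matching"`/`"nonmatching"`/`"undefined"`).
#' @export
classify_matching <- function(sites) {
  prod <- sites$ard_hi * sites$ard_lo
  sites$matching <- ifelse(prod > 0, "matching",
                    ifelse(prod < 0, "nonmatching", "undefined"))
  sites
}

#' Run the full candidate-detection filter chain
#'
#' Applies, in order: region restriction, removal of double
#' homozygous-reference loci, the clear-call filter, the ARD threshold on
#' both platforms, and sign-matching classification, recording the number of
#' loci remaining after each stage.
#'
#' @inheritParams clear_call_filter
#' @param include,exclude optional `GRanges` region sets.
#' @return A `candidate_set`: list with `sites` (classified `joint_sites`),
#'   `stage_counts` (named, non-increasing), `n_total`, `n_match`,
#'   `n_nonmatch` (`n_match + n_nonmatch == n_total`; zero-ARD loci are
#'   excluded from the tally) and `params`.
#' @export
detect <- function(sites, params = filter_params(), include = NULL, exclude = NULL) {
  stage_counts <- c(joined = nrow(sites))
  sites <- filter_regions(sites, include, exclude)
  stage_counts["regions"] <- nrow(sites)
  sites <- drop_double_homref(sites)
  stage_counts["not_double_homref"] <- nrow(sites)
  sites <- clear_call_filter(sites, params)
  stage_counts["clear_call"] <- nrow(sites)
  sites <- threshold_filter(sites, params)
  stage_counts["ard_threshold"] <- nrow(sites)
  sites <- classify_matching(sites)
  n_match <- sum(sites$matching == "matching")
  n_nonmatch <- sum(sites$matching == "nonmatching")
  structure(list(sites = sites, stage_counts = stage_counts,
                 n_total = n_match + n_nonmatch,
                 n_match = n_match, n_nonmatch = n_nonmatch,
                 params = params),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate set of putative postzygotic mutations\n")
  cat("  stage counts: ", paste(names(x$stage_counts), x$stage_counts,
                                sep = "=", collapse = ", "), "\n")
  cat(sprintf("  matching %d / %d (%.2f%%), nonmatching %d\n",
              x$n_match, x$n_total,
              if (x$n_total > 0) 100 * x$n_match / x$n_total else NA_real_,
              x$n_nonmatch))
  invisible(x)
}

#' Write a candidate set as TSV (sites) and JSON (stage counts)
#'
#' @param cs a `candidate_set` from [detect()].
#' @param tsv_path,json_path output paths; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_candidate_set <- function(cs, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    cols <- c("chrom", "pos", "ref", "alt", "r_a_hi", "r_b_hi", "r_a_lo",
              "r_b_lo", "ard_hi", "ard_lo", "matching")
    con <- file(tsv_path, "w")
    writeLines(pkg_header(c(ard_threshold = cs$params$ard_threshold,
                            clear_call_tolerance = cs$params$clear_call_tolerance)), con)
    utils::write.table(as.data.frame(cs$sites)[, cols], con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(stage_counts = as.list(cs$stage_counts),
                              n_total = cs$n_total, n_match = cs$n_match,
                              n_nonmatch = cs$n_nonmatch),
                         json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(c(tsv = tsv_path, json = json_path))
}
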
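#' Exact binomial test of cross-platform sign matching
#'
#' Under pure sampling noise the sign of the between-twin allelic-ratio
#' difference agrees across two independent platforms half the time, so the
#' matching fraction of a candidate set is tested against 0.5 with the exact
#' two-sided binomial test (for p0 = 0.5 this equals twice the smaller exact
#' tail). The confidence interval is the exact Clopper-Pearson interval.
#'
#' @param n_match number of matching loci.
#' @param n_total total classified loci (matching + nonmatching).
#' @param conf_level confidence level for the interval; default 0.95.
#' @return A `match_test` list: `n_match`, `n_total`, `fraction`, `p_value`,
#'   `ci_low`, `ci_high`.
#' @export
matching_test <- function(n_match, n_total, conf_level = 0.95) {
  if (length(n_match) != 1 || length(n_total) != 1 || n_total < 1)
    stop("matching_test needs scalar counts with n_total >= 1")
  if (n_match < 0 || n_match > n_total)
    stop("n_match must lie in [0, n_total]")
  bt <- stats::binom.test(n_match, n_total, p = 0.5,
                          alternative = "two.sided", conf.level = conf_level)
  structure(list(n_match = as.integer(n_match), n_total = as.integer(n_total),
                 fraction = n_match / n_total, p_value = bt$p.value,
                 ci_low = bt$conf.int[1], ci_high = bt$conf.int[2]),
            class = "match_test")
}

#' @export
print.match_test <- function(x, ...) {
  cat(sprintf("matching %d/%d = %.2f%%  (95%% CI %.4f-%.4f), exact binomial p = %.4g\n",
              x$n_match, x$n_total, 100 * x$fraction, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' True-positive-rate estimate of a candidate set
#'
#' Matching fraction minus nonmatching fraction,
#' `(n_match - (n_total - n_match)) / n_total = 2 n_match/n_total - 1`:
#' false positives split evenly between signs, so the excess of matching
#' over nonmatching loci estimates the true-positive content. May be
#' negative by chance.
#'
#' @inheritParams matching_test
#' @return A number in `[-1, 1]`.
#' @export
true_positive_estimate <- function(n_match, n_total) {
  if (any(n_total < 1)) stop("n_total must be >= 1")
  if (any(n_match < 0 | n_match > n_total)) stop("n_match must lie in [0, n_total]")
  2 * n_match / n_total - 1
}

#' Sweep the ARD threshold and re-test sign matching
#'
#' Re-runs the threshold filter, matching classification and exact binomial
#' test at each threshold on sites that already passed the upstream filters
#' (regions, double hom-ref, clear call).
#'
#' @param sites `joint_sites` (typically after [clear_call_filter()]).
#' @param thresholds numeric vector of ARD thresholds in `[0, 1]`.
#' @param params a [filter_params()]; its `ard_threshold` is replaced by each
#'   sweep value in turn.
#' @return Data frame with one row per threshold: `threshold`, `n_total`,
#'   `n_match`, `fraction`, `p_value`, `ci_low`, `ci_high` (`NA` statistics
#'   where no loci remain). `n_total` is non-increasing in the threshold.
#' @export
threshold_sweep <- function(sites, thresholds = seq(0, 0.5, by = 0.05),
                            params = filter_params()) {
  stopifnot(all(thresholds >= 0 & thresholds <= 1))
  rows <- lapply(thresholds, function(t) {
    p <- params; p$ard_threshold <- t
    kept <- classify_matching(threshold_filter(sites, p))
    n_match <- sum(kept$matching == "matching")
    n_total <- n_match + sum(kept$matching == "nonmatching")
    if (n_total == 0)
      return(data.frame(threshold = t, n_total = 0L, n_match = 0L,
                        fraction = NA_real_, p_value = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    mt <- matching_test(n_match, n_total)
    data.frame(threshold = t, n_total = n_total, n_match = n_match,
               fraction = mt$fraction, p_value = mt$p_value,
               ci_low = mt$ci_low, ci_high = mt$ci_high)
  })
  do.call(rbind, rows)
}

#' Write a threshold sweep table as TSV
#'
#' @param sweep a data frame from [threshold_sweep()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep_tsv <- function(sweep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(pkg_header(), con)
  utils::write.table(sweep, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bias of a Falconer-style twin heritability estimate under mosaicism
#'
#' Classical twin models assume additive genetic correlations r_MZ = 1 and
#' r_DZ = 0.5. Postzygotic mosaicism erodes both. If the true correlations
#' are `rmz_true` and `rdz_true` while the model still assumes 1 and 0.5,
#' the Falconer estimator `2 (r_MZ - r_DZ) a2` recovers
#' `2 * a2_true * (rmz_true - rdz_true)` instead of `a2_true`.
#'
#' @param a2_true true additive genetic variance proportion, in `[0, 1]`.
#' @param rmz_true,rdz_true true additive genetic correlations for MZ and DZ
#'   twins, in `[0, 1]` with `rmz_true >= rdz_true`.
#' @return The biased additive-variance estimate.
#' @examples
#' heritability_bias(0.35, 0.99, 0.495)  # 0.3465: a 1% erosion, ~1% bias
#' @export
heritability_bias <- function(a2_true, rmz_true = 0.99, rdz_true = 0.495) {
  stopifnot(a2_true >= 0, a2_true <= 1,
            rmz_true >= 0, rmz_true <= 1, rdz_true >= 0, rdz_true <= 1,
            rmz_true >= rdz_true)
  2 * a2_true * (rmz_true - rdz_true)
}
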
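#' Configuration of the binomial sampling null
#'
#' The null model of the false-positive calibration: both co-twins are true
#' heterozygotes at every locus, so on each platform the alternative read
#' count is Binomial(depth, 0.5) and any between-twin allelic-ratio
#' difference is pure sampling noise.
#'
#' @param depth_hi,depth_lo per-locus read depths of the two platforms
#'   (defaults 40 and 13).
#' @param threshold ARD threshold applied on both platforms (strict `>`);
#'   default 0.25.
#' @param n_loci heterozygous loci per simulation replicate; default 893581,
#'   the average analyzed heterozygous-locus count per twin pair.
#' @param n_sims number of replicates; default 1000.
#' @param seed RNG seed.
#' @param require_sign_match if `TRUE`, a locus is only flagged when the two
#'   platforms' differences also share a sign (sensitivity analysis; default
#'   `FALSE`, flag on magnitudes alone).
#' @param depth_model `"fixed"` (exact depths, the reference null) or
#'   `"poisson"` (per-locus depths Poisson around the means, truncated at 1).
#' @return A `calibration_config` list.
#' @export
calibration_config <- function(depth_hi = 40, depth_lo = 13, threshold = 0.25,
                               n_loci = 893581, n_sims = 1000, seed = 1,
                               require_sign_match = FALSE,
                               depth_model = c("fixed", "poisson")) {
  depth_model <- match.arg(depth_model)
  stopifnot(depth_hi >= 1, depth_lo >= 1, threshold >= 0, threshold <= 1,
            n_loci >= 1, n_sims >= 1)
  structure(list(depth_hi = as.integer(depth_hi), depth_lo = as.integer(depth_lo),
                 threshold = threshold, n_loci = as.integer(n_loci),
                 n_sims = as.integer(n_sims), seed = as.integer(seed),
                 require_sign_match = require_sign_match,
                 depth_model = depth_model),
            class = "calibration_config")
}

draw_depths <- function(n, mean_depth, model) {
  if (model == "fixed") return(rep.int(as.integer(mean_depth), n))
  d <- stats::rpois(n, mean_depth)
  d[d == 0L] <- 1L
  d
}

#' Monte Carlo false-positive rate of the ARD threshold under the null
#'
#' Per locus, draws independent alternative-read counts
#' `kA_hi, kB_hi ~ Binomial(depth_hi, 0.5)` and
#' `kA_lo, kB_lo ~ Binomial(depth_lo, 0.5)` and flags the locus when the
#' absolute allelic-ratio difference exceeds the threshold on *both*
#' platforms. Returns the flagged fraction averaged over replicates,
#' together with the exact enumeration rate for comparison.
#'
#' @param config a [calibration_config()].
#' @return A `calibration_result` list: `fp_rate` (mean flagged fraction),
#'   `per_sim` (per-replicate fractions), `mc_se` (standard error across
#'   replicates, or the binomial SE when `n_sims == 1`), `exact_rate`
#'   (from [exact_fp_rate()]; `NA` under the Poisson depth model) and
#'   `config`.
#' @export
simulate_fp_rate <- function(config = calibration_config()) {
  set.seed(config$seed)
  n <- config$n_loci
  per_sim <- vapply(seq_len(config$n_sims), function(i) {
    d_hi_a <- draw_depths(n, config$depth_hi, config$depth_model)
    d_hi_b <- draw_depths(n, config$depth_hi, config$depth_model)
    d_lo_a <- draw_depths(n, config$depth_lo, config$depth_model)
    d_lo_b <- draw_depths(n, config$depth_lo, config$depth_model)
    diff_hi <- stats::rbinom(n, d_hi_a, 0.5) / d_hi_a -
               stats::rbinom(n, d_hi_b, 0.5) / d_hi_b
    diff_lo <- stats::rbinom(n, d_lo_a, 0.5) / d_lo_a -
               stats::rbinom(n, d_lo_b, 0.5) / d_lo_b
    flag <- abs(diff_hi) > config$threshold & abs(diff_lo) > config$threshold
    if (config$require_sign_match) flag <- flag & (diff_hi * diff_lo > 0)
    mean(flag)
  }, numeric(1))
  fp <- mean(per_sim)
  mc_se <- if (config$n_sims > 1) stats::sd(per_sim) / sqrt(config$n_sims)
           else sqrt(fp * (1 - fp) / n)
  exact <- if (config$depth_model == "fixed")
    exact_fp_rate(config$depth_hi, config$depth_lo, config$threshold,
                  require_sign_match = config$require_sign_match)
  else NA_real_
  structure(list(fp_rate = fp, per_sim = per_sim, mc_se = mc_se,
                 exact_rate = exact, config = config),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("null false-positive rate at |ARD| > %g (depths %d/%d):\n",
              x$config$threshold, x$config$depth_hi, x$config$depth_lo))
  cat(sprintf("  Monte Carlo %.4f%% (SE %.2g%%, %d x %d loci); exact %s%%\n",
              100 * x$fp_rate, 100 * x$mc_se, x$config$n_sims, x$config$n_loci,
              if (is.na(x$exact_rate)) "NA" else sprintf("%.4f", 100 * x$exact_rate)))
  invisible(x)
}

# P(|K - d| > t*d), K ~ Binomial(2d, 0.5): the difference of two independent
# Binomial(d, 0.5) counts, shifted by d, is Binomial(2d, 0.5)
binom_diff_tail <- function(d, threshold) {
  k <- 0:(2 * d)
  sum(stats::dbinom(k, 2 * d, 0.5)[abs(k - d) > threshold * d])
}

# enumeration of the predicate the pipeline evaluates: |kA/d - kB/d| > t
# in double precision
ratio_diff_tail <- function(d, threshold) {
  kA <- rep(0:d, each = d + 1)
  kB <- rep(0:d, times = d + 1)
  sum(stats::dbinom(kA, d, 0.5) * stats::dbinom(kB, d, 0.5) *
        (abs(kA / d - kB / d) > threshold))
}

#' Exact false-positive rate of the ARD threshold under the null
#'
#' Probability that pure binomial sampling noise at two heterozygous twins
#' exceeds the ARD threshold on both platforms simultaneously: the product
#' of the two per-platform tail probabilities (platforms are independent).
#' Depths are fixed per platform.
#'
#' Two threshold semantics are available. `"ratio"` (default) enumerates all
#' count pairs and evaluates the predicate the pipeline actually tests,
#' `|kA/d - kB/d| > t` in double precision. `"count"` evaluates the
#' idealized integer event `|kA - kB| > t * d` via the convolution identity
#' (the difference of two independent Binomial(d, 0.5) counts plus d is
#' Binomial(2d, 0.5)). The two differ only when `t * d` falls exactly on the
#' count grid (e.g. t = 0.25 at depth 40, where `t * d = 10`): there,
#' rounding of the double-precision ratio difference pushes part of the
#' boundary mass `|kA - kB| = t * d` over the strict threshold. At depths
#' 40/13 and t = 0.25 the ratio semantics give 0.356% and the count
#' semantics 0.309%.
#'
#' @param depth_hi,depth_lo per-platform read depths.
#' @param threshold ARD threshold (strict `>`).
#' @param require_sign_match if `TRUE`, additionally require the same sign on
#'   both platforms (halves the rate, by symmetry and independence).
#' @param semantics `"ratio"` (the implemented predicate, default) or
#'   `"count"` (idealized integer event).
#' @return The false-positive probability.
#' @export
exact_fp_rate <- function(depth_hi = 40, depth_lo = 13, threshold = 0.25,
                          require_sign_match = FALSE,
                          semantics = c("ratio", "count")) {
  semantics <- match.arg(semantics)
  stopifnot(depth_hi >= 1, depth_lo >= 1, threshold >= 0)
  tail_fun <- if (semantics == "ratio") ratio_diff_tail else binom_diff_tail
  p <- tail_fun(depth_hi, threshold) * tail_fun(depth_lo, threshold)
  if (require_sign_match) p <- p / 2
  p
}

#' False-positive rate across a grid of ARD thresholds
#'
#' @param depth_hi,depth_lo per-platform read depths.
#' @param thresholds ascending vector of ARD thresholds.
#' @param n_loci,n_sims,seed Monte Carlo settings (see
#'   [calibration_config()]); set `n_sims = 0` to skip simulation and report
#'   exact rates only.
#' @return Data frame with `threshold`, `exact_rate`, `simulated_rate`
#'   (`NA` when simulation is skipped); exact rates are non-increasing.
#' @export
fp_curve <- function(depth_hi = 40, depth_lo = 13,
                     thresholds = seq(0, 0.5, by = 0.05),
                     n_loci = 10000, n_sims = 20, seed = 1) {
  stopifnot(!is.unsorted(thresholds))
  exact <- vapply(thresholds, function(t) exact_fp_rate(depth_hi, depth_lo, t),
                  numeric(1))
  simulated <- rep(NA_real_, length(thresholds))
  if (n_sims > 0)
    simulated <- vapply(seq_along(thresholds), function(i) {
      cfg <- calibration_config(depth_hi, depth_lo, thresholds[i],
                                n_loci = n_loci, n_sims = n_sims,
                                seed = seed + i)
      simulate_fp_rate(cfg)$fp_rate
    }, numeric(1))
  data.frame(threshold = thresholds, exact_rate = exact,
             simulated_rate = simulated)
}

#' Plot the false-positive calibration curve
#'
#' Threshold versus null false-positive fraction, with a dotted reference
#' line at 5% false positives.
#'
#' @param curve a data frame from [fp_curve()].
#' @param ... passed to [graphics::plot()].
#' @return `curve`, invisibly.
#' @export
plot_fp_curve <- function(curve, ...) {
  graphics::plot(curve$threshold, curve$exact_rate, type = "l",
                 xlab = "ARD threshold",
                 ylab = "null false-positive fraction", ...)
  if (any(!is.na(curve$simulated_rate)))
    graphics::points(curve$threshold, curve$simulated_rate, pch = 1)
  graphics::abline(h = 0.05, lty = 3, col = "red")
  invisible(curve)
}
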
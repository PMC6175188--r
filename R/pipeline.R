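#' Run the candidate-detection stage end to end
#'
#' Joins the four count tracks, applies the full filter chain, and computes
#' the sign-matching summary (exact binomial test, Clopper-Pearson interval,
#' true-positive estimate). Inputs may be [sample_track()] objects or paths
#' to count TSVs; region sets may be `GRanges` or BED paths.
#'
#' @param a_hi,b_hi,a_lo,b_lo tracks (or TSV paths): twins A/B on the high-
#'   and low-depth platforms.
#' @param include,exclude optional region sets (or BED paths).
#' @param params a [filter_params()].
#' @param out_dir optional output directory; when given, writes
#'   `candidates.tsv`, `stage_counts.json` and `summary.json`.
#' @return A list: `candidates` (the `candidate_set`), `test` (the
#'   `match_test`), `true_positive_estimate`, and `outputs` (paths written,
#'   or `NULL`).
#' @export
run_detect <- function(a_hi, b_hi, a_lo, b_lo, include = NULL, exclude = NULL,
                       params = filter_params(), out_dir = NULL) {
  as_track <- function(x, nm) {
    if (inherits(x, "sample_track")) return(x)
    if (is.character(x)) return(read_counts_from_tsv(x))
    stop("track '", nm, "' must be a sample_track or a TSV path")
  }
  as_regions <- function(x) {
    if (is.null(x) || inherits(x, "GRanges")) return(x)
    read_regions_bed(x)
  }
  joint <- join_tracks(as_track(a_hi, "a_hi"), as_track(b_hi, "b_hi"),
                       as_track(a_lo, "a_lo"), as_track(b_lo, "b_lo"))
  cs <- detect(joint, params, as_regions(include), as_regions(exclude))
  test <- if (cs$n_total > 0) matching_test(cs$n_match, cs$n_total) else NULL
  tpe <- if (cs$n_total > 0) true_positive_estimate(cs$n_match, cs$n_total) else NA_real_

  outputs <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    outputs <- c(candidates = file.path(out_dir, "candidates.tsv"),
                 stage_counts = file.path(out_dir, "stage_counts.json"),
                 summary = file.path(out_dir, "summary.json"))
    write_candidate_set(cs, outputs[["candidates"]], outputs[["stage_counts"]])
    jsonlite::write_json(list(
      n_total = cs$n_total, n_match = cs$n_match, n_nonmatch = cs$n_nonmatch,
      matching_fraction = if (cs$n_total > 0) cs$n_match / cs$n_total else NA,
      p_value = if (!is.null(test)) test$p_value else NA,
      ci_low = if (!is.null(test)) test$ci_low else NA,
      ci_high = if (!is.null(test)) test$ci_high else NA,
      true_positive_estimate = tpe),
      outputs[["summary"]], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(candidates = cs, test = test, true_positive_estimate = tpe,
       outputs = outputs)
}

#' Run the full analysis pipeline on one twin-pair dataset
#'
#' Detection, null calibration, within-pair clustering, category enrichment
#' and the same-individual negative control, written to one directory with a
#' machine-readable manifest (file checksums and the seeds used).
#'
#' @param dataset a dataset as returned by [generate_twin_dataset()], or a
#'   list with the same elements built from files.
#' @param out_dir output directory.
#' @param params a [filter_params()].
#' @param calib a [calibration_config()] (scaled-down by default so the full
#'   pipeline stays interactive); set to `NULL` to skip calibration.
#' @param windows cluster-test distance windows; default [distance_windows()].
#' @param n_perm permutations for the cluster test; `0` skips clustering
#'   with a notice.
#' @param control_category category for the negative control (default
#'   `"intronic"`).
#' @param seed seed for the permutation stage.
#' @return A list of stage results plus `manifest` (also written as
#'   `manifest.json`).
#' @export
run_full <- function(dataset, out_dir, params = filter_params(),
                     calib = calibration_config(n_loci = 50000, n_sims = 20),
                     windows = distance_windows(), n_perm = 1000,
                     control_category = "intronic", seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  det <- run_detect(dataset$tracks$a_hi, dataset$tracks$b_hi,
                    dataset$tracks$a_lo, dataset$tracks$b_lo,
                    include = dataset$include, exclude = dataset$exclude,
                    params = params, out_dir = out_dir)

  calibration <- NULL
  if (!is.null(calib)) {
    calibration <- simulate_fp_rate(calib)
    curve <- fp_curve(calib$depth_hi, calib$depth_lo, n_sims = 0)
    write_cluster_tsv(curve, file.path(out_dir, "fp_curve.tsv"))
  }

  clustering <- NULL
  cand_sites <- det$candidates$sites
  background <- clear_call_filter(drop_double_homref(
    filter_regions(join_tracks(dataset$tracks$a_hi, dataset$tracks$b_hi,
                               dataset$tracks$a_lo, dataset$tracks$b_lo),
                   dataset$include, dataset$exclude)), params)
  if (n_perm > 0 && nrow(cand_sites) > 1) {
    clustering <- within_pair_cluster_test(
      cand_sites[, c("chrom", "pos")], background[, c("chrom", "pos")],
      windows = windows, n_perm = n_perm, seed = seed)
    write_cluster_tsv(clustering, file.path(out_dir, "clustering.tsv"))
  } else if (n_perm == 0) {
    message("n_perm = 0: clustering stage skipped")
  }

  enrichment <- NULL
  if (nrow(cand_sites) > 0) {
    cand_keys <- locus_key(cand_sites$chrom, cand_sites$pos,
                           cand_sites$ref, cand_sites$alt)
    back_keys <- locus_key(background$chrom, background$pos,
                           background$ref, background$alt)
    enrichment <- category_enrichment(cand_keys, back_keys, dataset$annotations)
    write_cluster_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
  }

  control <- control_comparison(dataset$tracks$a_hi, dataset$tracks$a_lo,
                                params, dataset$annotations, control_category)
  write_cluster_tsv(control, file.path(out_dir, "control.tsv"))

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("twinmosaic")),
    seeds = list(permutation = seed,
                 calibration = if (!is.null(calib)) calib$seed else NULL,
                 generator = if (!is.null(dataset$config)) dataset$config$seed else NULL),
    params = list(ard_threshold = params$ard_threshold,
                  clear_call_tolerance = params$clear_call_tolerance,
                  n_perm = n_perm, control_category = control_category),
    files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(detect = det, calibration = calibration, clustering = clustering,
       enrichment = enrichment, control = control, manifest = manifest)
}
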
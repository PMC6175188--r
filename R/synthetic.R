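#' Configuration of the synthetic twin-dataset generator
#'
#' Describes a monozygotic twin pair sequenced on a high-depth (~40X) and a
#' low-depth (~13X) platform, with planted twin-specific mosaic loci of known
#' cell fraction, optional positional hotspots and annotation categories with
#' configurable enrichment among mosaic loci.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param n_loci number of variant loci to place.
#' @param genotype_freqs named probabilities of the shared germline genotype
#'   (`hom_ref`, `het`, `hom_alt`); must sum to 1. Heterozygotes dominate
#'   because the analysis background is the heterozygous locus set.
#' @param n_mosaic number of planted twin-specific mosaic loci.
#' @param mosaic_cell_fraction cell fraction f in (0, 1] carrying the
#'   postzygotic mutation; a single haplotype is affected, so the carrier
#'   twin's allele fraction shifts by f/2.
#' @param p_mutated_twin_a probability the mutated twin is twin A.
#' @param hotspots list with `n_hotspots`, `span_bp` and
#'   `fraction_in_hotspots` (share of mosaic loci placed inside hotspots);
#'   default: no hotspots.
#' @param hotspot_centers optional data frame (`chrom`, `start`) fixing the
#'   hotspot start positions (e.g. to co-locate hotspots across two pairs);
#'   overrides random placement.
#' @param depth_hi,depth_lo mean read depths of the platforms (defaults 40, 13).
#' @param depth_model `"poisson"` (per-locus depths Poisson around the mean,
#'   truncated at 1; default) or `"fixed"`.
#' @param category_probs named per-category baseline annotation
#'   probabilities (multi-label); defaults follow genome-wide proportions of
#'   the 14 consequence categories among heterozygous variants.
#' @param category_multipliers named multipliers applied to the baseline
#'   probabilities at mosaic loci (capped at probability 1); default all 1.
#' @param error_rate per-read error rate folded into the allele fraction
#'   (default 0: pure binomial sampling).
#' @param include,exclude optional `GRanges` region sets; defaults: whole
#'   chromosomes included, nothing excluded. Loci are placed uniformly over
#'   include minus exclude, without replacement.
#' @param seed RNG seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(chrom_lengths = c(chr1 = 6e7, chr2 = 6e7),
                             n_loci = 20000,
                             genotype_freqs = c(hom_ref = 0.10, het = 0.70, hom_alt = 0.20),
                             n_mosaic = 100,
                             mosaic_cell_fraction = 0.5,
                             p_mutated_twin_a = 0.5,
                             hotspots = list(n_hotspots = 0, span_bp = 10000,
                                             fraction_in_hotspots = 0),
                             hotspot_centers = NULL,
                             depth_hi = 40, depth_lo = 13,
                             depth_model = c("poisson", "fixed"),
                             category_probs = default_category_probs(),
                             category_multipliers = NULL,
                             error_rate = 0,
                             include = NULL, exclude = NULL,
                             seed = 1) {
  depth_model <- match.arg(depth_model)
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            n_loci >= 1, n_mosaic >= 0, n_mosaic <= n_loci,
            mosaic_cell_fraction > 0, mosaic_cell_fraction <= 1,
            p_mutated_twin_a >= 0, p_mutated_twin_a <= 1,
            depth_hi >= 1, depth_lo >= 1,
            error_rate >= 0, error_rate < 0.5,
            abs(sum(genotype_freqs) - 1) < 1e-8,
            all(c("hom_ref", "het", "hom_alt") %in% names(genotype_freqs)),
            all(category_probs >= 0 & category_probs <= 1))
  if (is.null(category_multipliers))
    category_multipliers <- stats::setNames(rep(1, length(category_probs)),
                                            names(category_probs))
  structure(list(chrom_lengths = chrom_lengths, n_loci = as.integer(n_loci),
                 genotype_freqs = genotype_freqs,
                 n_mosaic = as.integer(n_mosaic),
                 mosaic_cell_fraction = mosaic_cell_fraction,
                 p_mutated_twin_a = p_mutated_twin_a,
                 hotspots = hotspots, hotspot_centers = hotspot_centers,
                 depth_hi = depth_hi, depth_lo = depth_lo,
                 depth_model = depth_model,
                 category_probs = category_probs,
                 category_multipliers = category_multipliers,
                 error_rate = error_rate,
                 include = include, exclude = exclude, seed = as.integer(seed)),
            class = "generator_config")
}

#' Baseline probabilities of the 14 consequence categories
#'
#' Multi-label baseline annotation probabilities representative of a
#' genome-wide heterozygous variant set (intronic and protein-coding loci
#' common, high-impact loci rare).
#'
#' @return Named numeric vector over [consequence_categories()].
#' @export
default_category_probs <- function() {
  c(intronic = 0.554, intergenic = 0.351, modifier = 0.997,
    low_impact = 0.009, moderate_impact = 0.006, high_impact = 0.0003,
    noncoding = 0.324, synonymous = 0.007, missense = 0.006,
    regulatory = 0.091, tf_binding = 0.007, protein_coding = 0.492,
    utr3 = 0.017, utr5 = 0.004)
}

# sample k distinct 1-based (chrom, pos) uniformly over a reduced GRanges
sample_positions <- function(allowed, k) {
  widths <- GenomicRanges::width(allowed)
  total <- sum(widths)
  if (total < k) stop("allowed region too small to place ", k, " distinct loci")
  flat <- sort(sample.int(total, k))
  cum <- cumsum(widths)
  range_idx <- findInterval(flat - 1L, c(0L, cum), rightmost.closed = FALSE)
  offset <- flat - c(0L, cum)[range_idx] - 1L
  data.frame(chrom = as.character(GenomicRanges::seqnames(allowed))[range_idx],
             pos = GenomicRanges::start(allowed)[range_idx] + offset,
             stringsAsFactors = FALSE)
}

nearest_genotype <- function(f) {
  ifelse(f < 0.25, "hom_ref", ifelse(f > 0.75, "hom_alt", "het"))
}

#' Generate a synthetic twin-pair dual-platform dataset with ground truth
#'
#' For each locus the shared germline genotype fixes a true allele fraction
#' of 0, 0.5 or 1 in both twins. At a planted mosaic locus the mutated
#' twin's fraction is shifted by +/- f/2 (a mutation carried by a fraction f
#' of cells occupies one haplotype), clamped to `[0, 1]`: gains from 0,
#' losses from 1, and either direction from 0.5. Read counts per track are
#' Binomial(depth, fraction) with per-track depths from the depth model.
#' Mosaic loci can be concentrated in positional hotspots, and annotation
#' categories are sampled with enrichment multipliers at mosaic loci. Fully
#' reproducible from the config seed.
#'
#' @param config a [generator_config()].
#' @return A list: `tracks` (list of [sample_track()]s `a_hi`, `b_hi`,
#'   `a_lo`, `b_lo`), `include` and `exclude` (`GRanges`), `annotations`
#'   (long-format data frame), `truth` (per-locus data frame: `key`,
#'   `chrom`, `pos`, `germline`, `is_mosaic`, `mutated_twin`, `f_a`, `f_b`,
#'   `hotspot_id`) and `config`.
#' @export
generate_twin_dataset <- function(config = generator_config()) {
  set.seed(config$seed)
  include <- if (!is.null(config$include)) config$include
    else regions_from_df(names(config$chrom_lengths),
                         rep(0L, length(config$chrom_lengths)),
                         as.integer(config$chrom_lengths))
  exclude <- if (!is.null(config$exclude)) config$exclude
    else GenomicRanges::GRanges()
  allowed <- if (length(exclude))
    suppressWarnings(GenomicRanges::setdiff(include, exclude)) else include

  n <- config$n_loci
  loci <- sample_positions(allowed, n)
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1),
                USE.NAMES = FALSE)
  germline <- sample(c("hom_ref", "het", "hom_alt"), n, replace = TRUE,
                     prob = config$genotype_freqs[c("hom_ref", "het", "hom_alt")])
  f_base <- c(hom_ref = 0, het = 0.5, hom_alt = 1)[germline]
  f_a <- f_b <- unname(f_base)

  # plant mosaics
  is_mosaic <- rep(FALSE, n)
  mutated_twin <- rep(NA_character_, n)
  hotspot_id <- rep(NA_integer_, n)
  if (config$n_mosaic > 0) {
    mos <- sample.int(n, config$n_mosaic)
    is_mosaic[mos] <- TRUE
    mutated_twin[mos] <- ifelse(stats::runif(config$n_mosaic) < config$p_mutated_twin_a,
                                "a", "b")
    shift <- config$mosaic_cell_fraction / 2
    dir <- ifelse(f_base[mos] == 0, 1,
           ifelse(f_base[mos] == 1, -1, sample(c(-1, 1), config$n_mosaic, replace = TRUE)))
    delta <- dir * shift
    f_mut <- pmin(1, pmax(0, f_base[mos] + delta))
    a_mut <- mutated_twin[mos] == "a"
    f_a[mos][a_mut] <- f_mut[a_mut]
    f_b[mos][!a_mut] <- f_mut[!a_mut]

    hs <- config$hotspots
    n_in_hs <- round(hs$fraction_in_hotspots * config$n_mosaic)
    if (n_in_hs > 0) {
      if (hs$n_hotspots < 1) stop("fraction_in_hotspots > 0 but n_hotspots = 0")
      centers <- config$hotspot_centers
      if (is.null(centers)) {
        fit <- GenomicRanges::width(allowed) >= hs$span_bp
        if (!any(fit)) stop("no allowed region can hold a hotspot of span ", hs$span_bp)
        ranges <- allowed[fit]
        ri <- sample(seq_along(ranges), hs$n_hotspots, replace = TRUE)
        centers <- data.frame(
          chrom = as.character(GenomicRanges::seqnames(ranges))[ri],
          start = GenomicRanges::start(ranges)[ri] +
            vapply(GenomicRanges::width(ranges)[ri] - hs$span_bp + 1L,
                   function(w) sample.int(w, 1) - 1L, integer(1)))
      }
      if (nrow(centers) < hs$n_hotspots)
        stop("hotspot_centers provides fewer centers than n_hotspots")
      assign_hs <- sample(rep_len(seq_len(hs$n_hotspots), n_in_hs))
      in_hs <- mos[seq_len(n_in_hs)]
      used <- paste(loci$chrom, loci$pos)
      for (h in seq_len(hs$n_hotspots)) {
        members <- in_hs[assign_hs == h]
        if (!length(members)) next
        cand_pos <- centers$start[h] + seq_len(hs$span_bp) - 1L
        cand_key <- paste(centers$chrom[h], cand_pos)
        free <- which(!cand_key %in% used)
        if (length(free) < length(members))
          stop("hotspot span ", hs$span_bp, " cannot hold ", length(members),
               " distinct mosaic loci")
        pick <- free[sample.int(length(free), length(members))]
        loci$chrom[members] <- centers$chrom[h]
        loci$pos[members] <- cand_pos[pick]
        used <- c(used, cand_key[pick])
        hotspot_id[members] <- h
      }
    }
  }

  # read counts per track
  e <- config$error_rate
  p_eff <- function(f) f * (1 - 2 * e) + e
  make_track <- function(f_twin, mean_depth, twin, platform) {
    depth <- draw_depths(n, mean_depth, config$depth_model)
    alt_count <- stats::rbinom(n, depth, p_eff(f_twin))
    sample_track(data.frame(
      chrom = loci$chrom, pos = loci$pos, ref = ref, alt = alt,
      ref_count = depth - alt_count, alt_count = alt_count,
      genotype = nearest_genotype(f_twin), stringsAsFactors = FALSE),
      individual_id = twin, platform = platform)
  }
  tracks <- list(a_hi = make_track(f_a, config$depth_hi, "a", "high_depth"),
                 b_hi = make_track(f_b, config$depth_hi, "b", "high_depth"),
                 a_lo = make_track(f_a, config$depth_lo, "a", "low_depth"),
                 b_lo = make_track(f_b, config$depth_lo, "b", "low_depth"))

  # annotation categories, enriched at mosaic loci
  key <- locus_key(loci$chrom, loci$pos, ref, alt)
  cats <- names(config$category_probs)
  ann <- lapply(cats, function(cat_name) {
    p <- config$category_probs[[cat_name]] *
      ifelse(is_mosaic, config$category_multipliers[[cat_name]], 1)
    hit <- stats::runif(n) < pmin(1, p)
    data.frame(key = key[hit], category = rep(cat_name, sum(hit)),
               stringsAsFactors = FALSE)
  })
  annotations <- do.call(rbind, ann)

  truth <- data.frame(key = key, chrom = loci$chrom, pos = loci$pos,
                      germline = unname(germline), is_mosaic = is_mosaic,
                      mutated_twin = mutated_twin, f_a = f_a, f_b = f_b,
                      hotspot_id = hotspot_id, stringsAsFactors = FALSE)
  list(tracks = tracks, include = include, exclude = exclude,
       annotations = annotations, truth = truth, config = config)
}

#' Generate a null dataset (no planted mosaics)
#'
#' Shorthand for [generate_twin_dataset()] with `n_mosaic = 0`: both twins
#' share identical true allele fractions everywhere, so every candidate
#' downstream is a sampling false positive.
#'
#' @inheritParams generate_twin_dataset
#' @return As [generate_twin_dataset()].
#' @export
generate_null_dataset <- function(config = generator_config()) {
  config$n_mosaic <- 0L
  generate_twin_dataset(config)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits the four count TSVs, include/exclude BEDs, the annotation TSV and
#' the truth TSV.
#'
#' @param dataset a list from [generate_twin_dataset()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    a_hi = file.path(dir, "twin_a_high_depth.counts.tsv"),
    b_hi = file.path(dir, "twin_b_high_depth.counts.tsv"),
    a_lo = file.path(dir, "twin_a_low_depth.counts.tsv"),
    b_lo = file.path(dir, "twin_b_low_depth.counts.tsv"),
    include = file.path(dir, "include.bed"),
    exclude = file.path(dir, "exclude.bed"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.tsv"))
  for (nm in c("a_hi", "b_hi", "a_lo", "b_lo"))
    write_counts_tsv(dataset$tracks[[nm]], paths[[nm]])
  write_regions_bed(dataset$include, paths[["include"]])
  write_regions_bed(dataset$exclude, paths[["exclude"]])
  write_annotations_tsv(dataset$annotations, paths[["annotations"]])
  con <- file(paths[["truth"]], "w")
  writeLines(pkg_header(), con)
  utils::write.table(dataset$truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(paths)
}
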
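#' @name io
#' @title Reading count tracks and region sets
#'
#' @description
#' A *sample track* holds per-locus allele read counts for one individual on
#' one sequencing platform: one row per biallelic SNV with columns `chrom`,
#' `pos` (1-based), `ref`, `alt` (single bases), `ref_count`, `alt_count`
#' (non-negative integers) and `genotype` (one of `hom_ref`, `het`, `hom_alt`,
#' `missing`). Region sets are `GRanges` objects; BED input is 0-based
#' half-open, internal coordinates are 1-based, so a BED interval `[s, e)`
#' contains 1-based positions `s+1 .. e`.
NULL

GENOTYPES <- c("hom_ref", "het", "hom_alt", "missing")
BASES <- c("A", "C", "G", "T")

locus_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

#' Construct a sample track from a data frame of allele counts
#'
#' @param df data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count` and optionally `genotype`.
#' @param individual_id twin label (e.g. `"A"`).
#' @param platform `"high_depth"` or `"low_depth"`.
#' @return A `sample_track`: a validated data frame with attributes
#'   `individual_id` and `platform`.
#' @export
sample_track <- function(df, individual_id = NA_character_, platform = NA_character_) {
  required <- c("chrom", "pos", "ref", "alt", "ref_count", "alt_count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("count table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(df$genotype)) df$genotype <- rep("missing", nrow(df))
  df <- df[c(required, "genotype")]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$ref_count <- as.integer(df$ref_count)
  df$alt_count <- as.integer(df$alt_count)
  df$genotype <- as.character(df$genotype)
  validate_track_rows(df)
  key <- locus_key(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(key))
    stop("duplicated locus key in track: ", key[duplicated(key)][1])
  rownames(df) <- NULL
  structure(df,
    individual_id = individual_id, platform = platform,
    class = c("sample_track", "data.frame"))
}

validate_track_rows <- function(df) {
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i)) stop(what, " at row ", i[1], " (", df$chrom[i[1]], ":", df$pos[i[1]], ")")
  }
  if (nrow(df) == 0) return(invisible(df))
  bad(is.na(df$pos) | df$pos < 1, "position must be a 1-based integer")
  bad(!(df$ref %in% BASES) | !(df$alt %in% BASES), "ref/alt must be single bases A/C/G/T")
  bad(df$ref == df$alt, "ref and alt alleles must differ")
  bad(is.na(df$ref_count) | df$ref_count < 0 | is.na(df$alt_count) | df$alt_count < 0,
      "read counts must be non-negative integers")
  bad(!(df$genotype %in% GENOTYPES), "genotype must be hom_ref/het/hom_alt/missing")
  invisible(df)
}

#' Read a sample track from a tab-separated count table
#'
#' Expects a header line with columns `chrom`, `pos`, `ref`, `alt`,
#' `ref_count`, `alt_count` and optionally `genotype`; lines starting with
#' `#` are ignored. Positions are 1-based.
#'
#' @inheritParams sample_track
#' @param path path to the TSV file.
#' @return A [sample_track()].
#' @export
read_counts_from_tsv <- function(path, individual_id = NA_character_, platform = NA_character_) {
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", check.names = TRUE)
  tryCatch(
    sample_track(df, individual_id = individual_id, platform = platform),
    error = function(e) stop("malformed count table '", path, "': ", conditionMessage(e), call. = FALSE))
}

#' Write a sample track as a tab-separated count table
#'
#' The first line is a `#`-prefixed header naming the package version;
#' [read_counts_from_tsv()] round-trips the file exactly.
#'
#' @param track a [sample_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(pkg_header(c(individual = attr(track, "individual_id"),
                          platform = attr(track, "platform"))), con)
  utils::write.table(as.data.frame(track), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample track from a VCF with per-sample allele depths
#'
#' Keeps biallelic SNV records with a non-missing `AD` (allele depth) entry
#' for `sample_name`; multi-allelic records, indels/MNVs and records with
#' missing allele depths are skipped and tallied in the `skipped` attribute
#' of the returned track. The genotype is taken from the `GT` field when
#' present, else `missing`.
#'
#' @inheritParams sample_track
#' @param path path to a VCF (plain or bgzipped).
#' @param sample_name sample column to extract.
#' @return A [sample_track()] with attribute `skipped`, a named integer
#'   vector counting `multiallelic`, `non_snv` and `missing_ad` records.
#' @export
read_counts_from_vcf <- function(path, sample_name,
                                 individual_id = sample_name,
                                 platform = NA_character_) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!sample_name %in% samples)
    stop("sample '", sample_name, "' not in VCF; available samples: ",
         paste(samples, collapse = ", "))
  fmt <- vcf@gt[, "FORMAT"]
  if (!any(vapply(strsplit(fmt, ":"), function(f) "AD" %in% f, logical(1))))
    stop("VCF has no AD (allele depth) entry in its FORMAT fields")

  fix <- vcf@fix
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  snv <- !multi & nchar(ref) == 1L & nchar(alt) == 1L &
    toupper(ref) %in% BASES & toupper(alt) %in% BASES

  ad <- vcfR::extract.gt(vcf, element = "AD")[, sample_name]
  gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT")[, sample_name],
                 error = function(e) rep(NA_character_, length(ad)))
  have_ad <- !is.na(ad) & grepl(",", ad, fixed = TRUE)
  keep <- snv & have_ad
  skipped <- c(multiallelic = sum(multi),
               non_snv = sum(!snv & !multi),
               missing_ad = sum(snv & !have_ad))

  counts <- do.call(rbind, strsplit(ad[keep], ",", fixed = TRUE))
  genotype <- vapply(gt[keep], function(g) {
    if (is.na(g)) return("missing")
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return("missing")
    n_alt <- sum(al == "1")
    if (n_alt == 0) "hom_ref" else if (n_alt == length(al)) "hom_alt" else "het"
  }, character(1), USE.NAMES = FALSE)

  track <- sample_track(
    data.frame(chrom = chrom[keep], pos = pos[keep],
               ref = toupper(ref[keep]), alt = toupper(alt[keep]),
               ref_count = as.integer(counts[, 1]),
               alt_count = as.integer(counts[, 2]),
               genotype = genotype, stringsAsFactors = FALSE),
    individual_id = individual_id, platform = platform)
  attr(track, "skipped") <- skipped
  track
}

#' Read a BED file into a merged region set
#'
#' Accepts 3+ column BED (0-based half-open); overlapping or adjacent
#' intervals are merged. The returned `GRanges` uses 1-based closed
#' coordinates internally, so a 1-based position `p` is in the set iff
#' `p - 1` lies in some BED interval.
#'
#' @param path path to a BED file.
#' @return A reduced [GenomicRanges::GRanges] region set (empty if the file
#'   has no intervals).
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                      colClasses = "character"),
    error = function(e) {
      # empty file (possibly header-only) is a valid empty region set
      if (grepl("no lines available", conditionMessage(e))) return(NULL)
      stop("malformed BED '", path, "': ", conditionMessage(e), call. = FALSE)
    })
  if (is.null(df) || nrow(df) == 0) return(GenomicRanges::GRanges())
  if (ncol(df) < 3) stop("BED file must have at least 3 columns: ", path)
  df[[2]] <- suppressWarnings(as.integer(df[[2]]))
  df[[3]] <- suppressWarnings(as.integer(df[[3]]))
  bad <- which(is.na(df[[2]]) | is.na(df[[3]]) | df[[2]] < 0 | df[[2]] >= df[[3]])
  if (length(bad))
    stop("invalid BED interval (start must be >= 0 and < end) at line ", bad[1],
         " of ", path)
  regions_from_df(df[[1]], df[[2]], df[[3]])
}

# build a reduced GRanges from 0-based half-open intervals
regions_from_df <- function(chrom, start0, end0) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1L, end = end0))
  GenomicRanges::reduce(gr)
}

#' Test membership of 1-based positions in a region set
#'
#' @param chrom,pos parallel vectors of chromosome names and 1-based positions.
#' @param regions a `GRanges` region set, e.g. from [read_regions_bed()].
#' @return Logical vector, `TRUE` where the position falls in the set.
#' @export
positions_in_regions <- function(chrom, pos, regions) {
  if (length(pos) == 0) return(logical(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  suppressWarnings(GenomicRanges::countOverlaps(q, regions) > 0)
}

#' Write a region set as BED (0-based half-open)
#'
#' @param regions a `GRanges` region set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(regions))
    writeLines(paste(as.character(GenomicRanges::seqnames(regions)),
                     GenomicRanges::start(regions) - 1L,
                     GenomicRanges::end(regions), sep = "\t"), con)
  invisible(path)
}

#' Join four count tracks into per-locus joint sites
#'
#' Intersects the loci of twin A and twin B on the high- and low-depth
#' platforms by full locus key (chrom, pos, ref, alt). Loci sharing a
#' position but disagreeing on ref/alt between tracks cannot yield a
#' comparable ratio and are excluded (tallied in attribute
#' `n_allele_mismatch`); loci with zero total depth in any track are
#' excluded (ratio undefined; attribute `n_zero_depth`). Allelic ratios
#' `r = alt / (ref + alt)` and the signed allelic-ratio differences
#' `ard = r_A - r_B` (twin A minus twin B, identically on both platforms)
#' are filled in.
#'
#' @param a_hi,b_hi,a_lo,b_lo [sample_track()]s: twins A and B on the
#'   high- and low-depth platforms.
#' @return A `joint_sites` data frame with one row per locus present in all
#'   four tracks: locus key columns, per-track counts, depths and genotypes,
#'   ratios `r_a_hi`, `r_b_hi`, `r_a_lo`, `r_b_lo`, and `ard_hi`, `ard_lo`.
#' @export
join_tracks <- function(a_hi, b_hi, a_lo, b_lo) {
  tracks <- list(a_hi = a_hi, b_hi = b_hi, a_lo = a_lo, b_lo = b_lo)
  keys <- lapply(tracks, function(tr) locus_key(tr$chrom, tr$pos, tr$ref, tr$alt))
  for (nm in names(keys))
    if (anyDuplicated(keys[[nm]]))
      stop("duplicated locus key in track ", nm, ": ",
           keys[[nm]][duplicated(keys[[nm]])][1])
  shared <- Reduce(intersect, keys)

  pos_key <- lapply(tracks, function(tr) paste(tr$chrom, tr$pos, sep = ":"))
  shared_pos <- Reduce(intersect, pos_key)
  shared_key_pos <- unique(sub("^([^:]+:[^:]+):.*$", "\\1", shared))
  n_mismatch <- length(setdiff(shared_pos, shared_key_pos))

  idx <- lapply(seq_along(tracks), function(i) match(shared, keys[[i]]))
  base <- tracks[[1]][idx[[1]], c("chrom", "pos", "ref", "alt")]
  out <- base
  for (i in seq_along(tracks)) {
    nm <- names(tracks)[i]
    tr <- tracks[[i]][idx[[i]], ]
    out[[paste0("ref_", nm)]] <- tr$ref_count
    out[[paste0("alt_", nm)]] <- tr$alt_count
    out[[paste0("depth_", nm)]] <- tr$ref_count + tr$alt_count
    out[[paste0("gt_", nm)]] <- tr$genotype
  }
  zero <- out$depth_a_hi == 0 | out$depth_b_hi == 0 |
          out$depth_a_lo == 0 | out$depth_b_lo == 0
  n_zero <- sum(zero)
  out <- out[!zero, , drop = FALSE]

  out$r_a_hi <- allelic_ratio(out$ref_a_hi, out$alt_a_hi)
  out$r_b_hi <- allelic_ratio(out$ref_b_hi, out$alt_b_hi)
  out$r_a_lo <- allelic_ratio(out$ref_a_lo, out$alt_a_lo)
  out$r_b_lo <- allelic_ratio(out$ref_b_lo, out$alt_b_lo)
  out$ard_hi <- ard(out$r_a_hi, out$r_b_hi)
  out$ard_lo <- ard(out$r_a_lo, out$r_b_lo)
  rownames(out) <- NULL
  structure(out, n_allele_mismatch = n_mismatch, n_zero_depth = n_zero,
            class = c("joint_sites", "data.frame"))
}
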
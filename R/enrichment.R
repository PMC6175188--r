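#' The 14 default variant consequence categories
#'
#' VEP-style annotation labels used for category enrichment; a locus may
#' carry several (multi-label).
#'
#' @return Character vector of 14 category names.
#' @export
consequence_categories <- function() {
  c("intronic", "intergenic", "modifier", "low_impact", "moderate_impact",
    "high_impact", "noncoding", "synonymous", "missense", "regulatory",
    "tf_binding", "protein_coding", "utr3", "utr5")
}

#' Read a locus annotation table
#'
#' Tab-separated file with a header and columns `key` (locus key
#' `chrom:pos:ref:alt`) and `categories` (comma-separated labels; empty for
#' none).
#'
#' @param path input path.
#' @return A long-format data frame with columns `key`, `category` (one row
#'   per locus-label assignment).
#' @export
read_annotations_tsv <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character")
  if (!all(c("key", "categories") %in% names(df)))
    stop("annotation table needs columns 'key' and 'categories'")
  labs <- strsplit(df$categories, ",", fixed = TRUE)
  n <- lengths(labs)
  data.frame(key = rep(df$key, n), category = trimws(unlist(labs)),
             stringsAsFactors = FALSE)
}

#' Write a locus annotation table
#'
#' @param annotations long-format data frame (`key`, `category`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(annotations, path) {
  wide <- vapply(split(annotations$category, annotations$key),
                 paste, character(1), collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(pkg_header(), con)
  utils::write.table(data.frame(key = names(wide), categories = unname(wide)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# cross-product odds ratio; 0.5 continuity correction only when a cell is 0
odds_ratio_2x2 <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  (a * d) / (b * c)
}

#' Fisher-exact category enrichment of candidate loci
#'
#' For each annotation category, builds the 2x2 table of candidate loci
#' versus the rest of the background (background minus candidates, keeping
#' the strata disjoint) by in-category versus not, and tests enrichment with
#' the one-sided (greater) Fisher exact test. P-values are adjusted across
#' categories with Benjamini-Hochberg ([bh_adjust()]).
#'
#' @param candidates,background character vectors of locus keys; candidates
#'   must be a non-empty subset of the background.
#' @param annotations long-format annotation data frame (`key`, `category`),
#'   e.g. from [read_annotations_tsv()].
#' @param categories category universe; defaults to all categories present
#'   in `annotations`, ordered as in [consequence_categories()] where
#'   applicable.
#' @return Data frame with one row per category: `category`, `k_cand`,
#'   `n_cand`, `k_back`, `n_back` (background *excluding* candidates),
#'   `pct_cand`, `pct_back_full` (percentage against the full background, for
#'   reporting), `odds_ratio`, `p_raw`, `q_fdr`.
#' @export
category_enrichment <- function(candidates, background, annotations,
                                categories = NULL) {
  candidates <- unique(candidates)
  background <- unique(background)
  if (length(candidates) == 0) stop("empty candidate set")
  if (!all(candidates %in% background))
    stop("candidates must be a subset of the background locus set")
  if (is.null(categories)) {
    categories <- unique(annotations$category)
    canon <- consequence_categories()
    categories <- c(intersect(canon, categories), setdiff(categories, canon))
  }
  rest <- setdiff(background, candidates)
  n_cand <- length(candidates); n_rest <- length(rest)
  ann <- annotations[annotations$key %in% background, , drop = FALSE]

  rows <- lapply(categories, function(cat) {
    keys_in <- unique(ann$key[ann$category == cat])
    k_cand <- sum(candidates %in% keys_in)
    k_rest <- sum(rest %in% keys_in)
    tab <- matrix(c(k_cand, n_cand - k_cand, k_rest, n_rest - k_rest), 2, 2)
    p <- if (k_cand == 0 && k_rest == 0) 1
         else stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(category = cat, k_cand = k_cand, n_cand = n_cand,
               k_back = k_rest, n_back = n_rest,
               pct_cand = 100 * k_cand / n_cand,
               pct_back_full = 100 * (k_cand + k_rest) / (n_cand + n_rest),
               odds_ratio = odds_ratio_2x2(k_cand, n_cand - k_cand,
                                           k_rest, n_rest - k_rest),
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_fdr <- bh_adjust(out$p_raw)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: sort p-values ascending, take
#' `min over j >= i of p_(j) * m / j` capped at 1, return in input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Same-individual platform contrast as a negative control
#'
#' Applies the twin filter chain to the two platforms of *one* individual:
#' the allelic-ratio difference is taken between the high- and low-depth
#' tracks, the clear-call condition requires one of the two tracks to sit
#' within tolerance of a canonical ratio, and loci exceeding the ARD
#' threshold are tested for enrichment of one annotation category against
#' the surviving background. Differences within an individual are noise, so
#' no enrichment is expected; a significant result would indicate
#' platform-specific artifacts.
#'
#' @param track_hi,track_lo [sample_track()]s of the same individual on the
#'   two platforms.
#' @param params a [filter_params()].
#' @param annotations long-format annotation data frame (`key`, `category`).
#' @param category the category to test (e.g. `"intronic"`).
#' @return A one-row data frame as in [category_enrichment()], plus columns
#'   `n_selected` and `empty`; when no locus passes the selection the test
#'   is flagged `empty = TRUE` with `NA` statistics.
#' @export
control_comparison <- function(track_hi, track_lo, params = filter_params(),
                               annotations, category) {
  keys <- list(locus_key(track_hi$chrom, track_hi$pos, track_hi$ref, track_hi$alt),
               locus_key(track_lo$chrom, track_lo$pos, track_lo$ref, track_lo$alt))
  shared <- intersect(keys[[1]], keys[[2]])
  i_hi <- match(shared, keys[[1]]); i_lo <- match(shared, keys[[2]])
  d_hi <- track_hi$ref_count[i_hi] + track_hi$alt_count[i_hi]
  d_lo <- track_lo$ref_count[i_lo] + track_lo$alt_count[i_lo]
  ok <- d_hi > 0 & d_lo > 0
  # drop loci with no alternative evidence on either platform (hom-ref analogue)
  gt_hi <- track_hi$genotype[i_hi]; gt_lo <- track_lo$genotype[i_lo]
  hr <- ifelse(gt_hi != "missing", gt_hi == "hom_ref", track_hi$alt_count[i_hi] == 0) &
        ifelse(gt_lo != "missing", gt_lo == "hom_ref", track_lo$alt_count[i_lo] == 0)
  ok <- ok & !hr
  shared <- shared[ok]; i_hi <- i_hi[ok]; i_lo <- i_lo[ok]

  r_hi <- allelic_ratio(track_hi$ref_count[i_hi], track_hi$alt_count[i_hi])
  r_lo <- allelic_ratio(track_lo$ref_count[i_lo], track_lo$alt_count[i_lo])
  clear <- rep(FALSE, length(shared))
  for (canon in params$canonical_ratios)
    clear <- clear | abs(r_hi - canon) < params$clear_call_tolerance |
                     abs(r_lo - canon) < params$clear_call_tolerance
  background <- shared[clear]
  selected <- background[abs(ard(r_hi, r_lo)[clear]) > params$ard_threshold]

  if (length(selected) == 0) {
    return(data.frame(category = category, k_cand = 0L, n_cand = 0L,
                      k_back = NA_integer_, n_back = NA_integer_,
                      pct_cand = NA_real_, pct_back_full = NA_real_,
                      odds_ratio = NA_real_, p_raw = NA_real_, q_fdr = NA_real_,
                      n_selected = 0L, empty = TRUE))
  }
  row <- category_enrichment(selected, background, annotations,
                             categories = category)
  row$n_selected <- length(selected)
  row$empty <- FALSE
  row
}
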
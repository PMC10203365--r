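#' Per-CDS depth and coverage statistics
#'
#' For every CDS of the supplied transcripts, statistics are computed over
#' the same span the panel captures: the CDS extended `flank_bp` each side
#' (clamped at 0). Positions absent from the depth profile count as depth
#' 0. "Coverage" is the percentage of span bases at depth >=
#' `cover_threshold`; the depth bin is decided solely by the mean depth,
#' with half-open edges \[0,30), \[30,100), \[100,Inf).
#'
#' @param profile a `depth_profile`.
#' @param transcripts CDS table (as from [read_gene_models()]).
#' @param cover_threshold minimum depth for a base to count as covered
#'   (default 1).
#' @param flank_bp flank applied around each CDS (default 10, matching the
#'   capture design).
#' @return tibble with `cds_id` (`gene.transcript.CDSk`), `ordinal`,
#'   `mean_depth`, `covered_fraction_pct`, `depth_bin`.
#' @export
cds_coverage_stats <- function(profile, transcripts, cover_threshold = 1,
                               flank_bp = 10) {
  stopifnot(cover_threshold >= 1)
  if (nrow(transcripts) == 0L) {
    return(tibble::tibble(cds_id = character(), ordinal = integer(),
                          mean_depth = numeric(),
                          covered_fraction_pct = numeric(),
                          depth_bin = character()))
  }
  spans <- transcripts |>
    dplyr::mutate(span_start = pmax(0, .data$start - flank_bp),
                  span_end = .data$end + flank_bp,
                  cds_id = paste0(.data$gene_id, ".", .data$transcript_id,
                                  ".CDS", .data$ordinal))
  span_gr <- GenomicRanges::GRanges(
    spans$chrom, IRanges::IRanges(spans$span_start + 1, spans$span_end))
  n <- nrow(spans)
  depth_sum <- numeric(n)
  covered <- numeric(n)
  if (nrow(profile)) {
    pos_gr <- GenomicRanges::GRanges(
      profile$chrom, IRanges::IRanges(profile$pos + 1, profile$pos + 1))
    hits <- GenomicRanges::findOverlaps(pos_gr, span_gr)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    d <- profile$depth[qh]
    depth_sum <- as.numeric(tapply(d, factor(sh, levels = seq_len(n)), sum,
                                   default = 0))
    covered <- as.numeric(tapply(d >= cover_threshold,
                                 factor(sh, levels = seq_len(n)), sum,
                                 default = 0))
    depth_sum[is.na(depth_sum)] <- 0
    covered[is.na(covered)] <- 0
  }
  width <- spans$span_end - spans$span_start
  mean_depth <- ifelse(width > 0, depth_sum / width, 0)
  tibble::tibble(
    cds_id = spans$cds_id,
    ordinal = spans$ordinal,
    mean_depth = mean_depth,
    covered_fraction_pct = ifelse(width > 0, 100 * covered / width, 0),
    depth_bin = depth_bin_of(mean_depth)
  )
}

#' Depth bin of a mean depth
#'
#' Half-open bins \[0,30), \[30,100), \[100,Inf): 30x and 100x land in the
#' upper bin.
#'
#' @param mean_depth numeric vector of mean depths.
#' @return character vector: `"low"`, `"mid"` or `"high"`.
#' @export
depth_bin_of <- function(mean_depth) {
  cut(mean_depth, breaks = c(-Inf, 30, 100, Inf), right = FALSE,
      labels = c("low", "mid", "high")) |> as.character()
}

#' Depth-bin summary across CDS regions
#'
#' Distribution of CDS regions over the three depth bins, with the mean
#' covered fraction inside each bin. Bin fractions are rounded half-up to
#' 2 decimals and sum to 100 up to rounding.
#'
#' @param stats output of [cds_coverage_stats()].
#' @return list with `summary` (tibble: `depth_bin`, `n_cds`,
#'   `fraction_of_cds_pct`, `mean_coverage_pct`) and `n_cds_total`.
#' @export
bin_depth_summary <- function(stats) {
  if (nrow(stats) == 0L) abort("no CDS statistics to summarize")
  bins <- c("low", "mid", "high")
  n_tot <- nrow(stats)
  out <- lapply(bins, function(b) {
    sub <- stats[stats$depth_bin == b, ]
    tibble::tibble(
      depth_bin = b,
      n_cds = nrow(sub),
      fraction_of_cds_pct = round_half_up(100 * nrow(sub) / n_tot, 2),
      mean_coverage_pct = if (nrow(sub)) round_half_up(mean(sub$covered_fraction_pct), 2) else NA_real_
    )
  })
  list(summary = dplyr::bind_rows(out), n_cds_total = n_tot)
}

#' Zero-coverage CDS report
#'
#' Identifies CDS regions with no covered base at all and reports which
#' fraction of them are first coding exons (ordinal 1) -- the segment next
#' to the GC-rich 5' UTR, where hybridization capture drops out most.
#'
#' @param stats output of [cds_coverage_stats()].
#' @return list with `zero_cov_ids` and `cds1_fraction_pct` (whole
#'   percent; 0 when there is no zero-coverage CDS).
#' @export
zero_coverage_report <- function(stats) {
  zero <- stats[stats$covered_fraction_pct == 0, ]
  if (nrow(zero) == 0L) {
    return(list(zero_cov_ids = character(), cds1_fraction_pct = 0))
  }
  list(zero_cov_ids = zero$cds_id,
       cds1_fraction_pct = round_half_up(100 * sum(zero$ordinal == 1L) / nrow(zero), 0))
}

#' Does a sample meet the recommended mean depth?
#'
#' Deduplicated mean depth of at least `min_mean` (default 100x) over the
#' captured positions is the working recommendation for reliable coverage
#' on this panel.
#'
#' @param profile a `depth_profile`.
#' @param min_mean recommended minimum mean depth.
#' @return logical.
#' @export
meets_recommended_depth <- function(profile, min_mean = 100) {
  nrow(profile) > 0 && mean(profile$depth) >= min_mean
}
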
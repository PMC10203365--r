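#' Panel design configuration
#'
#' Tunables for capture-region construction. Defaults are the rules the
#' panel was designed under: every CDS of the representative transcript
#' extended 10 bp each side to catch splice-site variation, abnormality
#' regions marked by one random 100 bp CDS tile per selected gene, and the
#' gene-count strata at 15 and 40 genes that decide how many bystander
#' genes get a tile.
#'
#' @param flank_bp bases added on both sides of each CDS (default 10).
#' @param tile_bp tile length for abnormality-region marking (default 100).
#' @param small_region_max_genes regions with at most this many non-major
#'   genes tile every gene (default 15).
#' @param medium_region_max_genes exclusive upper bound of the middle
#'   stratum, which tiles two of every three genes (default 40); at or
#'   above it every other gene is tiled.
#' @param genome_length denominator for the genome-fraction statistic
#'   (default 3e9 bp, the approximate human genome).
#' @param seed base seed for tile placement.
#' @return a `panel_design_config` list.
#' @export
panel_design_config <- function(flank_bp = 10L, tile_bp = 100L,
                                small_region_max_genes = 15L,
                                medium_region_max_genes = 40L,
                                genome_length = 3e9, seed = 1L) {
  stopifnot(flank_bp >= 0, tile_bp >= 1,
            small_region_max_genes > 0,
            small_region_max_genes < medium_region_max_genes,
            genome_length > 0)
  structure(list(flank_bp = as.integer(flank_bp), tile_bp = as.integer(tile_bp),
                 small_region_max_genes = as.integer(small_region_max_genes),
                 medium_region_max_genes = as.integer(medium_region_max_genes),
                 genome_length = genome_length, seed = as.integer(seed)),
            class = "panel_design_config")
}

#' Select the representative transcript of a gene
#'
#' With no usage-frequency source, "most common or longest" resolves to the
#' transcript with the largest summed CDS length; ties break to the
#' lexicographically smallest `transcript_id`, so the choice is independent
#' of input order.
#'
#' @param candidates CDS table (as from [read_gene_models()]) for one gene;
#'   may contain several transcripts.
#' @return the CDS rows of the chosen transcript.
#' @export
select_representative_transcript <- function(candidates) {
  if (nrow(candidates) == 0L) abort("no candidate transcripts")
  if (length(unique(candidates$gene_id)) != 1L) {
    abort("candidates must all belong to one gene")
  }
  sums <- candidates |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(len = sum(.data$end - .data$start), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$len), .data$transcript_id)
  dplyr::filter(candidates, .data$transcript_id == sums$transcript_id[1])
}

#' Merge intervals into a disjoint sorted union
#'
#' Overlapping and book-ended (end == start) intervals are merged; the
#' union of covered bases is preserved exactly. Delegates to
#' [IRanges::reduce()] per chromosome.
#'
#' @param intervals tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return `genomic_intervals` tibble, sorted, pairwise disjoint.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  gr <- GenomicRanges::reduce(as_granges0(intervals))
  gr <- GenomicRanges::sort(gr)
  genomic_intervals(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
}

#' Capture targets for one gene (CDS + flanks)
#'
#' Every CDS of the transcript is extended `flank_bp` on both sides
#' (clamped at position 0), and overlapping or adjacent extended spans are
#' merged. UTRs are never captured: a transcript with no CDS yields no
#' targets.
#'
#' @param transcript CDS rows of one transcript.
#' @param cfg a [panel_design_config()].
#' @return tibble of capture targets with `provenance = "gene_cds"`.
#' @export
design_gene_capture <- function(transcript, cfg = panel_design_config()) {
  if (nrow(transcript) == 0L) {
    return(empty_targets())
  }
  ext <- genomic_intervals(chrom = transcript$chrom,
                           start = pmax(0, transcript$start - cfg$flank_bp),
                           end = transcript$end + cfg$flank_bp,
                           label = transcript$gene_id[1])
  merged <- merge_intervals(ext)
  tibble::tibble(chrom = merged$chrom, start = merged$start, end = merged$end,
                 label = transcript$gene_id[1],
                 provenance = "gene_cds", gene_id = transcript$gene_id[1])
}

empty_targets <- function() {
  tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                 label = character(), provenance = character(),
                 gene_id = character())
}

# which 0-based gene indices (after sorting by CDS-union start) get a tile
tile_gene_indices <- function(n, cfg) {
  if (n <= cfg$small_region_max_genes) {
    seq_len(n)
  } else if (n < cfg$medium_region_max_genes) {
    # groups of three consecutive genes; the first two of each group
    idx <- seq_len(n)
    keep <- ((idx - 1L) %% 3L) < 2L
    idx[keep]
  } else {
    seq(1L, n, by = 2L)
  }
}

#' Random CDS tiles marking bystander genes of an abnormality region
#'
#' Non-major genes inside a chromosomal-abnormality region are marked by a
#' single random tile of at most `tile_bp` bases on their CDS. How many
#' genes get a tile depends on the gene count `n`: all of them when
#' `n <= 15`, two of every three when `15 < n < 40` (genes ordered by CDS
#' start; the partial final group contributes up to its first two), and
#' every other gene when `n >= 40`. The tile sits inside a single CDS,
#' chosen with probability proportional to CDS length, at a uniform offset;
#' a CDS shorter than `tile_bp` is captured whole. Placement is
#' deterministic for a fixed `cfg$seed`.
#'
#' @param region one row of an abnormality table (needs `disease` or
#'   `label` for seed derivation; used only to decorrelate regions).
#' @param genes_in_region CDS table of the region's non-major genes
#'   (representative transcripts).
#' @param cfg a [panel_design_config()].
#' @return tibble of `cnv_tile` capture targets, one per selected gene.
#' @export
sample_region_tiles <- function(region, genes_in_region,
                                cfg = panel_design_config()) {
  if (nrow(genes_in_region) == 0L) return(empty_targets())
  region_tag <- if (!is.null(region$disease)) region$disease[1] else
    if (!is.null(region$label)) region$label[1] else "region"
  per_gene <- genes_in_region |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(cds_start = min(.data$start), .groups = "drop") |>
    dplyr::arrange(.data$cds_start, .data$gene_id)
  chosen <- per_gene$gene_id[tile_gene_indices(nrow(per_gene), cfg)]
  out <- vector("list", length(chosen))
  withr::with_seed(as.integer(str_seed(region_tag, cfg$seed)) %% 2147483646L + 1L, {
    for (i in seq_along(chosen)) {
      g <- dplyr::filter(genes_in_region, .data$gene_id == chosen[i])
      widths <- g$end - g$start
      if (all(widths <= 0)) {
        warn(sprintf("gene %s has no CDS bases; skipped for tiling", chosen[i]))
        next
      }
      k <- sample.int(nrow(g), 1L, prob = widths)
      w <- widths[k]
      if (w <= cfg$tile_bp) {
        s <- g$start[k]; e <- g$end[k]
      } else {
        off <- sample.int(w - cfg$tile_bp + 1L, 1L) - 1L
        s <- g$start[k] + off; e <- s + cfg$tile_bp
      }
      out[[i]] <- tibble::tibble(chrom = g$chrom[k], start = s, end = e,
                                 label = paste0(chosen[i], ".tile"),
                                 provenance = "cnv_tile", gene_id = chosen[i])
    }
  })
  dplyr::bind_rows(out)
}

#' Build the full capture panel
#'
#' Composes (I) per-gene CDS capture for every gene in the gene table,
#' (II) full capture of each region's major pathogenic genes, and random
#' tiles on the region's remaining genes. Pre-merge targets keep their
#' provenance; a merged disjoint track is returned alongside.
#'
#' @param gene_table CDS table of all panel genes (all candidate
#'   transcripts; representative transcripts are selected per gene).
#' @param regions abnormality table (as from [read_abnormality_table()]).
#' @param region_gene_index tibble `(disease, gene_id, major)` listing the
#'   genes contained in each region and whether each is a major pathogenic
#'   gene (captured in full).
#' @param cfg a [panel_design_config()].
#' @param panel_genes gene ids receiving full single-gene-disease capture
#'   (part I). Defaults to every gene in `gene_table` except genes that
#'   appear only as non-major bystanders of abnormality regions (those
#'   get tiles, not full capture).
#' @return list with `targets` (pre-merge, with provenance) and `merged`
#'   (disjoint union), of class `capture_panel`.
#' @export
build_panel <- function(gene_table, regions = NULL, region_gene_index = NULL,
                        cfg = panel_design_config(), panel_genes = NULL) {
  reps <- if (nrow(gene_table)) {
    gene_table |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::group_split() |>
      lapply(select_representative_transcript) |>
      dplyr::bind_rows()
  } else {
    empty_cds_table()
  }
  if (is.null(panel_genes)) {
    bystander_only <- if (!is.null(region_gene_index)) {
      setdiff(region_gene_index$gene_id[!region_gene_index$major],
              region_gene_index$gene_id[region_gene_index$major])
    } else {
      character()
    }
    panel_genes <- setdiff(unique(gene_table$gene_id), bystander_only)
  }
  parts <- list()
  part1 <- dplyr::filter(reps, .data$gene_id %in% panel_genes)
  if (nrow(part1)) {
    parts <- part1 |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::group_split() |>
      lapply(design_gene_capture, cfg = cfg)
  }
  if (!is.null(regions) && nrow(regions)) {
    if (is.null(region_gene_index)) {
      abort("regions supplied without a region_gene_index")
    }
    for (r in seq_len(nrow(regions))) {
      reg <- regions[r, ]
      idx <- dplyr::filter(region_gene_index, .data$disease == reg$disease)
      unknown <- setdiff(idx$gene_id, unique(gene_table$gene_id))
      if (length(unknown)) {
        abort(sprintf("region '%s' references unknown gene '%s'",
                      reg$disease, unknown[1]))
      }
      majors <- idx$gene_id[idx$major]
      others <- idx$gene_id[!idx$major]
      if (length(majors)) {
        parts <- c(parts, reps |>
                     dplyr::filter(.data$gene_id %in% majors) |>
                     dplyr::group_by(.data$gene_id) |>
                     dplyr::group_split() |>
                     lapply(function(tx) {
                       t <- design_gene_capture(tx, cfg)
                       t$provenance <- "cnv_full_gene"
                       t
                     }))
      }
      if (length(others)) {
        parts <- c(parts, list(sample_region_tiles(
          reg, dplyr::filter(reps, .data$gene_id %in% others), cfg)))
      }
    }
  }
  targets <- dplyr::bind_rows(parts)
  if (nrow(targets) == 0L) targets <- empty_targets()
  structure(list(targets = targets, merged = merge_intervals(targets)),
            class = "capture_panel")
}

#' Panel summary statistics
#'
#' @param panel a `capture_panel` (or a plain targets tibble).
#' @param genome_length denominator for the genome fraction, bp.
#' @return list with `n_targets`, `total_bp` (merged union) and
#'   `genome_fraction_pct` (rounded half-up to 2 decimals).
#' @export
#' @examples
#' # 10 Mb of merged targets against a 3 Gb genome is 0.33 %
summarize_panel <- function(panel, genome_length = 3e9) {
  if (genome_length <= 0) abort("genome_length must be > 0")
  targets <- if (inherits(panel, "capture_panel")) panel$targets else panel
  merged <- if (inherits(panel, "capture_panel")) panel$merged else merge_intervals(panel)
  total_bp <- sum(merged$end - merged$start)
  list(n_targets = nrow(targets),
       total_bp = total_bp,
       genome_fraction_pct = round_half_up(100 * total_bp / genome_length, 2))
}
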
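#' Read gene models from GFF3/GTF
#'
#' Parses `gene`/`mRNA`/`CDS` features and returns one row per CDS, grouped
#' under its parent transcript, with coordinates converted from the 1-based
#' closed GFF convention to the package's 0-based half-open convention and
#' translation-order ordinals assigned strand-aware (ordinal 1 is the
#' 5'-most CDS on `+`, the 3'-most genomic CDS on `-`).
#'
#' @param file path to a GFF3 (or GTF) file. Parsing itself is delegated to
#'   [rtracklayer::import()]; this function validates the feature hierarchy.
#' @param format `"gff3"` (default) or `"gtf"`.
#' @return tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open), `ordinal`.
#' @export
read_gene_models <- function(file, format = c("gff3", "gtf")) {
  format <- match.arg(format)
  gr <- tryCatch(
    rtracklayer::import(file, format = format),
    error = function(e) abort(paste0("gene model format error: ", conditionMessage(e)))
  )
  type <- as.character(gr$type)
  if (format == "gtf") {
    cds <- gr[type == "CDS"]
    if (length(cds) == 0L) {
      return(empty_cds_table())
    }
    tx_of_cds <- as.character(cds$transcript_id)
    gene_of_cds <- as.character(cds$gene_id)
    if (any(is.na(tx_of_cds))) abort("gene model format error: CDS without transcript_id")
  } else {
    mrna <- gr[type %in% c("mRNA", "transcript")]
    genes <- gr[type == "gene"]
    cds <- gr[type == "CDS"]
    if (length(cds) == 0L) {
      return(empty_cds_table())
    }
    feat_id <- function(x) {
      if (!is.null(x$ID)) as.character(x$ID) else rep(NA_character_, length(x))
    }
    first_parent <- function(x) {
      p <- x$Parent
      if (is.null(p)) return(rep(NA_character_, length(x)))
      vapply(as.list(p), function(v) if (length(v)) as.character(v[[1]]) else NA_character_, "")
    }
    mrna_id <- feat_id(mrna)
    mrna_gene <- first_parent(mrna)
    cds_parent <- first_parent(cds)
    unknown <- is.na(cds_parent) | !(cds_parent %in% mrna_id)
    if (any(unknown)) {
      bad <- cds[which(unknown)[1]]
      abort(sprintf(
        "gene model format error: CDS at %s:%d-%d references no known transcript parent (Parent=%s)",
        as.character(GenomicRanges::seqnames(bad)),
        GenomicRanges::start(bad), GenomicRanges::end(bad),
        cds_parent[which(unknown)[1]]
      ))
    }
    tx_of_cds <- cds_parent
    gene_of_cds <- mrna_gene[match(cds_parent, mrna_id)]
    # genes without explicit gene rows keep the transcript's Parent string
    gene_of_cds[is.na(gene_of_cds)] <- tx_of_cds[is.na(gene_of_cds)]
  }
  out <- tibble::tibble(
    gene_id = gene_of_cds,
    transcript_id = tx_of_cds,
    chrom = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds) - 1L,
    end = as.integer(GenomicRanges::end(cds))
  )
  out <- dplyr::arrange(out, .data$gene_id, .data$transcript_id, .data$start)
  out <- dplyr::group_by(out, .data$transcript_id)
  out <- dplyr::mutate(out, ordinal = if (.data$strand[1] == "-") rev(seq_len(dplyr::n())) else seq_len(dplyr::n()))
  dplyr::ungroup(out)
}

empty_cds_table <- function() {
  tibble::tibble(gene_id = character(), transcript_id = character(),
                 chrom = character(), strand = character(),
                 start = integer(), end = integer(), ordinal = integer())
}

#' Read a chromosomal-abnormality region table
#'
#' Reads a TSV with columns `Disease`, `Chromosome`, `Start`, `End` and an
#' optional `MajorGenes` column (comma-separated gene ids). Coordinates are
#' stored verbatim as printed; sizes are computed as `End - Start` (see
#' [region_size()]). Row order is preserved and duplicate disease names on
#' different chromosomes stay distinct records.
#'
#' @param file path to the TSV.
#' @return tibble with columns `disease`, `chrom`, `start`, `end`,
#'   `major_genes` (list column of character vectors).
#' @export
#' @examples
#' tab <- read_abnormality_table(panelsmith_example("chromosomal_abnormalities.tsv"))
#' nrow(tab) # 148
read_abnormality_table <- function(file) {
  raw <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "")
  need <- c("Disease", "Chromosome", "Start", "End")
  if (!all(need %in% names(raw))) {
    abort(paste0("abnormality table must have columns ",
                 paste(need, collapse = ", ")))
  }
  start <- suppressWarnings(as.numeric(raw$Start))
  end <- suppressWarnings(as.numeric(raw$End))
  bad_num <- which(is.na(start) | is.na(end) |
                     start != trunc(start) | end != trunc(end))
  if (length(bad_num)) {
    abort(sprintf("abnormality table row %d: non-integer coordinate", bad_num[1]))
  }
  bad_ord <- which(start >= end)
  if (length(bad_ord)) {
    abort(sprintf("abnormality table row %d ('%s'): Start >= End",
                  bad_ord[1], raw$Disease[bad_ord[1]]))
  }
  majors <- if ("MajorGenes" %in% names(raw)) {
    lapply(raw$MajorGenes, function(x) {
      x <- trimws(strsplit(as.character(x), ",")[[1]])
      x[nzchar(x) & !is.na(x)]
    })
  } else {
    rep(list(character()), nrow(raw))
  }
  tibble::tibble(disease = as.character(raw$Disease),
                 chrom = as.character(raw$Chromosome),
                 start = start, end = end, major_genes = majors)
}

#' Path to a bundled example/fixture file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path (or a vector of file names).
#' @export
panelsmith_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "panelsmith")))
  }
  path <- system.file("extdata", file, package = "panelsmith")
  if (!nzchar(path)) abort(sprintf("no bundled file '%s'", file))
  path
}

#' Read a per-base depth table
#'
#' Three tab-separated columns in `samtools depth` style: chromosome,
#' 1-based position, integer depth. Positions are stored 0-based
#' internally; positions absent from the table are depth 0 by contract.
#'
#' @param file path to the TSV (no header).
#' @param sample_id sample identifier attached to the profile.
#' @param source_reads optional total read count behind the profile (used
#'   by [downsample_spec()] to turn a target read count into a fraction).
#' @return a `depth_profile`: tibble `(chrom, pos, depth)` with `pos`
#'   0-based, plus `sample_id`/`source_reads` attributes.
#' @export
read_depth_table <- function(file, sample_id = basename(file), source_reads = NULL) {
  raw <- tryCatch(
    utils::read.delim(file, header = FALSE, sep = "\t",
                      colClasses = c("character", "numeric", "numeric"),
                      col.names = c("chrom", "pos", "depth"), quote = ""),
    error = function(e) {
      # empty file is a valid empty profile
      if (grepl("no lines available", conditionMessage(e))) return(NULL)
      abort(paste0("depth table format error: ", conditionMessage(e)))
    }
  )
  if (is.null(raw) || nrow(raw) == 0L) {
    return(depth_profile(tibble::tibble(chrom = character(), pos = integer(),
                                        depth = integer()),
                         sample_id = sample_id, source_reads = source_reads))
  }
  if (any(is.na(raw$depth)) || any(raw$depth < 0)) {
    abort("depth table format error: negative or non-numeric depth")
  }
  depth_profile(tibble::tibble(chrom = raw$chrom,
                               pos = as.numeric(raw$pos) - 1,
                               depth = as.numeric(raw$depth)),
                sample_id = sample_id, source_reads = source_reads)
}

#' Construct a depth profile
#'
#' @param depths tibble with columns `chrom`, `pos` (0-based), `depth`.
#' @param sample_id sample identifier.
#' @param source_reads optional total read count.
#' @return tibble of class `depth_profile`.
#' @export
depth_profile <- function(depths, sample_id = "sample", source_reads = NULL) {
  stopifnot(all(c("chrom", "pos", "depth") %in% names(depths)))
  if (any(depths$depth < 0)) abort("depths must be >= 0")
  out <- tibble::as_tibble(depths[, c("chrom", "pos", "depth")])
  attr(out, "sample_id") <- sample_id
  attr(out, "source_reads") <- source_reads
  class(out) <- c("depth_profile", class(out))
  out
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> sample %s: %d positions, mean depth %.1f\n",
              attr(x, "sample_id"), nrow(x),
              if (nrow(x)) mean(x$depth) else 0))
  invisible(x)
}

#' Read genotyped sites from a minimal single-sample VCF
#'
#' Understands VCF v4.x with a `GT` entry in FORMAT (the all-sites output of
#' an emit-all-sites genotyper). Phased and unphased separators are treated
#' identically; `./.` (or `.|.`) is a missing genotype, marked uncovered and
#' never genotype-identical to anything, including another missing site.
#'
#' @param file path to the VCF.
#' @return tibble with columns `chrom`, `pos` (1-based), `a1`, `a2`
#'   (allele strings, unordered pair sorted lexicographically), `covered`.
#' @export
read_site_table <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  fmt <- v@gt
  if (is.null(fmt) || ncol(fmt) < 2L) {
    abort("site table format error: VCF has no sample genotype column")
  }
  keys <- strsplit(fmt[, 1], ":", fixed = TRUE)
  gt_idx <- vapply(keys, function(k) match("GT", k), 0L)
  if (any(is.na(gt_idx))) {
    abort("site table format error: record without GT in FORMAT")
  }
  raw_gt <- mapply(function(cell, i) strsplit(cell, ":", fixed = TRUE)[[1]][i],
                   fmt[, 2], gt_idx, USE.NAMES = FALSE)
  alleles <- strsplit(gsub("|", "/", raw_gt, fixed = TRUE), "/", fixed = TRUE)
  ref <- fx[, "REF"]
  alt <- strsplit(ifelse(is.na(fx[, "ALT"]), "", fx[, "ALT"]), ",", fixed = TRUE)
  resolve <- function(code, r, a) {
    if (is.na(code) || code == ".") return(NA_character_)
    i <- suppressWarnings(as.integer(code))
    if (is.na(i)) return(NA_character_)
    if (i == 0L) r else if (i <= length(a)) a[i] else NA_character_
  }
  n <- nrow(fx)
  a1 <- character(n); a2 <- character(n)
  for (i in seq_len(n)) {
    al <- alleles[[i]]
    x1 <- resolve(al[1], ref[i], alt[[i]])
    x2 <- resolve(if (length(al) > 1) al[2] else al[1], ref[i], alt[[i]])
    pair <- sort(c(x1, x2), na.last = TRUE)
    a1[i] <- pair[1]; a2[i] <- pair[2]
  }
  missing <- is.na(a1) | is.na(a2)
  tibble::tibble(chrom = fx[, "CHROM"],
                 pos = as.numeric(fx[, "POS"]),
                 a1 = a1, a2 = a2,
                 covered = !missing)
}

#' Write / read BED3+1
#'
#' `write_bed()` emits `chrom`, `start`, `end`, `label` (0-based half-open,
#' the internal convention, so no coordinate shift happens); `read_bed()`
#' inverts it. Reading a written file is the identity on
#' `(chrom, start, end, label)`.
#'
#' @param intervals a `genomic_intervals` tibble (or any tibble with those
#'   columns).
#' @param file path to write to / read from.
#' @return `write_bed()` returns `file` invisibly; `read_bed()` returns a
#'   `genomic_intervals` tibble.
#' @export
write_bed <- function(intervals, file) {
  if (nrow(intervals) == 0L) {
    file.create(file)
    return(invisible(file))
  }
  gr <- as_granges0(intervals)
  names(gr) <- if ("label" %in% names(intervals)) intervals$label else NULL
  rtracklayer::export(gr, file, format = "bed")
  invisible(file)
}

#' @rdname write_bed
#' @export
read_bed <- function(file) {
  if (file.size(file) == 0L) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  gr <- rtracklayer::import(file, format = "bed")
  genomic_intervals(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    label = if (!is.null(gr$name)) gr$name else NA_character_)
}

#' Interval size in bp, Kb or Mb
#'
#' Size is `end - start` (half-open width; the same arithmetic the printed
#' abnormality tables use, e.g. 51,244,066 - 49,411,085 = 1,832,981 bp ->
#' 1.83 Mb). Kb and Mb are rounded half-up to 2 decimals; bp is exact.
#'
#' @param intervals tibble with `start` and `end` columns (one or more rows).
#' @param unit `"bp"`, `"Kb"` or `"Mb"`.
#' @return numeric vector of sizes.
#' @export
#' @examples
#' region_size(tibble::tibble(start = 69783279, end = 69952448), "Kb") # 169.17
region_size <- function(intervals, unit = c("bp", "Kb", "Mb")) {
  unit <- match.arg(unit)
  bp <- intervals$end - intervals$start
  if (any(bp < 0)) abort("intervals require end >= start")
  switch(unit,
         bp = bp,
         Kb = round_half_up(bp / 1e3, 2),
         Mb = round_half_up(bp / 1e6, 2))
}
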
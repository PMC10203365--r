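# Fixture builders and independent oracles shared across the test files.

write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a tiny two-CDS gene in GFF3 (1-based closed coordinates)
gff_two_cds <- function(strand = "+") {
  c("##gff-version 3",
    sprintf("chr1\ttest\tgene\t101\t400\t.\t%s\t.\tID=G1", strand),
    sprintf("chr1\ttest\tmRNA\t101\t400\t.\t%s\t.\tID=G1.T1;Parent=G1", strand),
    sprintf("chr1\ttest\tCDS\t101\t200\t.\t%s\t0\tID=c1;Parent=G1.T1", strand),
    sprintf("chr1\ttest\tCDS\t301\t400\t.\t%s\t0\tID=c2;Parent=G1.T1", strand))
}

write_vcf <- function(records, sample = "S1") {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample),
    records)
}

vcf_rec <- function(chrom, pos, ref, alt, gt) {
  sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s", chrom, pos, ref, alt, gt)
}

# uniform-depth profile over [start, end) of one chromosome
flat_profile <- function(chrom, start, end, depth, sample_id = "S") {
  pos <- seq(start, end - 1)
  depth_profile(tibble::tibble(chrom = chrom, pos = pos,
                               depth = rep(depth, length(pos))),
                sample_id = sample_id)
}

# brute-force union of interval bases on one chromosome (mask oracle)
mask_union_bp <- function(starts, ends, limit = max(ends) + 1) {
  mask <- logical(limit)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) mask[(starts[i] + 1):ends[i]] <- TRUE
  }
  sum(mask)
}

mask_union_spans <- function(starts, ends) {
  limit <- max(ends) + 1
  mask <- logical(limit)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) mask[(starts[i] + 1):ends[i]] <- TRUE
  }
  r <- rle(mask)
  stops <- cumsum(r$lengths)
  starts0 <- stops - r$lengths
  tibble::tibble(start = starts0[r$values], end = stops[r$values])
}

# group-enumeration oracle for the tile-count law
tile_count_oracle <- function(n, small_max = 15, medium_max = 40) {
  if (n <= small_max) return(n)
  if (n < medium_max) {
    groups <- split(seq_len(n), ceiling(seq_len(n) / 3))
    return(sum(vapply(groups, function(g) min(2L, length(g)), 0L)))
  }
  sum(seq_len(n) %% 2 == 1)
}

# n_genes single-CDS genes laid out along a chromosome
single_cds_genes <- function(n_genes, cds_len = 200, spacing = 1000) {
  starts <- seq(0, by = spacing, length.out = n_genes)
  tibble::tibble(gene_id = sprintf("g%03d", seq_len(n_genes)),
                 transcript_id = sprintf("g%03d.t1", seq_len(n_genes)),
                 chrom = "chr1", strand = "+",
                 start = starts, end = starts + cds_len,
                 ordinal = 1L)
}

# sparse tile panel for CNV simulations: 100 bp targets every `spacing` bp
sparse_panel <- function(span_bp = 12e6, spacing = 70000, width = 100) {
  starts <- seq(0, span_bp - width, by = spacing)
  tibble::tibble(chrom = "chr1", start = starts, end = starts + width,
                 label = NA_character_)
}
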
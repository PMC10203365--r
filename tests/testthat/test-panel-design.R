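test_that("representative transcript maximizes CDS length with order-independent tie-break", {
  two_tx <- tibble::tibble(
    gene_id = "G1",
    transcript_id = c("T1", "T1", "T2", "T2", "T2"),
    chrom = "chr1", strand = "+",
    start = c(0, 500, 1000, 2000, 3000),
    end = c(400, 1000, 1400, 2400, 3400),
    ordinal = c(1L, 2L, 1L, 2L, 3L))
  # T1 sums 900, T2 sums 1200
  expect_equal(unique(select_representative_transcript(two_tx)$transcript_id), "T2")

  tie <- tibble::tibble(gene_id = "G1",
                        transcript_id = c("NM_002", "NM_001"),
                        chrom = "chr1", strand = "+",
                        start = c(0, 5000), end = c(1000, 6000),
                        ordinal = 1L)
  # oracle: stable sort of (-(length), id) picks NM_001 under any input order
  for (perm in list(1:2, 2:1)) {
    expect_equal(unique(select_representative_transcript(tie[perm, ])$transcript_id),
                 "NM_001")
  }
  expect_error(select_representative_transcript(tie[0, ]), "no candidate")
})

test_that("gene capture extends CDS by the flank and merges overlapping spans", {
  one <- tibble::tibble(gene_id = "G1", transcript_id = "T1", chrom = "chr1",
                        strand = "+", start = 100, end = 200, ordinal = 1L)
  t1 <- design_gene_capture(one, panel_design_config(flank_bp = 10))
  expect_equal(t1$start, 90); expect_equal(t1$end, 210)
  expect_equal(t1$provenance, "gene_cds")

  # extended spans (90,210) and (194,310) overlap -> single merged target;
  # oracle: the union of the two base sets
  two <- dplyr::bind_rows(one, tibble::tibble(
    gene_id = "G1", transcript_id = "T1", chrom = "chr1", strand = "+",
    start = 204, end = 300, ordinal = 2L))
  t2 <- design_gene_capture(two, panel_design_config(flank_bp = 10))
  expect_equal(nrow(t2), 1L)
  expect_equal(c(t2$start, t2$end), c(90, 310))
  expect_equal(t2$end - t2$start, mask_union_bp(c(90, 194), c(210, 310)))

  # UTR-only transcript: nothing captured
  expect_equal(nrow(design_gene_capture(one[0, ])), 0L)

  # flank clamps at zero
  near0 <- tibble::tibble(gene_id = "G", transcript_id = "T", chrom = "chr1",
                          strand = "+", start = 4, end = 50, ordinal = 1L)
  expect_equal(design_gene_capture(near0)$start, 0)
})

test_that("merge_intervals matches the base-mask oracle and is idempotent", {
  expect_equal(merge_intervals(tibble::tibble(
    chrom = "chr1", start = c(0, 10), end = c(10, 20)))$end, 20)
  m <- merge_intervals(tibble::tibble(chrom = "chr1",
                                      start = c(5, 0), end = c(9, 3)))
  expect_equal(m$start, c(0, 5)); expect_equal(m$end, c(3, 9))

  withr::with_seed(11, {
    for (rep in 1:10) {
      n <- 200
      s <- sample.int(5e3, n); w <- sample.int(300, n)
      iv <- tibble::tibble(chrom = "chr1", start = s, end = s + w)
      merged <- merge_intervals(iv)
      oracle <- mask_union_spans(iv$start, iv$end)
      expect_equal(merged$start, oracle$start)
      expect_equal(merged$end, oracle$end)
      # idempotent and order-invariant
      expect_equal(merge_intervals(merged)[, c("start", "end")],
                   merged[, c("start", "end")])
      expect_equal(merge_intervals(iv[sample.int(n), ])$start, merged$start)
    }
  })
})

test_that("tile counts follow the three gene-count strata", {
  cfg <- panel_design_config(seed = 3)
  region <- tibble::tibble(disease = "test region")
  for (n in c(1, 12, 15, 16, 20, 39, 40, 41, 80)) {
    tiles <- sample_region_tiles(region, single_cds_genes(n), cfg)
    expect_equal(nrow(tiles), tile_count_oracle(n), info = paste("n =", n))
  }
  # spelled-out cases: n=16 gives 5 full triples x 2 + min(1,2) = 11; n=40
  # keeps every other gene = 20
  expect_equal(nrow(sample_region_tiles(region, single_cds_genes(16), cfg)), 11L)
  expect_equal(nrow(sample_region_tiles(region, single_cds_genes(40), cfg)), 20L)
})

test_that("tiles stay inside their gene's CDS, respect tile_bp, and are seed-deterministic", {
  genes <- single_cds_genes(12, cds_len = 250)
  genes$end[1] <- genes$start[1] + 60 # shorter than tile_bp: captured whole
  cfg <- panel_design_config(seed = 5)
  tiles <- sample_region_tiles(tibble::tibble(disease = "R"), genes, cfg)
  expect_equal(nrow(tiles), 12L)
  expect_true(all(tiles$end - tiles$start <= cfg$tile_bp))
  for (i in seq_len(nrow(tiles))) {
    g <- genes[genes$gene_id == tiles$gene_id[i], ]
    expect_true(any(tiles$start[i] >= g$start & tiles$end[i] <= g$end))
  }
  expect_equal(tiles$start[tiles$gene_id == genes$gene_id[1]], genes$start[1])

  again <- sample_region_tiles(tibble::tibble(disease = "R"), genes, cfg)
  expect_identical(tiles, again)
  # a different seed moves offsets but never counts or gene choices
  other <- sample_region_tiles(tibble::tibble(disease = "R"), genes,
                               panel_design_config(seed = 99))
  expect_equal(other$gene_id, tiles$gene_id)
  expect_equal(nrow(other), nrow(tiles))
})

test_that("build_panel composes gene capture, major genes and tiles", {
  sim <- simulate_gene_models(sim_spec(seed = 23, n_genes = 6))
  cfg <- panel_design_config(seed = 2)

  # one gene, no regions: identical to design_gene_capture of its representative
  g1 <- sim$models[sim$models$gene_id == "G001", ]
  solo <- build_panel(g1, cfg = cfg)
  direct <- design_gene_capture(select_representative_transcript(g1), cfg)
  expect_equal(solo$targets$start, direct$start)
  expect_equal(solo$targets$end, direct$end)

  # a region over three non-major genes adds exactly three tiles
  region <- tibble::tibble(disease = "regA", chrom = "chr1",
                           start = 1, end = 1e6,
                           major_genes = list(character()))
  idx <- tibble::tibble(disease = "regA",
                        gene_id = c("G002", "G003", "G004"),
                        major = FALSE)
  pan <- build_panel(sim$models, region, idx, cfg)
  expect_equal(sum(pan$targets$provenance == "cnv_tile"), 3L)
  # bystander-only genes get tiles, never full part-I capture
  expect_false(any(pan$targets$provenance == "gene_cds" &
                     pan$targets$gene_id %in% idx$gene_id))

  # a gene table holding only the region's bystanders yields exactly 3 tiles
  only_region <- sim$models[sim$models$gene_id %in% idx$gene_id, ]
  pan_tiles <- build_panel(only_region, region, idx, cfg)
  expect_equal(nrow(pan_tiles$targets), 3L)
  expect_true(all(pan_tiles$targets$provenance == "cnv_tile"))

  # major genes are captured in full
  idx$major <- c(TRUE, FALSE, FALSE)
  pan2 <- build_panel(sim$models, region, idx, cfg)
  expect_true(any(pan2$targets$provenance == "cnv_full_gene" &
                    pan2$targets$gene_id == "G002"))
  expect_equal(sum(pan2$targets$provenance == "cnv_tile"), 2L)

  idx_bad <- tibble::tibble(disease = "regA", gene_id = "GHOST", major = FALSE)
  expect_error(build_panel(sim$models, region, idx_bad, cfg), "GHOST")
})

test_that("panel summary reports the merged union and genome fraction", {
  iv <- tibble::tibble(chrom = "chr1", start = 0, end = 1e7,
                       label = NA, provenance = "gene_cds", gene_id = "G")
  s <- summarize_panel(iv, genome_length = 3e9)
  expect_equal(s$total_bp, 1e7)
  expect_equal(s$genome_fraction_pct, 0.33)

  # duplicated targets add no union bases
  s2 <- summarize_panel(dplyr::bind_rows(iv, iv), genome_length = 3e9)
  expect_equal(s2$total_bp, 1e7)

  empty <- summarize_panel(iv[0, ], genome_length = 3e9)
  expect_equal(empty$total_bp, 0)
  expect_equal(empty$genome_fraction_pct, 0)
  expect_error(summarize_panel(iv, genome_length = 0), "genome_length")
})
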
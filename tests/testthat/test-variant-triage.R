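vrec <- function(id, gene = "GENE1", vtype = "missense", pop_freq = 0.001,
                 hf = FALSE, db = TRUE, mech = FALSE, votes = 0L,
                 zyg = "het", pheno = TRUE, reported = TRUE) {
  tibble::tibble(gene_id = gene, variant_id = id, vtype = vtype,
                 pop_freq = pop_freq, known_pathogenic_hf = hf,
                 db_pathogenic = db, mechanism_deleterious = mech,
                 prediction_damaging_votes = as.integer(votes),
                 zygosity = zyg, phenotype_match = pheno,
                 reported_before = reported)
}
ad_map <- function(genes, model = "AD") tibble::tibble(gene_id = genes, model = model)

test_that("common variants fall at the frequency gate unless rescued as known pathogenic", {
  cfg <- triage_config(inheritance_map = ad_map("GENE1"))
  common <- vrec("v1", pop_freq = 0.05)
  res <- triage_variants(common, cfg)
  expect_equal(nrow(res$kept), 0L)
  expect_equal(res$dropped$failed_rule, "R2")
  expect_equal(res$trace$v1$result[res$trace$v1$rule == "R2"], "fail")

  rescued <- vrec("v2", pop_freq = 0.03, hf = TRUE, db = FALSE, votes = 0L)
  res2 <- triage_variants(rescued, cfg)
  expect_equal(res2$kept$variant_id, "v2")
  expect_equal(res2$trace$v2$result, c("pass", "skip", "skip", "pass"))

  # unknown frequency passes the gate
  unk <- vrec("v3", pop_freq = NA_real_)
  expect_equal(triage_variants(unk, cfg)$kept$variant_id, "v3")
})

test_that("the evidence screen accepts database, mechanism or prediction support", {
  cfg <- triage_config(inheritance_map = ad_map("GENE1"))
  by_votes <- vrec("v1", db = FALSE, mech = FALSE, votes = 2L)
  expect_equal(nrow(triage_variants(by_votes, cfg)$kept), 1L)
  by_mech <- vrec("v2", db = FALSE, mech = TRUE, votes = 0L)
  expect_equal(nrow(triage_variants(by_mech, cfg)$kept), 1L)
  none <- vrec("v3", db = FALSE, mech = FALSE, votes = 1L)
  res <- triage_variants(none, cfg)
  expect_equal(res$dropped$failed_rule, "R3-5")

  # conjunctive mode requires all three
  strict <- triage_config(evidence_mode = "all", inheritance_map = ad_map("GENE1"))
  allev <- vrec("v4", db = TRUE, mech = TRUE, votes = 3L)
  expect_equal(nrow(triage_variants(allev, strict)$kept), 1L)
  expect_equal(nrow(triage_variants(vrec("v5", db = TRUE, mech = FALSE, votes = 3L),
                                    strict)$kept), 0L)
})

test_that("inheritance models gate genotypes; XL hets are carrier-flagged", {
  map <- tibble::tibble(gene_id = c("A1", "R1", "X1"),
                        model = c("AD", "AR", "XL"))
  cfg <- triage_config(inheritance_map = map)
  recs <- dplyr::bind_rows(
    vrec("ad_het", gene = "A1"),
    vrec("ar_het_single", gene = "R1"),
    vrec("ar_hom", gene = "R1", zyg = "hom"),
    vrec("xl_hemi", gene = "X1", zyg = "hemi"),
    vrec("xl_het", gene = "X1", zyg = "het"),
    vrec("no_pheno", gene = "A1", pheno = FALSE))
  res <- triage_variants(recs, cfg)
  expect_setequal(res$kept$variant_id, c("ad_het", "ar_hom", "xl_hemi", "xl_het"))
  expect_true(res$kept$carrier_flag[res$kept$variant_id == "xl_het"])
  expect_false(any(res$kept$carrier_flag[res$kept$variant_id != "xl_het"]))
  expect_equal(res$dropped$failed_rule[res$dropped$variant_id == "ar_het_single"], "R6")
})

test_that("AR compound heterozygotes stand or fall together", {
  cfg <- triage_config(inheritance_map = ad_map("R1", "AR"))
  pair <- dplyr::bind_rows(vrec("h1", gene = "R1"), vrec("h2", gene = "R1"))
  expect_setequal(triage_variants(pair, cfg)$kept$variant_id, c("h1", "h2"))
  # removing either het removes both from the diagnostic set
  expect_equal(nrow(triage_variants(pair[1, ], cfg)$kept), 0L)
  expect_equal(nrow(triage_variants(pair[2, ], cfg)$kept), 0L)
  # and a het knocked out upstream cannot support its partner
  pair$pop_freq[2] <- 0.2
  expect_equal(nrow(triage_variants(pair, cfg)$kept), 0L)
})

test_that("every record lands in exactly one of kept/dropped with a full trace", {
  vt <- simulate_variant_table(sim_spec(seed = 61, planted_pathogenic = 7), 60)
  res <- triage_variants(vt$variants, triage_config(inheritance_map = vt$inheritance))
  expect_equal(nrow(res$kept) + nrow(res$dropped), nrow(vt$variants))
  expect_setequal(c(res$kept$variant_id, res$dropped$variant_id),
                  vt$variants$variant_id)
  expect_setequal(names(res$trace), vt$variants$variant_id)
  expect_true(all(vapply(res$trace, nrow, 0L) == 4L))
})

test_that("triage keeps exactly the planted qualifying records", {
  vt <- simulate_variant_table(sim_spec(seed = 71), 100)
  res <- triage_variants(vt$variants, triage_config(inheritance_map = vt$inheritance))
  expect_setequal(res$kept$variant_id,
                  vt$truth$variant_id[vt$truth$role == "planted"])
})

test_that("lowering the frequency cutoff can only shrink the kept set", {
  vt <- simulate_variant_table(sim_spec(seed = 83, planted_pathogenic = 10), 80)
  kept_at <- function(cut) {
    triage_variants(vt$variants,
                    triage_config(freq_cutoff = cut,
                                  inheritance_map = vt$inheritance))$kept$variant_id
  }
  k_loose <- kept_at(0.5); k_mid <- kept_at(0.01); k_tight <- kept_at(1e-4)
  expect_true(all(k_mid %in% k_loose))
  expect_true(all(k_tight %in% k_mid))
})

test_that("a surviving gene missing from the inheritance map is a configuration error", {
  cfg <- triage_config(inheritance_map = ad_map("OTHER"))
  expect_error(triage_variants(vrec("v1", gene = "GENE1"), cfg), "GENE1")
})

test_that("ddG significance is a strict 1.6 kcal/mol threshold", {
  expect_true(classify_ddg(4.07063))
  expect_false(classify_ddg(-0.138577))
  expect_false(classify_ddg(1.6))
  expect_true(classify_ddg(1.6000001))
  expect_true(is.na(classify_ddg(NA_real_)))
})

test_that("variant summaries count categories and the reported/novel split", {
  kept <- dplyr::bind_rows(
    vrec("m1", vtype = "missense"), vrec("m2", vtype = "missense"),
    vrec("f1", vtype = "frameshift"), vrec("s1", vtype = "splicing"),
    vrec("c1", vtype = "intragenic_cnv", reported = FALSE),
    vrec("w1", vtype = "whole_gene_del", reported = FALSE))
  s <- summarize_variants(kept)
  expect_equal(s$total, 6L)
  expect_equal(s$counts$n[s$counts$vtype == "missense"], 2L)
  expect_equal(s$n_reported, 4L)
  expect_equal(s$n_novel, 2L)

  empty <- summarize_variants(kept[0, ])
  expect_equal(empty$total, 0L)
  expect_true(all(empty$counts$n == 0L))
})
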
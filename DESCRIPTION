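Package: panelsmith
Title: Targeted Capture Panel Design, Coverage QC, Depth-Ratio CNV Calling
    and Variant Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for clinical targeted-capture sequencing panels that
    combine single-gene disease content with recurrent chromosomal
    abnormality regions. Builds capture-region sets from gene models using
    rule-based CDS flanking and random tile sampling of abnormality regions,
    computes per-CDS depth and coverage statistics with depth-bin summaries,
    assesses triple-replicate genotype stability and NGS-versus-array
    concordance, detects intragenic and large copy-number variants from
    batch depth ratios with binomial downsampling sensitivity analysis, and
    prioritizes annotated variants through a six-criterion Mendelian triage
    cascade. Seeded synthetic-data generators provide every input format
    with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    withr,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
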
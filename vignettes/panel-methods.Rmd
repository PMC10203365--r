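---
title: "Methods: panel design rules, QC statistics, depth-ratio CNV calling and variant triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel design rules, QC statistics, depth-ratio CNV calling and variant triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelsmith)
```

panelsmith implements the analytical core of a clinical targeted-capture
workflow: a hybridization chip that captures the coding regions of a few
thousand Mendelian-disease genes and, on top of that, marks ~150 recurrent
chromosomal-abnormality regions so that large deletions and duplications
become visible from read depth alone. This vignette documents the models
and rules, the tunable parameters, the numerical conventions, and what the
synthetic-data generators do and do not emulate.

## Coordinate conventions

All intervals are stored 0-based half-open (`[start, end)`), the BED
convention. GFF3 and VCF inputs (1-based) and the printed abnormality
tables are converted at the boundary, so interval arithmetic has a single
convention everywhere. Two consequences worth knowing:

* Interval size is `end - start`, not `end - start + 1`. This matches the
  arithmetic of the published region tables (e.g. a chr22 call of
  49,411,085-51,244,066 prints as 1.83 Mb = 1,832,981 bp / 10^6).
* Reported sizes and percentages round **half-up** (169.169 Kb prints as
  169.17), via `round_half_up()`; base R's round-half-even would
  occasionally disagree with how clinical tables print.

Chromosome names are kept verbatim but joins across files strip an
optional `chr` prefix, because region catalogs print bare names while
call sets are usually `chr`-prefixed.

## Capture-region design

For single-gene content, one transcript represents each gene. Lacking a
transcript-usage source, "most common or longest" is resolved as *largest
summed CDS length*, with ties broken by lexicographically smallest
transcript id so the choice is order-independent. Every CDS of the
representative transcript is extended by `flank_bp` (default 10 bp) on
both sides to catch splice-site variation; UTRs are never captured.
Overlapping or book-ended extended spans merge.

For each chromosomal-abnormality region, the major pathogenic genes are
captured in full (same rule as above), and the remaining "bystander"
genes are marked with one random tile of at most `tile_bp` (default 100
bp) on their CDS. How many bystanders get a tile depends on the gene
count *n* of the region:

| genes in region | genes tiled            | tile count  |
|-----------------|------------------------|-------------|
| n <= 15         | every gene             | n           |
| 15 < n < 40     | two of every three     | ceil(2n/3)  |
| n >= 40         | every other gene       | ceil(n/2)   |

Three details are the package's own choices where the design rules are
silent. Genes are ordered by the genomic start of their CDS union before
grouping, making the selection deterministic and reproducible. "Every
other gene" keeps even 0-based indices, so the first (most boundary-
proximal) gene is always kept. A tile is placed inside a single CDS,
chosen with probability proportional to CDS length and then at a uniform
offset; a CDS shorter than the tile is captured whole. Tile placement is
a pure function of the design seed (decorrelated per region), so a fixed
seed reproduces the panel byte-for-byte and changing the seed moves only
tile offsets, never tile counts or gene choices.

The genome fraction statistic divides the merged-union size by a genome
length parameter (default 3 Gb); a ~10 Mb merged panel therefore reports
~0.33 %.

The bundled catalog `chromosomal_abnormalities.tsv` lists 148 recurrent
chromosomal abnormalities (DECIPHER/OMIM-derived regions, e.g. 22q11.2
deletion, Prader-Willi/Angelman, the SHOX deletions on X and Y) with
verbatim coordinates. Which genes are "major" in each region is an input
(`region_gene_index`), never guessed.

## Coverage QC

Per-CDS statistics are computed over the same spans the panel captures
(CDS plus flank): mean depth, and "coverage" defined as the percentage of
bases at depth at least `cover_threshold`. The threshold is a knob with
default 1 because the underlying definition is not standardized across
pipelines; covered fraction is non-increasing in it, which the tests
assert. CDS regions are binned by mean deduplicated depth into half-open
bins `[0,30)`, `[30,100)`, `[100,Inf)` -- 30x and 100x land in the upper
bin. `zero_coverage_report()` singles out CDS with no covered base and
reports the fraction that are CDS1 (first coding exon in translation
order, strand-aware), the segment adjacent to the GC-rich 5' UTR where
capture dropout concentrates. `meets_recommended_depth()` encodes the
working recommendation of a 100x deduplicated mean.

## Replicate stability and array concordance

Stability is the fraction of jointly covered sites whose genotypes agree
in all three technical replicates. The denominator is the sites present,
covered and genotyped in **all three** tables (sites missing in any
replicate are excluded entirely rather than counted discordant); this is
why totals sit slightly below the capture-region size. Genotypes compare
as unordered allele pairs -- `0/1`, `1|0` and `0|1` are identical -- and a
missing genotype is never identical to anything, including another
missing genotype. `classify_sites()` is invariant to replicate order, and
on generator output with a planted discordance fraction eps it returns
exactly `100 * (1 - floor(eps*n)/n)` percent. Array concordance uses the
same unordered-equality rule over the loci genotyped by both platforms
and refuses to emit a percentage when no locus is shared.

## Depth-ratio CNV detection

Copy-number events are detected by comparing average depth between
samples of the same batch. For each sample, per-target mean depths are
divided by the sample's **median target depth**, which puts every sample
on a copy-ratio scale that is exactly invariant to library size: scaling
a sample's depths by any constant leaves its log2 ratios unchanged to
floating-point precision (a property the acceptance suite checks at
1e-6). The per-target reference is the median of the *other* samples'
normalized depths (leave-one-out, so a sample's own event cannot drag
its reference). The reported statistic is
`log2((x + eps) / (ref + eps))` with `eps = 1e-3` on the copy-ratio
scale -- a numerical guard for zero-depth targets, small enough that a
doubled target still reads as log2 ~ 1. We chose this over a read-scale
pseudocount precisely to keep the exact scale-invariance property.
Targets with zero depth in every sample are uninformative; they are
flagged and set to ratio 0. A sample whose median depth is zero yields
`NA` ratios and no calls.

Segmentation is a deliberately simple threshold-and-merge rule (this
package does not reimplement circular binary segmentation): consecutive
targets beyond the same threshold merge into one call, and runs shorter
than `min_targets` (default 3) are suppressed as single-target noise.
Default thresholds are log2 <= -0.4 for loss and >= +0.32 for gain,
approximating heterozygous single-copy expectations (log2 of 1/2 and 3/2
are -1 and +0.58; the defaults sit well inside those, tolerating
dispersion and event impurity). Call intervals span the first to the
last supporting target, so breakpoint precision is limited by target
spacing -- kilobase-scale breakpoint deltas against an orthogonal method
are expected behaviour, which `compare_cnv_calls()` quantifies via
signed start/end deltas and reciprocal overlap
(`intersection / max(len)`, matched at >= 0.5, the common benchmarking
convention).

Lower sequencing throughput is simulated by binomial thinning:
`downsample_depth()` replaces each per-base depth with a
`Binomial(depth, fraction)` draw. Reads are not an input to this
package, and thinning is expectation-equivalent to random read
extraction for coverage purposes. `sensitivity_curve()` composes
generator, thinning, caller and comparator into a recall table over
(event size, depth fraction) cells with per-replicate seeds derived from
one master seed. At the tile spacing the simulations emulate (targets
every ~70 kb inside an abnormality region), events well under 200 kb
overlap fewer than `min_targets` targets and are invisible at any depth
-- the practical detection floor of sparse tiling -- while megabase-scale
events are recovered even after thinning to a tenth of the depth.

## Variant triage

`triage_variants()` applies six screens in order, with a complete
per-record rule trace:

1. **R1** known high-frequency pathogenic variants are retained outright.
   This is the only coherent reading of a rule that *selects* known
   *high-frequency* pathogenic variants before a frequency filter: R1
   bypasses the frequency and evidence gates but not the phenotype gate.
2. **R2** population frequency below `freq_cutoff` (default 0.01).
   Unknown frequency passes -- absence of evidence is not evidence of
   commonness.
3. -- 5. The evidence screens (database pathogenicity, clarified gene
   mechanism, in-silico predictions with at least `min_damaging_votes`
   of 3 damaging votes) combine as OR by default. The source rules list
   them as successive screens without stating conjunction; OR is the
   permissive reading, and `evidence_mode = "all"` switches to AND.
6. **R6** the variant must match the patient phenotype and satisfy the
   gene's inheritance model: AD takes a het or hom; AR takes a hom (or
   hemi) or two distinct surviving hets in the same gene (compound het,
   so removing either partner removes both); XL takes hemi or hom, and
   an XL het is retained but flagged as a carrier finding.

Lowering the frequency cutoff can only shrink the kept set; the totals of
kept plus dropped are always conserved. Protein-stability support uses
the strict rule ddG > 1.6 kcal/mol (`classify_ddg()`); the values
themselves are inputs from structure-based prediction, never recomputed.

## Synthetic data: what it emulates, and what it does not

The generators in `sim_spec()` are pure functions of their seed and
produce every input format the toolkit reads, plus first-class ground
truth (so tests never re-derive truth from generated files). Defaults
are the study conditions the package targets: ~300x deduplicated mean
depth (within the 157-380x range of real runs), negative-binomial
per-base depth with size 10 (hybridization capture is overdispersed
relative to Poisson), a replicate discordance of 0.0022 (1 - 99.78 %
stability), and planted CNVs in the 0.1-7 Mb range at copy number 1 or 3.
Depth simulation uses mean `mean_depth * copy / 2`, i.e. depth scales
linearly with copy number around a diploid baseline. 5' dropout is
emulated by zeroing CDS1 spans with a configurable probability.

What the generators do **not** emulate -- and therefore what passing
tests cannot show about real data: GC-content and mappability bias along
the genome, batch effects between capture experiments, duplicate-marking
artifacts, mosaic (non-integer) copy number, read-level error profiles,
and breakpoints that fall inside targets rather than between them. The
per-bin coverage percentages of a real run (e.g. 93.84 % in the mid
bin) depend on the actual BAMs and are not reproducible from synthetic
inputs; the suite therefore checks the summary mechanics, not those
numbers.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a laptop-class single
core: replicate-stability recovery on 10,000 sites, interval-merge
equivalence against a base-mask oracle on 1,000 random instances,
tile-count law for every region size from 1 to 120 genes, and CNV
sensitivity over a 12 Mb region with 172 sparse targets, 4-sample
batches and 20 replicates per (size, fraction) cell. Degenerate inputs
are defined rather than crashed on: empty depth tables are valid empty
profiles, an empty panel summarizes to 0 bp / 0.00 %, zero-coverage
reports on no zero-coverage CDS return an empty set and 0 %, and
stability or concordance with an empty denominator is a usage error
rather than NaN.
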
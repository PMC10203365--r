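#' Simulation specification
#'
#' One object holding the knobs of every generator. Defaults emulate the
#' study conditions the toolkit is meant for: a deduplicated mean depth of
#' ~300x (inside the 157-380x range of real runs), negative-binomial
#' overdispersion typical of hybridization capture, a triple-replicate
#' genotype discordance of ~0.22% (1 - 99.78% stability), and CNV events
#' in the 0.17-7 Mb size range.
#'
#' @param seed master seed; every generator is a pure function of
#'   (spec, seed).
#' @param n_genes genes to simulate.
#' @param cds_per_gene inclusive range of CDS count per transcript.
#' @param cds_len inclusive range of CDS lengths (bp).
#' @param mean_depth mean deduplicated per-base depth (diploid baseline).
#' @param depth_dispersion negative-binomial size parameter (default 10).
#' @param cnv_events tibble `(chrom, start, end, copy_number[, sample_id])`
#'   of planted events; the carrier defaults to the first sample.
#' @param replicate_discordance fraction of sites perturbed in one
#'   replicate (default 0.0022).
#' @param fivep_dropout_prob probability that a gene's first coding exon
#'   (CDS1) is zero-covered, emulating 5' GC-rich capture dropout.
#' @param planted_pathogenic records that must survive the full triage
#'   cascade in [simulate_variant_table()].
#' @param chrom chromosome name used by the generators.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(seed = 1L, n_genes = 30L, cds_per_gene = c(2L, 8L),
                     cds_len = c(80L, 300L), mean_depth = 300,
                     depth_dispersion = 10, cnv_events = NULL,
                     replicate_discordance = 0.0022,
                     fivep_dropout_prob = 0, planted_pathogenic = 5L,
                     chrom = "chr1") {
  stopifnot(mean_depth > 0, depth_dispersion > 0,
            replicate_discordance >= 0, replicate_discordance <= 1,
            fivep_dropout_prob >= 0, fivep_dropout_prob <= 1)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 cds_per_gene = as.integer(cds_per_gene),
                 cds_len = as.integer(cds_len), mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 cnv_events = cnv_events,
                 replicate_discordance = replicate_discordance,
                 fivep_dropout_prob = fivep_dropout_prob,
                 planted_pathogenic = as.integer(planted_pathogenic),
                 chrom = chrom),
            class = "sim_spec")
}

#' Simulate gene models (GFF3 + CDS table)
#'
#' Generates non-overlapping genes along one chromosome, each with 1-3
#' transcripts (so representative-transcript selection is exercised:
#' alternative transcripts drop a random subset of CDS). Returns both the
#' GFF3 text and the already-parsed CDS table; the text round-trips
#' through [read_gene_models()].
#'
#' @param spec a [sim_spec()].
#' @param gene_spacing_bp mean intergenic gap (default 2000).
#' @param chrom_length_bp available chromosome length; genes that do not
#'   fit raise an error.
#' @return list: `gff` (character vector of GFF3 lines), `models`
#'   (CDS table of all transcripts).
#' @export
simulate_gene_models <- function(spec = sim_spec(), gene_spacing_bp = 2000,
                                 chrom_length_bp = NULL) {
  withr::with_seed(spec$seed, {
    lines <- c("##gff-version 3")
    rows <- list()
    cursor <- 1000
    for (g in seq_len(spec$n_genes)) {
      gene_id <- sprintf("G%03d", g)
      strand <- sample(c("+", "-"), 1)
      n_cds <- sample(seq(spec$cds_per_gene[1], spec$cds_per_gene[2]), 1)
      lens <- sample(seq(spec$cds_len[1], spec$cds_len[2]), n_cds, replace = TRUE)
      gaps <- sample(100:600, n_cds, replace = TRUE)
      starts <- cursor + cumsum(gaps) + c(0, cumsum(lens))[seq_len(n_cds)]
      ends <- starts + lens # 1-based closed in GFF terms: [start, end-1]
      gene_start <- starts[1]; gene_end <- ends[n_cds] - 1
      n_tx <- sample(1:3, 1)
      lines <- c(lines, sprintf(
        "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s", spec$chrom, gene_start,
        gene_end, strand, gene_id))
      for (t in seq_len(n_tx)) {
        tx_id <- sprintf("%s.T%d", gene_id, t)
        keep <- if (t == 1) seq_len(n_cds) else
          sort(sample(seq_len(n_cds), max(1, n_cds - sample(0:2, 1))))
        lines <- c(lines, sprintf(
          "%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s", spec$chrom,
          starts[keep[1]], ends[keep[length(keep)]] - 1, strand, tx_id, gene_id))
        ord <- if (strand == "-") rev(seq_along(keep)) else seq_along(keep)
        lines <- c(lines, sprintf(
          "%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
          spec$chrom, starts[keep], ends[keep] - 1, strand, tx_id,
          seq_along(keep), tx_id))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene_id = gene_id, transcript_id = tx_id, chrom = spec$chrom,
          strand = strand, start = starts[keep] - 1, end = ends[keep] - 1,
          ordinal = ord)
      }
      cursor <- gene_end + sample(seq(gene_spacing_bp %/% 2, gene_spacing_bp * 2), 1)
      if (!is.null(chrom_length_bp) && cursor > chrom_length_bp) {
        abort("genes do not fit on the chromosome; lower n_genes or sizes")
      }
    }
    list(gff = lines, models = dplyr::bind_rows(rows))
  })
}

#' Simulate per-base depth profiles over a panel, with CNV truth
#'
#' Per-base depth is drawn from a negative binomial with mean
#' `mean_depth * copy / 2` and size `depth_dispersion`; the copy number
#' comes from the spec's planted events for the carrier sample and is 2
#' elsewhere. With probability `fivep_dropout_prob`, a gene's CDS1 span is
#' zeroed in every sample, emulating GC-driven capture dropout next to the
#' 5' UTR.
#'
#' @param panel targets tibble (`chrom`, `start`, `end`; 0-based
#'   half-open). Depth is generated for every base of every target.
#' @param spec a [sim_spec()].
#' @param n_samples samples in the batch.
#' @param transcripts optional CDS table; needed only when
#'   `fivep_dropout_prob > 0` to locate CDS1 spans.
#' @return list: `profiles` (list of `depth_profile`), `truth` (tibble of
#'   planted events with `sample_id`).
#' @export
simulate_depth_profiles <- function(panel, spec = sim_spec(), n_samples = 4L,
                                    transcripts = NULL) {
  if (nrow(panel) == 0L) abort("panel must be non-empty")
  pos <- unlist(lapply(seq_len(nrow(panel)), function(i) {
    if (panel$end[i] > panel$start[i]) seq(panel$start[i], panel$end[i] - 1) else numeric()
  }))
  chrom <- rep(panel$chrom, times = pmax(0, panel$end - panel$start))
  sample_ids <- sprintf("S%d", seq_len(n_samples))
  events <- spec$cnv_events
  if (!is.null(events) && nrow(events)) {
    if (!"sample_id" %in% names(events)) events$sample_id <- sample_ids[1]
  }
  dropout_spans <- NULL
  withr::with_seed(spec$seed, {
    if (spec$fivep_dropout_prob > 0) {
      if (is.null(transcripts)) {
        abort("fivep_dropout_prob > 0 needs a transcripts table")
      }
      cds1 <- transcripts[transcripts$ordinal == 1L, ]
      hit <- stats::runif(nrow(cds1)) < spec$fivep_dropout_prob
      dropout_spans <- cds1[hit, ]
    }
    profiles <- lapply(sample_ids, function(sid) {
      copy <- rep(2, length(pos))
      if (!is.null(events) && nrow(events)) {
        mine <- events[events$sample_id == sid, ]
        for (k in seq_len(nrow(mine))) {
          inside <- norm_chrom(chrom) == norm_chrom(mine$chrom[k]) &
            pos >= mine$start[k] & pos < mine$end[k]
          copy[inside] <- mine$copy_number[k]
        }
      }
      d <- stats::rnbinom(length(pos), mu = spec$mean_depth * copy / 2,
                          size = spec$depth_dispersion)
      if (!is.null(dropout_spans) && nrow(dropout_spans)) {
        for (k in seq_len(nrow(dropout_spans))) {
          z <- norm_chrom(chrom) == norm_chrom(dropout_spans$chrom[k]) &
            pos >= dropout_spans$start[k] - 10 & pos < dropout_spans$end[k] + 10
          d[z] <- 0L
        }
      }
      depth_profile(tibble::tibble(chrom = chrom, pos = pos, depth = as.numeric(d)),
                    sample_id = sid)
    })
    truth <- if (!is.null(events) && nrow(events)) tibble::as_tibble(events) else
      tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                     copy_number = numeric(), sample_id = character())
    list(profiles = profiles, truth = truth)
  })
}

#' Simulate three technical-replicate site tables
#'
#' All sites are covered and genotyped in every replicate; exactly
#' `floor(epsilon * n_sites)` sites receive a perturbed genotype in
#' exactly one randomly chosen replicate, so the expected stability is
#' `100 * (1 - floor(eps*n)/n)` percent by construction.
#'
#' @param n_sites number of sites.
#' @param epsilon discordance fraction in \[0, 1\].
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @return list: `reps` (list of three site tables), `truth` (tibble
#'   `pos`, `perturbed_rep`).
#' @export
simulate_replicate_sites <- function(n_sites, epsilon, seed = 1L,
                                     chrom = "chr1") {
  stopifnot(epsilon >= 0, epsilon <= 1, n_sites >= 1)
  withr::with_seed(seed, {
    pos <- seq_len(n_sites)
    base_codes <- sample(c("ref_ref", "ref_alt", "alt_alt"), n_sites,
                         replace = TRUE, prob = c(0.8, 0.15, 0.05))
    pair <- function(code) switch(code,
      ref_ref = c("A", "A"), ref_alt = c("A", "G"), alt_alt = c("G", "G"))
    mk <- function(codes) {
      alle <- t(vapply(codes, pair, character(2)))
      tibble::tibble(chrom = chrom, pos = pos,
                     a1 = pmin(alle[, 1], alle[, 2]),
                     a2 = pmax(alle[, 1], alle[, 2]),
                     covered = TRUE)
    }
    n_perturb <- floor(epsilon * n_sites)
    which_sites <- if (n_perturb > 0) sample(n_sites, n_perturb) else integer()
    which_rep <- if (n_perturb > 0) sample(1:3, n_perturb, replace = TRUE) else integer()
    flip <- function(code) switch(code,
      ref_ref = "ref_alt", ref_alt = "alt_alt", alt_alt = "ref_alt")
    reps <- lapply(1:3, function(r) {
      codes <- base_codes
      mine <- which_sites[which_rep == r]
      codes[mine] <- vapply(codes[mine], flip, "")
      mk(codes)
    })
    list(reps = reps,
         truth = tibble::tibble(pos = which_sites, perturbed_rep = which_rep))
  })
}

#' Simulate an annotated variant table with planted diagnostic findings
#'
#' `planted_pathogenic` records are constructed to survive the whole
#' triage cascade under the emitted inheritance map (a mix of AD hets, AR
#' homs, one AR compound-het pair when space allows, XL hemis and one
#' frequency-rescued known pathogenic variant). Every decoy fails exactly
#' one named gate -- `freq` (common variant), `prediction` (no supporting
#' evidence), `phenotype` (no phenotype match) or `AR-single-het`
#' (single het in a recessive gene) -- recorded in the truth table.
#'
#' @param spec a [sim_spec()]; `planted_pathogenic` and `seed` are used.
#' @param n_records total rows (default 100).
#' @return list: `variants` (records tibble), `inheritance` (tibble
#'   `gene_id`, `model`), `truth` (tibble `variant_id`, `role`,
#'   `fail_rule`).
#' @export
simulate_variant_table <- function(spec = sim_spec(), n_records = 100L) {
  n_plant <- spec$planted_pathogenic
  if (n_plant > n_records) abort("planted_pathogenic exceeds n_records")
  withr::with_seed(spec$seed, {
    vtypes <- c("missense", "frameshift", "splicing")
    rows <- list(); truth <- list(); inh <- list()
    gene_no <- 0L
    new_gene <- function(model) {
      gene_no <<- gene_no + 1L
      g <- sprintf("VG%03d", gene_no)
      inh[[length(inh) + 1L]] <<- tibble::tibble(gene_id = g, model = model)
      g
    }
    add <- function(gene_id, zygosity, role, fail_rule = NA_character_,
                    pop_freq = stats::runif(1, 0, 0.005),
                    known_hf = FALSE, db = NA, mech = NA, votes = NA,
                    pheno = TRUE) {
      id <- sprintf("v%04d", length(rows) + 1L)
      if (is.na(db)) db <- sample(c(TRUE, FALSE), 1)
      # guarantee the evidence gate passes for qualifying records
      if (is.na(votes)) votes <- if (db) sample(0:3, 1) else 3L
      if (is.na(mech)) mech <- sample(c(TRUE, FALSE), 1)
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        gene_id = gene_id, variant_id = id,
        vtype = sample(vtypes, 1), pop_freq = pop_freq,
        known_pathogenic_hf = known_hf, db_pathogenic = db,
        mechanism_deleterious = mech,
        prediction_damaging_votes = as.integer(votes),
        zygosity = zygosity, phenotype_match = pheno,
        reported_before = sample(c(TRUE, FALSE), 1))
      truth[[length(truth) + 1L]] <<- tibble::tibble(
        variant_id = id, role = role, fail_rule = fail_rule)
      id
    }
    # planted survivors
    plant_kind <- rep(c("AD_het", "AR_hom", "XL_hemi", "R1_rescue"),
                      length.out = max(0, n_plant))
    k <- 1L
    while (k <= n_plant) {
      if (plant_kind[k] == "AR_hom" && k + 1L <= n_plant) {
        g <- new_gene("AR") # compound het pair uses two slots
        add(g, "het", "planted")
        add(g, "het", "planted")
        k <- k + 2L
      } else if (plant_kind[k] == "AD_het") {
        add(new_gene("AD"), "het", "planted"); k <- k + 1L
      } else if (plant_kind[k] == "AR_hom") {
        add(new_gene("AR"), "hom", "planted"); k <- k + 1L
      } else if (plant_kind[k] == "XL_hemi") {
        add(new_gene("XL"), "hemi", "planted"); k <- k + 1L
      } else {
        add(new_gene("AD"), "het", "planted",
            pop_freq = 0.03, known_hf = TRUE, db = FALSE, mech = FALSE,
            votes = 0L)
        k <- k + 1L
      }
    }
    # decoys, each failing exactly one named gate
    decoy_kind <- rep(c("freq", "prediction", "phenotype", "AR-single-het"),
                      length.out = n_records - n_plant)
    for (d in decoy_kind) {
      switch(d,
        freq = add(new_gene("AD"), "het", "decoy", "freq",
                   pop_freq = stats::runif(1, 0.02, 0.3)),
        prediction = add(new_gene("AD"), "het", "decoy", "prediction",
                         db = FALSE, mech = FALSE, votes = sample(0:1, 1)),
        phenotype = add(new_gene("AD"), "het", "decoy", "phenotype",
                        pheno = FALSE),
        `AR-single-het` = add(new_gene("AR"), "het", "decoy", "AR-single-het"))
    }
    list(variants = dplyr::bind_rows(rows),
         inheritance = dplyr::bind_rows(inh),
         truth = dplyr::bind_rows(truth))
  })
}
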
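#' Triage configuration
#'
#' @param freq_cutoff population-frequency gate; variants at or above it
#'   are dropped unless rescued as known high-frequency pathogenic
#'   (default 0.01).
#' @param min_damaging_votes in-silico prediction votes (of SIFT /
#'   PolyPhen / splice-predictor style flags, 0..3) needed to count as
#'   "high pathogenicity score" (default 2).
#' @param ddg_cutoff kcal/mol; predicted folding free-energy change above
#'   which a missense variant is called destabilizing (default 1.6,
#'   strict inequality).
#' @param evidence_mode how the database / mechanism / prediction screens
#'   combine: `"any"` (default, a variant passes if any of the three
#'   supports it) or `"all"` (conjunctive).
#' @param inheritance_map tibble `(gene_id, model)` with model one of
#'   `"AD"`, `"AR"`, `"XL"`. Must cover every gene that reaches the
#'   phenotype/inheritance step.
#' @return a `triage_config` list.
#' @export
triage_config <- function(freq_cutoff = 0.01, min_damaging_votes = 2L,
                          ddg_cutoff = 1.6, evidence_mode = c("any", "all"),
                          inheritance_map = NULL) {
  stopifnot(freq_cutoff > 0, freq_cutoff < 1)
  structure(list(freq_cutoff = freq_cutoff,
                 min_damaging_votes = as.integer(min_damaging_votes),
                 ddg_cutoff = ddg_cutoff,
                 evidence_mode = match.arg(evidence_mode),
                 inheritance_map = inheritance_map),
            class = "triage_config")
}

#' Six-criterion variant triage cascade
#'
#' Applies, in order: R1 known high-frequency pathogenic variants are
#' retained outright (bypassing the frequency and evidence gates, but not
#' the phenotype gate); R2 population frequency below `freq_cutoff`
#' (unknown frequency passes); R3-R5 evidence screen -- reported
#' pathogenic in variant databases, OR a clarified deleterious gene
#' mechanism, OR at least `min_damaging_votes` damaging prediction votes
#' (`"all"` mode makes this conjunctive); R6 the variant must match the
#' patient phenotype and satisfy the gene's inheritance model: AD needs
#' one het or hom, AR needs a hom (or hemi) or two distinct surviving hets
#' in the same gene (compound het), XL needs hemi or hom -- an XL het is
#' retained but flagged as a carrier finding.
#'
#' @param records tibble of annotated variants; required columns:
#'   `gene_id`, `variant_id`, `vtype`, `pop_freq`, `known_pathogenic_hf`,
#'   `db_pathogenic`, `mechanism_deleterious`, `prediction_damaging_votes`,
#'   `zygosity`, `phenotype_match`, `reported_before`.
#' @param cfg a [triage_config()] whose `inheritance_map` covers every
#'   gene among candidate survivors.
#' @return a `triage_result` list: `kept` (with `carrier_flag`),
#'   `dropped` (with `failed_rule`), `trace` (per-variant rule outcomes),
#'   `summary`, `n_reported`, `n_novel`.
#' @export
triage_variants <- function(records, cfg = triage_config()) {
  need <- c("gene_id", "variant_id", "vtype", "pop_freq",
            "known_pathogenic_hf", "db_pathogenic", "mechanism_deleterious",
            "prediction_damaging_votes", "zygosity", "phenotype_match",
            "reported_before")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort(paste0("variant records lack columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(records)
  if (n == 0L) {
    return(finish_triage(records[0, ], records[0, ], list(), character()))
  }
  if (anyDuplicated(records$variant_id)) {
    abort("variant_id values must be unique")
  }
  r1 <- isTRUE_v(records$known_pathogenic_hf)
  r2 <- is.na(records$pop_freq) | records$pop_freq < cfg$freq_cutoff
  ev <- cbind(db = isTRUE_v(records$db_pathogenic),
              mech = isTRUE_v(records$mechanism_deleterious),
              pred = records$prediction_damaging_votes >= cfg$min_damaging_votes)
  r345 <- if (cfg$evidence_mode == "any") rowSums(ev) > 0 else rowSums(ev) == 3
  survives_evidence <- r1 | (r2 & r345)

  # R6 needs gene-level context among evidence survivors
  surv <- records[survives_evidence, , drop = FALSE]
  pheno <- isTRUE_v(surv$phenotype_match)
  candidates <- surv[pheno, , drop = FALSE]
  if (nrow(candidates)) {
    imap <- cfg$inheritance_map
    if (is.null(imap)) abort("triage_config has no inheritance_map")
    unknown <- setdiff(unique(candidates$gene_id), imap$gene_id)
    if (length(unknown)) {
      abort(sprintf("gene '%s' missing from the inheritance map", unknown[1]))
    }
  }
  het_per_gene <- table(candidates$gene_id[candidates$zygosity == "het"])
  r6 <- logical(n); carrier <- logical(n)
  model_of <- function(g) {
    cfg$inheritance_map$model[match(g, cfg$inheritance_map$gene_id)]
  }
  for (i in which(survives_evidence)) {
    if (!isTRUE_v(records$phenotype_match[i])) next
    g <- records$gene_id[i]; z <- records$zygosity[i]
    ok <- switch(model_of(g),
      AD = z %in% c("het", "hom"),
      AR = z %in% c("hom", "hemi") ||
        (z == "het" && !is.na(het_per_gene[g]) && het_per_gene[g] >= 2),
      XL = z %in% c("hemi", "hom", "het"),
      FALSE)
    if (isTRUE(ok)) {
      r6[i] <- TRUE
      carrier[i] <- model_of(g) == "XL" && z == "het"
    }
  }
  kept_mask <- survives_evidence & r6
  failed_rule <- rep(NA_character_, n)
  failed_rule[!r1 & !r2] <- "R2"
  failed_rule[!r1 & r2 & !r345] <- "R3-5"
  failed_rule[survives_evidence & !r6] <- "R6"
  trace <- lapply(seq_len(n), function(i) {
    tibble::tibble(
      rule = c("R1", "R2", "R3-5", "R6"),
      result = c(
        if (r1[i]) "pass" else "fail",
        if (r1[i]) "skip" else if (r2[i]) "pass" else "fail",
        if (r1[i]) "skip" else if (!r2[i]) "skip" else if (r345[i]) "pass" else "fail",
        if (!survives_evidence[i]) "skip" else if (r6[i]) "pass" else "fail"))
  })
  names(trace) <- records$variant_id
  kept <- records[kept_mask, , drop = FALSE]
  kept$carrier_flag <- carrier[kept_mask]
  dropped <- records[!kept_mask, , drop = FALSE]
  dropped$failed_rule <- failed_rule[!kept_mask]
  finish_triage(kept, dropped, trace, records$variant_id)
}

isTRUE_v <- function(x) !is.na(x) & x

finish_triage <- function(kept, dropped, trace, ids) {
  s <- summarize_variants(kept)
  structure(list(kept = kept, dropped = dropped, trace = trace,
                 summary = s$counts, n_total = s$total,
                 n_reported = s$n_reported, n_novel = s$n_novel),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("<triage_result> %d kept (%d reported, %d novel), %d dropped\n",
              x$n_total, x$n_reported, x$n_novel, nrow(x$dropped)))
  invisible(x)
}

#' Is a ddG value significant for protein stability?
#'
#' A predicted folding free-energy change strictly greater than the cutoff
#' (default 1.6 kcal/mol) is considered to have a significant
#' destabilizing effect; a missing value is never significant (`NA`).
#'
#' @param ddg_kcal_mol numeric vector of ddG values.
#' @param cutoff kcal/mol, strict inequality.
#' @return logical vector (NA where ddG is missing).
#' @export
#' @examples
#' classify_ddg(c(4.07063, -0.138577, 1.6)) # TRUE FALSE FALSE
classify_ddg <- function(ddg_kcal_mol, cutoff = 1.6) {
  ifelse(is.na(ddg_kcal_mol), NA, ddg_kcal_mol > cutoff)
}

#' Summarize kept variants by category
#'
#' @param kept_records tibble of retained variants with `vtype` and
#'   `reported_before` columns.
#' @return list: `counts` (tibble `vtype`, `n` over the five standard
#'   categories plus `other`), `total`, `n_reported`, `n_novel`.
#' @export
summarize_variants <- function(kept_records) {
  vtypes <- c("missense", "frameshift", "splicing", "intragenic_cnv",
              "whole_gene_del", "other")
  counts <- tibble::tibble(
    vtype = vtypes,
    n = vapply(vtypes, function(v) sum(kept_records$vtype == v), 0L,
               USE.NAMES = FALSE))
  n_rep <- sum(isTRUE_v(kept_records$reported_before))
  list(counts = counts, total = nrow(kept_records),
       n_reported = n_rep, n_novel = nrow(kept_records) - n_rep)
}
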
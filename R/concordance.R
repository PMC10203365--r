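#' Stability percentage
#'
#' The ratio of sites identified identically in all three technical
#' replicates to all jointly covered sites, as a percentage rounded
#' half-up to two decimals.
#'
#' @param n_all_same sites with identical genotypes in all three replicates.
#' @param n_total sites covered and genotyped in all three replicates.
#' @return percentage (two decimals).
#' @export
#' @examples
#' stability(9881645, 9903792) # 99.78
stability <- function(n_all_same, n_total) {
  if (any(n_total <= 0)) abort("stability undefined for n_total == 0")
  if (any(n_all_same < 0) || any(n_all_same > n_total)) {
    abort("need 0 <= n_all_same <= n_total")
  }
  round_half_up(100 * n_all_same / n_total, 2)
}

site_key <- function(sites) paste(norm_chrom(sites$chrom), sites$pos)
site_geno <- function(sites) paste(sites$a1, sites$a2) # a1/a2 already sorted

#' Classify sites across three technical replicates
#'
#' Joins the three all-sites tables on position. The denominator is the
#' sites present, covered and genotyped in all three replicates (sites
#' missing or uncovered in any replicate are excluded entirely -- this is
#' why the total sits slightly below the capture-region size). Each
#' remaining site is classified as all-same, exactly-two-same or
#' all-different by unordered genotype equality; phasing is ignored.
#'
#' @param rep1,rep2,rep3 site tables (as from [read_site_table()]).
#' @return a `concordance_result` list: `n_total`, `n_all_same`,
#'   `n_two_same`, `n_all_diff`, `stability_pct`.
#' @export
classify_sites <- function(rep1, rep2, rep3) {
  usable <- function(s) s[s$covered & !is.na(s$a1) & !is.na(s$a2), ]
  r1 <- usable(rep1); r2 <- usable(rep2); r3 <- usable(rep3)
  k1 <- site_key(r1); k2 <- site_key(r2); k3 <- site_key(r3)
  common <- intersect(intersect(k1, k2), k3)
  g1 <- site_geno(r1)[match(common, k1)]
  g2 <- site_geno(r2)[match(common, k2)]
  g3 <- site_geno(r3)[match(common, k3)]
  eq12 <- g1 == g2; eq13 <- g1 == g3; eq23 <- g2 == g3
  n_pairs <- eq12 + eq13 + eq23
  n_all_same <- sum(n_pairs == 3L)
  n_two_same <- sum(n_pairs == 1L)
  n_all_diff <- sum(n_pairs == 0L)
  n_total <- length(common)
  structure(list(n_total = n_total, n_all_same = n_all_same,
                 n_two_same = n_two_same, n_all_diff = n_all_diff,
                 stability_pct = if (n_total > 0) stability(n_all_same, n_total) else NA_real_),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(paste0("<concordance_result> %d sites: %d all-same, ",
                     "%d two-same, %d all-different (stability %.2f%%)\n"),
              x$n_total, x$n_all_same, x$n_two_same, x$n_all_diff,
              x$stability_pct))
  invisible(x)
}

#' NGS-vs-array genotype concordance
#'
#' Compares the chip's genotypes with orthogonal SNP-array genotypes over
#' the loci genotyped (non-missing) by both, by unordered allele-pair
#' equality.
#'
#' @param ngs_sites,array_sites site tables with columns `chrom`, `pos`,
#'   `a1`, `a2` (and optionally `covered`).
#' @return list with `n_shared`, `n_concordant`, `pct` (two decimals).
#' @export
#' @examples
#' # 3647 concordant of 3664 shared loci -> 99.54
array_concordance <- function(ngs_sites, array_sites) {
  usable <- function(s) {
    ok <- !is.na(s$a1) & !is.na(s$a2)
    if ("covered" %in% names(s)) ok <- ok & s$covered
    s[ok, ]
  }
  a <- usable(ngs_sites); b <- usable(array_sites)
  ka <- site_key(a); kb <- site_key(b)
  shared <- intersect(ka, kb)
  if (length(shared) == 0L) {
    abort("no shared genotyped loci; concordance undefined")
  }
  ga <- site_geno(a)[match(shared, ka)]
  gb <- site_geno(b)[match(shared, kb)]
  n_conc <- sum(ga == gb)
  list(n_shared = length(shared), n_concordant = n_conc,
       pct = round_half_up(100 * n_conc / length(shared), 2))
}
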
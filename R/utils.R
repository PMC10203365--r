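#' Round half-up
#'
#' Decimal rounding where ties go away from zero (so 169.169 Kb prints as
#' 169.17, not 169.16). Base `round()` rounds half to even, which is wrong
#' for reporting sizes and percentages the way clinical tables print them.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return `x` rounded half-up to `digits` places.
#' @export
#' @examples
#' round_half_up(169.169, 2) # 169.17
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  # small epsilon counters binary representation of decimal ties (janitor-style)
  sign(x) * floor(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

#' Construct a table of genomic intervals
#'
#' The package-wide interval container: a tibble with columns `chrom`,
#' `start`, `end` (0-based half-open) and `label`. All readers convert into
#' this convention at the boundary; BED output needs no further shifting.
#'
#' @param chrom chromosome names (kept verbatim; `"chr"` prefixes are only
#'   stripped when joining across files, see [norm_chrom()]).
#' @param start,end 0-based half-open span, `0 <= start <= end`.
#' @param label free-text identifiers (recycled).
#' @return a tibble with class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, label = NA_character_) {
  if (length(chrom) == 0L) {
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), label = character())
    class(out) <- c("genomic_intervals", class(out))
    return(out)
  }
  stopifnot(is.numeric(start), is.numeric(end))
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    abort("interval chrom must be non-empty")
  }
  if (any(start < 0) || any(end < start)) {
    abort("intervals require 0 <= start <= end")
  }
  out <- tibble::tibble(chrom = as.character(chrom),
                        start = as.numeric(start),
                        end = as.numeric(end),
                        label = rep_len(as.character(label), length(chrom)))
  class(out) <- c("genomic_intervals", class(out))
  out
}

#' Normalize a chromosome name for cross-file joins
#'
#' Strips an optional `"chr"` prefix; names are otherwise compared verbatim.
#' Abnormality tables print bare names (`7`, `X`) while call sets are
#' usually `chr`-prefixed, so joins normalize both sides.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector without `"chr"` prefixes.
#' @export
norm_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

# intervals (0-based half-open tibble) -> IRanges per chromosome is handled
# where needed; this converts a whole table to a GRanges (1-based closed).
as_granges0 <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = pmax(intervals$end, intervals$start)),
    label = if ("label" %in% names(intervals)) intervals$label else NA_character_
  )
}

from_granges0 <- function(gr) {
  lab <- if (!is.null(gr$label)) as.character(gr$label) else NA_character_
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    label = lab
  )
}

# deterministic small hash of a string, for deriving per-entity seeds
str_seed <- function(x, base_seed) {
  h <- sum(utf8ToInt(paste(x, collapse = "|")) *
             seq_along(utf8ToInt(paste(x, collapse = "|")))) %% 1000003L
  (as.integer(base_seed) %% 1000003L) * 1009L %% 2147483647L + h
}
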
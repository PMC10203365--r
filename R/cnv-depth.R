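#' Mean target depths for a batch of samples
#'
#' Builds the dense targets x samples matrix of mean per-base depth that
#' the in-batch depth-ratio CNV caller works on. Positions absent from a
#' profile are depth 0.
#'
#' @param profiles list of `depth_profile` objects (one batch).
#' @param targets capture targets (tibble with `chrom`, `start`, `end`).
#' @return a `target_depth_matrix` list: `targets`, `samples`,
#'   `mean_depth` (samples x targets matrix), `size_factor` (per-sample
#'   median target depth).
#' @export
target_depth_matrix <- function(profiles, targets) {
  if (length(profiles) < 1L) abort("need at least one profile")
  samples <- vapply(profiles, function(p) attr(p, "sample_id") %||% "sample", "")
  if (anyDuplicated(samples)) samples <- make.unique(samples)
  tgt_gr <- as_granges0(targets)
  width <- targets$end - targets$start
  m <- matrix(0, nrow = length(profiles), ncol = nrow(targets),
              dimnames = list(samples, NULL))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    if (nrow(p) == 0L) next
    pos_gr <- GenomicRanges::GRanges(p$chrom,
                                     IRanges::IRanges(p$pos + 1, p$pos + 1))
    hits <- GenomicRanges::findOverlaps(pos_gr, tgt_gr)
    sums <- tapply(p$depth[S4Vectors::queryHits(hits)],
                   factor(S4Vectors::subjectHits(hits), levels = seq_len(nrow(targets))),
                   sum, default = 0)
    m[i, ] <- ifelse(width > 0, as.numeric(sums) / width, 0)
  }
  structure(list(targets = targets, samples = samples, mean_depth = m,
                 size_factor = apply(m, 1, stats::median)),
            class = "target_depth_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample, per-target log2 depth ratios
#'
#' Each sample's target depths are divided by that sample's median target
#' depth (its size factor), putting every sample on a copy-ratio scale
#' that is exactly invariant to library size. The per-target reference is
#' the median of the *other* samples' normalized depths (leave-one-out, so
#' a sample's own event cannot pollute its reference), and the reported
#' value is `log2((x + eps) / (ref + eps))` with a small pseudocount
#' guarding zeros. Targets with zero depth in every sample get ratio 0 and
#' are flagged.
#'
#' @param matrix a `target_depth_matrix` (needs >= 2 samples).
#' @param eps pseudocount on the copy-ratio scale (default 1e-3).
#' @return samples x targets matrix of log2 ratios, with attribute
#'   `flagged_targets` (indices dark in all samples).
#' @export
normalize_target_depths <- function(matrix, eps = 1e-3) {
  m <- matrix$mean_depth
  if (nrow(m) < 2L) abort("in-batch normalization needs >= 2 samples")
  sf <- matrix$size_factor
  rel <- m
  for (i in seq_len(nrow(m))) {
    rel[i, ] <- if (sf[i] > 0) m[i, ] / sf[i] else NA_real_
  }
  dark <- which(colSums(m) == 0)
  out <- rel
  for (i in seq_len(nrow(m))) {
    ref <- apply(rel[-i, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    out[i, ] <- log2((rel[i, ] + eps) / (ref + eps))
  }
  out[, dark] <- 0
  attr(out, "flagged_targets") <- dark
  out
}

#' Call CNVs from log2 depth ratios
#'
#' Threshold-and-merge segmentation: consecutive targets (per sample, per
#' chromosome, in genomic order) beyond the same threshold are merged into
#' one call; runs shorter than `min_targets` are suppressed. The call
#' interval spans from the first supporting target's start to the last's
#' end. Default thresholds approximate heterozygous single-copy loss
#' (log2 <= -0.4) and gain (log2 >= +0.32).
#'
#' @param log2_ratios samples x targets matrix from
#'   [normalize_target_depths()], or a numeric vector for one sample.
#' @param targets the targets tibble the columns refer to.
#' @param del_threshold,dup_threshold log2 thresholds (del < 0 < dup).
#' @param min_targets minimum supporting targets per call (default 3).
#' @return tibble of calls: `sample_id`, `chrom`, `start`, `end`, `kind`,
#'   `mean_log2`, `n_targets`.
#' @export
call_depth_cnv <- function(log2_ratios, targets, del_threshold = -0.4,
                           dup_threshold = 0.32, min_targets = 3L) {
  stopifnot(del_threshold < 0, dup_threshold > 0, min_targets >= 1)
  if (is.null(dim(log2_ratios))) {
    log2_ratios <- matrix(log2_ratios, nrow = 1,
                          dimnames = list("sample", NULL))
  }
  calls <- list()
  ord <- order(targets$chrom, targets$start)
  for (s in seq_len(nrow(log2_ratios))) {
    lr <- log2_ratios[s, ord]
    tg <- targets[ord, ]
    state <- ifelse(is.na(lr), "none",
                    ifelse(lr <= del_threshold, "del",
                           ifelse(lr >= dup_threshold, "dup", "none")))
    # break runs at chromosome boundaries
    grp <- cumsum(c(TRUE, state[-1] != state[-length(state)] |
                      tg$chrom[-1] != tg$chrom[-nrow(tg)]))
    for (g in split(seq_along(state), grp)) {
      if (state[g[1]] == "none" || length(g) < min_targets) next
      calls[[length(calls) + 1L]] <- tibble::tibble(
        sample_id = rownames(log2_ratios)[s],
        chrom = tg$chrom[g[1]],
        start = tg$start[g[1]],
        end = tg$end[g[length(g)]],
        kind = state[g[1]],
        mean_log2 = mean(lr[g]),
        n_targets = length(g))
    }
  }
  if (length(calls) == 0L) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          kind = character(), mean_log2 = numeric(),
                          n_targets = integer()))
  }
  dplyr::bind_rows(calls)
}

#' Downsampling specification
#'
#' @param target_reads reads to simulate.
#' @param source_reads reads behind the original profile.
#' @param fraction thinning fraction; computed as
#'   `target_reads / source_reads` when not given directly.
#' @param seed RNG seed for reproducible thinning.
#' @return a `downsample_spec` list.
#' @export
downsample_spec <- function(target_reads = NULL, source_reads = NULL,
                            fraction = NULL, seed = 1L) {
  if (is.null(fraction)) {
    if (is.null(target_reads) || is.null(source_reads)) {
      abort("give either fraction or target_reads and source_reads")
    }
    fraction <- target_reads / source_reads
  }
  if (fraction < 0 || fraction > 1) abort("thinning fraction must be in [0, 1]")
  structure(list(target_reads = target_reads, source_reads = source_reads,
                 fraction = fraction, seed = as.integer(seed)),
            class = "downsample_spec")
}

#' Binomial depth downsampling
#'
#' Simulates a lower-throughput run by thinning every per-base depth with
#' an independent Binomial(depth, fraction) draw -- expectation-equivalent
#' to random read extraction for coverage purposes, without needing reads.
#'
#' @param profile a `depth_profile`.
#' @param spec a [downsample_spec()]; its `fraction` and `seed` are used.
#' @return a thinned `depth_profile`.
#' @export
downsample_depth <- function(profile, spec) {
  stopifnot(inherits(spec, "downsample_spec"))
  if (spec$fraction == 1) return(profile)
  d <- profile$depth
  new_d <- withr::with_seed(spec$seed, stats::rbinom(length(d), size = d,
                                                     prob = spec$fraction))
  out <- profile
  out$depth <- as.numeric(new_d)
  attr(out, "source_reads") <- if (!is.null(spec$target_reads)) spec$target_reads else
    attr(profile, "source_reads")
  out
}

#' Compare a called CNV interval against a truth interval
#'
#' Reciprocal overlap is `|intersection| / max(|truth|, |called|)`;
#' breakpoint deltas are truth minus called (signed bp). A call matches
#' when the reciprocal overlap reaches `match_threshold` (default 0.5, the
#' common CNV-benchmarking convention).
#'
#' @param truth,called single intervals (1-row tibbles or lists with
#'   `chrom`, `start`, `end`); `called = NULL` means no call.
#' @param match_threshold reciprocal-overlap threshold.
#' @return list: `start_delta_bp`, `end_delta_bp`, `reciprocal_overlap`,
#'   `matched`.
#' @export
compare_cnv_calls <- function(truth, called, match_threshold = 0.5) {
  if (is.null(called) || (is.data.frame(called) && nrow(called) == 0L)) {
    return(list(start_delta_bp = NA_real_, end_delta_bp = NA_real_,
                reciprocal_overlap = 0, matched = FALSE))
  }
  t_chr <- norm_chrom(truth$chrom[1]); c_chr <- norm_chrom(called$chrom[1])
  inter <- if (t_chr == c_chr) {
    max(0, min(truth$end[1], called$end[1]) - max(truth$start[1], called$start[1]))
  } else 0
  ro <- inter / max(truth$end[1] - truth$start[1], called$end[1] - called$start[1])
  list(start_delta_bp = truth$start[1] - called$start[1],
       end_delta_bp = truth$end[1] - called$end[1],
       reciprocal_overlap = ro,
       matched = ro >= match_threshold)
}

#' Recall of planted CNVs across depths and event sizes
#'
#' For every (event size, depth fraction) cell, a small in-batch cohort is
#' simulated over the supplied panel targets with one planted heterozygous
#' deletion of that size, depths are binomially thinned to the fraction,
#' the depth-ratio caller runs, and the planted event counts as recovered
#' when some call of the right kind reaches the reciprocal-overlap match
#' threshold. Per-replicate seeds are derived deterministically from
#' `seed`.
#'
#' @param panel targets tibble the simulated profiles cover.
#' @param cnv_sizes event sizes in bp.
#' @param fractions depth thinning fractions in (0, 1].
#' @param replicates planted events per cell.
#' @param seed master seed.
#' @param spec a [sim_spec()] controlling depth level and dispersion.
#' @param n_samples batch size (default 4).
#' @param match_threshold reciprocal-overlap threshold (default 0.5).
#' @param ... passed to [call_depth_cnv()].
#' @return tibble `size_bp`, `fraction`, `n_detected`, `n_planted`,
#'   `recall`.
#' @export
sensitivity_curve <- function(panel, cnv_sizes, fractions, replicates = 20L,
                              seed = 1L, spec = sim_spec(seed = seed),
                              n_samples = 4L, match_threshold = 0.5, ...) {
  stopifnot(replicates >= 1)
  chrom_span <- range(c(panel$start, panel$end))
  rows <- list()
  for (size in cnv_sizes) {
    for (fr in fractions) {
      detected <- 0L
      if (fr == 0) { # nothing sequenced; nothing detectable
        rows[[length(rows) + 1L]] <- tibble::tibble(
          size_bp = size, fraction = fr, n_detected = 0L,
          n_planted = replicates, recall = 0)
        next
      }
      for (r in seq_len(replicates)) {
        rseed <- (as.integer(seed) * 10007L + as.integer(size / 1e4) * 101L + r) %% 2147483647L
        ev_start <- withr::with_seed(rseed, {
          lo <- chrom_span[1]
          hi <- max(lo + 1, chrom_span[2] - size)
          floor(stats::runif(1, lo, hi))
        })
        ev <- tibble::tibble(chrom = panel$chrom[1], start = ev_start,
                             end = ev_start + size, copy_number = 1,
                             sample_id = "S1")
        sp <- spec
        sp$seed <- rseed + 1L
        sp$cnv_events <- ev
        sim <- simulate_depth_profiles(panel, sp, n_samples = n_samples)
        profs <- sim$profiles
        if (fr < 1) {
          profs <- lapply(seq_along(profs), function(i) {
            downsample_depth(profs[[i]],
                             downsample_spec(fraction = fr,
                                             seed = rseed + 100L + i))
          })
        }
        mat <- target_depth_matrix(profs, panel)
        if (mat$size_factor[1] == 0) next
        lr <- normalize_target_depths(mat)
        calls <- call_depth_cnv(lr, panel, ...)
        calls <- calls[calls$sample_id == mat$samples[1] & calls$kind == "del", ]
        hit <- FALSE
        for (k in seq_len(nrow(calls))) {
          cmp <- compare_cnv_calls(ev, calls[k, ], match_threshold)
          if (cmp$matched) { hit <- TRUE; break }
        }
        if (hit) detected <- detected + 1L
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        size_bp = size, fraction = fr,
        n_detected = detected, n_planted = replicates,
        recall = detected / replicates)
    }
  }
  dplyr::bind_rows(rows)
}
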
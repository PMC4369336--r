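# Top-level two-pipeline CNV detection.

#' Configuration for CNV detection
#'
#' Defaults follow the method's published settings: 100-base minimum and
#' 10,000-base maximum window, one-sided tail probability 1e-6, 10,000-base
#' masking blocks flagged above twice the chromosome average, GC bins of at
#' least 100 bases, mapping-quality stratification below 5, high-coverage
#' rank capping at twice the chromosome average, and the diploid abnormality
#' ratios 0.70 (deletion) and 1.3 (duplication).
#'
#' @param alpha one-sided tail probability for a call.
#' @param w_min,w_max sliding window size range in bases.
#' @param block_size,mask_multiple excessive-coverage masking parameters.
#' @param mq_low mapping-quality stratum threshold (strictly below is low).
#' @param gc_bin_width GC weighting discretization width.
#' @param min_bin_size minimum bases per normalization bin.
#' @param cap_multiple high-coverage rank-capping threshold multiple.
#' @param w_base window size of the mapping-quality track.
#' @param min_repeat_len minimum dinucleotide run length.
#' @param min_occurrences minimum runs per motif for the bias test.
#' @param repeat_sd_mult repeat bias threshold in genome depth SDs.
#' @param dist_bin repeat distance bin width in bases.
#' @param del_ratio,dup_ratio abnormality screen ratios (diploid defaults).
#' @param n_grid,n_sample window-distribution sampling parameters.
#' @param mask_enabled run the masked pipeline (set `FALSE` for a
#'   single-pipeline debug mode).
#' @param seed seed for window-distribution sampling.
#' @return A named list of class `rdcnv_config`.
#' @export
rdcnv_config <- function(alpha = 1e-6, w_min = 100L, w_max = 10000L,
                         block_size = 10000L, mask_multiple = 2.0,
                         mq_low = 5, gc_bin_width = 0.01, min_bin_size = 100L,
                         cap_multiple = 2.0, w_base = 100L,
                         min_repeat_len = 20L, min_occurrences = 50L,
                         repeat_sd_mult = 1.5, dist_bin = 10L,
                         del_ratio = 0.70, dup_ratio = 1.3,
                         n_grid = 20L, n_sample = 1000L,
                         mask_enabled = TRUE, seed = 17L) {
  structure(list(alpha = alpha, w_min = as.integer(w_min),
                 w_max = as.integer(w_max), block_size = as.integer(block_size),
                 mask_multiple = mask_multiple, mq_low = mq_low,
                 gc_bin_width = gc_bin_width,
                 min_bin_size = as.integer(min_bin_size),
                 cap_multiple = cap_multiple, w_base = as.integer(w_base),
                 min_repeat_len = as.integer(min_repeat_len),
                 min_occurrences = as.integer(min_occurrences),
                 repeat_sd_mult = repeat_sd_mult, dist_bin = as.integer(dist_bin),
                 del_ratio = del_ratio, dup_ratio = dup_ratio,
                 n_grid = as.integer(n_grid), n_sample = as.integer(n_sample),
                 mask_enabled = isTRUE(mask_enabled), seed = as.integer(seed)),
            class = "rdcnv_config")
}

# Dilate a logical mask by `pad` bases on each side of every TRUE run.
dilate_mask <- function(m, pad) {
  if (!any(m)) return(m)
  r <- IRanges::IRanges(m)
  r <- IRanges::restrict(r - (-pad), start = 1L, end = length(m))
  as.logical(IRanges::coverage(r, width = length(m)) > 0)
}

# Union of optional per-chromosome logical masks.
combine_masks <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  out <- a
  for (ch in names(b)) out[[ch]] <- a[[ch]] | b[[ch]]
  out
}

# Bias normalization for one pipeline (mask = NULL for the unmasked one).
# Returns the normalized track plus the structures behind it.
normalize_pipeline <- function(tracks, weights, runs, library, nmask,
                               mask = NULL, cfg = rdcnv_config()) {
  bias <- assess_motif_bias(runs, tracks, library,
                            cfg$min_occurrences, cfg$repeat_sd_mult)
  assignments <- repeat_assignments(bias, runs, library, tracks, nmask, mask,
                                    cfg$dist_bin, cfg$min_bin_size)
  gcbins <- assign_gc_bins(weights, tracks, nmask, mask,
                           exclude = if (nrow(assignments)) assignments[, .(chrom, pos)] else NULL,
                           gc_bin_width = cfg$gc_bin_width,
                           min_bin_size = cfg$min_bin_size,
                           mq_threshold = cfg$mq_low)
  chrom_lengths <- vapply(tracks, function(t) length(t$depth), integer(1))
  norm <- quantile_normalize(gcbins, library, chrom_lengths, cfg$cap_multiple)
  norm <- normalize_repeat_regions(norm, bias, runs, tracks, library, nmask,
                                   mask, assignments = assignments,
                                   cap_multiple = cfg$cap_multiple)
  list(norm = norm, gcbins = gcbins, bias = bias, assignments = assignments)
}

# One pipeline end to end: normalize, sample window distributions, scan.
# `shadow` marks gap-shadow bases excluded from binning (depth next to an N
# run is structurally truncated because no fragment spans N); `hard` is the
# excessive-coverage mask that windows must additionally never enter.
run_pipeline <- function(tracks, weights, runs, library, nmask, shadow, hard,
                         cfg, pipeline_label) {
  excl <- combine_masks(shadow, hard)
  np <- normalize_pipeline(tracks, weights, runs, library, nmask, excl, cfg)
  dists <- sample_window_distributions(np$norm, cfg$w_min, cfg$w_max,
                                       cfg$n_grid, cfg$n_sample, cfg$seed)
  calls <- scan_cnvs(np$norm, tracks, dists, hard, cfg$alpha, cfg$w_min,
                     cfg$w_max, cfg$del_ratio, cfg$dup_ratio, pipeline_label)
  list(calls = calls, norm = np$norm, gcbins = np$gcbins, bias = np$bias,
       dists = dists)
}

#' Detect copy number variants from read depth
#'
#' Runs the full two-pipeline analysis: per-base depth and library
#' statistics, dinucleotide repeat bias assessment, GC/repeat quantile
#' normalization to standard-deviation units, excessive-coverage masking
#' (pipeline 1 only), the size-varying sliding-window z-score scan in both
#' pipelines, and the union merge of their calls.
#'
#' Inputs may be given as files (`bam` + `fasta`) or as in-memory objects
#' (`reads` table + `ref` `DNAStringSet`), the latter being convenient for
#' simulated data.
#'
#' @param bam path to a coordinate-sorted indexed BAM file.
#' @param fasta path to the matching reference FASTA.
#' @param reads alignment table (alternative to `bam`).
#' @param ref `DNAStringSet` reference (alternative to `fasta`).
#' @param config an [rdcnv_config()].
#' @param filters record filters for BAM input, see [read_filters()].
#' @param exclude optional `GRanges` excluded a priori.
#' @param verbose print per-stage progress.
#' @return An object of class `rdcnv_result`: `calls` (with fold coverage
#'   and source pipeline), `clusters` (masked regions), `repeat_bias`,
#'   `library`, `config`, plus the per-pipeline window distributions.
#' @export
detect_cnvs <- function(bam = NULL, fasta = NULL, reads = NULL, ref = NULL,
                        config = rdcnv_config(), filters = read_filters(),
                        exclude = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)
  if (is.null(ref)) {
    stopifnot(!is.null(fasta))
    ref <- Biostrings::readDNAStringSet(fasta)
    names(ref) <- sub("\\s.*$", "", names(ref))
  }
  if (is.null(reads)) {
    stopifnot(!is.null(bam))
    say("reading alignments")
    reads <- read_alignments(bam, filters, exclude)
  }
  chroms <- names(ref)
  chrom_lengths <- stats::setNames(vapply(seq_along(ref),
                                          function(i) length(ref[[i]]), integer(1)),
                                   chroms)
  say("estimating library model")
  library <- estimate_library_model(reads)
  say("computing depth tracks")
  tracks <- lapply(chroms, function(ch)
    compute_depth_track(reads, ch, chrom_lengths[[ch]], config$w_base))
  names(tracks) <- chroms
  nmask <- reference_n_mask(ref)
  library <- summarize_depth(tracks, nmask, library)
  say("annotating dinucleotide runs and GC weights")
  runs <- rbindlist(lapply(chroms, function(ch)
    find_dinucleotide_runs(ref[[ch]], config$min_repeat_len, ch)))
  weights <- lapply(chroms, function(ch) compute_gc_weights(ref[[ch]], library))
  names(weights) <- chroms

  # bases within one insert of an N run have structurally truncated coverage
  # (no fragment spans N); exclude that shadow from binning and scanning
  shadow <- lapply(nmask, dilate_mask, pad = library$mean_insert)
  say("pipeline 2 (unmasked)")
  p2 <- run_pipeline(tracks, weights, runs, library, nmask, shadow, NULL,
                     config, "unmasked")
  if (config$mask_enabled) {
    say("pipeline 1 (masked)")
    mk <- compute_coverage_mask(tracks, library, nmask,
                                config$block_size, config$mask_multiple)
    if (any(vapply(mk$mask, any, logical(1)))) {
      # dilate the masked view by one insert: fragments spanning a cluster
      # edge leave an excess-coverage shoulder just outside the blocks
      hard1 <- lapply(mk$mask, dilate_mask, pad = library$mean_insert)
      p1 <- run_pipeline(tracks, weights, runs, library, nmask, shadow,
                         hard1, config, "masked")
      calls <- merge_pipeline_union(p1$calls, p2$calls)
    } else {
      # nothing masked: pipeline 1 is identical to pipeline 2
      calls <- data.table::copy(p2$calls)
      if (nrow(calls) > 0L) calls[, pipeline := "both"]
    }
    clusters <- mk$clusters
  } else {
    calls <- data.table::copy(p2$calls)
    clusters <- data.table(chrom = character(), first_block = integer(),
                           last_block = integer(), n_blocks = integer(),
                           n_high = integer())
  }
  calls <- add_fold(calls, tracks, library)
  setorder(calls, chrom, start, end)
  say("done: ", nrow(calls), " calls")
  structure(list(calls = calls[], clusters = clusters, repeat_bias = p2$bias,
                 library = library, config = config, dists = p2$dists),
            class = "rdcnv_result")
}

#' @export
print.rdcnv_result <- function(x, ...) {
  cat("rdcnv result:", nrow(x$calls), "calls (",
      sum(x$calls$type == "DEL"), "DEL,", sum(x$calls$type == "DUP"), "DUP ),",
      nrow(x$clusters), "masked clusters\n")
  if (nrow(x$calls) > 0L) print(x$calls)
  invisible(x)
}
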
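# Dinucleotide repeat bias: run detection, per-motif bias test, and
# distance-binned quantile normalization replacing GC normalization near
# biased repeats.

#' Find maximal dinucleotide repeat runs
#'
#' Detects maximal runs of period-2 repetition with two distinct bases
#' (homopolymers are a different bias class and are excluded). N bases
#' terminate runs. The motif is canonicalized to the lexicographically
#' smaller rotation, so `ATAT...` and `TATA...` both report `AT`.
#'
#' @param seq chromosome sequence (`DNAString` or character scalar).
#' @param min_len minimum run length in bases (default 20).
#' @param chrom chromosome name recorded in the output.
#' @return `data.table` with `chrom`, `start`, `end` (1-based closed),
#'   `motif`, `length`.
#' @export
find_dinucleotide_runs <- function(seq, min_len = 20L, chrom = "chr") {
  s <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1L]]
  n <- length(s)
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      motif = character(), length = integer())
  if (n < min_len) return(empty)
  valid <- s %in% c("A", "C", "G", "T")
  eq2 <- s[seq_len(n - 2L)] == s[3L:n] &
    valid[seq_len(n - 2L)] & valid[2L:(n - 1L)] & valid[3L:n]
  r <- rle(eq2)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- list()
  for (k in which(keep)) {
    a <- starts[k]; b <- ends[k] + 2L       # run spans [a, b] in sequence
    if (b - a + 1L < min_len) next
    c1 <- s[a]; c2 <- s[a + 1L]
    if (c1 == c2) next                       # homopolymer
    m1 <- paste0(c1, c2); m2 <- paste0(c2, c1)
    out[[length(out) + 1L]] <- data.table(
      chrom = chrom, start = a, end = b,
      motif = if (m1 <= m2) m1 else m2, length = b - a + 1L)
  }
  if (length(out) == 0L) return(empty)
  rbindlist(out)
}

#' Test each dinucleotide motif class for coverage bias
#'
#' A motif is biased when the mean per-base coverage over all of its run
#' bases differs from the genome mean by more than `sd_mult` genome per-base
#' depth standard deviations (in either direction). Motifs with fewer than
#' `min_occurrences` runs are reported unbiased.
#'
#' @param runs run table from [find_dinucleotide_runs()] (all chromosomes).
#' @param tracks named list of `rdcnv_depth` tracks.
#' @param library `rdcnv_library` with genome coverage statistics.
#' @param min_occurrences minimum number of runs per motif (default 50).
#' @param sd_mult bias threshold in genome depth SD units (default 1.5).
#' @return An object of class `rdcnv_repeatbias`: a `data.table` with
#'   `motif`, `n_runs`, `n_bases`, `mean_cov`, `direction`
#'   (`low`/`high`/`unbiased`).
#' @export
assess_motif_bias <- function(runs, tracks, library, min_occurrences = 50L,
                              sd_mult = 1.5) {
  gm <- library$genome_mean_depth
  gsd <- library$genome_depth_sd
  stopifnot(!is.na(gm), !is.na(gsd))
  if (nrow(runs) == 0L)
    return(structure(data.table(motif = character(), n_runs = integer(),
                                n_bases = integer(), mean_cov = numeric(),
                                direction = character()),
                     class = c("rdcnv_repeatbias", "data.table", "data.frame")))
  per <- runs[, {
    tot <- 0; nb <- 0L
    for (i in seq_len(.N)) {
      d <- tracks[[chrom[i]]]$depth[start[i]:end[i]]
      tot <- tot + sum(d); nb <- nb + length(d)
    }
    .(n_runs = .N, n_bases = nb, mean_cov = tot / nb)
  }, by = motif]
  per[, direction := "unbiased"]
  per[n_runs >= min_occurrences & mean_cov < gm - sd_mult * gsd, direction := "low"]
  per[n_runs >= min_occurrences & mean_cov > gm + sd_mult * gsd, direction := "high"]
  low_n <- per[n_runs < min_occurrences]
  if (nrow(low_n) > 0L)
    message("motifs below ", min_occurrences, " occurrences treated as unbiased: ",
            paste(low_n$motif, collapse = ", "))
  setorder(per, motif)
  structure(per, class = c("rdcnv_repeatbias", class(per)))
}

#' Assign bases near biased repeats to (motif, distance-bin) populations
#'
#' Every unmasked non-N base within half an insert length of a biased run is
#' assigned to the motif of its nearest biased run, with the distance (0
#' inside the run) discretized into 10-base bins. Bins smaller than
#' `min_bin_size` are merged into the adjacent farther bin of the same motif;
#' bases left in an undersized farthest bin fall back to GC normalization
#' (they are simply not assigned).
#'
#' @param bias `rdcnv_repeatbias` table.
#' @param runs run table.
#' @param library `rdcnv_library` (for the half-insert reach).
#' @param tracks named list of depth tracks.
#' @param nmask named list of logical N masks.
#' @param mask optional named list of exclusion masks.
#' @param dist_bin width of the distance bins (default 10 bases).
#' @param min_bin_size minimum population per bin (default 100).
#' @return `data.table` with `chrom`, `pos`, `depth`, `motif`, `dist`, `bin`,
#'   or an empty table when no motif is biased.
#' @keywords internal
repeat_assignments <- function(bias, runs, library, tracks, nmask, mask = NULL,
                               dist_bin = 10L, min_bin_size = 100L) {
  empty <- data.table(chrom = character(), pos = integer(), depth = integer(),
                      motif = character(), dist = integer(), bin = character())
  biased <- bias[direction != "unbiased", motif]
  if (length(biased) == 0L) return(empty)
  reach <- library$mean_insert %/% 2L
  br <- runs[motif %in% biased]
  if (nrow(br) == 0L) return(empty)
  cand <- vector("list", nrow(br))
  for (i in seq_len(nrow(br))) {
    ch <- br$chrom[i]
    len <- length(tracks[[ch]]$depth)
    p <- max(1L, br$start[i] - reach + 1L):min(len, br$end[i] + reach - 1L)
    d <- pmax(pmax(br$start[i] - p, p - br$end[i]), 0L)
    cand[[i]] <- data.table(chrom = ch, pos = p, dist = d,
                            motif = br$motif[i], runid = i)
  }
  cand <- rbindlist(cand)
  # nearest biased run wins when two runs compete (ties: earlier run)
  setorder(cand, chrom, pos, dist, runid)
  cand <- cand[!duplicated(cand, by = c("chrom", "pos"))]
  # drop N / masked bases
  keepv <- logical(nrow(cand))
  for (ch in unique(cand$chrom)) {
    sel <- cand$chrom == ch
    k <- !nmask[[ch]][cand$pos[sel]]
    if (!is.null(mask) && !is.null(mask[[ch]])) k <- k & !mask[[ch]][cand$pos[sel]]
    keepv[sel] <- k
  }
  cand <- cand[keepv]
  if (nrow(cand) == 0L) return(empty)
  for (ch in unique(cand$chrom))
    cand[chrom == ch, depth := tracks[[ch]]$depth[pos]]
  cand[, dbin := dist %/% dist_bin]
  # merge undersized distance bins into the adjacent farther bin, per motif
  out <- vector("list", 0L)
  for (m in unique(cand$motif)) {
    sub <- cand[motif == m]
    tab <- sub[, .N, by = dbin][order(dbin)]
    grp <- merge_farther(tab$dbin, tab$N, min_bin_size)
    mp <- data.table(dbin = tab$dbin, grp = grp)
    sub <- sub[mp, on = "dbin"]
    sub <- sub[!is.na(grp)]
    if (nrow(sub) > 0L) {
      sub[, bin := paste0("rep:", m, ":", grp)]
      out[[length(out) + 1L]] <- sub[, .(chrom, pos, depth, motif, dist, bin)]
    }
  }
  if (length(out) == 0L) return(empty)
  rbindlist(out)
}

# Merge ordered distance bins forward (toward larger distance) until every
# group reaches min_size; a trailing undersized group gets NA (fallback).
merge_farther <- function(dbins, cnt, min_size) {
  k <- length(dbins)
  grp <- integer(k)
  gid <- 0L
  acc <- 0
  start <- 1L
  for (i in seq_len(k)) {
    acc <- acc + cnt[i]
    grp[i] <- gid + 1L
    if (acc >= min_size) {
      gid <- gid + 1L
      grp[start:i] <- gid
      acc <- 0
      start <- i + 1L
    }
  }
  if (acc > 0) {                 # leftover undersized tail
    if (gid >= 1L) {
      # fold the tail into the last complete group only if it is adjacent;
      # distance bins are ordered so it always is
      grp[start:k] <- gid
    } else {
      grp[start:k] <- NA_integer_
    }
  }
  grp
}

#' Replace GC normalization with distance-binned normalization near repeats
#'
#' Applies the rank-based quantile normalization of [quantile_normalize()]
#' within each (motif, distance-bin) population and patches the resulting
#' standard-deviation units into the supplied normalized track. With no
#' biased motif the track is returned unchanged.
#'
#' @param norm `rdcnv_normtrack` from [quantile_normalize()].
#' @param bias `rdcnv_repeatbias` table.
#' @param runs run table.
#' @param tracks named list of depth tracks.
#' @param library `rdcnv_library`.
#' @param nmask named list of logical N masks.
#' @param mask optional named list of exclusion masks.
#' @param assignments optional precomputed [repeat_assignments()] table (the
#'   pipeline passes the same table used to exclude bases from GC binning).
#' @param cap_multiple high-coverage capping threshold multiple (default 2).
#' @return The patched `rdcnv_normtrack`.
#' @export
normalize_repeat_regions <- function(norm, bias, runs, tracks, library,
                                     nmask, mask = NULL, assignments = NULL,
                                     cap_multiple = 2.0) {
  if (is.null(assignments))
    assignments <- repeat_assignments(bias, runs, library, tracks, nmask, mask)
  if (nrow(assignments) == 0L) return(norm)
  patches <- normalize_bin_members(assignments, library, cap_multiple)
  patch_normtrack(norm, patches)
}

# Rank -> capped rank -> sd units for an arbitrary member table with a `bin`
# column; returns chrom/pos/x/r_ave patches.
normalize_bin_members <- function(mem, library, cap_multiple = 2.0) {
  cmd <- library$chrom_mean_depth
  mem <- data.table::copy(mem)
  setorder(mem, bin, depth, chrom, pos)
  mem[, `:=`(rank0 = seq_len(.N) - 1L, n = .N), by = bin]
  mem[, thr := cap_multiple * cmd[chrom]]
  mem[, rank_adj := cap_high_coverage_ranks(rank0, depth, thr), by = bin]
  mem[, x := rank_to_sd_units(rank_adj, n[1L]), by = bin]
  mem[, r_ave := mean(depth), by = bin]
  mem[, .(chrom, pos, x, r_ave)]
}

#' Export repeat runs as BED
#'
#' @param runs run table from [find_dinucleotide_runs()].
#' @param file output path (0-based half-open coordinates).
#' @export
export_repeat_bed <- function(runs, file) {
  dt <- data.table(chrom = runs$chrom, start = runs$start - 1L,
                   end = runs$end, name = runs$motif)
  utils::write.table(dt, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
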
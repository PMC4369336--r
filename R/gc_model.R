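# GC bias model: per-base insert-weighted GC content, mapping-quality
# stratified GC bins, rank capping, and quantile normalization of read depth
# to standard-deviation units.

# Logical flags per base of a reference sequence: gc (G or C), ok (A/C/G/T).
seq_flags <- function(seq) {
  s <- charToRaw(toupper(as.character(seq)))
  gc <- s == charToRaw("G") | s == charToRaw("C")
  ok <- gc | s == charToRaw("A") | s == charToRaw("T")
  list(gc = as.logical(gc), ok = as.logical(ok))
}

#' Per-base GC weighting
#'
#' For each base `i` the GC weighting is `h_i = sum_j w_j a_j / sum_j w_j`
#' over bases `j` within one mean insert length of `i`, where `a_j` is 1 for
#' G/C and 0 for A/T, and `w_j` counts the distinct insert placements (of the
#' library's mean insert length) that cover both `i` and `j` and fit within
#' the chromosome. In the chromosome interior `w_j = L - |i - j|`; near the
#' ends fewer placements fit and the weights are truncated accordingly.
#' N bases contribute to neither numerator nor denominator; a base whose
#' whole context is N gets `NaN`.
#'
#' @param seq chromosome sequence (`DNAString` or character scalar).
#' @param library an `rdcnv_library`, or a single integer mean insert length.
#' @return Numeric vector of `h` values in `[0, 1]` (or `NaN`), one per base.
#' @export
compute_gc_weights <- function(seq, library) {
  L <- if (inherits(library, "rdcnv_library")) library$mean_insert else as.integer(library)
  stopifnot(L >= 1L)
  fl <- seq_flags(seq)
  n <- length(fl$gc)
  L <- min(L, n)
  if (L == 1L) {
    h <- ifelse(fl$ok, as.numeric(fl$gc), NaN)
    return(h)
  }
  num <- tri_conv(as.numeric(fl$gc), L)
  den <- tri_conv(as.numeric(fl$ok), L)
  # exact end-truncated weights where interior triangular weights are wrong
  edge <- unique(c(seq_len(min(L - 1L, n)),
                   seq.int(max(n - L + 2L, 1L), n)))
  smax <- n - L + 1L
  for (i in edge) {
    j <- seq.int(max(1L, i - L + 1L), min(n, i + L - 1L))
    w <- pmin(pmin(i, j), smax) - pmax(1L, pmax(i, j) - L + 1L) + 1L
    w <- pmax(w, 0L)
    num[i] <- sum(w * fl$gc[j])
    den[i] <- sum(w * fl$ok[j])
  }
  h <- ifelse(den > 0, num / den, NaN)
  h[!fl$ok & is.nan(h)] <- NaN
  h
}

#' Convert a within-bin depth rank to standard-deviation units
#'
#' The rank proportion is `p = R/n` when `2R <= n` and `p = (n - R)/n`
#' otherwise, with the numerator floored at 0.5 when it would be zero. The
#' proportion maps through the inverse standard-normal CDF with the sign
#' restored so that `x` is monotone non-decreasing in `R` and `R = n/2` maps
#' to exactly 0. Fractional ranks (after high-coverage capping) are allowed.
#'
#' @param R rank(s) in `[0, n - 1]`.
#' @param n bin size.
#' @return Numeric vector of depth in standard-deviation units.
#' @export
rank_to_sd_units <- function(R, n) {
  stopifnot(n >= 1)
  if (any(R < 0 | R > n - 1)) stop("rank outside [0, n-1]")
  below <- 2 * R <= n
  p <- ifelse(below, pmax(R, 0.5), pmax(n - R, 0.5)) / n
  x <- stats::qnorm(p)
  ifelse(below, x, -x)
}

#' Average high-coverage ranks toward the rank of twice the chromosome mean
#'
#' Members of a bin whose raw depth exceeds the capping threshold (twice the
#' chromosome average by default) have their rank replaced by the mean of the
#' observed rank and the rank that a depth equal to the threshold would take
#' in the bin (interpolated between neighbouring sorted depths when the exact
#' value is absent). Other ranks are unchanged.
#'
#' @param ranks 0-based ranks of the bin members.
#' @param depths raw depths of the bin members.
#' @param threshold capping threshold(s); recycled, so per-member thresholds
#'   (bins can span chromosomes with different means) are supported.
#' @return Numeric vector of adjusted (possibly fractional) ranks.
#' @export
cap_high_coverage_ranks <- function(ranks, depths, threshold) {
  nn <- length(depths)
  out <- as.numeric(ranks)
  thr <- rep_len(as.numeric(threshold), nn)
  over <- depths > thr
  if (!any(over)) return(out)
  dsort <- sort(depths)
  for (t in unique(thr[over])) {
    sel <- over & thr == t
    less <- findInterval(t, dsort, left.open = TRUE)
    leq <- findInterval(t, dsort)
    r2x <- if (leq > less) (less + leq - 1) / 2
      else if (less == 0L) 0
      else if (less == nn) nn - 1
      else (less - 1) + (t - dsort[less]) / (dsort[less + 1L] - dsort[less])
    out[sel] <- (out[sel] + r2x) / 2
  }
  out
}

#' Assign non-N bases to mapping-quality stratified GC bins
#'
#' The GC weighting is discretized to bins of width `gc_bin_width`; each
#' unmasked non-N base joins the bin for its (discretized `h`, mapping
#' quality stratum) pair, where the stratum is low when the mean mapping
#' quality of the base's containing window is below `mq_threshold`. Bins
#' smaller than `min_bin_size` are merged into the nearest adjacent GC level
#' of the same stratum.
#'
#' @param weights named list of per-base `h` vectors (one per chromosome).
#' @param tracks named list of `rdcnv_depth` tracks.
#' @param nmask named list of logical N masks.
#' @param mask optional named list of logical masks (`TRUE` = excluded, e.g.
#'   excessive-coverage clusters in the masked pipeline).
#' @param exclude optional `data.table(chrom, pos)` of bases normalized
#'   elsewhere (repeat distance bins).
#' @param gc_bin_width,min_bin_size,mq_threshold binning parameters.
#' @return An object of class `rdcnv_gcbins`: `members` (a `data.table` with
#'   `chrom`, `pos`, `depth`, `bin`) and `bins` (per-bin `n` and mean raw
#'   depth `r_ave`).
#' @export
assign_gc_bins <- function(weights, tracks, nmask, mask = NULL, exclude = NULL,
                           gc_bin_width = 0.01, min_bin_size = 100L,
                           mq_threshold = 5) {
  stopifnot(all(names(tracks) %in% names(weights)))
  pieces <- lapply(names(tracks), function(ch) {
    tr <- tracks[[ch]]
    h <- weights[[ch]]
    keep <- !nmask[[ch]] & !is.nan(h)
    if (!is.null(mask) && !is.null(mask[[ch]])) keep <- keep & !mask[[ch]]
    pos <- which(keep)
    if (length(pos) == 0L) return(NULL)
    widx <- pmin((pos - 1L) %/% tr$w_base + 1L, length(tr$window_mq))
    wmq <- tr$window_mq[widx]
    data.table(chrom = ch, pos = pos,
               depth = tr$depth[pos],
               gc_level = as.integer(round(h[pos] / gc_bin_width)),
               stratum = ifelse(!is.na(wmq) & wmq < mq_threshold, "low", "high"))
  })
  members <- rbindlist(pieces)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    members <- members[!exclude, on = c("chrom", "pos")]
  }
  if (nrow(members) == 0L) stop("no bases available for GC binning")
  # merge small GC levels within each stratum
  members[, bin := NA_character_]
  for (st in unique(members$stratum)) {
    tab <- members[stratum == st, .N, by = gc_level][order(gc_level)]
    grp <- merge_small_groups(tab$gc_level, tab$N, min_bin_size)
    mp <- data.table(gc_level = tab$gc_level, bin = paste0(st, ":", grp))
    members[stratum == st, bin := mp$bin[match(gc_level, mp$gc_level)]]
  }
  bins <- members[, .(n = .N, r_ave = mean(depth),
                      gc_level = stats::weighted.mean(gc_level, rep(1, .N)),
                      stratum = stratum[1L]), by = bin]
  structure(list(members = members[, .(chrom, pos, depth, bin)],
                 bins = bins,
                 gc_bin_width = gc_bin_width,
                 min_bin_size = as.integer(min_bin_size),
                 mq_threshold = mq_threshold),
            class = "rdcnv_gcbins")
}

# Merge ordered groups (levels lv with counts cnt) so that every surviving
# group has >= min_size members, always folding the smallest group into its
# nearest neighbour (ties: the lower level). Returns a group id per level.
merge_small_groups <- function(lv, cnt, min_size) {
  g <- seq_along(lv)
  glo <- as.numeric(lv); ghi <- as.numeric(lv); gn <- as.numeric(cnt)
  while (length(gn) > 1L && min(gn) < min_size) {
    i <- which.min(gn)
    j <- if (i == 1L) 2L
      else if (i == length(gn)) i - 1L
      else if (glo[i] - ghi[i - 1L] <= glo[i + 1L] - ghi[i]) i - 1L
      else i + 1L
    k <- min(i, j); m <- max(i, j)
    ghi[k] <- ghi[m]; gn[k] <- gn[k] + gn[m]
    glo <- glo[-m]; ghi <- ghi[-m]; gn <- gn[-m]
    g[g == m] <- k
    g[g > m] <- g[g > m] - 1L
  }
  g
}

#' Quantile-normalize depth within GC bins to standard-deviation units
#'
#' Within each bin, members are ranked by raw depth (ties broken by genomic
#' position), high-coverage ranks are capped via
#' [cap_high_coverage_ranks()], and ranks map to standard-normal quantiles
#' via [rank_to_sd_units()]. Bases not in any bin (N, masked, repeat-bin
#' bases) are `NaN`.
#'
#' @param gcbins an `rdcnv_gcbins` object.
#' @param library an `rdcnv_library` with `chrom_mean_depth` filled in.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param cap_multiple capping threshold as a multiple of the chromosome
#'   mean depth (default 2).
#' @return An object of class `rdcnv_normtrack`: lists `x` and `r_ave` of
#'   per-chromosome numeric vectors.
#' @export
quantile_normalize <- function(gcbins, library, chrom_lengths,
                               cap_multiple = 2.0) {
  cmd <- library$chrom_mean_depth
  mem <- data.table::copy(gcbins$members)
  setorder(mem, bin, depth, chrom, pos)
  mem[, `:=`(rank0 = seq_len(.N) - 1L, n = .N), by = bin]
  mem[, thr := cap_multiple * cmd[chrom]]
  mem[, rank_adj := cap_high_coverage_ranks(rank0, depth, thr), by = bin]
  mem[, x := rank_to_sd_units(rank_adj, n[1L]), by = bin]
  mem <- mem[gcbins$bins[, .(bin, r_ave)], on = "bin"]
  new_normtrack(mem, chrom_lengths)
}

# Assemble per-chromosome x / r_ave vectors from a member table.
new_normtrack <- function(mem, chrom_lengths) {
  xs <- lapply(names(chrom_lengths), function(ch) rep(NaN, chrom_lengths[[ch]]))
  ra <- lapply(names(chrom_lengths), function(ch) rep(NA_real_, chrom_lengths[[ch]]))
  names(xs) <- names(ra) <- names(chrom_lengths)
  for (ch in unique(mem$chrom)) {
    sub <- mem[chrom == ch]
    xs[[ch]][sub$pos] <- sub$x
    ra[[ch]][sub$pos] <- sub$r_ave
  }
  structure(list(x = xs, r_ave = ra), class = "rdcnv_normtrack")
}

# Patch normalized values (data.table chrom,pos,x,r_ave) into a track.
patch_normtrack <- function(norm, patches) {
  if (is.null(patches) || nrow(patches) == 0L) return(norm)
  for (ch in unique(patches$chrom)) {
    sub <- patches[chrom == ch]
    norm$x[[ch]][sub$pos] <- sub$x
    norm$r_ave[[ch]][sub$pos] <- sub$r_ave
  }
  norm
}

#' Mean-normalization diagnostic (per-GC-bin standard deviations)
#'
#' Implements the classical GC correction `r_norm = r * m / m_GC` on
#' fixed-size non-overlapping windows (reads assigned by read center) and
#' tabulates the per-GC-bin standard deviation of the corrected counts. The
#' mean correction equalizes bin means but not bin variances, which is the
#' phenomenon motivating the quantile approach; this function is a
#' diagnostic only and takes no part in CNV calling.
#'
#' @param reads alignment table.
#' @param ref `DNAStringSet` reference.
#' @param window window size in bases (default 100).
#' @param gc_bin_width width of the GC-content bins (default 0.01).
#' @return `data.table` with one row per GC bin: `gc`, `n`, `mean`, `sd`.
#' @export
gc_mean_normalize_diagnostic <- function(reads, ref, window = 100L,
                                         gc_bin_width = 0.01) {
  pieces <- lapply(names(ref), function(ch) {
    len <- length(ref[[ch]])
    nwin <- len %/% window
    if (nwin == 0L) return(NULL)
    fl <- seq_flags(ref[[ch]])
    csg <- c(0, cumsum(as.numeric(fl$gc)))
    cso <- c(0, cumsum(as.numeric(fl$ok)))
    e <- seq_len(nwin) * window
    s <- e - window
    okn <- cso[e + 1L] - cso[s + 1L]
    gcw <- ifelse(okn == window, (csg[e + 1L] - csg[s + 1L]) / window, NA_real_)
    r <- reads[chrom == ch]
    center <- (r$start + r$end) %/% 2L
    cnt <- tabulate(pmin((center - 1L) %/% window + 1L, nwin), nbins = nwin)
    data.table(gc = gcw, r = cnt)[!is.na(gc)]
  })
  wdt <- rbindlist(pieces)
  if (nrow(wdt) == 0L) stop("no usable windows")
  wdt[, gc := round(gc / gc_bin_width) * gc_bin_width]
  m <- mean(wdt$r)
  wdt[, r_norm := r * m / mean(r), by = gc]
  out <- wdt[, .(n = .N, mean = mean(r_norm),
                 sd = if (.N > 1L) stats::sd(r_norm) else 0), by = gc]
  setorder(out, gc)
  out[]
}
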
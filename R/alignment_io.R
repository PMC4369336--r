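# Alignment input: per-base depth, per-window mapping quality, and library
# statistics (read length, insert size, coverage moments).

#' Default alignment record filters
#'
#' Unmapped, secondary, supplementary, duplicate-flagged and QC-fail records
#' are dropped; MAPQ 0 reads are kept (low mapping quality is handled by the
#' mapping-quality stratification of the GC model, not by discarding reads).
#'
#' @param drop_duplicates,drop_secondary,drop_supplementary,drop_qcfail
#'   logical; drop records with the corresponding SAM flag.
#' @param min_mapq minimum mapping quality to retain (default 0, keep all).
#' @return A named list of filter settings.
#' @export
read_filters <- function(drop_duplicates = TRUE, drop_secondary = TRUE,
                         drop_supplementary = TRUE, drop_qcfail = TRUE,
                         min_mapq = 0L) {
  list(drop_duplicates = drop_duplicates, drop_secondary = drop_secondary,
       drop_supplementary = drop_supplementary, drop_qcfail = drop_qcfail,
       min_mapq = as.integer(min_mapq))
}

#' Read alignments from an indexed BAM file
#'
#' Loads primary alignments into the flat table used by all downstream steps.
#' Coordinates are 1-based closed (the R/Bioconductor convention); the span
#' of a record covers every reference-consuming CIGAR operation.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param filters record filters from [read_filters()].
#' @param exclude optional `GRanges` of regions whose reads are dropped
#'   a priori (reads whose span overlaps any excluded region).
#' @return A `data.table` with columns `chrom`, `start`, `end`, `mapq`,
#'   `tlen`, `paired`, `proper`, `isdup`.
#' @export
read_alignments <- function(bam, filters = read_filters(), exclude = NULL) {
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (filters$drop_secondary) FALSE else NA,
    isSupplementaryAlignment = if (filters$drop_supplementary) FALSE else NA,
    isDuplicate = if (filters$drop_duplicates) FALSE else NA,
    isNotPassingQualityControls = if (filters$drop_qcfail) FALSE else NA)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("mapq", "isize", "flag"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(ga) == 0L) stop("no usable alignments")
  md <- S4Vectors::mcols(ga)
  reads <- data.table(
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga),
    end   = GenomicAlignments::end(ga),
    mapq  = ifelse(is.na(md$mapq), 0L, md$mapq),
    tlen  = ifelse(is.na(md$isize), 0L, md$isize),
    paired = bitwAnd(md$flag, 1L) > 0L,
    proper = bitwAnd(md$flag, 2L) > 0L,
    isdup  = FALSE)
  if (filters$min_mapq > 0L) reads <- reads[mapq >= filters$min_mapq]
  if (!is.null(exclude) && length(exclude) > 0L) {
    gr <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(reads$start, reads$end))
    hit <- IRanges::overlapsAny(gr, exclude)
    reads <- reads[!hit]
  }
  if (nrow(reads) == 0L) stop("no usable alignments")
  reads[]
}

#' Estimate library statistics from alignments
#'
#' The mean insert size is the rounded mean of absolute template lengths over
#' the first `sample_size` properly-paired records; the read length is the
#' modal aligned read length. For single-end libraries the insert size equals
#' the read length (the fragment is the read).
#'
#' @param reads alignment table from [read_alignments()] or
#'   [simulate_alignments()].
#' @param sample_size number of properly-paired records used for the insert
#'   estimate.
#' @return An object of class `rdcnv_library` with fields `read_length`,
#'   `mean_insert`, `paired`, plus coverage statistics filled in later by
#'   [summarize_depth()].
#' @export
estimate_library_model <- function(reads, sample_size = 100000L) {
  if (is.null(reads) || nrow(reads) == 0L) stop("no usable alignments")
  stopifnot(sample_size >= 1L)
  widths <- reads$end - reads$start + 1L
  tab <- table(widths)
  if (length(tab) > 1L)
    warning("mixed read lengths; using the mode")
  read_length <- as.integer(names(tab)[which.max(tab)])
  pp <- reads[paired & proper & tlen != 0L]
  if (nrow(pp) > 0L) {
    n <- min(nrow(pp), sample_size)
    mean_insert <- as.integer(round(mean(abs(pp$tlen[seq_len(n)]))))
    paired <- TRUE
  } else {
    mean_insert <- read_length
    paired <- FALSE
  }
  structure(list(read_length = read_length,
                 mean_insert = max(mean_insert, read_length),
                 paired = paired,
                 chrom_mean_depth = NULL,
                 genome_mean_depth = NA_real_,
                 genome_depth_sd = NA_real_),
            class = "rdcnv_library")
}

#' @export
print.rdcnv_library <- function(x, ...) {
  cat("rdcnv library model\n")
  cat("  read length :", x$read_length, "\n")
  cat("  mean insert :", x$mean_insert, if (x$paired) "(paired)" else "(single-end)", "\n")
  if (!is.na(x$genome_mean_depth))
    cat("  genome depth:", round(x$genome_mean_depth, 3), "+/-",
        round(x$genome_depth_sd, 3), "\n")
  invisible(x)
}

#' Compute a per-base depth track for one chromosome
#'
#' Depth at base `b` counts every retained read whose aligned span covers `b`
#' (pileup convention). Mean mapping quality is recorded per non-overlapping
#' window of `w_base` bases, assigning each read to the window containing its
#' center; windows with no reads get `NA` (no mapping quality is observed
#' there, so such windows are not treated as low-quality).
#'
#' @param reads alignment table (any chromosomes; subset internally).
#' @param chrom chromosome name.
#' @param chrom_length reference length of the chromosome.
#' @param w_base window size for the mapping-quality track (default 100).
#' @return An object of class `rdcnv_depth` with fields `chrom`, `depth`
#'   (integer, length `chrom_length`), `window_mq`, `w_base`.
#' @export
compute_depth_track <- function(reads, chrom, chrom_length, w_base = 100L) {
  stopifnot(chrom_length > 0L)
  sel <- reads$chrom == chrom
  r <- reads[which(sel)]
  nwin <- as.integer(ceiling(chrom_length / w_base))
  if (nrow(r) == 0L) {
    warning("no reads on chromosome ", chrom, "; empty track")
    return(structure(list(chrom = chrom, depth = integer(chrom_length),
                          window_mq = rep(NA_real_, nwin),
                          w_base = as.integer(w_base)),
                     class = "rdcnv_depth"))
  }
  if (is.unsorted(r$start)) stop("alignments are not coordinate-sorted")
  if ("isdup" %in% names(r)) r <- r[!r$isdup]
  ir <- IRanges::IRanges(pmax(r$start, 1L), pmin(r$end, chrom_length))
  depth <- as.integer(IRanges::coverage(ir, width = chrom_length))
  center <- (r$start + r$end) %/% 2L
  widx <- pmin((center - 1L) %/% w_base + 1L, nwin)
  wm <- r[, .(m = mean(mapq)), by = .(win = widx)]
  window_mq <- rep(NA_real_, nwin)
  window_mq[wm$win] <- wm$m
  structure(list(chrom = chrom, depth = depth, window_mq = window_mq,
                 w_base = as.integer(w_base)),
            class = "rdcnv_depth")
}

#' Coverage moments over all depth tracks
#'
#' Chromosome means, genome mean and genome per-base depth standard deviation
#' are computed over non-N bases only. All-N chromosomes are excluded with a
#' warning.
#'
#' @param tracks named list of `rdcnv_depth` tracks.
#' @param nmask named list of logical vectors, `TRUE` at N bases.
#' @param library optional `rdcnv_library` to fill in; a bare list of the
#'   three statistics is returned otherwise.
#' @return The updated library model (or a list with `chrom_mean_depth`,
#'   `genome_mean_depth`, `genome_depth_sd`).
#' @export
summarize_depth <- function(tracks, nmask, library = NULL) {
  stopifnot(length(tracks) >= 1L)
  s0 <- 0; s1 <- 0; s2 <- 0
  cm <- numeric(0)
  for (tr in tracks) {
    keep <- !nmask[[tr$chrom]]
    n <- sum(keep)
    if (n == 0L) {
      warning("chromosome ", tr$chrom, " is all N; excluded from coverage statistics")
      next
    }
    d <- as.numeric(tr$depth[keep])
    cm[tr$chrom] <- sum(d) / n
    s0 <- s0 + n; s1 <- s1 + sum(d); s2 <- s2 + sum(d * d)
  }
  if (s0 == 0L) stop("no non-N bases in any track")
  gm <- s1 / s0
  gsd <- sqrt(max(s2 / s0 - gm^2, 0))
  if (is.null(library))
    return(list(chrom_mean_depth = cm, genome_mean_depth = gm, genome_depth_sd = gsd))
  library$chrom_mean_depth <- cm
  library$genome_mean_depth <- gm
  library$genome_depth_sd <- gsd
  library
}

#' Export a per-base track as BedGraph
#'
#' Consecutive equal values are collapsed into one interval; coordinates are
#' written 0-based half-open.
#'
#' @param values numeric vector (per base) or an `rdcnv_depth` track.
#' @param chrom chromosome name (ignored when a track is given).
#' @param file output path.
#' @export
export_bedgraph <- function(values, chrom = NULL, file) {
  if (inherits(values, "rdcnv_depth")) {
    chrom <- values$chrom
    values <- values$depth
  }
  r <- rle(as.numeric(values))
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  keep <- !is.na(r$values)
  dt <- data.table(chrom = chrom, start = s[keep], end = e[keep],
                   value = r$values[keep])
  utils::write.table(dt, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

# N-base mask (TRUE at any base that is not A/C/G/T) per chromosome.
reference_n_mask <- function(ref) {
  out <- lapply(seq_along(ref), function(i) {
    f <- Biostrings::alphabetFrequency(ref[[i]])
    if (sum(f[c("A", "C", "G", "T")]) == length(ref[[i]]))
      return(rep(FALSE, length(ref[[i]])))
    s <- strsplit(as.character(ref[[i]]), "", fixed = TRUE)[[1]]
    !(s %in% c("A", "C", "G", "T"))
  })
  names(out) <- names(ref)
  out
}
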
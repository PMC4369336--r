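# Excessive-coverage masking: flag high-coverage blocks, cluster them, and
# build the masked-genome view used by the first calling pipeline.

#' Flag blocks of excessive coverage
#'
#' The chromosome is cut into non-overlapping blocks of `block_size` bases
#' (the trailing partial block is evaluated on its actual length); a block is
#' flagged when its mean depth over non-N bases strictly exceeds
#' `multiple` times the chromosome average.
#'
#' @param track an `rdcnv_depth` track.
#' @param chrom_mean mean depth of the chromosome (non-N bases).
#' @param block_size block size in bases (default 10000).
#' @param multiple flagging threshold as a multiple of the chromosome mean
#'   (default 2; strictly greater than).
#' @param nmask optional logical N mask for the chromosome.
#' @return Logical vector, one entry per block.
#' @export
compute_block_flags <- function(track, chrom_mean, block_size = 10000L,
                                multiple = 2.0, nmask = NULL) {
  stopifnot(chrom_mean > 0)
  n <- length(track$depth)
  nb <- as.integer(ceiling(n / block_size))
  d <- as.numeric(track$depth)
  ok <- if (is.null(nmask)) rep(1, n) else as.numeric(!nmask)
  cs <- c(0, cumsum(d * ok))
  cn <- c(0, cumsum(ok))
  ends <- pmin(seq_len(nb) * block_size, n)
  starts <- (seq_len(nb) - 1L) * block_size
  sums <- cs[ends + 1L] - cs[starts + 1L]
  cnts <- cn[ends + 1L] - cn[starts + 1L]
  means <- ifelse(cnts > 0, sums / cnts, 0)
  as.vector(means > multiple * chrom_mean)
}

#' Cluster high-coverage blocks
#'
#' A cluster is a maximal stretch of blocks, beginning and ending on high
#' blocks, whose high-block density strictly exceeds `min_density` and that
#' contains at least `min_high` high blocks. Maximality is by interval
#' inclusion, so the definition is symmetric under reversal of the block
#' order; clusters produced by distinct starts may overlap (they are masked
#' as a union anyway).
#'
#' @param flags logical block flags from [compute_block_flags()].
#' @param min_high minimum number of high blocks per cluster (default 4).
#' @param min_density minimum high-block fraction over the cluster span
#'   (default 0.25, strictly greater than).
#' @return `data.table` with `first_block`, `last_block` (1-based block
#'   indices), `n_blocks`, `n_high`.
#' @export
find_excess_clusters <- function(flags, min_high = 4L, min_density = 0.25) {
  empty <- data.table(first_block = integer(), last_block = integer(),
                      n_blocks = integer(), n_high = integer())
  hi <- which(flags)
  K <- length(hi)
  if (K == 0L) return(empty)
  # J[i]: largest j such that the interval from high block i to high block j
  # keeps high-block density > min_density (j = i always qualifies)
  J <- integer(K)
  for (i in seq_len(K)) {
    nh <- seq_len(K - i + 1L)
    span <- hi[i:K] - hi[i] + 1L
    J[i] <- i + max(which(nh / span > min_density)) - 1L
  }
  # [i, J[i]] is maximal iff no earlier start reaches at least as far
  keep <- J > cummax(c(0L, J[-K]))
  keep <- keep & (J - seq_len(K) + 1L >= min_high)
  data.table(first_block = hi[keep], last_block = hi[J[keep]],
             n_blocks = hi[J[keep]] - hi[keep] + 1L,
             n_high = J[keep] - which(keep) + 1L)
}

#' Convert block clusters into a per-base exclusion mask
#'
#' @param clusters cluster table from [find_excess_clusters()].
#' @param chrom_length chromosome length in bases.
#' @param block_size block size used for flagging.
#' @return Logical vector of length `chrom_length`, `TRUE` inside clusters.
#' @export
apply_mask <- function(clusters, chrom_length, block_size = 10000L) {
  m <- rep(FALSE, chrom_length)
  if (nrow(clusters) > 0L) {
    for (i in seq_len(nrow(clusters))) {
      a <- (clusters$first_block[i] - 1L) * block_size + 1L
      b <- min(clusters$last_block[i] * block_size, chrom_length)
      m[a:b] <- TRUE
    }
  }
  m
}

# Full masking step for all chromosomes; returns list(mask = named list of
# logical vectors, clusters = data.table with chrom column).
compute_coverage_mask <- function(tracks, library, nmask,
                                  block_size = 10000L, multiple = 2.0) {
  masks <- list(); cl <- list()
  for (ch in names(tracks)) {
    cm <- library$chrom_mean_depth[[ch]]
    len <- length(tracks[[ch]]$depth)
    if (is.null(cm) || is.na(cm) || cm <= 0) {
      masks[[ch]] <- rep(FALSE, len)
      next
    }
    fl <- compute_block_flags(tracks[[ch]], cm, block_size, multiple, nmask[[ch]])
    cc <- find_excess_clusters(fl)
    masks[[ch]] <- apply_mask(cc, len, block_size)
    if (nrow(cc) > 0L) cl[[ch]] <- data.table(chrom = ch, cc)
  }
  clusters <- if (length(cl)) rbindlist(cl) else
    data.table(chrom = character(), first_block = integer(),
               last_block = integer(), n_blocks = integer(), n_high = integer())
  list(mask = masks, clusters = clusters)
}

#' Export mask clusters as BED
#'
#' @param clusters cluster table with a `chrom` column (from the pipeline).
#' @param block_size block size used for flagging.
#' @param file output path (0-based half-open coordinates).
#' @export
export_mask_bed <- function(clusters, block_size = 10000L, file) {
  dt <- data.table(chrom = clusters$chrom,
                   start = (clusters$first_block - 1L) * block_size,
                   end = clusters$last_block * block_size,
                   name = paste0("mask_nhigh=", clusters$n_high))
  utils::write.table(dt, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
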
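# Internal numeric helpers shared across modules.

#' @import data.table
#' @importFrom Rcpp sourceCpp
#' @useDynLib rdcnv, .registration = TRUE
NULL

utils::globalVariables(c(
  ".", ".N", ".I", "chrom", "pos", "depth", "bin", "gc_level", "stratum",
  "r_ave", "motif", "dist", "dbin", "rank0", "x", "win", "mapq", "start",
  "end", "tlen", "proper", "paired", "isdup", "type", "z", "pipeline",
  "fold", "score", "n_runs", "n_bases", "mean_cov", "direction", "width",
  "thr", "J", "N", "runid", "d", "cn", "mid", "keepn", "ro", "qid", "tid",
  "n_high", "first_block", "last_block", "sizes", "mu", "sigma", "l",
  "gc", "r_norm", "level", "strata", "i.x", "i.r_ave", "call_id",
  "rank_adj", "bp_err", "grp", "mate", "fid", "r", "name", "value"
))

# Rolling sum of all length-`l` windows; returns vector of length n - l + 1.
win_sum <- function(v, l) {
  n <- length(v)
  if (l > n) return(numeric(0))
  cs <- cumsum(as.numeric(v))
  c(cs[l], cs[(l + 1L):n] - cs[1L:(n - l)])[seq_len(n - l + 1L)]
}

# Triangular-kernel convolution: out[i] = sum_j max(0, L - |i - j|) * v[j],
# with v treated as 0 outside [1, n].  Equivalent to two boxcar passes.
tri_conv <- function(v, L) {
  n <- length(v)
  if (L <= 1L) return(as.numeric(v))
  cs <- c(0, cumsum(as.numeric(v)))
  # y[i] = sum of v over [i - L + 1, i]
  idx_hi <- pmin(seq_len(n + L - 1L), n)
  idx_lo <- pmax(seq_len(n + L - 1L) - L, 0L)
  y <- cs[idx_hi + 1L] - cs[idx_lo + 1L]          # defined for i in 1..n+L-1
  cy <- c(0, cumsum(y))
  # out[i] = sum of y over [i, i + L - 1]
  cy[seq_len(n) + L] - cy[seq_len(n)]
}

# 0-based ranks (0..n-1) in the order given by `ord` (a permutation).
rank0_from_order <- function(ord) {
  r <- integer(length(ord))
  r[ord] <- seq_along(ord) - 1L
  r
}

# One-sided normal tail probability of |z|, as a Phred-like BED score.
z_to_score <- function(z) {
  lp <- stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
  pmin(1000, round(-10 * lp / log(10)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
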
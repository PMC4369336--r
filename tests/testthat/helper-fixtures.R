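# Shared helpers: read-table constructors, brute-force oracles and cached
# simulated fixtures (built once per test session).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# minimal alignment table
make_reads <- function(chrom, start, width = 50L, mapq = 60L, tlen = 0L,
                       paired = FALSE, proper = paired, isdup = FALSE) {
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(start + width - 1L),
                         mapq = as.integer(mapq), tlen = as.integer(tlen),
                         paired = paired, proper = proper, isdup = isdup)
}

# brute-force per-base interval-stabbing depth
oracle_depth <- function(starts, ends, len) {
  d <- integer(len)
  for (i in seq_along(starts))
    d[starts[i]:ends[i]] <- d[starts[i]:ends[i]] + 1L
  d
}

# brute-force GC weighting with end-truncated insert placements
oracle_gc_weights <- function(s, L) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  n <- length(ch)
  L <- min(L, n)
  gc <- ch %in% c("G", "C")
  ok <- gc | ch %in% c("A", "T")
  smax <- n - L + 1L
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - L + 1L):min(n, i + L - 1L)
    w <- pmax(pmin(pmin(i, j), smax) - pmax(1L, pmax(i, j) - L + 1L) + 1L, 0L)
    den <- sum(w[ok[j]])
    if (den > 0) sum(w[gc[j]]) / den else NaN
  }, numeric(1))
}

# brute-force maximal period-2 runs with two distinct bases
oracle_dinuc_runs <- function(s, min_len) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  n <- length(ch)
  valid <- ch %in% c("A", "C", "G", "T")
  out <- list()
  i <- 1L
  while (i <= n - 1L) {
    if (valid[i] && valid[i + 1L] && ch[i] != ch[i + 1L]) {
      j <- i + 1L
      while (j + 1L <= n && valid[j + 1L] && ch[j + 1L] == ch[j - 1L]) j <- j + 1L
      len <- j - i + 1L
      # maximal to the left?
      left_ext <- i > 1L && valid[i - 1L] && ch[i - 1L] == ch[i + 1L]
      if (!left_ext && len >= min_len) {
        m <- sort(c(ch[i], ch[i + 1L]))
        out[[length(out) + 1L]] <- data.frame(
          start = i, end = j, motif = paste0(m[1], m[2]), length = len,
          stringsAsFactors = FALSE)
      }
      if (!left_ext) i <- j else i <- i + 1L
    } else i <- i + 1L
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), length = integer()))
  do.call(rbind, out)
}

# brute-force greedy reciprocal-overlap matching
oracle_match <- function(calls, truth, min_ro) {
  pairs <- list()
  for (q in seq_len(nrow(calls))) for (t in seq_len(nrow(truth))) {
    if (calls$chrom[q] != truth$chrom[t] || calls$type[q] != truth$type[t]) next
    ov <- min(calls$end[q], truth$end[t]) - max(calls$start[q], truth$start[t]) + 1L
    if (ov <= 0L) next
    ro <- min(ov / (calls$end[q] - calls$start[q] + 1L),
              ov / (truth$end[t] - truth$start[t] + 1L))
    if (ro >= min_ro)
      pairs[[length(pairs) + 1L]] <- data.frame(qid = q, tid = t, ro = ro)
  }
  if (length(pairs) == 0L) return(data.frame(qid = integer(), tid = integer()))
  p <- do.call(rbind, pairs)
  p <- p[order(-p$ro, p$qid, p$tid), ]
  uq <- logical(nrow(calls)); ut <- logical(nrow(truth)); sel <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    if (!uq[p$qid[i]] && !ut[p$tid[i]]) {
      sel[i] <- TRUE; uq[p$qid[i]] <- TRUE; ut[p$tid[i]] <- TRUE
    }
  }
  p[sel, c("qid", "tid")]
}

# small simulated fixture shared across test files
small_fixture <- function() {
  cached("small_fix", {
    spec <- fixture_spec(chrom_lengths = c(chr1 = 500000L), n_del = 2L,
                         n_dup = 2L, repeats_per_chrom = 10L,
                         n_gap_length = 5000L, seed = 5L)
    ref <- build_reference(spec)
    fix <- simulate_alignments(spec, ref)
    list(spec = spec, ref = ref, fix = fix)
  })
}

# full default fixture (study conditions), shared
default_fixture <- function() {
  cached("default_fix", {
    spec <- fixture_spec(seed = 42L)
    ref <- build_reference(spec)
    fix <- simulate_alignments(spec, ref)
    list(spec = spec, ref = ref, fix = fix)
  })
}
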
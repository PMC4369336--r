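# Sliding-window CNV search: window-mean distributions, per-base abnormality
# screening, z-test growth/extension (compiled scanner), pipeline union and
# BED output.

#' Sample window-mean distributions
#'
#' For each window size on a geometric grid between `w_min` and `w_max`,
#' `n_sample` window positions free of N/masked bases are drawn uniformly and
#' the mean and standard deviation of the window-averaged normalized depth
#' are recorded. Parameters for intermediate sizes are obtained by
#' interpolation on the log-size scale, which avoids estimating every one of
#' the thousands of sizes the one-base window sweep visits.
#'
#' @param norm an `rdcnv_normtrack`.
#' @param w_min,w_max minimum and maximum window sizes (defaults 100, 10000).
#' @param n_grid number of sizes on the geometric grid (default 20).
#' @param n_sample windows sampled per size (default 1000; reduced with a
#'   warning when fewer eligible windows exist).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return An object of class `rdcnv_windists`: a `data.table` with `l`,
#'   `mu`, `sigma`, `n_sampled`, plus the interpolation range as attributes.
#' @export
sample_window_distributions <- function(norm, w_min = 100L, w_max = 10000L,
                                        n_grid = 20L, n_sample = 1000L,
                                        seed = 17L) {
  sizes <- unique(as.integer(round(exp(seq(log(w_min), log(w_max),
                                           length.out = n_grid)))))
  res <- withr::with_seed(as.integer(seed), {
    lapply(sizes, function(l) {
      means <- numeric(0)
      starts <- list()
      for (ch in names(norm$x)) {
        v <- norm$x[[ch]]
        if (length(v) < l) next
        valid <- !is.na(v)
        okn <- win_sum(valid, l)
        starts[[ch]] <- which(okn == l)
      }
      tot <- sum(lengths(starts))
      if (tot == 0L)
        return(data.table(l = l, mu = NA_real_, sigma = NA_real_, n_sampled = 0L))
      ns <- n_sample
      if (tot < n_sample) {
        warning("only ", tot, " eligible windows of size ", l,
                "; reducing sample")
        ns <- tot
      }
      pick <- sort(sample.int(tot, ns))
      offs <- cumsum(c(0L, lengths(starts)))
      vals <- numeric(ns)
      k <- 1L
      for (ci in seq_along(starts)) {
        sel <- pick[pick > offs[ci] & pick <= offs[ci + 1L]]
        if (length(sel) == 0L) next
        ch <- names(starts)[ci]
        v <- norm$x[[ch]]
        cs <- c(0, cumsum(ifelse(is.na(v), 0, v)))
        s <- starts[[ch]][sel - offs[ci]]
        vals[k:(k + length(sel) - 1L)] <- (cs[s + l] - cs[s]) / l
        k <- k + length(sel)
      }
      data.table(l = l, mu = mean(vals),
                 sigma = if (ns > 1L) stats::sd(vals) else 0,
                 n_sampled = ns)
    })
  })
  out <- rbindlist(res)
  out <- out[!is.na(mu)]
  if (nrow(out) == 0L) stop("no eligible windows at any size")
  structure(out, class = c("rdcnv_windists", class(out)),
            w_min = w_min, w_max = w_max)
}

# mu/sigma for every size w_min..w_max by interpolation on log(l);
# sigma interpolated on the log scale (approximately power-law in l).
interp_window_dists <- function(dists, w_min, w_max) {
  l_all <- seq.int(w_min, w_max)
  if (nrow(dists) == 1L) {
    return(list(mu = rep(dists$mu, length(l_all)),
                sigma = rep(dists$sigma, length(l_all))))
  }
  mu <- stats::approx(log(dists$l), dists$mu, xout = log(l_all), rule = 2)$y
  sg <- dists$sigma
  if (all(sg > 0)) {
    sigma <- exp(stats::approx(log(dists$l), log(sg), xout = log(l_all), rule = 2)$y)
  } else {
    sigma <- stats::approx(log(dists$l), sg, xout = log(l_all), rule = 2)$y
  }
  list(mu = mu, sigma = sigma)
}

#' Screen per-base abnormal coverage
#'
#' A base is abnormal when its raw depth is at least `dup_ratio` times (or at
#' most `del_ratio` times) the mean raw depth of its own normalization bin.
#' The screen uses raw depth against the bin average; the z-test uses the
#' normalized track. Returns -1/0/+1 per base.
#'
#' @param depth integer depth vector.
#' @param r_ave per-base bin mean depth (`NA` where unbinned).
#' @param del_ratio,dup_ratio abnormality thresholds (diploid defaults 0.70
#'   and 1.3).
#' @return Integer vector of abnormality directions.
#' @export
screen_abnormal <- function(depth, r_ave, del_ratio = 0.70, dup_ratio = 1.3) {
  ab <- integer(length(depth))
  ok <- !is.na(r_ave)
  ab[ok & depth >= dup_ratio * r_ave] <- 1L
  ab[ok & depth <= del_ratio * r_ave] <- -1L
  ab
}

#' Run the sliding-window scan over all chromosomes of one pipeline
#'
#' @param norm `rdcnv_normtrack` (x and per-base bin means).
#' @param tracks named list of depth tracks (for the raw-depth screen).
#' @param dists `rdcnv_windists` from [sample_window_distributions()].
#' @param mask optional named list of hard-exclusion masks (pipeline 1).
#' @param alpha one-sided tail probability required for a call (default 1e-6).
#' @param w_min,w_max window size range.
#' @param del_ratio,dup_ratio abnormality screen thresholds.
#' @param pipeline label recorded on the calls.
#' @return `data.table` of calls: `chrom`, `start`, `end` (1-based closed),
#'   `type`, `z`, `pipeline`.
#' @export
scan_cnvs <- function(norm, tracks, dists, mask = NULL, alpha = 1e-6,
                      w_min = 100L, w_max = 10000L,
                      del_ratio = 0.70, dup_ratio = 1.3,
                      pipeline = "unmasked") {
  ip <- interp_window_dists(dists, w_min, w_max)
  zthr <- stats::qnorm(1 - alpha)
  out <- list()
  for (ch in names(norm$x)) {
    x <- norm$x[[ch]]
    ab <- screen_abnormal(tracks[[ch]]$depth, norm$r_ave[[ch]],
                          del_ratio, dup_ratio)
    hard <- if (!is.null(mask) && !is.null(mask[[ch]])) mask[[ch]]
            else rep(FALSE, length(x))
    res <- .scan_cnv_chrom(x, ab, hard, ip$mu, ip$sigma,
                           as.integer(w_min), as.integer(w_max), zthr)
    if (nrow(res) > 0L)
      out[[ch]] <- data.table(chrom = ch, start = res$start, end = res$end,
                              type = ifelse(res$dir == -1L, "DEL", "DUP"),
                              z = res$z, pipeline = pipeline)
  }
  if (length(out) == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      type = character(), z = numeric(), pipeline = character()))
  rbindlist(out)
}

#' Union-merge the calls of the two pipelines
#'
#' Same-type calls that overlap by at least one base are merged into the
#' spanning interval with pipeline tag `both` and the more extreme z; all
#' other calls pass through with their own tag. Overlapping calls of
#' different types are never merged.
#'
#' @param calls_masked,calls_unmasked call tables from [scan_cnvs()].
#' @return Combined call table sorted by `(chrom, start)`.
#' @export
merge_pipeline_union <- function(calls_masked, calls_unmasked) {
  all_calls <- rbindlist(list(calls_masked, calls_unmasked))
  if (nrow(all_calls) == 0L) return(all_calls)
  merged <- list()
  for (tp in unique(all_calls$type)) {
    sub <- all_calls[type == tp]
    gr <- GenomicRanges::GRanges(sub$chrom, IRanges::IRanges(sub$start, sub$end))
    red <- GenomicRanges::reduce(gr)
    hit <- GenomicRanges::findOverlaps(gr, red)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    sub[, call_id := grp]
    merged[[tp]] <- sub[, {
      pls <- unique(pipeline)
      .(chrom = chrom[1L], start = min(start), end = max(end), type = type[1L],
        z = z[which.max(abs(z))],
        pipeline = if (length(pls) > 1L) "both" else pls)
    }, by = call_id][, call_id := NULL]
  }
  out <- rbindlist(merged)
  setorder(out, chrom, start, end)
  out[]
}

# fold coverage (mean raw depth over the call / chromosome mean) per call
add_fold <- function(calls, tracks, library) {
  if (nrow(calls) == 0L) {
    calls[, fold := numeric(0)]
    return(calls)
  }
  f <- numeric(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    ch <- calls$chrom[i]
    f[i] <- mean(tracks[[ch]]$depth[calls$start[i]:calls$end[i]]) /
      library$chrom_mean_depth[[ch]]
  }
  calls[, fold := f]
  calls
}

#' Write CNV calls as BED6+
#'
#' Columns: chrom, start (0-based), end, name (`DEL`/`DUP`), score
#' (`min(1000, round(-10 log10 p))` for the one-sided tail probability of
#' the reported z), strand (`.`), fold coverage, source pipeline, z. The
#' file begins with a `#` header line and is ordered by (chrom, start).
#'
#' @param calls call table from [detect_cnvs()] or [scan_cnvs()].
#' @param file output path.
#' @export
write_calls <- function(calls, file) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand\tfold\tpipeline\tz", con)
  if (nrow(calls) > 0L) {
    fold <- if ("fold" %in% names(calls)) calls$fold else rep(NA_real_, nrow(calls))
    dt <- data.table(chrom = calls$chrom, start = calls$start - 1L,
                     end = calls$end, name = calls$type,
                     score = z_to_score(calls$z), strand = ".",
                     fold = sprintf("%.6g", fold),
                     pipeline = calls$pipeline,
                     z = sprintf("%.6g", calls$z))
    setorder(dt, chrom, start, end)
    utils::write.table(dt, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}

#' Read a call BED written by [write_calls()]
#'
#' @param file path to the BED file.
#' @return Call table with 1-based closed coordinates.
#' @export
read_calls <- function(file) {
  cols <- c("chrom", "start", "end", "type", "score", "strand",
            "fold", "pipeline", "z")
  dt <- tryCatch(
    data.table::fread(file, sep = "\t", header = FALSE, col.names = cols,
                      skip = 1L),
    error = function(e) NULL)
  if (is.null(dt) || nrow(dt) == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      type = character(), z = numeric(), pipeline = character(),
                      fold = numeric()))
  dt[, start := start + 1L]
  dt[, .(chrom, start, end, type, z, pipeline, fold)]
}
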
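# Benchmark scoring: reciprocal-overlap matching of calls against a truth
# set; sensitivity, FDR and breakpoint error per CNV type.

#' Match CNV calls against a truth set
#'
#' Calls and truth events of the same type are matched greedily by
#' descending reciprocal overlap, defined as
#' `min(|intersection|/|call|, |intersection|/|truth|)`; a pair is a true
#' positive when the reciprocal overlap reaches `min_reciprocal`. Each truth
#' event matches at most one call and vice versa. The breakpoint error of a
#' match is the mean of the two endpoint distances (configurable to the
#' maximum endpoint distance).
#'
#' @param calls call table (`chrom`, `start`, `end`, `type`; 1-based closed)
#'   or a path to a BED file from [write_calls()].
#' @param truth truth table of the same shape, or a BED path
#'   (`chrom start end name` with `name` = DEL/DUP).
#' @param min_reciprocal required reciprocal overlap (default 0.1).
#' @param bp_error `"mean"` (default) or `"max"` endpoint error per match.
#' @return An object of class `rdcnv_eval`: `summary` (per type and overall:
#'   `n_truth`, `n_calls`, `tp`, `other`, `sensitivity`, `fdr`,
#'   `mean_bp_error`) and `matches` (matched pairs with overlap and error).
#' @export
match_calls <- function(calls, truth, min_reciprocal = 0.1,
                        bp_error = c("mean", "max")) {
  bp_error <- match.arg(bp_error)
  calls <- as_interval_table(calls)
  truth <- as_interval_table(truth)
  if (any(calls$end < calls$start) || any(truth$end < truth$start))
    stop("malformed intervals")
  matches <- data.table(qid = integer(), tid = integer(), ro = numeric(),
                        bp_err = numeric())
  if (nrow(calls) > 0L && nrow(truth) > 0L) {
    qg <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$start, calls$end))
    tg <- GenomicRanges::GRanges(truth$chrom, IRanges::IRanges(truth$start, truth$end))
    hit <- GenomicRanges::findOverlaps(qg, tg)
    qi <- S4Vectors::queryHits(hit); ti <- S4Vectors::subjectHits(hit)
    same <- calls$type[qi] == truth$type[ti]
    qi <- qi[same]; ti <- ti[same]
    if (length(qi) > 0L) {
      ov <- IRanges::width(IRanges::pintersect(qg[qi], tg[ti]))
      ro <- pmin(ov / IRanges::width(qg[qi]), ov / IRanges::width(tg[ti]))
      keep <- ro >= min_reciprocal
      cand <- data.table(qid = qi[keep], tid = ti[keep], ro = ro[keep])
      setorder(cand, -ro, qid, tid)
      used_q <- logical(nrow(calls)); used_t <- logical(nrow(truth))
      sel <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        if (!used_q[cand$qid[i]] && !used_t[cand$tid[i]]) {
          sel[i] <- TRUE
          used_q[cand$qid[i]] <- TRUE
          used_t[cand$tid[i]] <- TRUE
        }
      }
      matches <- cand[sel]
      if (nrow(matches) > 0L) {
        ds <- abs(calls$start[matches$qid] - truth$start[matches$tid])
        de <- abs(calls$end[matches$qid] - truth$end[matches$tid])
        matches[, bp_err := if (bp_error == "mean") (ds + de) / 2
                            else pmax(ds, de)]
      }
    }
  }
  types <- sort(unique(c(calls$type, truth$type)))
  summ <- rbindlist(lapply(c(types, "all"), function(tp) {
    qsel <- if (tp == "all") rep(TRUE, nrow(calls)) else calls$type == tp
    tsel <- if (tp == "all") rep(TRUE, nrow(truth)) else truth$type == tp
    m <- matches[qid %in% which(qsel)]
    n_calls <- sum(qsel); n_truth <- sum(tsel); tp_n <- nrow(m)
    data.table(type = tp, n_truth = n_truth, n_calls = n_calls, tp = tp_n,
               other = n_calls - tp_n,
               sensitivity = if (n_truth > 0L) tp_n / n_truth else NA_real_,
               fdr = if (n_calls > 0L) (n_calls - tp_n) / n_calls else NA_real_,
               mean_bp_error = if (tp_n > 0L) mean(m$bp_err) else NA_real_)
  }))
  structure(list(summary = summ, matches = matches,
                 min_reciprocal = min_reciprocal),
            class = "rdcnv_eval")
}

as_interval_table <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    dt <- data.table::fread(x, header = FALSE)
    if (ncol(dt) < 4L) stop("expected at least 4 BED columns")
    first <- as.character(dt[[1L]][1L])
    if (startsWith(first, "#")) dt <- dt[-1L]
    out <- data.table(chrom = as.character(dt[[1L]]),
                      start = as.integer(dt[[2L]]) + 1L,
                      end = as.integer(dt[[3L]]),
                      type = as.character(dt[[4L]]))
    return(out)
  }
  dt <- as.data.table(x)
  dt[, .(chrom = as.character(chrom), start = as.integer(start),
         end = as.integer(end), type = as.character(type))]
}

#' @export
print.rdcnv_eval <- function(x, ...) {
  cat("rdcnv evaluation (reciprocal overlap >=", x$min_reciprocal, ")\n")
  print(x$summary)
  invisible(x)
}

#' Write an evaluation summary as TSV
#'
#' @param eval an `rdcnv_eval` from [match_calls()].
#' @param file output path.
#' @export
write_eval <- function(eval, file) {
  utils::write.table(eval$summary, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
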
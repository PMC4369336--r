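# Deterministic synthetic fixtures: reference sequences with a GC gradient,
# embedded dinucleotide runs and N gaps; aligned reads with fragment-level GC
# bias, motif-specific repeat suppression, coverage hotspots and spiked CNVs.

#' Specify a synthetic fixture
#'
#' Builds a fully resolved fixture specification: repeat runs, N gaps and CNV
#' events are placed at construction time (deterministically from `seed`), so
#' the same spec always yields byte-identical references and alignments.
#'
#' The default is a desk-scale genome of two 2-Mb chromosomes at 10x
#' coverage with paired 100-base reads on 500-base fragments, a 0.35-0.60 GC
#' gradient per chromosome, 40 embedded runs per chromosome for each of the
#' AT/CA/GA motifs, one 20-kb N gap per chromosome, a unimodal fragment-GC
#' bias curve, and 10 heterozygous deletions plus 10 duplications (3-10
#' copies) with sizes drawn log-uniformly between 500 and 10,000 bases.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param coverage target mean depth over non-N bases.
#' @param read_length read length in bases.
#' @param mean_insert fragment (insert) length; ignored for single-end.
#' @param paired paired-end sequencing.
#' @param gc_range GC gradient endpoints along each chromosome.
#' @param repeat_motifs,repeats_per_chrom,repeat_len_range embedded
#'   dinucleotide runs per chromosome.
#' @param n_gap_length length of the N gap placed in each chromosome
#'   (0 for none).
#' @param n_del,n_dup,del_cn,dup_cn_range,event_size_range spiked CNVs;
#'   deletion copy number 1 is heterozygous, 0 homozygous.
#' @param gc_bias `list(optimum, width, floor)` for the multiplicative
#'   fragment-GC exposure curve
#'   `floor + (1 - floor) * exp(-((gc - optimum)/width)^2 / 2)`,
#'   or `NULL` for no GC bias.
#' @param motif_suppression named numeric vector of per-motif coverage
#'   multipliers for fragments overlapping runs of that motif.
#' @param hotspots `data.table(chrom, start, end, mult)` of exposure
#'   hotspots, or `NULL`.
#' @param low_mq_regions `data.table(chrom, start, end)` whose reads get
#'   MAPQ 0, or `NULL`.
#' @param events explicit event table (`chrom`, `start`, `end`, `type`,
#'   `cn`), or `NULL` to place `n_del` + `n_dup` events automatically.
#' @param seed integer seed controlling every random choice.
#' @return An object of class `rdcnv_fixture_spec`.
#' @export
fixture_spec <- function(chrom_lengths = c(chr1 = 2000000L, chr2 = 2000000L),
                         coverage = 10, read_length = 100L, mean_insert = 500L,
                         paired = TRUE, gc_range = c(0.35, 0.60),
                         repeat_motifs = c("AT", "CA", "GA"),
                         repeats_per_chrom = 40L,
                         repeat_len_range = c(20L, 60L),
                         n_gap_length = 20000L,
                         n_del = 10L, n_dup = 10L, del_cn = 1L,
                         dup_cn_range = c(3L, 10L),
                         event_size_range = c(500L, 10000L),
                         gc_bias = list(optimum = 0.45, width = 0.15, floor = 0.3),
                         motif_suppression = NULL, hotspots = NULL,
                         low_mq_regions = NULL, events = NULL, seed = 1L) {
  stopifnot(coverage > 0, read_length >= 1L, length(chrom_lengths) >= 1L,
            !is.null(names(chrom_lengths)))
  if (!paired) mean_insert <- read_length
  stopifnot(mean_insert >= read_length)
  chroms <- names(chrom_lengths)
  empty_iv <- data.table(chrom = character(), start = integer(), end = integer())
  withr::with_seed(as.integer(seed), {
    gaps <- rbindlist(c(list(empty_iv), lapply(chroms, function(ch) {
      if (n_gap_length <= 0L) return(NULL)
      a <- as.integer(0.55 * chrom_lengths[[ch]])
      data.table(chrom = ch, start = a, end = a + as.integer(n_gap_length) - 1L)
    })))
    repeats <- rbindlist(c(list(data.table(empty_iv, motif = character())),
                           lapply(chroms, function(ch) {
      n_rep <- repeats_per_chrom * length(repeat_motifs)
      if (n_rep == 0L) return(NULL)
      lens <- sample(seq.int(repeat_len_range[1L], repeat_len_range[2L]),
                     n_rep, replace = TRUE)
      lens <- lens + lens %% 2L            # whole motif copies
      st <- place_intervals(lens, chrom_lengths[[ch]],
                            forbidden = gaps[chrom == ch],
                            margin = 2000L, min_sep = 1000L)
      data.table(chrom = ch, start = st, end = st + lens - 1L,
                 motif = rep(repeat_motifs, each = repeats_per_chrom))
    })))
    if (is.null(events)) {
      n_ev <- n_del + n_dup
      if (n_ev > 0L) {
        sizes <- as.integer(round(exp(stats::runif(n_ev,
                                                   log(event_size_range[1L]),
                                                   log(event_size_range[2L])))))
        type <- c(rep("DEL", n_del), rep("DUP", n_dup))
        cn <- c(rep(as.integer(del_cn), n_del),
                sample(seq.int(dup_cn_range[1L], dup_cn_range[2L]), n_dup,
                       replace = TRUE))
        evch <- sample(chroms, n_ev, replace = TRUE,
                       prob = chrom_lengths / sum(chrom_lengths))
        pieces <- lapply(chroms, function(ch) {
          sel <- which(evch == ch)
          if (length(sel) == 0L) return(NULL)
          forb <- rbind(gaps[chrom == ch, .(chrom, start, end)],
                        data.table(chrom = character(), start = integer(),
                                   end = integer()))
          st <- place_intervals(sizes[sel], chrom_lengths[[ch]],
                                forbidden = forb, margin = 20000L,
                                min_sep = 20000L)
          data.table(chrom = ch, start = st, end = st + sizes[sel] - 1L,
                     type = type[sel], cn = cn[sel])
        })
        events <- rbindlist(pieces)
        setorder(events, chrom, start)
      } else {
        events <- data.table(chrom = character(), start = integer(),
                             end = integer(), type = character(), cn = integer())
      }
    } else {
      events <- as.data.table(events)
    }
  })
  structure(list(chrom_lengths = chrom_lengths, coverage = coverage,
                 read_length = as.integer(read_length),
                 mean_insert = as.integer(mean_insert), paired = paired,
                 gc_range = gc_range, repeats = repeats, gaps = gaps,
                 events = events, gc_bias = gc_bias,
                 motif_suppression = motif_suppression, hotspots = hotspots,
                 low_mq_regions = low_mq_regions, seed = as.integer(seed)),
            class = "rdcnv_fixture_spec")
}

# Place intervals of the given sizes uniformly, avoiding forbidden intervals,
# chromosome margins and each other (min_sep). Errors when no placement fits.
place_intervals <- function(sizes, chrom_len, forbidden = NULL, margin = 1000L,
                            min_sep = 1000L, max_tries = 2000L) {
  taken <- if (!is.null(forbidden) && nrow(forbidden) > 0L)
    data.table(start = forbidden$start, end = forbidden$end)
  else data.table(start = integer(), end = integer())
  starts <- integer(length(sizes))
  for (i in seq_along(sizes)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(chrom_len - sizes[i] - 2L * margin, 1L) + margin
      e <- s + sizes[i] - 1L
      if (nrow(taken) == 0L ||
          all(s > taken$end + min_sep | e < taken$start - min_sep)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("cannot place interval of size ", sizes[i],
                  " on a chromosome of length ", chrom_len)
    starts[i] <- s
    taken <- rbind(taken, data.table(start = s, end = e))
  }
  starts
}

#' Build the reference sequences of a fixture
#'
#' Bases are drawn independently with the G+C probability following the
#' spec's linear gradient (piecewise constant over 1-kb segments), then the
#' specified dinucleotide runs and N gaps are stamped in. Deterministic
#' given the spec seed.
#'
#' @param spec an [fixture_spec()] object.
#' @return A `DNAStringSet`.
#' @export
build_reference <- function(spec) {
  chroms <- names(spec$chrom_lengths)
  seqs <- withr::with_seed(spec$seed + 1L, {
    lapply(chroms, function(ch) {
      len <- spec$chrom_lengths[[ch]]
      seg <- pmin((seq_len(len) - 1L) %/% 1000L * 1000L / max(len - 1L, 1L), 1)
      gc <- spec$gc_range[1L] + (spec$gc_range[2L] - spec$gc_range[1L]) * seg
      u <- stats::runif(len)
      v <- stats::runif(len)
      base <- ifelse(u < gc, ifelse(v < 0.5, "G", "C"),
                     ifelse(v < 0.5, "A", "T"))
      reps <- spec$repeats[chrom == ch]
      if (nrow(reps) > 0L) {
        for (i in seq_len(nrow(reps))) {
          idx <- reps$start[i]:reps$end[i]
          mm <- strsplit(reps$motif[i], "", fixed = TRUE)[[1L]]
          base[idx] <- rep_len(mm, length(idx))
        }
      }
      gp <- spec$gaps[chrom == ch]
      if (nrow(gp) > 0L)
        for (i in seq_len(nrow(gp))) base[gp$start[i]:gp$end[i]] <- "N"
      paste(base, collapse = "")
    })
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- chroms
  out
}

# Gaussian-bell multiplicative exposure vs fragment GC.
gc_bias_multiplier <- function(gc, curve) {
  if (is.null(curve)) return(rep(1, length(gc)))
  curve$floor + (1 - curve$floor) *
    exp(-0.5 * ((gc - curve$optimum) / curve$width)^2)
}

#' Simulate aligned reads for a fixture
#'
#' Fragments are sampled with a rate proportional to the fragment-GC bias
#' curve (PCR acts on the whole fragment), motif-specific suppression for
#' fragments overlapping suppressed runs, and hotspot multipliers; fragments
#' touching an N gap have rate zero. Each fragment yields paired
#' `read_length` reads from its two ends (one read for single-end specs).
#' Copy-number events then thin or replicate each read according to the
#' copy-number multiplier `cn/2` at the read's center, which keeps depth
#' transitions at breakpoints sharp at the read-length scale.
#'
#' @param spec an [fixture_spec()].
#' @param ref the reference from [build_reference()].
#' @return An object of class `rdcnv_fixture`: `reads` (alignment table
#'   sorted by coordinate), `truth` (event table), and the `spec`.
#' @export
simulate_alignments <- function(spec, ref) {
  chroms <- names(spec$chrom_lengths)
  rl <- spec$read_length
  frag <- if (spec$paired) spec$mean_insert else rl
  reads <- withr::with_seed(spec$seed + 2L, {
    pieces <- lapply(chroms, function(ch) {
      len <- spec$chrom_lengths[[ch]]
      fl <- seq_flags(ref[[ch]])
      csg <- c(0, cumsum(as.numeric(fl$gc)))
      cso <- c(0, cumsum(as.numeric(fl$ok)))
      S <- len - frag + 1L
      s <- seq_len(S)
      okf <- (cso[s + frag] - cso[s]) == frag
      gcf <- (csg[s + frag] - csg[s]) / frag
      rate <- ifelse(okf, gc_bias_multiplier(gcf, spec$gc_bias), 0)
      base_rate_sum <- sum(rate)
      if (!is.null(spec$motif_suppression) && length(spec$motif_suppression)) {
        reps <- spec$repeats[chrom == ch & motif %in% names(spec$motif_suppression)]
        if (nrow(reps) > 0L) {
          for (i in seq_len(nrow(reps))) {
            lo <- max(1L, reps$start[i] - frag + 1L)
            hi <- min(S, reps$end[i])
            if (lo <= hi)
              rate[lo:hi] <- rate[lo:hi] *
                spec$motif_suppression[[reps$motif[i]]]
          }
        }
      }
      if (!is.null(spec$hotspots)) {
        hs <- as.data.table(spec$hotspots)[chrom == ch]
        if (nrow(hs) > 0L) {
          for (i in seq_len(nrow(hs))) {
            lo <- max(1L, hs$start[i] - frag %/% 2L)
            hi <- min(S, hs$end[i] - frag %/% 2L)
            if (lo <= hi) rate[lo:hi] <- rate[lo:hi] * hs$mult[i]
          }
        }
      }
      if (all(rate == 0)) stop("zero sampling rate over chromosome ", ch)
      n_ok <- sum(fl$ok)
      reads_per_frag <- if (spec$paired) 2L else 1L
      # suppression and hotspot multipliers add or remove fragments relative
      # to the GC-bias-only baseline, so baseline coverage stays at target
      n_frag <- as.integer(round(spec$coverage * n_ok / (rl * reads_per_frag) *
                                   sum(rate) / base_rate_sum))
      st <- sample.int(S, n_frag, replace = TRUE, prob = rate)
      pos <- if (spec$paired) c(st, st + frag - rl) else st
      mate <- if (spec$paired) rep(1:2, each = n_frag) else rep(0L, n_frag)
      fid <- if (spec$paired) c(seq_len(n_frag), seq_len(n_frag)) else seq_len(n_frag)
      # copy-number thinning / replication at the read center
      cnmult <- rep(1, len)
      ev <- spec$events[chrom == ch]
      if (nrow(ev) > 0L)
        for (i in seq_len(nrow(ev)))
          cnmult[ev$start[i]:ev$end[i]] <- ev$cn[i] / 2
      m <- cnmult[pos + rl %/% 2L]
      nrep <- floor(m) + (stats::runif(length(m)) < (m - floor(m)))
      keep <- rep.int(seq_along(pos), nrep)
      pos <- pos[keep]; mate <- mate[keep]; fid <- fid[keep]
      mq <- rep(60L, length(pos))
      if (!is.null(spec$low_mq_regions)) {
        lm <- as.data.table(spec$low_mq_regions)[chrom == ch]
        if (nrow(lm) > 0L) {
          ctr <- pos + rl %/% 2L
          for (i in seq_len(nrow(lm)))
            mq[ctr >= lm$start[i] & ctr <= lm$end[i]] <- 0L
        }
      }
      data.table(chrom = ch, start = pos, end = pos + rl - 1L, mapq = mq,
                 tlen = if (spec$paired) ifelse(mate == 1L, frag, -frag)
                        else 0L,
                 paired = spec$paired, proper = spec$paired, isdup = FALSE,
                 fid = paste0(ch, ".", fid), mate = mate)
    })
    rbindlist(pieces)
  })
  setorder(reads, chrom, start, fid, mate)
  truth <- data.table::copy(spec$events)
  structure(list(reads = reads[], truth = truth, spec = spec),
            class = "rdcnv_fixture")
}

#' Write a fixture to disk (FASTA + index, BAM + index, truth BED, spec JSON)
#'
#' @param fix an `rdcnv_fixture` from [simulate_alignments()].
#' @param ref the matching reference.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Named list of the written paths.
#' @export
write_fixture <- function(fix, ref, dir, prefix = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  Biostrings::writeXStringSet(ref, fa)
  Rsamtools::indexFa(fa)
  sam <- file.path(dir, paste0(prefix, ".sam"))
  write_sam(fix$reads, fix$spec, sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, prefix), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  truth_bed <- file.path(dir, paste0(prefix, ".truth.bed"))
  td <- fix$truth
  utils::write.table(
    data.table(chrom = td$chrom, start = td$start - 1L, end = td$end,
               name = td$type, score = 0L, strand = ".", cn = td$cn),
    truth_bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  spec_json <- file.path(dir, paste0(prefix, ".spec.json"))
  sp <- fix$spec
  jsonlite::write_json(
    list(chrom_lengths = as.list(sp$chrom_lengths), coverage = sp$coverage,
         read_length = sp$read_length, mean_insert = sp$mean_insert,
         paired = sp$paired, gc_range = sp$gc_range, seed = sp$seed,
         events = sp$events, gaps = sp$gaps,
         n_repeats = nrow(sp$repeats)),
    spec_json, auto_unbox = TRUE, digits = NA)
  list(fasta = fa, bam = bam, truth = truth_bed, spec = spec_json)
}

# Minimal SAM writer for simulated reads (SEQ/QUAL omitted as '*').
write_sam <- function(reads, spec, file) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (ch in names(spec$chrom_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, spec$chrom_lengths[[ch]]), con)
  r <- reads
  rl <- spec$read_length
  if (spec$paired) {
    flag <- ifelse(r$mate == 1L, 99L, 147L)
    pnext <- ifelse(r$mate == 1L, r$start + spec$mean_insert - rl,
                    r$start - spec$mean_insert + rl)
    rnext <- "="
  } else {
    flag <- 0L
    pnext <- 0L
    rnext <- "*"
  }
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t%d\t*\t*",
                   r$fid, flag, r$chrom, r$start, r$mapq, rl, rnext,
                   pnext, r$tlen)
  writeLines(lines, con)
  invisible(file)
}
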
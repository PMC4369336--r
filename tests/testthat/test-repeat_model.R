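test_that("dinucleotide run detection respects length, motif and N rules", {
  r <- find_dinucleotide_runs(strrep("AT", 10L), 20L, "c")
  expect_equal(nrow(r), 1L)
  expect_equal(r$motif, "AT")
  expect_equal(r$length, 20L)
  expect_equal(c(r$start, r$end), c(1L, 20L))

  expect_equal(nrow(find_dinucleotide_runs(strrep("AT", 9L), 20L)), 0L)
  expect_equal(nrow(find_dinucleotide_runs(strrep("A", 30L), 20L)), 0L)  # homopolymer
  # canonical motif: TA... run reports AT
  r2 <- find_dinucleotide_runs(paste0("GG", strrep("TA", 12L), "GG"), 20L)
  expect_equal(r2$motif, "AT")
  # N terminates runs
  s <- paste0(strrep("CA", 8L), "N", strrep("CA", 8L))
  expect_equal(nrow(find_dinucleotide_runs(s, 16L)), 2L)
})

test_that("run detection matches the brute-force period-2 oracle", {
  withr::with_seed(21L, {
    for (i in 1:40) {
      s <- paste(sample(c("A", "C", "G", "T", "N"), 400L, TRUE,
                        prob = c(.28, .22, .22, .26, .02)), collapse = "")
      # salt with a few explicit runs
      s <- paste0(s, strrep("GT", sample(3:12, 1)), s)
      got <- find_dinucleotide_runs(s, 8L, "c")
      exp <- oracle_dinuc_runs(s, 8L)
      expect_equal(nrow(got), nrow(exp))
      if (nrow(exp) > 0L) {
        expect_equal(got$start, exp$start)
        expect_equal(got$end, exp$end)
        expect_equal(got$motif, exp$motif)
      }
    }
  })
})

make_const_track <- function(d, len) structure(
  list(chrom = "c1", depth = rep(as.integer(d), len),
       window_mq = rep(60, ceiling(len / 100)), w_base = 100L),
  class = "rdcnv_depth")

test_that("motif bias test uses the 1.5-SD rule and an occurrence floor", {
  lib <- structure(list(read_length = 100L, mean_insert = 400L, paired = TRUE,
                        chrom_mean_depth = c(c1 = 10), genome_mean_depth = 10,
                        genome_depth_sd = 2),
                   class = "rdcnv_library")
  runs <- data.table::data.table(
    chrom = "c1", start = seq(1000L, by = 1000L, length.out = 60L))
  runs[, `:=`(end = start + 29L, motif = "AT", length = 30L)]
  tr <- list(c1 = make_const_track(10L, 70000L))
  # repeat coverage equals the genome mean -> unbiased
  expect_equal(assess_motif_bias(runs, tr, lib)$direction, "unbiased")
  # mean 2 SD below -> biased low
  tr2 <- list(c1 = make_const_track(10L, 70000L))
  for (i in seq_len(nrow(runs))) tr2$c1$depth[runs$start[i]:runs$end[i]] <- 6L
  expect_equal(assess_motif_bias(runs, tr2, lib)$direction, "low")
  # 1.4 SD above -> still unbiased
  tr3 <- list(c1 = make_const_track(10L, 70000L))
  for (i in seq_len(nrow(runs))) tr3$c1$depth[runs$start[i]:runs$end[i]] <- 12L
  expect_equal(assess_motif_bias(runs, tr3, lib, sd_mult = 1.5)$direction,
               "unbiased")
  # below the occurrence floor -> unbiased even with strong signal
  expect_message(
    b <- assess_motif_bias(runs[1:10], tr2, lib, min_occurrences = 50L),
    "below 50")
  expect_equal(b$direction, "unbiased")
})

test_that("repeat normalization reaches half an insert and replaces GC bins", {
  lib <- structure(list(read_length = 100L, mean_insert = 400L, paired = TRUE,
                        chrom_mean_depth = c(c1 = 10), genome_mean_depth = 10,
                        genome_depth_sd = 2),
                   class = "rdcnv_library")
  len <- 80000L
  runs <- data.table::data.table(
    chrom = "c1", start = seq(2000L, by = 1500L, length.out = 52L))
  runs[, `:=`(end = start + 39L, motif = "AT", length = 40L)]
  withr::with_seed(9L, {
    d <- rpois(len, 10)
    for (i in seq_len(nrow(runs))) {
      lo <- runs$start[i] - 199L; hi <- runs$end[i] + 199L
      d[lo:hi] <- rpois(hi - lo + 1L, 5)        # suppressed neighbourhood
    }
    tr <- list(c1 = structure(list(chrom = "c1", depth = d,
                                   window_mq = rep(60, len / 100), w_base = 100L),
                              class = "rdcnv_depth"))
    nm <- list(c1 = rep(FALSE, len))
    bias <- assess_motif_bias(runs, tr, lib)
    expect_equal(bias$direction, "low")
    asg <- rdcnv:::repeat_assignments(bias, runs, lib, tr, nm)
    # distance reach is mean_insert / 2 = 200: distance 0..199 assigned
    r1 <- runs[1]
    expect_true(all(c(r1$start, r1$end, r1$end + 199L) %in% asg[chrom == "c1", pos]))
    expect_false((r1$end + 200L) %in% asg$pos)
    expect_equal(sort(unique(asg$dist %/% 10L)), 0:19)
    # no base assigned twice
    expect_false(any(duplicated(asg[, .(chrom, pos)])))
    # patched normalization: repeat bases move from GC bins to distance bins
    w <- list(c1 = rep(0.40, len))
    gb <- assign_gc_bins(w, tr, nm, exclude = asg[, .(chrom, pos)])
    expect_equal(nrow(gb$members) + nrow(asg), len)   # partition
    norm <- quantile_normalize(gb, lib, c(c1 = len))
    norm2 <- normalize_repeat_regions(norm, bias, runs, tr, lib, nm,
                                      assignments = asg)
    runbases <- unlist(Map(seq, runs$start, runs$end))
    expect_lt(abs(mean(norm2$x$c1[runbases])), 0.1)   # bias removed
    expect_false(any(is.na(norm2$x$c1[runbases])))
  })
})

test_that("repeat normalization is the identity when no motif is biased", {
  lib <- structure(list(read_length = 100L, mean_insert = 400L, paired = TRUE,
                        chrom_mean_depth = c(c1 = 10), genome_mean_depth = 10,
                        genome_depth_sd = 2),
                   class = "rdcnv_library")
  bias <- assess_motif_bias(
    data.table::data.table(chrom = character(), start = integer(),
                           end = integer(), motif = character(),
                           length = integer()),
    list(), lib)
  norm <- structure(list(x = list(c1 = rnorm(100)),
                         r_ave = list(c1 = rep(10, 100))),
                    class = "rdcnv_normtrack")
  out <- normalize_repeat_regions(norm, bias, bias, list(), lib,
                                  list(c1 = rep(FALSE, 100)))
  expect_identical(out, norm)
})
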
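mk_norm <- function(x, rave = rep(10, length(x))) structure(
  list(x = list(c1 = x), r_ave = list(c1 = rave)), class = "rdcnv_normtrack")

test_that("window distributions: degenerate, i.i.d. and deterministic cases", {
  # constant zero track -> mu 0, sigma 0
  d0 <- sample_window_distributions(mk_norm(rep(0, 5000L)), w_min = 100L,
                                    w_max = 400L, n_grid = 3L,
                                    n_sample = 200L, seed = 1L)
  expect_true(all(d0$mu == 0))
  expect_true(all(d0$sigma == 0))
  withr::with_seed(2L, x <- rnorm(200000L))
  d1 <- sample_window_distributions(mk_norm(x), w_min = 100L, w_max = 100L,
                                    n_sample = 2000L, seed = 3L)
  expect_equal(nrow(d1), 1L)
  expect_lt(abs(d1$sigma - 0.1), 0.01)          # 1/sqrt(100) under independence
  d1b <- sample_window_distributions(mk_norm(x), w_min = 100L, w_max = 100L,
                                     n_sample = 2000L, seed = 3L)
  expect_identical(d1, d1b)                     # same seed, same draw
  expect_warning(
    sample_window_distributions(mk_norm(rnorm(300L)), w_min = 200L,
                                w_max = 200L, n_sample = 1000L, seed = 1L),
    "eligible windows")
})

test_that("abnormality screen applies the 0.70/1.3 ratios to bin means", {
  rave <- rep(10, 6)
  expect_equal(screen_abnormal(rep(10L, 6), rave), rep(0L, 6))
  expect_equal(screen_abnormal(c(12L, 12L, 12L), rep(10, 3)), rep(0L, 3))  # 1.2x
  expect_equal(screen_abnormal(c(13L, 7L, 8L), rep(10, 3)), c(1L, -1L, 0L))
  expect_equal(screen_abnormal(c(5L, NA, 5L)[c(1, 3)], c(10, NA)[c(1, 2)]),
               c(-1L, 0L))                       # unbinned base never abnormal
})

test_that("the scanner finds a clean spiked deletion with sharp breakpoints", {
  withr::with_seed(10L, {
    n <- 200000L
    x <- rnorm(n)
    depth <- rpois(n, 10)
    a <- 120001L; b <- 122000L
    x[a:b] <- rnorm(2000L, -3, 0.3)
    depth[a:b] <- rpois(2000L, 0.2)
    norm <- mk_norm(x)
    tracks <- list(c1 = structure(list(chrom = "c1", depth = depth,
                                       window_mq = rep(60, n / 100),
                                       w_base = 100L), class = "rdcnv_depth"))
    dists <- sample_window_distributions(norm, seed = 6L)
    calls <- scan_cnvs(norm, tracks, dists)
    del <- calls[calls$type == "DEL"]
    expect_equal(nrow(del), 1L)
    expect_lt(abs(del$start - a), 100L)
    expect_lt(abs(del$end - b), 100L)
    expect_lt(pnorm(del$z), 1e-6)                # one-sided tail probability
    # tightening alpha never increases the number of calls
    calls_loose <- scan_cnvs(norm, tracks, dists, alpha = 1e-4)
    expect_lte(nrow(calls), nrow(calls_loose))
    # unbinned bases are never abnormal -> no candidates, no calls
    calls0 <- scan_cnvs(mk_norm(x, rave = rep(NA_real_, n)), tracks, dists)
    expect_equal(nrow(calls0), 0L)
  })
})

test_that("candidates whose minimum window is not half-abnormal are skipped", {
  n <- 50000L
  withr::with_seed(11L, {
    x <- rnorm(n)
    depth <- rpois(n, 10)
    # isolated abnormal bases (far below 50% of any 100-base window)
    pos <- seq(1000L, 40000L, by = 500L)
    depth[pos] <- 0L
    x[pos] <- -3
    norm <- mk_norm(x)
    tracks <- list(c1 = structure(list(chrom = "c1", depth = depth,
                                       window_mq = rep(60, n / 100),
                                       w_base = 100L), class = "rdcnv_depth"))
    dists <- sample_window_distributions(norm, w_max = 1000L, n_grid = 5L,
                                         seed = 2L)
    expect_equal(nrow(scan_cnvs(norm, tracks, dists, w_max = 1000L)), 0L)
  })
})

test_that("pipeline union merges same-type overlaps and keeps the rest", {
  mk <- function(start, end, type, z, pipeline)
    data.table::data.table(chrom = "c1", start = start, end = end, type = type,
                           z = z, pipeline = pipeline)
  # identical calls -> one call tagged both, more extreme z kept
  u <- merge_pipeline_union(mk(100L, 500L, "DEL", -5, "masked"),
                            mk(100L, 500L, "DEL", -6, "unmasked"))
  expect_equal(nrow(u), 1L)
  expect_equal(u$pipeline, "both")
  expect_equal(u$z, -6)
  # overlapping same-type calls span the union interval
  u2 <- merge_pipeline_union(mk(100L, 500L, "DUP", 5, "masked"),
                             mk(400L, 900L, "DUP", 7, "unmasked"))
  expect_equal(c(u2$start, u2$end), c(100L, 900L))
  # disjoint calls both pass through with their tags
  u3 <- merge_pipeline_union(mk(100L, 200L, "DEL", -5, "masked"),
                             mk(1000L, 1200L, "DEL", -5, "unmasked"))
  expect_equal(nrow(u3), 2L)
  expect_setequal(u3$pipeline, c("masked", "unmasked"))
  # a deletion overlapping a duplication is never merged
  u4 <- merge_pipeline_union(mk(100L, 500L, "DEL", -5, "masked"),
                             mk(300L, 700L, "DUP", 5, "unmasked"))
  expect_equal(nrow(u4), 2L)
  expect_setequal(u4$type, c("DEL", "DUP"))
})

test_that("call BED round trip preserves the call set", {
  f <- withr::local_tempfile(fileext = ".bed")
  calls <- data.table::data.table(
    chrom = c("chr1", "chr2"), start = c(1001L, 5001L), end = c(3000L, 7000L),
    type = c("DEL", "DUP"), z = c(-8.1, 12.5), pipeline = c("both", "unmasked"),
    fold = c(0.48, 3.02))
  write_calls(calls, f)
  lines <- readLines(f)
  expect_match(lines[1L], "^#chrom")
  expect_match(lines[2L], "^chr1\t1000\t3000\tDEL\t")
  back <- read_calls(f)
  expect_equal(back$start, calls$start)
  expect_equal(back$end, calls$end)
  expect_equal(back$type, calls$type)
  expect_equal(back$fold, calls$fold, tolerance = 1e-5)
  # empty call set -> header-only file that reads back empty
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_calls(calls[0], f2)
  expect_equal(length(readLines(f2)), 1L)
  expect_equal(nrow(read_calls(f2)), 0L)
})

test_that("end-to-end: strong events on a small genome are recovered", {
  sf <- small_fixture()
  res <- detect_cnvs(reads = sf$fix$reads, ref = sf$ref)
  expect_s3_class(res, "rdcnv_result")
  ev <- match_calls(res$calls, sf$fix$truth, min_reciprocal = 0.5)
  s <- ev$summary
  # the two large events (an 8.6-kb-scale DEL and a CN6 DUP) must be found
  expect_gte(s[s$type == "all", ]$tp, 2L)
  expect_true(all(res$calls[res$calls$type == "DEL", ]$fold < 1))
  expect_true(all(res$calls[res$calls$type == "DUP", ]$fold > 1))
  expect_true(all(res$calls$end - res$calls$start + 1L >= 100L))
})
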
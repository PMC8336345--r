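qc_row <- function(sample_id = "s1", sd_lrr = 0, baf_drift = 0,
                   gc_wave_factor = 0, sd_baf = 0, outlier_rate = 0,
                   n_calls = 0L) {
  data.frame(sample_id = sample_id, sd_lrr = sd_lrr, baf_drift = baf_drift,
             gc_wave_factor = gc_wave_factor, sd_baf = sd_baf,
             outlier_rate = outlier_rate, n_calls = n_calls,
             stringsAsFactors = FALSE)
}

test_that("sample limits follow the per-caller exclusion rules", {
  thr <- qc_thresholds()
  # SD of LRR > 0.35 drops a sample under the HMM caller; 0.35 itself passes
  res <- filter_samples(qc_row(sd_lrr = 0.36), thr, "hmm")
  expect_equal(res$dropped$sample_id, "s1")
  expect_match(res$dropped$reasons, "sd_lrr")
  expect_equal(filter_samples(qc_row(sd_lrr = 0.35), thr, "hmm")$kept, "s1")
  # clean metrics keep the sample everywhere
  for (cl in c("hmm", "bayes", "gaussian")) {
    expect_equal(filter_samples(qc_row(), thr, cl)$kept, "s1")
  }
  # > 50 calls drops the sample under any caller
  for (cl in c("hmm", "bayes", "gaussian")) {
    res <- filter_samples(qc_row(n_calls = 51L), thr, cl)
    expect_equal(res$dropped$reasons, "n_calls")
  }
  # bayes-specific limits
  res <- filter_samples(qc_row(sd_lrr = 0.3, sd_baf = 0.31, outlier_rate = 0.02),
                        thr, "bayes")
  expect_equal(res$dropped$reasons, "sd_lrr;sd_baf;outlier_rate")
  # ... which do not apply under hmm
  expect_equal(filter_samples(qc_row(sd_lrr = 0.3, sd_baf = 0.31,
                                     outlier_rate = 0.02), thr, "hmm")$kept, "s1")
  expect_error(filter_samples(qc_row(), thr, "penncnv"),
               class = "cnvrassoc_invalid_argument")
})

test_that("call limits use the documented boundary semantics", {
  mk <- function(n_probes, len, conf, caller = "hmm") {
    data.frame(sample_id = "s1", chr = 1L, start = 10000L,
               end = 10000L + len - 1L, copy_number = 1L, copy_type = "loss",
               n_probes = n_probes, confidence = conf, caller = caller,
               stringsAsFactors = FALSE)
  }
  expect_equal(nrow(filter_calls(mk(4, 8000, 20))), 0)      # < 5 probes
  expect_equal(nrow(filter_calls(mk(5, 4999, 20))), 0)      # < 5 kb
  expect_equal(nrow(filter_calls(mk(5, 5000, 10))), 1)      # hmm boundary inclusive
  expect_equal(nrow(filter_calls(mk(5, 5000, 10, "bayes"))), 0)  # MaxLogBF must exceed 10
  expect_equal(nrow(filter_calls(mk(5, 5000, 10.01, "bayes"))), 1)
  expect_equal(nrow(filter_calls(mk(5, 5000, 34.9, "gaussian"))), 0)
  expect_equal(nrow(filter_calls(mk(5, 5000, 35, "gaussian"))), 1)
})

test_that("call filtering equals the three predicates evaluated independently", {
  calls <- random_calls(200, seed = 12)
  got <- filter_calls(calls)
  thr <- qc_thresholds()$call
  keep <- vapply(seq_len(nrow(calls)), function(i) {
    conf_ok <- if (calls$caller[i] == "bayes") calls$confidence[i] > 10
      else calls$confidence[i] >= thr$min_confidence[[calls$caller[i]]]
    calls$n_probes[i] >= 5 &&
      (calls$end[i] - calls$start[i] + 1) >= 5000 &&
      conf_ok
  }, logical(1))
  expect_same_calls(got, calls[keep, ])
})

test_that("exclusion-region overlap rule applies at 50% of the call length", {
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1500, 2000))
  mk <- function(start, end) {
    data.frame(sample_id = "s1", chr = 1L, start = start, end = end,
               copy_number = 1L, copy_type = "loss", n_probes = 10L,
               confidence = 20, caller = "hmm", stringsAsFactors = FALSE)
  }
  expect_equal(nrow(exclude_regions(mk(1600, 1900), region)), 0) # fully inside
  # overlap 501 of 1001 bp >= 50% -> removed
  expect_equal(nrow(exclude_regions(mk(1000, 2000), region)), 0)
  # overlap 490 of 1001 bp (49%) -> kept
  expect_equal(nrow(exclude_regions(mk(1511, 2511), region)), 1)
  # overlap accumulates over the union of several regions
  two <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1000, 1600), c(1300, 1900)))
  expect_equal(nrow(exclude_regions(mk(1000, 2000), two)), 0)
})

test_that("adjacent-call merging follows the half-combined-length rule", {
  map <- data.frame(marker = paste0("m", 1:40), chr = 1L,
                    pos = seq(1, 20000, length.out = 40),
                    pbaf = 0.5, gc = 0.5)
  map$pos <- as.integer(round(map$pos))
  class(map) <- c("snp_map", "data.frame")
  mk <- function(start, end, type = "loss", cn = 1L) {
    data.frame(sample_id = "s1", chr = 1L, start = start, end = end,
               copy_number = cn, copy_type = type, n_probes = 1L,
               confidence = 10, caller = "hmm", stringsAsFactors = FALSE)
  }
  # gap 1999 < (10000 + 8001)/2 -> merged into one spanning call
  two <- rbind(mk(1, 10000), mk(12000, 20000))
  merged <- merge_adjacent(two, map)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(1, 20000))
  expect_equal(merged$confidence, 20)
  # gap exactly half the combined length is NOT merged (strict <)
  a <- mk(1, 1000); b <- mk(2001, 3000) # L1 = L2 = 1000, gap = 1000 = half
  expect_equal(nrow(merge_adjacent(rbind(a, b), map)), 2)
  b2 <- mk(1900, 2899) # gap 899 < 1000 -> merged
  expect_equal(nrow(merge_adjacent(rbind(a, b2), map)), 1)
  # single call unchanged
  expect_same_calls(merge_adjacent(mk(5, 800), map), mk(5, 800))
  # different copy types never merge
  expect_equal(nrow(merge_adjacent(rbind(mk(1, 10000),
                                         mk(12000, 20000, "gain", 3L)), map)), 2)
})

test_that("merging is idempotent and never shrinks covered bases", {
  map <- build_snp_map(2, 300, 3000, seed = 3)
  calls <- random_calls(120, seed = 9)
  once <- merge_adjacent(calls, map)
  twice <- merge_adjacent(once, map)
  expect_same_calls(once, twice)
  covered <- function(df) {
    sum(GenomicRanges::width(GenomicRanges::reduce(
      cnvrassoc:::calls_to_granges(df)
    )))
  }
  expect_gte(covered(once), covered(calls))
})

test_that("call-level filters commute with exclusion-region filtering", {
  calls <- random_calls(150, seed = 30)
  regions <- GenomicRanges::GRanges(
    rep(c("chr1", "chr2"), each = 3),
    IRanges::IRanges(c(1e5, 1e6, 3e6, 2e5, 2e6, 4e6), width = 50000)
  )
  a <- filter_calls(exclude_regions(calls, regions))
  b <- exclude_regions(filter_calls(calls), regions)
  expect_same_calls(a, b)
})
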
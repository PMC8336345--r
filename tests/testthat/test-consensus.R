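mk_call <- function(start, end, caller, type = "loss", sample = "s1",
                    chr = 1L) {
  cn <- if (type == "loss") 1L else 3L
  data.frame(sample_id = sample, chr = chr, start = start, end = end,
             copy_number = cn, copy_type = type, n_probes = 10L,
             confidence = 20, caller = caller, stringsAsFactors = FALSE)
}

test_that("consensus requires two callers, same type, reciprocal overlap", {
  # reciprocal overlap of [100,200] and [120,220] is 81/101 = 0.80 each
  two <- rbind(mk_call(100, 200, "hmm"), mk_call(120, 220, "bayes"))
  cons <- consensus_calls(two)
  expect_equal(nrow(cons), 1)
  expect_equal(c(cons$start, cons$end), c(120, 200)) # intersection
  expect_equal(cons$callers, "bayes,hmm")
  expect_equal(cons$n_callers, 2L)

  expect_equal(nrow(consensus_calls(mk_call(100, 200, "hmm"))), 0)
  mixed <- rbind(mk_call(100, 200, "hmm"),
                 mk_call(100, 200, "bayes", type = "gain"))
  expect_equal(nrow(consensus_calls(mixed)), 0)
  # overlap below the reciprocal threshold does not pair
  weak <- rbind(mk_call(100, 200, "hmm"), mk_call(180, 400, "bayes"))
  expect_equal(nrow(consensus_calls(weak)), 0)
})

test_that("three concordant callers give one consensus call over the triple intersection", {
  three <- rbind(mk_call(100, 200, "hmm"), mk_call(110, 210, "bayes"),
                 mk_call(95, 195, "gaussian"))
  cons <- consensus_calls(three)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$n_callers, 3L)
  expect_equal(c(cons$start, cons$end), c(110, 195))
})

test_that("each caller's call supports at most one consensus call", {
  calls <- rbind(mk_call(100, 200, "hmm"), mk_call(100, 200, "bayes"),
                 mk_call(100, 200, "hmm")) # duplicate hmm call
  cons <- consensus_calls(calls)
  expect_equal(nrow(cons), 1)
})

test_that("CNVR construction uses innermost boundaries with sweep restarts", {
  one <- data.frame(sample_id = "s1", chr = 1L, start = 100L, end = 200L,
                    copy_type = "loss", callers = "bayes,hmm", n_callers = 2L,
                    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                        phenotype = c("case", "case", "control"),
                        stringsAsFactors = FALSE)
  expect_equal(build_cnvrs(one, samples)[, c("start", "end")],
               data.frame(start = 100L, end = 200L))

  two <- rbind(one, within(one, { sample_id <- "s2"; start <- 150L; end <- 250L }))
  cnvr <- build_cnvrs(two, samples)
  expect_equal(c(cnvr$start, cnvr$end), c(150, 200))
  expect_equal(cnvr$n_carriers, 2L)

  three <- rbind(two, within(one, { sample_id <- "s3"; start <- 240L; end <- 300L }))
  cnvr <- build_cnvrs(three, samples)
  expect_equal(cnvr$start, c(150, 240))
  expect_equal(cnvr$end, c(200, 250)) # s2's call still covers the second CNVR
  expect_equal(cnvr$n_carriers, c(2L, 2L))
  expect_equal(cnvr$n_case_carriers, c(2L, 1L))
  expect_equal(cnvr$n_control_carriers, c(0L, 1L))
})

test_that("consensus and CNVRs are invariant to input row order", {
  calls <- random_calls(60, seed = 17)
  calls <- calls[calls$sample_id == calls$sample_id[1], ]
  calls$sample_id <- "s1"
  perm <- withr::with_seed(2, sample.int(nrow(calls)))
  expect_same_calls(consensus_calls(calls), consensus_calls(calls[perm, ]))

  cons <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(sample_id = paste0("s", i), chr = 1L,
               start = 100L + 37L * i, end = 400L + 11L * i,
               copy_type = "loss", callers = "bayes,hmm", n_callers = 2L,
               stringsAsFactors = FALSE)
  }))
  samples <- data.frame(sample_id = paste0("s", 1:6),
                        phenotype = rep(c("case", "control"), 3),
                        stringsAsFactors = FALSE)
  perm <- withr::with_seed(3, sample.int(nrow(cons)))
  expect_equal(build_cnvrs(cons, samples), build_cnvrs(cons[perm, ], samples))
})

test_that("same-type CNVRs on one chromosome are pairwise disjoint", {
  cons <- withr::with_seed(19, {
    start <- sample.int(1e5, 40)
    data.frame(sample_id = sprintf("s%02d", sample.int(20, 40, replace = TRUE)),
               chr = 1L, start = start, end = start + sample.int(5000, 40),
               copy_type = "loss", callers = "bayes,hmm", n_callers = 2L,
               stringsAsFactors = FALSE)
  })
  samples <- data.frame(sample_id = sprintf("s%02d", 1:20),
                        phenotype = rep(c("case", "control"), 10),
                        stringsAsFactors = FALSE)
  cnvrs <- build_cnvrs(cons, samples)
  if (nrow(cnvrs) > 1) {
    o <- order(cnvrs$start)
    expect_true(all(cnvrs$start[o][-1] > cnvrs$end[o][-nrow(cnvrs)]))
  }
  # every contributing consensus call covers its CNVR
  for (i in seq_len(nrow(cnvrs))) {
    members <- strsplit(cnvrs$carriers[i], ",")[[1]]
    sub <- cons[cons$sample_id %in% members &
                  cons$start <= cnvrs$start[i] & cons$end >= cnvrs$end[i], ]
    expect_gte(nrow(sub), 1)
  }
})

test_that("the cohort frequency floor keeps CNVRs at or above 1%", {
  cnvr <- function(n) {
    data.frame(chr = 1L, start = 1L, end = 2L, copy_type = "loss",
               n_carriers = n, n_case_carriers = n, n_control_carriers = 0L,
               case_freq = 0, control_freq = 0, carriers = "x",
               stringsAsFactors = FALSE)
  }
  expect_equal(nrow(frequency_filter(cnvr(3L), 131, 121)), 1)  # 3/252 = 1.19%
  expect_equal(nrow(frequency_filter(cnvr(2L), 131, 121)), 0)  # 0.79%
  expect_equal(nrow(frequency_filter(cnvr(1L), 131, 121, min_freq = 0)), 1)
  expect_error(frequency_filter(cnvr(1L), 0, 0), class = "cnvrassoc_invalid_argument")
})

test_that("carrier tables reproduce the printed frequency layout", {
  cnvr <- data.frame(chr = 13L, start = 32912236L, end = 32921033L,
                     copy_type = "loss", n_carriers = 68L,
                     n_case_carriers = 49L, n_control_carriers = 19L,
                     case_freq = 49 / 131, control_freq = 19 / 121,
                     carriers = "", stringsAsFactors = FALSE)
  tab <- carrier_table(cnvr, 131, 121)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(49, 82, 19, 102))
  expect_equal(round(tab$case_pct, 1), 37.4)
  expect_equal(round(tab$control_pct, 1), 15.7)
  zero <- within(cnvr, { n_case_carriers <- 0L; n_control_carriers <- 0L })
  tabz <- carrier_table(zero, 131, 121)
  expect_equal(c(tabz$a, tabz$b, tabz$c, tabz$d), c(0, 131, 0, 121))
  full <- within(cnvr, { n_case_carriers <- 131L; n_control_carriers <- 121L })
  tabf <- carrier_table(full, 131, 121)
  expect_equal(c(tabf$case_pct, tabf$control_pct), c(100, 100))
})
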
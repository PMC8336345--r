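# Small cohort/map builders shared across test files.

tiny_map <- function(n = 300, spacing = 3000, seed = 7) {
  build_snp_map(1, n, spacing, seed = seed)
}

# A noise-free diploid track over `map`.
clean_track <- function(map, id = "s1") {
  coh <- simulate_cohort(map, NULL, 1, 0, sd_lrr = 0, baf_noise = 0, seed = 5)
  tr <- get_track(coh, 1)
  tr$sample_id <- id
  tr
}

# One carrier track with a single implanted locus spanning markers i0..i1.
carrier_track <- function(map, i0, i1, copy_number, sd_lrr = 0.15,
                          baf_noise = 0.03, seed = 3) {
  locus <- cnv_locus(1, map$pos[i0], map$pos[i1], copy_number, 1, 1)
  coh <- simulate_cohort(map, locus, 1, 0, sd_lrr = sd_lrr,
                         baf_noise = baf_noise, seed = seed)
  get_track(coh, 1)
}

# Random CNV-call table for filter/merge round-trip properties.
random_calls <- function(n, seed = 1) {
  withr::with_seed(seed, {
    start <- sample.int(5e6, n)
    len <- sample.int(20000, n)
    cn <- sample(c(0L, 1L, 3L, 4L), n, replace = TRUE)
    data.frame(
      sample_id = sample(sprintf("s%02d", 1:8), n, replace = TRUE),
      chr = sample(1:2, n, replace = TRUE),
      start = start, end = start + len,
      copy_number = cn, copy_type = ifelse(cn < 2, "loss", "gain"),
      n_probes = sample(1:60, n, replace = TRUE),
      confidence = round(runif(n, 0, 60), 3),
      caller = sample(c("hmm", "bayes", "gaussian"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

expect_same_calls <- function(a, b) {
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, ignore_attr = TRUE)
}
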
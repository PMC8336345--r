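#' Default sample- and call-level QC thresholds
#'
#' The defaults encode the per-caller exclusion rules applied before any
#' association analysis:
#' * HMM caller samples: SD of LRR > 0.35, BAF drift > 0.01, GC-wave factor
#'   magnitude > 0.05, or > 50 calls are dropped.
#' * Bayes caller samples: SD of LRR > 0.25, SD of BAF > 0.3, outlier rate
#'   > 0.01, or > 50 calls are dropped.
#' * Gaussian caller: no signal-metric sample limits (its stringency is the
#'   call confidence threshold of 35), but the > 50 calls-per-sample rule
#'   still applies.
#' * Calls (all callers): fewer than five probes, shorter than 5 kb, or below
#'   the caller's confidence threshold (HMM >= 10 inclusive; Bayes
#'   `MaxLogBF` strictly > 10; Gaussian >= 35) are dropped.
#' * Exclusion regions: a call overlapping telomeric / centromeric /
#'   immunoglobulin / segmental-duplication regions over at least 50% of its
#'   length is dropped.
#'
#' @return Nested threshold list (class `qc_thresholds`).
#' @export
qc_thresholds <- function() {
  structure(list(
    sample = list(
      hmm = list(max_sd_lrr = 0.35, max_baf_drift = 0.01, max_gcwf = 0.05,
                 max_calls = 50),
      bayes = list(max_sd_lrr = 0.25, max_sd_baf = 0.3, max_outlier_rate = 0.01,
                   max_calls = 50),
      gaussian = list(max_calls = 50)
    ),
    call = list(
      min_probes = 5L, min_length_bp = 5000L,
      min_confidence = c(hmm = 10, bayes = 10, gaussian = 35),
      strict = c(hmm = FALSE, bayes = TRUE, gaussian = FALSE)
    ),
    exclusion_overlap_fraction = 0.5
  ), class = "qc_thresholds")
}

#' Apply sample-level QC for one caller
#'
#' A sample is dropped iff it violates at least one of the caller's limits;
#' every violated limit is reported as a machine-readable reason code.
#'
#' @param qcs A `data.frame` of per-sample metrics ([sample_qc_metrics()]
#'   rows), optionally with an `n_calls` column for the calls-per-sample
#'   limit.
#' @param thresholds A [qc_thresholds()] list.
#' @param caller One of `"hmm"`, `"bayes"`, `"gaussian"`.
#' @return List with `kept` (sample ids) and `dropped` (`data.frame` with
#'   `sample_id`, `reasons` — semicolon-joined codes).
#' @export
filter_samples <- function(qcs, thresholds = qc_thresholds(), caller) {
  if (!caller %in% names(thresholds$sample)) stop_invalid("unknown caller: ", caller)
  lim <- thresholds$sample[[caller]]
  checks <- list(
    sd_lrr = function(q) q$sd_lrr > lim$max_sd_lrr,
    baf_drift = function(q) q$baf_drift > lim$max_baf_drift,
    gc_wave_factor = function(q) abs(q$gc_wave_factor) > lim$max_gcwf,
    sd_baf = function(q) q$sd_baf > lim$max_sd_baf,
    outlier_rate = function(q) q$outlier_rate > lim$max_outlier_rate,
    n_calls = function(q) q$n_calls > lim$max_calls
  )
  active <- names(checks)[c(
    !is.null(lim$max_sd_lrr), !is.null(lim$max_baf_drift),
    !is.null(lim$max_gcwf), !is.null(lim$max_sd_baf),
    !is.null(lim$max_outlier_rate),
    !is.null(lim$max_calls) && "n_calls" %in% names(qcs)
  )]
  reasons <- vapply(seq_len(nrow(qcs)), function(i) {
    hit <- Filter(function(nm) isTRUE(checks[[nm]](qcs[i, ])), active)
    paste(unlist(hit), collapse = ";")
  }, character(1))
  dropped <- reasons != ""
  list(
    kept = qcs$sample_id[!dropped],
    dropped = data.frame(sample_id = qcs$sample_id[dropped],
                         reasons = reasons[dropped], stringsAsFactors = FALSE)
  )
}

#' Apply call-level QC
#'
#' Keeps calls with at least five probes, at least 5 kb length (1-based
#' inclusive, `end - start + 1`) and a confidence meeting the caller's
#' threshold (HMM >= 10; Bayes strictly > 10; Gaussian >= 35).
#'
#' @param calls CNV-call `data.frame`.
#' @param thresholds A [qc_thresholds()] list.
#' @return The surviving calls.
#' @export
filter_calls <- function(calls, thresholds = qc_thresholds()) {
  if (nrow(calls) == 0) return(calls)
  cl <- thresholds$call
  min_conf <- cl$min_confidence[calls$caller]
  strict <- cl$strict[calls$caller]
  conf_ok <- ifelse(strict, calls$confidence > min_conf, calls$confidence >= min_conf)
  keep <- calls$n_probes >= cl$min_probes &
    call_length(calls) >= cl$min_length_bp &
    conf_ok
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop calls overlapping exclusion regions
#'
#' A call is removed iff the fraction of its length (1-based inclusive)
#' covered by the union of the exclusion regions is at least `fraction`.
#'
#' @param calls CNV-call `data.frame`.
#' @param regions A `GRanges` of exclusion regions (e.g. from
#'   [make_exclusion_bed()] or [read_bed()]).
#' @param fraction Overlap fraction at or above which a call is dropped.
#' @return The surviving calls.
#' @export
exclude_regions <- function(calls, regions, fraction = 0.5) {
  if (nrow(calls) == 0 || length(regions) == 0) return(calls)
  regions <- GenomicRanges::reduce(regions)
  gr <- calls_to_granges(calls)
  hits <- GenomicRanges::findOverlaps(gr, regions)
  ov_bp <- numeric(nrow(calls))
  if (length(hits)) {
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr)[S4Vectors::queryHits(hits)],
      IRanges::ranges(regions)[S4Vectors::subjectHits(hits)]
    ))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    ov_bp[as.integer(names(agg))] <- agg
  }
  out <- calls[ov_bp / call_length(calls) < fraction, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge adjacent same-type calls of one sample
#'
#' Within each (sample, caller, chromosome, copy type) group, sweeps left to
#' right and merges two neighbouring calls with gap `g` and lengths `L1`,
#' `L2` iff `g < (L1 + L2) / 2` (strict), repeating to a fixpoint. The merged
#' call spans the union, its probe count is recomputed from the map, its
#' confidence is the sum, and its copy number is taken from the longer
#' constituent.
#'
#' @param calls CNV-call `data.frame`.
#' @param map The `snp_map` used to recompute probe counts.
#' @return The merged calls.
#' @export
merge_adjacent <- function(calls, map) {
  if (nrow(calls) == 0) return(calls)
  key <- interaction(calls$sample_id, calls$caller, calls$chr, calls$copy_type,
                     drop = TRUE)
  merged <- lapply(split(calls, key), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    repeat {
      if (nrow(g) < 2) break
    changed <- FALSE
      i <- 1L
      while (i < nrow(g)) {
        L1 <- g$end[i] - g$start[i] + 1L
        L2 <- g$end[i + 1L] - g$start[i + 1L] + 1L
        gap <- g$start[i + 1L] - g$end[i] - 1L
        if (gap < (L1 + L2) / 2) {
          g$end[i] <- max(g$end[i], g$end[i + 1L])
          g$copy_number[i] <- if (L2 > L1) g$copy_number[i + 1L] else g$copy_number[i]
          g$confidence[i] <- g$confidence[i] + g$confidence[i + 1L]
          g <- g[-(i + 1L), , drop = FALSE]
          changed <- TRUE
        } else {
          i <- i + 1L
        }
      }
      if (!changed) break
    }
    g$n_probes <- vapply(seq_len(nrow(g)), function(r) {
      sum(map$chr == g$chr[r] & map$pos >= g$start[r] & map$pos <= g$end[r])
    }, integer(1))
    g
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out[order(out$sample_id, out$caller, out$chr, out$start), , drop = FALSE]
}
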
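#' Per-sample signal quality metrics
#'
#' Computes the sample-level metrics the callers' QC thresholds are applied
#' to: `sd_lrr` (standard deviation of autosomal LRR), `baf_drift` (fraction
#' of markers with BAF in the off-cluster bands (0.2, 0.25) or (0.75, 0.8)),
#' `gc_wave_factor` (slope of LRR regressed on standardized local GC),
#' `sd_baf` (SD of the distance from BAF to its nearest canonical band
#' {0, 0.5, 1}) and `outlier_rate` (fraction of markers with |LRR| > 1).
#'
#' @param track A `signal_track` (or list with `lrr`, `baf`, `sample_id`).
#' @param map The `snp_map` the track was measured on.
#' @return One-row `data.frame` of class `sample_qc`.
#' @export
sample_qc_metrics <- function(track, map) {
  if (length(track$lrr) == 0) stop_invalid("empty track")
  if (length(track$lrr) != nrow(map) || length(track$baf) != nrow(map)) {
    stop_invalid("track length does not match the map")
  }
  gcz <- standardized_gc(map)
  slope <- if (sd(gcz) == 0) 0 else stats::cov(track$lrr, gcz) / stats::var(gcz)
  baf <- track$baf
  drift <- mean((baf > 0.2 & baf < 0.25) | (baf > 0.75 & baf < 0.8))
  band_dev <- pmin(abs(baf), abs(baf - 0.5), abs(baf - 1))
  out <- data.frame(
    sample_id = track$sample_id %||% NA_character_,
    sd_lrr = stats::sd(track$lrr),
    baf_drift = drift,
    gc_wave_factor = slope,
    sd_baf = stats::sd(band_dev),
    outlier_rate = mean(abs(track$lrr) > 1.0),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sample_qc", "data.frame")
  out
}

#' Remove GC-wave artifacts from an LRR track
#'
#' "Genomic waves" are long-range LRR oscillations correlated with local GC
#' content. The correction residualizes LRR on standardized local GC
#' (removing both the fitted slope and intercept, so a wave-free diploid
#' track keeps its zero baseline); it is idempotent up to numerical
#' tolerance.
#'
#' @param track A `signal_track`.
#' @param map The `snp_map` providing local GC.
#' @return The track with corrected `lrr`.
#' @export
gc_correct <- function(track, map) {
  gcz <- standardized_gc(map)
  if (sd(gcz) == 0) return(track)
  fit <- stats::lm.fit(cbind(1, gcz), track$lrr)
  track$lrr <- track$lrr - fit$coefficients[1] - fit$coefficients[2] * gcz
  track
}
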
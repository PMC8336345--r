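# Three independent CNV callers over one shared emission model:
#   call_hmm      — Viterbi decoding of a 5-state copy-number HMM with
#                   distance-dependent transitions (PennCNV-style).
#   call_bayes    — GC-corrects the track first, then the same segmentation;
#                   confidence is the maximum log10 Bayes factor of any
#                   non-diploid state against diploid (QuantiSNP-style).
#   call_gaussian — no chain: maximal-scoring segments of the per-marker
#                   log-likelihood advantage of the best non-diploid state
#                   over diploid (cnvPartition-style).

prepare_emissions <- function(track, map, params, baf_ll = NULL) {
  sd_lrr <- params$sd_lrr %||% estimate_sd_lrr(track$lrr)
  emission_loglik(track$lrr, track$baf, map$pbaf, sd_lrr, params$baf_sd, baf_ll)
}

segments_from_path <- function(path) {
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 3L # state index 3 == CN2
  data.frame(i0 = starts[keep], i1 = ends[keep], state = r$values[keep])
}

# Decode one chromosome, return non-diploid runs as marker-index rows.
decode_chromosome <- function(emis, pos, params) {
  log_init <- log(c(rep((1 - params$prior_diploid) / 4, 2), params$prior_diploid,
                    rep((1 - params$prior_diploid) / 4, 2)))
  path <- viterbi_decode(emis, diff(pos), log_init, params$p_stay, params$D)
  segments_from_path(path)
}

finish_calls <- function(seg_rows, map_chr, sample_id, caller, conf) {
  if (nrow(seg_rows) == 0) return(empty_calls())
  cn <- STATE_CN[seg_rows$state]
  data.frame(
    sample_id = sample_id,
    chr = map_chr$chr[1],
    start = map_chr$pos[seg_rows$i0],
    end = map_chr$pos[seg_rows$i1],
    copy_number = cn,
    copy_type = copy_type_of(cn),
    n_probes = seg_rows$i1 - seg_rows$i0 + 1L,
    confidence = conf,
    caller = caller,
    stringsAsFactors = FALSE
  )
}

# Per-segment log10 likelihood ratio of state `s` (or the best non-diploid
# state when s = NA) against diploid, from the emission matrix.
segment_log10_lr <- function(emis, seg_rows, best_state = FALSE) {
  vapply(seq_len(nrow(seg_rows)), function(r) {
    rows <- seg_rows$i0[r]:seg_rows$i1[r]
    if (best_state) {
      max(vapply(c(1L, 2L, 4L, 5L), function(t) {
        sum(emis[rows, t] - emis[rows, 3L])
      }, numeric(1))) / log(10)
    } else {
      sum(emis[rows, seg_rows$state[r]] - emis[rows, 3L]) / log(10)
    }
  }, numeric(1))
}

hmm_scaffold <- function(track, map, params, caller, best_state_conf,
                         baf_ll = NULL) {
  validate_snp_map(map)
  if (length(track$lrr) != nrow(map)) stop_invalid("track does not match the map")
  pieces <- lapply(split(seq_len(nrow(map)), map$chr), function(idx) {
    map_chr <- map[idx, , drop = FALSE]
    emis <- prepare_emissions(
      list(lrr = track$lrr[idx], baf = track$baf[idx]), map_chr, params,
      if (is.null(baf_ll)) NULL else baf_ll[idx, , drop = FALSE]
    )
    seg <- decode_chromosome(emis, map_chr$pos, params)
    finish_calls(seg, map_chr, track$sample_id, caller,
                 segment_log10_lr(emis, seg, best_state = best_state_conf))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$chr, out$start), , drop = FALSE]
}

#' Call CNVs with the hidden-Markov-model caller
#'
#' Viterbi decoding over copy-number states {CN0..CN4}; emissions combine a
#' Gaussian LRR term with a BAF genotype mixture weighted by the population
#' B-allele frequency; the self-transition probability decays with
#' inter-marker distance as `1 - (1 - p_stay) * (1 - exp(-d/D))`. Contiguous
#' non-diploid runs of the decoded path become calls; confidence is the
#' log10 likelihood ratio of the called state against diploid over the
#' segment.
#'
#' @param track A `signal_track`.
#' @param map The matching `snp_map`.
#' @param params A [caller_params()] list.
#' @return A CNV-call `data.frame` (`sample_id`, `chr`, `start`, `end`,
#'   `copy_number`, `copy_type`, `n_probes`, `confidence`, `caller`);
#'   coordinates are 1-based inclusive marker positions.
#' @export
call_hmm <- function(track, map, params = caller_params()) {
  hmm_scaffold(track, map, params, "hmm", best_state_conf = FALSE)
}

#' Call CNVs with the Bayes-factor caller
#'
#' GC-corrects the LRR track first, then applies the same hidden-Markov
#' segmentation as [call_hmm()]. The per-call confidence is the maximum log10
#' Bayes factor (`MaxLogBF`) of any non-diploid state against diploid over
#' the segment (state priors uniform over the non-diploid states cancel in
#' the ratio). Calls with `MaxLogBF <= 10` are retained here but tagged
#' sub-threshold by the downstream call filter, which drops them.
#'
#' @inheritParams call_hmm
#' @return A CNV-call `data.frame`; see [call_hmm()].
#' @export
call_bayes <- function(track, map, params = caller_params()) {
  hmm_scaffold(gc_correct(track, map), map, params, "bayes",
               best_state_conf = TRUE)
}

gaussian_scaffold <- function(track, map, params, baf_ll = NULL) {
  validate_snp_map(map)
  if (length(track$lrr) != nrow(map)) stop_invalid("track does not match the map")
  thr_nat <- params$gaussian_threshold * log(10)
  pieces <- lapply(split(seq_len(nrow(map)), map$chr), function(idx) {
    map_chr <- map[idx, , drop = FALSE]
    emis <- prepare_emissions(
      list(lrr = track$lrr[idx], baf = track$baf[idx]), map_chr, params,
      if (is.null(baf_ll)) NULL else baf_ll[idx, , drop = FALSE]
    )
    cand <- do.call(rbind, lapply(c(1L, 2L, 4L, 5L), function(s) {
      seg <- maximal_scoring_segments(emis[, s] - emis[, 3L])
      if (nrow(seg) == 0) return(NULL)
      data.frame(i0 = as.integer(seg[, 1]), i1 = as.integer(seg[, 2]),
                 score = seg[, 3], state = s)
    }))
    if (is.null(cand)) return(empty_calls())
    cand <- cand[cand$score >= thr_nat, , drop = FALSE]
    if (nrow(cand) == 0) return(empty_calls())
    # greedy non-overlap resolution, best score first (deterministic ties)
    cand <- cand[order(-cand$score, cand$i0, cand$state), , drop = FALSE]
    taken <- rep(FALSE, nrow(map_chr))
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      span <- cand$i0[r]:cand$i1[r]
      if (!any(taken[span])) {
        keep[r] <- TRUE
        taken[span] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    finish_calls(cand[, c("i0", "i1", "state")], map_chr, track$sample_id,
                 "gaussian", cand$score / log(10))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$chr, out$start), , drop = FALSE]
}

#' Call CNVs with the Gaussian-partition caller
#'
#' Scores every marker with the log-likelihood advantage of its best
#' non-diploid copy state over diploid under the shared bivariate
#' (LRR, BAF-band) Gaussian emission model, then extracts all maximal-scoring
#' segments of that advantage; segments whose cumulative advantage reaches
#' the confidence threshold (default 35, log10 scale) become calls.
#' Overlapping candidate segments from different copy states are resolved by
#' score (highest first).
#'
#' @inheritParams call_hmm
#' @return A CNV-call `data.frame`; see [call_hmm()].
#' @export
call_gaussian <- function(track, map, params = caller_params()) {
  gaussian_scaffold(track, map, params)
}

#' Run all three callers over every sample of a cohort
#'
#' Equivalent to calling [call_hmm()], [call_bayes()] and [call_gaussian()]
#' per sample, but shares the BAF mixture term (identical across callers —
#' GC correction only alters LRR) and the per-map Binomial mixture weights.
#'
#' @param cohort A `cnv_cohort`.
#' @param params A [caller_params()] list.
#' @param callers Subset of `c("hmm", "bayes", "gaussian")`.
#' @return One CNV-call `data.frame` pooling all callers and samples.
#' @export
call_cohort <- function(cohort, params = caller_params(),
                        callers = c("hmm", "bayes", "gaussian")) {
  unknown <- setdiff(callers, c("hmm", "bayes", "gaussian"))
  if (length(unknown)) stop_invalid("unknown caller: ", paste(unknown, collapse = ", "))
  map <- cohort$map
  logw <- baf_logweights(map$pbaf)
  out <- lapply(seq_len(nrow(cohort$samples)), function(j) {
    track <- get_track(cohort, j)
    baf_ll <- baf_mixture_loglik(track$baf, map$pbaf, params$baf_sd, logw)
    res <- list()
    if ("hmm" %in% callers) {
      res$hmm <- hmm_scaffold(track, map, params, "hmm", FALSE, baf_ll)
    }
    if ("bayes" %in% callers) {
      res$bayes <- hmm_scaffold(gc_correct(track, map), map, params, "bayes",
                                TRUE, baf_ll)
    }
    if ("gaussian" %in% callers) {
      res$gaussian <- gaussian_scaffold(track, map, params, baf_ll)
    }
    do.call(rbind, res[callers])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
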
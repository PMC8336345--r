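reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1
  if (ov <= 0) return(0)
  min(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

#' Build per-sample multi-caller consensus calls
#'
#' A consensus call requires the same event to be detected by at least two
#' distinct callers with a consistent copy-change type and pairwise
#' reciprocal overlap at or above `reciprocal_overlap` (the overlap must
#' cover that fraction of BOTH intervals). Groups are formed greedily from
#' the leftmost-starting unused call (ties broken by the longest), each
#' caller's call contributes to at most one consensus call, and the emitted
#' interval is the common intersection of the supporting calls.
#'
#' @param calls QC-filtered CNV calls of ONE sample.
#' @param reciprocal_overlap Pairwise reciprocal-overlap threshold.
#' @return `data.frame` of consensus calls: `sample_id`, `chr`, `start`,
#'   `end`, `copy_type`, `callers` (comma-joined supporting callers),
#'   `n_callers`.
#' @export
consensus_calls <- function(calls, reciprocal_overlap = 0.5) {
  empty <- data.frame(
    sample_id = character(), chr = integer(), start = integer(), end = integer(),
    copy_type = character(), callers = character(), n_callers = integer(),
    stringsAsFactors = FALSE
  )
  if (nrow(calls) == 0) return(empty)
  if (length(unique(calls$sample_id)) > 1) {
    stop_invalid("consensus_calls expects the calls of a single sample")
  }
  ro <- function(i, j) reciprocal_overlap_num(calls, i, j)
  out <- list()
  for (grp in split(seq_len(nrow(calls)),
                    interaction(calls$chr, calls$copy_type, drop = TRUE))) {
    sub <- grp[order(calls$start[grp], -(calls$end[grp] - calls$start[grp]))]
    used <- rep(FALSE, length(sub))
    for (a in seq_along(sub)) {
      if (used[a]) next
      i <- sub[a]
      # best reciprocally-overlapping unused partner from each other caller
      partners <- integer(0)
      for (cl in setdiff(unique(calls$caller[sub]), calls$caller[i])) {
        cand <- sub[!used & calls$caller[sub] == cl]
        if (length(cand) == 0) next
        ovs <- vapply(cand, function(j) ro(i, j), numeric(1))
        if (max(ovs) >= reciprocal_overlap) {
          partners <- c(partners, cand[which.max(ovs)])
        }
      }
      if (length(partners) == 2) {
        # require pairwise consistency within the triple; otherwise keep the
        # partner overlapping the anchor more
        if (ro(partners[1], partners[2]) < reciprocal_overlap) {
          ov1 <- ro(i, partners[1]); ov2 <- ro(i, partners[2])
          partners <- partners[which.max(c(ov1, ov2))]
        }
      }
      if (length(partners) == 0) next
      members <- c(i, partners)
      used[match(members, sub)] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        sample_id = calls$sample_id[i],
        chr = calls$chr[i],
        start = max(calls$start[members]),
        end = min(calls$end[members]),
        copy_type = calls$copy_type[i],
        callers = paste(sort(calls$caller[members]), collapse = ","),
        n_callers = length(members),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) return(empty)
  out <- do.call(rbind, out)
  out <- out[order(out$chr, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

reciprocal_overlap_num <- function(calls, i, j) {
  reciprocal_overlap(calls$start[i], calls$end[i], calls$start[j], calls$end[j])
}

#' Build CNV regions (CNVRs) by innermost boundaries
#'
#' Pools consensus calls across samples per chromosome and copy type, sweeps
#' them by start position and accumulates calls while the running
#' intersection (max start, min end) stays non-empty; when a call starts past
#' the running intersection, the accumulated intersection is emitted as a
#' CNVR and the sweep restarts from that call, retaining the still-
#' overlapping members. Every contributing call fully covers its CNVR, and
#' same-type CNVRs on one chromosome are pairwise disjoint.
#'
#' @param consensus Pooled consensus calls (all samples).
#' @param samples Cohort sample table (`sample_id`, `phenotype`).
#' @return `data.frame` of CNVRs: `chr`, `start`, `end`, `copy_type`,
#'   `n_carriers`, `n_case_carriers`, `n_control_carriers`, `case_freq`,
#'   `control_freq`, `carriers` (comma-joined sample ids).
#' @export
build_cnvrs <- function(consensus, samples) {
  empty <- data.frame(
    chr = integer(), start = integer(), end = integer(), copy_type = character(),
    n_carriers = integer(), n_case_carriers = integer(),
    n_control_carriers = integer(), case_freq = numeric(),
    control_freq = numeric(), carriers = character(), stringsAsFactors = FALSE
  )
  if (nrow(consensus) == 0) return(empty)
  n_cases <- sum(samples$phenotype == "case")
  n_controls <- sum(samples$phenotype == "control")
  pheno <- stats::setNames(samples$phenotype, samples$sample_id)
  emit <- function(int_start, int_end, members, chr, type) {
    ids <- sort(unique(members$sample_id))
    ph <- pheno[ids]
    if (anyNA(ph)) stop_invalid("consensus call from a sample absent from the cohort")
    data.frame(
      chr = chr, start = int_start, end = int_end, copy_type = type,
      n_carriers = length(ids),
      n_case_carriers = sum(ph == "case"),
      n_control_carriers = sum(ph == "control"),
      case_freq = if (n_cases) sum(ph == "case") / n_cases else 0,
      control_freq = if (n_controls) sum(ph == "control") / n_controls else 0,
      carriers = paste(ids, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  out <- list()
  for (g in split(consensus, interaction(consensus$chr, consensus$copy_type,
                                         drop = TRUE))) {
    g <- g[order(g$start, g$end), , drop = FALSE]
    active <- g[1, , drop = FALSE]
    int_start <- g$start[1]; int_end <- g$end[1]
    for (r in seq_len(nrow(g))[-1]) {
      if (g$start[r] <= int_end) {
        active <- rbind(active, g[r, , drop = FALSE])
        int_start <- max(int_start, g$start[r])
        int_end <- min(int_end, g$end[r])
      } else {
        out[[length(out) + 1L]] <-
          emit(int_start, int_end, active, g$chr[r], g$copy_type[r])
        active <- active[active$end >= g$start[r], , drop = FALSE]
        active <- rbind(active, g[r, , drop = FALSE])
        int_start <- g$start[r]
        int_end <- min(active$end)
      }
    }
    out[[length(out) + 1L]] <-
      emit(int_start, int_end, active, g$chr[1], g$copy_type[1])
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chr, out$start, out$copy_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep CNVRs reaching the cohort carrier-frequency floor
#'
#' @param cnvrs CNVR table from [build_cnvrs()].
#' @param n_cases,n_controls Post-QC cohort sizes.
#' @param min_freq Minimum carrier fraction of the whole cohort (default 1%).
#' @return The surviving CNVRs.
#' @export
frequency_filter <- function(cnvrs, n_cases, n_controls, min_freq = 0.01) {
  if (n_cases + n_controls <= 0) stop_invalid("cohort size must be positive")
  keep <- cnvrs$n_carriers / (n_cases + n_controls) >= min_freq
  out <- cnvrs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-CNVR 2x2 carrier contingency counts
#'
#' @param cnvrs CNVR table.
#' @param n_cases,n_controls Post-QC cohort sizes.
#' @return The CNVR table with columns `a` (case carriers), `b` (case
#'   non-carriers), `c` (control carriers), `d` (control non-carriers),
#'   `case_pct`, `control_pct`.
#' @export
carrier_table <- function(cnvrs, n_cases, n_controls) {
  if (any(cnvrs$n_case_carriers > n_cases) ||
      any(cnvrs$n_control_carriers > n_controls)) {
    stop_invalid("carrier counts exceed cohort sizes")
  }
  cnvrs$a <- cnvrs$n_case_carriers
  cnvrs$b <- n_cases - cnvrs$n_case_carriers
  cnvrs$c <- cnvrs$n_control_carriers
  cnvrs$d <- n_controls - cnvrs$n_control_carriers
  cnvrs$case_pct <- 100 * cnvrs$a / n_cases
  cnvrs$control_pct <- 100 * cnvrs$c / n_controls
  cnvrs
}
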
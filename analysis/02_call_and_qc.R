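#!/usr/bin/env Rscript
# Call CNVs on both simulated cohorts with the three callers, then apply the
# sample-level exclusion rules, the call-level filters (>= 5 probes, >= 5 kb,
# caller confidence), the 50% exclusion-region overlap rule and adjacent-call
# merging. Writes raw and filtered calls (rawcnv-like text) plus the QC drop
# report under results/.

suppressMessages(library(cnvrassoc))

in_dir <- "results/cohorts"
out_dir <- "results/calls"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
thr <- qc_thresholds()

for (nm in c("discovery", "replication")) {
  cohort <- read_signal_tsv(file.path(in_dir, paste0(nm, "_signal.tsv")))
  regions <- read_bed(file.path(in_dir, paste0(nm, "_exclusions.bed")))

  calls_raw <- call_cohort(cohort)
  write_calls(calls_raw, file.path(out_dir, paste0(nm, "_raw.rawcnv")))

  qcs <- do.call(rbind, lapply(seq_len(nrow(cohort$samples)), function(j) {
    sample_qc_metrics(get_track(cohort, j), cohort$map)
  }))
  dropped <- list()
  for (cl in c("hmm", "bayes", "gaussian")) {
    q <- qcs
    tab <- table(calls_raw$sample_id[calls_raw$caller == cl])
    q$n_calls <- ifelse(is.na(tab[q$sample_id]), 0L, tab[q$sample_id])
    d <- filter_samples(q, thr, cl)$dropped
    if (nrow(d)) { d$caller <- cl; dropped[[cl]] <- d }
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(sample_id = character(), reasons = character(), caller = character())
  write.table(dropped, file.path(out_dir, paste0(nm, "_dropped_samples.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  kept <- !calls_raw$sample_id %in% dropped$sample_id
  calls <- merge_adjacent(
    exclude_regions(filter_calls(calls_raw[kept, ], thr), regions,
                    thr$exclusion_overlap_fraction),
    cohort$map
  )
  write_calls(calls, file.path(out_dir, paste0(nm, "_filtered.rawcnv")))
  message(sprintf(
    "%s: %d raw calls -> %d after QC (%d samples dropped)",
    nm, nrow(calls_raw), nrow(calls), length(unique(dropped$sample_id))
  ))
}
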
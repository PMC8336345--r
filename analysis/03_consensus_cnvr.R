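#!/usr/bin/env Rscript
# Build per-sample multi-caller consensus calls (>= 2 callers, consistent
# type, reciprocal overlap >= 0.5), pool them into innermost-boundary CNVRs,
# and apply the 1% cohort frequency floor. Writes the consensus calls and the
# CNVR catalogue per cohort.

suppressMessages(library(cnvrassoc))

out_dir <- "results/cnvr"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

for (nm in c("discovery", "replication")) {
  cohort <- read_signal_tsv(file.path("results/cohorts", paste0(nm, "_signal.tsv")))
  calls <- read_calls(file.path("results/calls", paste0(nm, "_filtered.rawcnv")))
  samples <- cohort$samples

  consensus <- do.call(rbind, lapply(
    split(calls, factor(calls$sample_id, levels = samples$sample_id)),
    consensus_calls
  ))
  write.table(consensus, file.path(out_dir, paste0(nm, "_consensus.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  n_cases <- sum(samples$phenotype == "case")
  n_controls <- sum(samples$phenotype == "control")
  cnvrs <- frequency_filter(build_cnvrs(consensus, samples),
                            n_cases, n_controls, min_freq = 0.01)
  write.table(cnvrs, file.path(out_dir, paste0(nm, "_cnvrs.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d consensus calls -> %d CNVRs at >= 1%% frequency",
                  nm, nrow(consensus), nrow(cnvrs)))
}
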
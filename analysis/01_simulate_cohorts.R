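#!/usr/bin/env Rscript
# Simulate the two synthetic case-control cohorts used throughout the
# analysis: a discovery-style cohort and a replication-style cohort, each
# over a 2000-marker single-chromosome SNP map with two implanted 50-probe
# loci — a deletion at 20% case / 2% control carrier frequency (the signal)
# and a duplication at 10% / 10% (a frequency-matched null). Writes the
# signal tracks, truth tables and exclusion regions under results/.

suppressMessages(library(cnvrassoc))

out_dir <- "results/cohorts"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

designs <- list(
  discovery = list(n_cases = 131, n_controls = 121, seed = 101L),
  replication = list(n_cases = 300, n_controls = 300, seed = 202L)
)

# one shared gene list (glist-style) for both cohorts, tiled over the
# discovery map's span — the analogue of supplying one genome build's gene
# coordinates to every cohort
shared_map <- build_snp_map(1, 2000, 3000, seed = designs$discovery$seed)
genes <- synthetic_genes(shared_map, 100, seed = 7L)
write.table(genes[, c("chr", "start", "end", "name")],
            file.path(out_dir, "genes.glist"),
            sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)

for (nm in names(designs)) {
  d <- designs[[nm]]
  map <- build_snp_map(1, 2000, 3000, seed = d$seed)
  loci <- recovery_loci(map)
  cohort <- simulate_cohort(map, loci, d$n_cases, d$n_controls,
                            sd_lrr = 0.2, baf_noise = 0.03,
                            gc_wave_amplitude = 0.02, seed = d$seed + 1L)
  write_signal_tsv(cohort, file.path(out_dir, paste0(nm, "_signal.tsv")))
  truth <- cohort$truth$loci
  truth$n_carriers <- lengths(cohort$truth$carriers)
  write.table(truth, file.path(out_dir, paste0(nm, "_truth.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  regions <- make_exclusion_bed(map, telomere_bp = 50000)
  write_bed(regions, file.path(out_dir, paste0(nm, "_exclusions.bed")))
  message(sprintf(
    "%s: %d markers, %d cases + %d controls, %d + %d implanted carriers",
    nm, nrow(map), d$n_cases, d$n_controls,
    truth$n_carriers[1], truth$n_carriers[2]
  ))
}
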
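#!/usr/bin/env Rscript
# Association stages per cohort: permutation burden test (one-sided, cases >
# controls, n = 10,000 label permutations) and per-CNVR two-tailed Fisher
# exact tests with Benjamini-Hochberg FDR over all tested CNVRs; CNVRs are
# annotated with the genes they overlap. Writes burden and association
# tables, then combines the cohorts' shared significant genes with Fisher's
# combined probability test (meta table).

suppressMessages(library(cnvrassoc))

out_dir <- "results/association"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

genes <- read_glist("results/cohorts/genes.glist")

assoc_tables <- list()
for (nm in c("discovery", "replication")) {
  cohort <- read_signal_tsv(file.path("results/cohorts", paste0(nm, "_signal.tsv")))
  consensus <- read.delim(file.path("results/cnvr", paste0(nm, "_consensus.tsv")))
  cnvrs <- read.delim(file.path("results/cnvr", paste0(nm, "_cnvrs.tsv")))
  samples <- cohort$samples

  n_cases <- sum(samples$phenotype == "case")
  n_controls <- sum(samples$phenotype == "control")

  summaries <- burden_summaries(consensus, samples, genes)
  burden <- burden_test(summaries, n_perm = 10000, seed = 11L)
  write.table(burden, file.path(out_dir, paste0(nm, "_burden.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s burden: CNV rate p = %.3g (case mean %.2f vs control %.2f)",
                  nm, burden$p_value[1], burden$case_mean[1], burden$control_mean[1]))

  assoc <- cnvr_association(carrier_table(cnvrs, n_cases, n_controls))
  assoc <- annotate_genes(assoc, genes)$intervals
  write.table(assoc, file.path(out_dir, paste0(nm, "_association.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s association: %d CNVRs, min p = %.3g, %d at FDR < 0.05",
                  nm, nrow(assoc), min(assoc$p_value),
                  sum(assoc$fdr_adjusted_p < 0.05)))
  assoc_tables[[nm]] <- assoc
}

meta <- meta_combine(assoc_tables$discovery, assoc_tables$replication)
write.table(meta, file.path(out_dir, "meta.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("meta-analysis: %d shared genes, min combined p = %.3g",
                nrow(meta), if (nrow(meta)) min(meta$combined_p) else NA))
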
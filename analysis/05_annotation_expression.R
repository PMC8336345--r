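#!/usr/bin/env Rscript
# Downstream interpretation stages on the discovery cohort's significant
# CNVRs: gene-set overrepresentation (one-sided Fisher with Bonferroni and
# fold enrichment) against synthetic term sets, the per-sample pathway
# enrichment permutation test, and expression-percentile selection of the
# associated genes in the bundled ocular-tissue expression table.

suppressMessages(library(cnvrassoc))

out_dir <- "results/annotation"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cohort <- read_signal_tsv("results/cohorts/discovery_signal.tsv")
assoc <- read.delim("results/association/discovery_association.tsv")
calls <- read_calls("results/calls/discovery_filtered.rawcnv")
genes <- read_glist("results/cohorts/genes.glist")

sig <- assoc[assoc$p_value < 0.05 & nzchar(assoc$genes), , drop = FALSE]
query <- unique(unlist(strsplit(sig$genes, ",")))
message(sprintf("%d genes in nominally significant CNVRs", length(query)))

# synthetic term sets over the same gene universe: one enriched for the
# query, the rest random
terms <- local({
  set.seed(13)
  others <- setdiff(genes$name, query)
  list(
    QUERY_NEIGHBOURHOOD = unique(c(query, sample(others, 5))),
    RANDOM_A = sample(genes$name, 20),
    RANDOM_B = sample(genes$name, 15)
  )
})
enrich <- overrepresentation_test(query, terms, genes$name)
write.table(enrich, file.path(out_dir, "overrepresentation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("top term %s: fold %.2f (%s), Bonferroni p = %.3g",
                enrich$term[1], enrich$fold_enrichment[1], enrich$direction[1],
                enrich$bonferroni_p[1]))

path_p <- cnv_enrichment_test(calls, cohort$samples, genes,
                              terms$QUERY_NEIGHBOURHOOD,
                              n_perm = 10000, seed = 17L)
message(sprintf("pathway enrichment permutation test: diff = %.3f, p = %.3g",
                path_p$observed, path_p$p_value))

# expression-percentile selection against the bundled ocular tissue table;
# the query genes are synthetic, so the table's own genes serve as the query
# to demonstrate the selection
expr <- read_expression_table(
  system.file("extdata", "otdb_plier_subset.tsv", package = "cnvrassoc")
)
sel <- expression_percentile_select(expr, expr$gene)
selections <- do.call(rbind, lapply(names(sel), function(ts) {
  data.frame(tissue = ts,
             high = paste(sel[[ts]]$high, collapse = ","),
             low = paste(sel[[ts]]$low, collapse = ","))
}))
write.table(selections, file.path(out_dir, "expression_percentiles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("expression percentile selections written (high > 90th, low < 10th)")
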
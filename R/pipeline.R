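#' Generate a synthetic gene set tiling a SNP map
#'
#' Draws gene intervals of log-normal length placed uniformly over each
#' chromosome's span, for use with the burden, annotation and enrichment
#' stages when no real gene list is supplied.
#'
#' @param map A `snp_map`.
#' @param n_genes Number of genes to draw.
#' @param mean_length_bp Median gene length in bp.
#' @param seed Integer seed.
#' @return Gene table (`name`, `chr`, `start`, `end`).
#' @export
synthetic_genes <- function(map, n_genes, mean_length_bp = 2e4, seed = 1L) {
  with_seed(seed, {
    chr_ends <- tapply(map$pos, map$chr, max)
    chrs <- sample(as.integer(names(chr_ends)), n_genes, replace = TRUE)
    len <- pmax(500, round(stats::rlnorm(n_genes, log(mean_length_bp), 0.6)))
    start <- vapply(seq_len(n_genes), function(i) {
      sample.int(max(1L, as.integer(chr_ends[[as.character(chrs[i])]] - len[i])), 1L)
    }, integer(1))
    df <- data.frame(
      name = sprintf("GENE%04d", seq_len(n_genes)),
      chr = chrs, start = start, end = start + len - 1L,
      stringsAsFactors = FALSE
    )
    df[order(df$chr, df$start), ]
  })
}

#' Run the full single-cohort CNVR analysis
#'
#' Executes the analysis stages in order: three-caller CNV calling,
#' sample-level QC (a sample failing any caller's limits is excluded from the
#' cohort), call-level QC, exclusion-region filtering, adjacent-call merging,
#' per-sample multi-caller consensus, innermost-boundary CNVR construction,
#' cohort frequency filtering, permutation burden test and per-CNVR Fisher
#' association with BH-FDR. Every stage's input/output counts are logged.
#'
#' @param cohort A `cnv_cohort`.
#' @param exclusions `GRanges` of exclusion regions (may be empty).
#' @param genes Optional gene table; enables gene annotation of CNVRs and the
#'   gene-based burden metrics.
#' @param params [caller_params()].
#' @param thresholds [qc_thresholds()].
#' @param reciprocal_overlap Consensus reciprocal-overlap fraction.
#' @param min_freq CNVR cohort frequency floor.
#' @param n_perm Burden-test permutations.
#' @param burden Set `FALSE` to skip the burden test (e.g. in replicate
#'   studies that only score association).
#' @param seed Integer seed for the permutation stages.
#' @return List: `sample_qc`, `dropped_samples`, `calls_raw`, `calls`,
#'   `consensus`, `cnvrs`, `association`, `burden`, `annotation_summary`,
#'   `n_cases`, `n_controls`, `log` (character vector of stage messages).
#' @export
run_cohort_analysis <- function(cohort, exclusions = GenomicRanges::GRanges(),
                                genes = NULL, params = caller_params(),
                                thresholds = qc_thresholds(),
                                reciprocal_overlap = 0.5, min_freq = 0.01,
                                n_perm = 10000, burden = TRUE, seed = 1L) {
  if (nrow(cohort$samples) == 0) stop_invalid("empty cohort")
  logs <- character(0)
  say <- function(...) logs <<- c(logs, sprintf(...))

  qcs <- do.call(rbind, lapply(seq_len(nrow(cohort$samples)), function(j) {
    sample_qc_metrics(get_track(cohort, j), cohort$map)
  }))
  calls_raw <- call_cohort(cohort, params)
  say("calling: %d raw calls over %d samples", nrow(calls_raw), nrow(cohort$samples))

  dropped <- list()
  for (cl in c("hmm", "bayes", "gaussian")) {
    q <- qcs
    tab <- table(calls_raw$sample_id[calls_raw$caller == cl])
    q$n_calls <- as.integer(tab[q$sample_id])
    q$n_calls[is.na(q$n_calls)] <- 0L
    res <- filter_samples(q, thresholds, cl)
    if (nrow(res$dropped)) {
      res$dropped$caller <- cl
      dropped[[cl]] <- res$dropped
    }
    say("sample QC [%s]: %d of %d samples dropped", cl, nrow(res$dropped), nrow(q))
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(sample_id = character(), reasons = character(),
               caller = character(), stringsAsFactors = FALSE)
  bad_samples <- unique(dropped$sample_id)
  samples <- cohort$samples[!cohort$samples$sample_id %in% bad_samples, , drop = FALSE]
  if (nrow(samples) == 0) stop_invalid("all samples failed QC")
  n_cases <- sum(samples$phenotype == "case")
  n_controls <- sum(samples$phenotype == "control")
  say("sample QC: %d of %d samples excluded; %d cases and %d controls remain",
      length(bad_samples), nrow(cohort$samples), n_cases, n_controls)

  calls <- calls_raw[calls_raw$sample_id %in% samples$sample_id, , drop = FALSE]
  n0 <- nrow(calls)
  calls <- filter_calls(calls, thresholds)
  say("call QC: %d -> %d calls", n0, nrow(calls))
  n0 <- nrow(calls)
  calls <- exclude_regions(calls, exclusions, thresholds$exclusion_overlap_fraction)
  say("exclusion regions: %d -> %d calls", n0, nrow(calls))
  n0 <- nrow(calls)
  calls <- merge_adjacent(calls, cohort$map)
  say("adjacent-call merging: %d -> %d calls", n0, nrow(calls))

  consensus <- do.call(rbind, lapply(
    split(calls, factor(calls$sample_id, levels = samples$sample_id)),
    consensus_calls, reciprocal_overlap = reciprocal_overlap
  ))
  rownames(consensus) <- NULL
  say("consensus (>= 2 callers): %d consensus calls", nrow(consensus))

  cnvrs <- build_cnvrs(consensus, samples)
  n0 <- nrow(cnvrs)
  cnvrs <- frequency_filter(cnvrs, n_cases, n_controls, min_freq)
  say("CNVRs: %d built, %d pass the %.0f%% cohort frequency floor",
      n0, nrow(cnvrs), 100 * min_freq)

  assoc <- cnvr_association(carrier_table(cnvrs, n_cases, n_controls))
  annotation_summary <- NULL
  if (!is.null(genes) && nrow(assoc) > 0) {
    ann <- annotate_genes(assoc, genes)
    assoc <- ann$intervals
    annotation_summary <- ann$summary
  } else if (nrow(assoc) > 0) {
    assoc$genes <- ""
  }
  say("association: %d CNVRs tested, %d with FDR < 0.05",
      nrow(assoc), sum(assoc$fdr_adjusted_p < 0.05))

  burden_res <- NULL
  if (burden) {
    summaries <- burden_summaries(consensus, samples, genes)
    burden_res <- burden_test(summaries, n_perm = n_perm, seed = seed)
    say("burden: rate metric p = %s",
        format_p(burden_res$p_value[burden_res$metric == "n_cnvs"]))
  }

  list(
    sample_qc = qcs, dropped_samples = dropped, calls_raw = calls_raw,
    calls = calls, consensus = consensus, cnvrs = cnvrs, association = assoc,
    burden = burden_res, annotation_summary = annotation_summary,
    n_cases = n_cases, n_controls = n_controls, log = logs
  )
}

config_loci <- function(sim) {
  if (length(sim$loci) == 0) return(NULL)
  do.call(rbind, lapply(sim$loci, function(l) {
    cnv_locus(l$chr, l$start, l$end, l$copy_number, l$case_freq, l$control_freq)
  }))
}

simulate_from_config <- function(sim, seed) {
  map <- build_snp_map(sim$n_chromosomes, sim$markers_per_chromosome,
                       sim$mean_spacing, seed = seed)
  simulate_cohort(map, config_loci(sim), sim$n_cases, sim$n_controls,
                  sd_lrr = sim$sd_lrr, baf_noise = sim$baf_noise,
                  gc_wave_amplitude = sim$gc_wave_amplitude, seed = seed + 1L)
}

#' Run the end-to-end pipeline from a configuration
#'
#' Simulates one cohort (or two, when the `simulation` block is a list of two
#' named cohort blocks), runs [run_cohort_analysis()] on each, combines
#' shared significant genes across two cohorts with [meta_combine()], and
#' writes the result tables (CNVR, association, burden, meta when
#' applicable) plus a stage log under the configured output directory. All
#' randomness flows from the single configured seed, so reruns are
#' byte-identical.
#'
#' @param config A [read_config()] list (or a path to a YAML file).
#' @param genes Optional gene table shared by all cohorts; when omitted a
#'   synthetic gene tiling is generated from the first cohort's map.
#' @return List with one entry per cohort plus `meta` (or `NULL`) and
#'   `out_dir`; result tables are written as TSV.
#' @export
run_pipeline <- function(config, genes = NULL) {
  if (is.character(config)) config <- read_config(config)
  sim <- config$simulation
  blocks <- if (!is.null(sim$n_cases)) list(cohort = sim) else sim
  seed <- as.integer(config$seed)
  out_dir <- config$paths$out_dir
  results <- list()
  for (i in seq_along(blocks)) {
    nm <- names(blocks)[i] %||% paste0("cohort", i)
    cohort <- simulate_from_config(blocks[[i]], seed + 1000L * i)
    if (is.null(genes)) {
      genes <- synthetic_genes(cohort$map, max(50L, nrow(cohort$map) %/% 20L),
                               seed = seed)
    }
    results[[nm]] <- run_cohort_analysis(
      cohort, genes = genes,
      params = do.call(caller_params, config$caller[names(config$caller) %in%
        names(formals(caller_params))]),
      reciprocal_overlap = config$consensus$reciprocal_overlap,
      min_freq = config$consensus$min_freq,
      n_perm = config$association$n_perm, seed = seed + i
    )
  }
  meta <- NULL
  if (length(results) == 2) {
    meta <- meta_combine(results[[1]]$association, results[[2]]$association,
                         alpha = config$association$alpha)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(results)) {
    res <- results[[nm]]
    write_result_tsv(res$cnvrs, file.path(out_dir, paste0(nm, "_cnvrs.tsv")))
    write_result_tsv(res$association, file.path(out_dir, paste0(nm, "_association.tsv")))
    write_result_tsv(res$burden, file.path(out_dir, paste0(nm, "_burden.tsv")))
  }
  if (!is.null(meta)) write_result_tsv(meta, file.path(out_dir, "meta.tsv"))
  writeLines(unlist(lapply(names(results), function(nm) {
    paste0("[", nm, "] ", results[[nm]]$log)
  })), file.path(out_dir, "pipeline.log"))
  c(results, list(meta = meta, out_dir = out_dir))
}
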
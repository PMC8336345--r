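#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Direct evaluation of the two-tailed rule: with margins fixed, the p-value
#' is the sum of hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table (with a
#' `1 + 1e-7` relative slack against floating-point ties, the dominant
#' software convention).
#'
#' @param a,b,c,d Non-negative cell counts, laid out as
#'   (case carrier, case non-carrier, control carrier, control non-carrier).
#' @return The two-tailed p-value.
#' @export
fisher_exact_two_tailed <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop_invalid("at least one margin must be positive")
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Per-CNVR case-control association with FDR control
#'
#' Runs the two-tailed Fisher exact test on every CNVR's carrier 2x2 table
#' and adjusts over ALL tested CNVRs with the Benjamini-Hochberg step-up
#' procedure; records are returned sorted by raw p-value.
#'
#' @param carriers Output of [carrier_table()] (columns `a`, `b`, `c`, `d`).
#' @return The input with `p_value` and `fdr_adjusted_p` columns, sorted by
#'   `p_value`.
#' @export
cnvr_association <- function(carriers) {
  if (nrow(carriers) == 0) {
    carriers$p_value <- numeric(0)
    carriers$fdr_adjusted_p <- numeric(0)
    return(carriers)
  }
  carriers$p_value <- vapply(seq_len(nrow(carriers)), function(i) {
    fisher_exact_two_tailed(carriers$a[i], carriers$b[i], carriers$c[i], carriers$d[i])
  }, numeric(1))
  carriers$fdr_adjusted_p <- stats::p.adjust(carriers$p_value, method = "BH")
  out <- carriers[order(carriers$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values via `X = -2 * sum(log(p))`, which is
#' chi-squared with `2k` degrees of freedom under the global null; the
#' combined p-value is the upper tail at X. With a single p-value the
#' combination is the identity.
#'
#' @param p Vector of p-values in (0, 1].
#' @return The combined p-value.
#' @export
fisher_combine <- function(p) {
  if (length(p) == 0) stop_invalid("no p-values to combine")
  if (any(p <= 0) || any(p > 1)) stop_invalid("p-values must lie in (0, 1]")
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Per-sample CNV load summaries for the burden test
#'
#' @param calls Post-QC calls or consensus calls of a cohort (needs
#'   `sample_id`, `chr`, `start`, `end`).
#' @param samples Cohort sample table (all samples, including zero-call ones).
#' @param genes Optional gene table (`name`, `chr`, `start`, `end`); enables
#'   the gene-based metrics.
#' @return `data.frame` with one row per sample: `n_cnvs`, `any_cnv`,
#'   `total_kb`, and with genes `n_genes`, `any_gene`, `genes_per_kb`.
#' @export
burden_summaries <- function(calls, samples, genes = NULL) {
  out <- data.frame(sample_id = samples$sample_id,
                    phenotype = samples$phenotype, stringsAsFactors = FALSE)
  idx <- split(seq_len(nrow(calls)), factor(calls$sample_id, levels = samples$sample_id))
  out$n_cnvs <- vapply(idx, length, integer(1))
  out$any_cnv <- as.numeric(out$n_cnvs > 0)
  out$total_kb <- vapply(idx, function(i) {
    if (length(i) == 0) 0 else sum(calls$end[i] - calls$start[i] + 1) / 1000
  }, numeric(1))
  if (!is.null(genes)) {
    gene_gr <- GenomicRanges::GRanges(
      seqnames = paste0("chr", genes$chr),
      ranges = IRanges::IRanges(genes$start, genes$end), name = genes$name
    )
    out$n_genes <- vapply(idx, function(i) {
      if (length(i) == 0) return(0L)
      hits <- GenomicRanges::findOverlaps(calls_to_granges(calls[i, , drop = FALSE]),
                                          gene_gr)
      length(unique(genes$name[S4Vectors::subjectHits(hits)]))
    }, integer(1))
    out$any_gene <- as.numeric(out$n_genes > 0)
    out$genes_per_kb <- ifelse(out$total_kb > 0, out$n_genes / out$total_kb, 0)
  }
  rownames(out) <- NULL
  out
}

#' Permutation burden test (one-sided, cases > controls)
#'
#' For each per-sample load metric, the observed statistic is the case mean
#' minus the control mean; its one-sided empirical p-value is
#' `(1 + #\{permuted >= observed\}) / (1 + n_perm)` under phenotype-label
#' permutation (so p never reaches 0).
#'
#' @param summaries Output of [burden_summaries()].
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return `data.frame` with one row per metric: `case_mean`, `control_mean`,
#'   `observed` (difference) and `p_value`.
#' @export
burden_test <- function(summaries, n_perm = 10000, seed = 1L) {
  pheno <- summaries$phenotype
  if (length(unique(pheno)) < 2) stop_invalid("both phenotypes must be present")
  metrics <- setdiff(names(summaries), c("sample_id", "phenotype"))
  x <- as.matrix(summaries[, metrics, drop = FALSE])
  is_case <- pheno == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case); n <- length(pheno)
  diff_stat <- function(case_idx) {
    colSums(x[case_idx, , drop = FALSE]) / n1 -
      (colSums(x) - colSums(x[case_idx, , drop = FALSE])) / n0
  }
  obs <- diff_stat(which(is_case))
  with_seed(seed, {
    exceed <- numeric(length(metrics))
    for (b in seq_len(n_perm)) {
      perm <- diff_stat(sample.int(n, n1))
      exceed <- exceed + (perm >= obs - 1e-12)
    }
    data.frame(
      metric = metrics,
      case_mean = colMeans(x[is_case, , drop = FALSE]),
      control_mean = colMeans(x[!is_case, , drop = FALSE]),
      observed = obs,
      p_value = (1 + exceed) / (1 + n_perm),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
}

#' Pathway enrichment permutation test over CNV-overlapped genes
#'
#' Per sample, the statistic is the number of pathway genes its CNVs overlap
#' divided by the total number of genes they overlap (0 for samples whose
#' CNVs hit no gene); the test statistic is the case mean minus the control
#' mean of that ratio, and significance comes from two-sided phenotype-label
#' permutation. The per-sample normalisation is what absorbs differences in
#' the size and rate distribution of genes and CNVs between the groups.
#'
#' @param calls Post-QC calls of a cohort.
#' @param samples Cohort sample table.
#' @param genes Gene table (`name`, `chr`, `start`, `end`).
#' @param pathway_genes Character vector of pathway gene names.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return List with `observed` (mean ratio difference) and `p_value`.
#' @export
cnv_enrichment_test <- function(calls, samples, genes, pathway_genes,
                                n_perm = 10000, seed = 1L) {
  if (length(pathway_genes) == 0) stop_invalid("empty pathway")
  if (length(unique(samples$phenotype)) < 2) stop_invalid("both phenotypes must be present")
  gene_gr <- GenomicRanges::GRanges(
    seqnames = paste0("chr", genes$chr),
    ranges = IRanges::IRanges(genes$start, genes$end)
  )
  ratio <- vapply(seq_len(nrow(samples)), function(j) {
    i <- which(calls$sample_id == samples$sample_id[j])
    if (length(i) == 0) return(0)
    hits <- GenomicRanges::findOverlaps(calls_to_granges(calls[i, , drop = FALSE]),
                                        gene_gr)
    hit_genes <- unique(genes$name[S4Vectors::subjectHits(hits)])
    if (length(hit_genes) == 0) return(0)
    sum(hit_genes %in% pathway_genes) / length(hit_genes)
  }, numeric(1))
  is_case <- samples$phenotype == "case"
  n1 <- sum(is_case); n <- length(ratio)
  stat <- function(idx) mean(ratio[idx]) - mean(ratio[-idx])
  obs <- stat(which(is_case))
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      if (abs(stat(sample.int(n, n1))) >= abs(obs) - 1e-12) exceed <- exceed + 1L
    }
    list(observed = obs, p_value = (1 + exceed) / (1 + n_perm))
  })
}

#' Power of the chi-squared goodness-of-fit test
#'
#' Power at effect size w (Cohen's w) and sample size n: the upper tail of
#' the noncentral chi-squared distribution with `df` degrees of freedom and
#' noncentrality `n * w^2`, evaluated at the central `1 - alpha` critical
#' value.
#'
#' @param w Cohen's w effect size (>= 0).
#' @param n Sample size.
#' @param df Degrees of freedom.
#' @param alpha Significance level in (0, 1).
#' @return The power, in [0, 1].
#' @export
power_chi2_gof <- function(w, n, df = 1, alpha = 0.05) {
  if (w < 0 || n < 1 || df < 1) stop_invalid("w, n and df must be valid")
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must lie in (0, 1)")
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = n * w^2, lower.tail = FALSE)
}

#' Fisher's-method meta-analysis over genes shared between two cohorts
#'
#' For every gene annotated to a significant CNVR in both cohorts, combines
#' the per-cohort CNVR p-values with [fisher_combine()] (degrees of freedom
#' `2 x` the number of p-values combined) and BH-adjusts the combined values
#' over the shared genes.
#'
#' @param assoc_a,assoc_b Association tables ([cnvr_association()]) carrying
#'   a `genes` column of comma-joined gene names.
#' @param alpha Per-cohort significance level a CNVR must reach to enter.
#' @return `data.frame`: `gene`, `p_values` (comma-joined inputs),
#'   `combined_p`, `combined_adjusted_p`.
#' @export
meta_combine <- function(assoc_a, assoc_b, alpha = 0.05) {
  gene_map <- function(assoc) {
    sig <- assoc[assoc$p_value < alpha & nzchar(assoc$genes %||% ""), , drop = FALSE]
    if (nrow(sig) == 0) return(list())
    m <- list()
    for (i in seq_len(nrow(sig))) {
      for (gn in strsplit(sig$genes[i], ",")[[1]]) {
        m[[gn]] <- c(m[[gn]], sig$p_value[i])
      }
    }
    m
  }
  ma <- gene_map(assoc_a); mb <- gene_map(assoc_b)
  shared <- sort(intersect(names(ma), names(mb)))
  if (length(shared) == 0) {
    return(data.frame(gene = character(), p_values = character(),
                      combined_p = numeric(), combined_adjusted_p = numeric(),
                      stringsAsFactors = FALSE))
  }
  combined <- vapply(shared, function(gn) fisher_combine(c(ma[[gn]], mb[[gn]])),
                     numeric(1))
  data.frame(
    gene = shared,
    p_values = vapply(shared, function(gn) {
      paste(signif(c(ma[[gn]], mb[[gn]]), 3), collapse = ",")
    }, character(1)),
    combined_p = combined,
    combined_adjusted_p = stats::p.adjust(combined, method = "BH"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
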
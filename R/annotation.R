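#' Read a gene list (glist-style: `chrom start end name`)
#'
#' @param path Whitespace-delimited file with columns chromosome, start, end,
#'   gene name (no header), 1-based inclusive coordinates.
#' @return `data.frame` with `name`, `chr`, `start`, `end`.
#' @export
read_glist <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chr", "start", "end", "name"))
  df$chr <- as.integer(sub("^chr", "", df$chr))
  if (anyDuplicated(df$name)) stop_invalid("duplicate gene names in ", path)
  if (any(df$start > df$end)) stop_invalid("inverted gene interval in ", path)
  df[, c("name", "chr", "start", "end")]
}

#' Read a GMT file of term-to-gene annotation sets
#'
#' @param path Tab-delimited GMT: term, description, gene names.
#' @return Named list of character vectors (term -> genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    if (length(f) < 3) stop_invalid("malformed GMT line: ", l)
    stats::setNames(list(unique(f[-(1:2)])), f[1])
  })
  out <- unlist(sets, recursive = FALSE)
  if (anyDuplicated(names(out))) stop_invalid("duplicate terms in ", path)
  out
}

#' Annotate intervals with overlapping genes
#'
#' A gene is assigned to an interval iff they overlap by at least one base
#' pair. When the interval table carries a `phenotype` column (e.g. per-call
#' annotation of a cohort), the summary reports the fraction of intervals
#' with at least one gene per phenotype.
#'
#' @param intervals `data.frame` with `chr`, `start`, `end` (1-based
#'   inclusive), optionally `phenotype`.
#' @param genes Gene table from [read_glist()] (or with the same columns).
#' @return List with `genes` (character vector per interval, comma-joined in
#'   the `genes` column added to `intervals`) and `summary` (`data.frame` of
#'   per-phenotype fraction of intervals overlapping >= 1 gene).
#' @export
annotate_genes <- function(intervals, genes) {
  gene_names <- vector("list", nrow(intervals))
  if (nrow(intervals) > 0 && nrow(genes) > 0) {
    gr <- calls_to_granges(intervals)
    gene_gr <- GenomicRanges::GRanges(
      seqnames = paste0("chr", genes$chr),
      ranges = IRanges::IRanges(genes$start, genes$end)
    )
    hits <- GenomicRanges::findOverlaps(gr, gene_gr)
    for (q in unique(S4Vectors::queryHits(hits))) {
      gene_names[[q]] <-
        sort(unique(genes$name[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == q]]))
    }
  }
  intervals$genes <- vapply(gene_names, function(g) paste(g %||% character(0), collapse = ","),
                            character(1))
  has_gene <- nzchar(intervals$genes)
  summary <- if ("phenotype" %in% names(intervals) && nrow(intervals) > 0) {
    agg <- tapply(has_gene, intervals$phenotype, mean)
    data.frame(phenotype = names(agg), fraction_with_gene = as.numeric(agg),
               stringsAsFactors = FALSE)
  } else {
    data.frame(phenotype = "all",
               fraction_with_gene = if (nrow(intervals)) mean(has_gene) else 0,
               stringsAsFactors = FALSE)
  }
  list(intervals = intervals, genes = gene_names, summary = summary)
}

#' Gene-set overrepresentation test with fold enrichment
#'
#' For each term: with `q` query genes in the term, `Q` query genes, `m`
#' reference genes in the term and `N` reference genes, the fold enrichment
#' is `(q/Q) / (m/N)`; the direction is `+` if fold > 1 and `-` otherwise;
#' the p-value is the one-sided Fisher exact (hypergeometric) tail in the
#' direction of the deviation, Bonferroni-corrected over the tested terms.
#'
#' @param query Character vector of query gene names (must be contained in
#'   `reference`).
#' @param terms Named list of term -> gene-name vectors (e.g. [read_gmt()]).
#' @param reference Character vector of reference (universe) gene names.
#' @return `data.frame` with one row per term: `term`, `n_query_in_term`,
#'   `n_query`, `n_term_in_reference`, `n_reference`, `fold_enrichment`,
#'   `direction`, `p_value`, `bonferroni_p`.
#' @export
overrepresentation_test <- function(query, terms, reference) {
  reference <- unique(reference)
  if (length(reference) == 0) stop_invalid("empty reference gene list")
  query <- unique(query)
  if (!all(query %in% reference)) stop_invalid("query genes must be a subset of the reference")
  N <- length(reference); Q <- length(query)
  rows <- lapply(names(terms), function(tm) {
    term_genes <- intersect(terms[[tm]], reference)
    m <- length(term_genes)
    q <- length(intersect(query, term_genes))
    fold <- if (m == 0 || Q == 0) 0 else (q / Q) / (m / N)
    over <- fold > 1
    p <- if (m == 0) {
      1
    } else if (over) {
      stats::phyper(q - 1, m, N - m, Q, lower.tail = FALSE)
    } else {
      stats::phyper(q, m, N - m, Q, lower.tail = TRUE)
    }
    data.frame(
      term = tm, n_query_in_term = q, n_query = Q, n_term_in_reference = m,
      n_reference = N, fold_enrichment = fold,
      direction = if (over) "+" else "-", p_value = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$bonferroni_p <- pmin(1, out$p_value * nrow(out))
  out[order(out$p_value), , drop = FALSE]
}

#' Read a per-gene, per-tissue expression table
#'
#' @param path TSV with header `gene<TAB>tissue1<TAB>tissue2...`; missing
#'   values as `NA` or `-`.
#' @return `data.frame` with `gene` plus one numeric column per tissue.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", "-", ""))
  names(df)[1] <- "gene"
  if (anyDuplicated(df$gene)) stop_invalid("duplicate genes in ", path)
  for (cl in names(df)[-1]) {
    df[[cl]] <- as.numeric(df[[cl]])
    if (any(df[[cl]] < 0, na.rm = TRUE)) stop_invalid("negative expression value in ", cl)
  }
  df
}

#' Select query genes at extreme expression percentiles
#'
#' Within each tissue a query gene enters the high list iff more than `hi`
#' percent of the column's genes lie strictly below its value, and the low
#' list iff fewer than `lo` percent lie at or below it (missing values are
#' excluded from the column). Ties therefore select nothing in either
#' direction — a column of identical values yields empty lists — and the two
#' lists are disjoint.
#'
#' @param table Expression table from [read_expression_table()].
#' @param query Character vector of gene names to rank.
#' @param tissues Tissue column names to use (default: all).
#' @param hi,lo Percentile cut-offs, `0 < lo < hi < 100`.
#' @return Named list per tissue, each with `high` and `low` character
#'   vectors of selected query genes.
#' @export
expression_percentile_select <- function(table, query, tissues = NULL,
                                         hi = 90, lo = 10) {
  if (!(lo > 0 && hi < 100 && lo < hi)) stop_invalid("need 0 < lo < hi < 100")
  tissues <- tissues %||% setdiff(names(table), "gene")
  missing <- setdiff(tissues, names(table))
  if (length(missing)) stop_invalid("tissue absent from table: ", paste(missing, collapse = ", "))
  out <- lapply(tissues, function(ts) {
    vals <- table[[ts]]
    ok <- !is.na(vals)
    rank_lo <- rank_hi <- rep(NA_real_, nrow(table))
    rank_lo[ok] <- 100 * vapply(vals[ok], function(v) mean(vals[ok] < v), numeric(1))
    rank_hi[ok] <- 100 * vapply(vals[ok], function(v) mean(vals[ok] <= v), numeric(1))
    names(rank_lo) <- names(rank_hi) <- table$gene
    q <- intersect(query, table$gene)
    q <- q[!is.na(rank_lo[q])]
    list(high = sort(q[rank_lo[q] > hi]), low = sort(q[rank_hi[q] < lo]))
  })
  stats::setNames(out, tissues)
}
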
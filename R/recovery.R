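# Synthetic recovery study: the package's standing experiment for checking
# that implanted case-control CNV contrasts survive the whole pipeline
# (calling -> QC -> consensus -> CNVR -> Fisher/FDR) at realistic signal
# levels, and that frequency-matched null loci do not.

#' Study loci for the recovery experiment
#'
#' Two 50-probe loci on a 2000-marker map: a deletion implanted at 20% case /
#' 2% control carrier frequency (the association signal to recover) and a
#' duplication at 10% / 10% (a frequency-matched null that measures the
#' false-positive rate of the association stage). Both spans are ~2.5% of the
#' map so whole-track QC metrics stay representative of the diploid
#' background, as on a genome-wide array.
#'
#' @param map A `snp_map` with at least 1249 markers on chromosome 1.
#' @return A two-row locus table ([cnv_locus()] rows); the first row is the
#'   true association, the second the null locus.
#' @export
recovery_loci <- function(map) {
  if (nrow(map) < 1249) stop_invalid("the recovery map needs >= 1249 markers")
  rbind(
    cnv_locus(1, map$pos[500], map$pos[549], 1L, 0.20, 0.02),
    cnv_locus(1, map$pos[1200], map$pos[1249], 3L, 0.10, 0.10)
  )
}

#' One replicate of the synthetic recovery study
#'
#' Simulates a 300 + 300 case-control cohort at LRR noise SD 0.2 with the
#' [recovery_loci()] implants, runs the full association pipeline and scores
#' the outcome.
#'
#' @param seed Integer seed for this replicate.
#' @param n_cases,n_controls Cohort sizes.
#' @param markers Markers on the (single-chromosome) map.
#' @param sd_lrr LRR noise SD.
#' @return A one-row `data.frame`: `recovered_true` / `recovered_null`
#'   (a CNVR of the implanted type overlaps the locus by >= 1 bp),
#'   `fdr_significant` (the true locus reaches BH-FDR < 0.05),
#'   `null_nominal` (the null locus reaches nominal p < 0.05) and
#'   `n_cnvrs` tested.
#' @export
recovery_replicate <- function(seed, n_cases = 300, n_controls = 300,
                               markers = 2000, sd_lrr = 0.2) {
  map <- build_snp_map(1, markers, 3000, seed = seed)
  loci <- recovery_loci(map)
  cohort <- simulate_cohort(map, loci, n_cases, n_controls, sd_lrr = sd_lrr,
                            seed = seed + 1L)
  res <- run_cohort_analysis(cohort, burden = FALSE, seed = seed)
  assoc <- res$association
  hit <- function(i, type) {
    assoc$copy_type == type & assoc$start <= loci$end[i] & assoc$end >= loci$start[i]
  }
  true_hits <- hit(1, "loss")
  null_hits <- hit(2, "gain")
  data.frame(
    seed = seed,
    recovered_true = any(true_hits),
    recovered_null = any(null_hits),
    fdr_significant = any(assoc$fdr_adjusted_p[true_hits] < 0.05),
    null_nominal = any(assoc$p_value[null_hits] < 0.05),
    n_cnvrs = nrow(assoc)
  )
}

#' Run the multi-seed recovery study
#'
#' @param n_seeds Number of independent replicates.
#' @param seed Master seed; per-replicate seeds are drawn from it.
#' @param ... Passed to [recovery_replicate()].
#' @return `data.frame` with one row per replicate (see
#'   [recovery_replicate()]).
#' @export
recovery_study <- function(n_seeds = 50, seed = 1L, ...) {
  rep_seeds <- with_seed(seed, sample.int(1e6, n_seeds))
  do.call(rbind, lapply(rep_seeds, recovery_replicate, ...))
}

#' Null calibration of the permutation burden test
#'
#' Draws `n_rep` exchangeable cohorts (per-sample CNV loads simulated
#' identically for cases and controls), computes the one-sided burden
#' p-value of the CNV-rate metric in each, and returns the p-values together
#' with a Kolmogorov-Smirnov comparison against the uniform distribution.
#'
#' @param n_rep Number of null replicates.
#' @param n_per_group Samples per phenotype group in each replicate.
#' @param n_perm Permutations per burden test.
#' @param seed Master seed.
#' @return List with `p_values` (length `n_rep`) and `ks_p`.
#' @export
burden_null_calibration <- function(n_rep = 500, n_per_group = 30,
                                    n_perm = 199, seed = 1L) {
  rep_seeds <- with_seed(seed, sample.int(1e6, n_rep))
  p <- vapply(rep_seeds, function(s) {
    sm <- with_seed(s, {
      n <- 2 * n_per_group
      data.frame(
        sample_id = sprintf("s%04d", seq_len(n)),
        phenotype = rep(c("case", "control"), each = n_per_group),
        n_cnvs = stats::rpois(n, 3) + stats::rnorm(n, 0, 1e-9),
        stringsAsFactors = FALSE
      )
    })
    burden_test(sm, n_perm = n_perm, seed = s + 1L)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  list(p_values = p, ks_p = ks$p.value)
}
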
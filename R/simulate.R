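# Copy-state LRR means shared between the simulator and all three callers.
# LRR is ~0 for the diploid state, negative under deletion and positive under
# duplication; the per-state values follow the common SNP-array convention
# (homozygous deletion is far below the single-copy band because the log of a
# near-zero intensity diverges).
STATE_CN <- c(0L, 1L, 2L, 3L, 4L)
STATE_LRR_MEAN <- c(-3.5, -0.66, 0, 0.40, 0.68)

#' Describe an implanted CNV locus
#'
#' @param chr Chromosome (integer).
#' @param start,end 1-based inclusive bounds in bp.
#' @param copy_number Integer copy number in {0, 1, 3, 4}.
#' @param case_freq,control_freq Carrier frequencies per phenotype, in [0, 1].
#' @return One-row `data.frame` suitable for `rbind`-ing into a locus table.
#' @export
cnv_locus <- function(chr, start, end, copy_number, case_freq, control_freq) {
  if (start > end) stop_invalid("locus start > end")
  if (!copy_number %in% c(0L, 1L, 3L, 4L)) {
    stop_invalid("copy_number must be one of 0, 1, 3, 4")
  }
  if (any(c(case_freq, control_freq) < 0) || any(c(case_freq, control_freq) > 1)) {
    stop_invalid("carrier frequencies must lie in [0, 1]")
  }
  data.frame(
    chr = as.integer(chr), start = as.integer(start), end = as.integer(end),
    copy_number = as.integer(copy_number),
    copy_type = copy_type_of(copy_number),
    case_freq = case_freq, control_freq = control_freq,
    stringsAsFactors = FALSE
  )
}

#' Simulate a case-control cohort of LRR/BAF signal tracks
#'
#' Emits, for every sample, a per-marker LogR-ratio (LRR) and B-allele
#' frequency (BAF) track over the supplied SNP map. The diploid baseline has
#' LRR mean 0; markers inside a carried CNV locus take the copy-state LRR
#' mean (CN0 -3.5, CN1 -0.66, CN3 +0.40, CN4 +0.68). Genotypes are drawn per
#' marker as Binomial(copy number, population B-allele frequency); BAF is the
#' implied allelic ratio (e.g. CN1 gives {0, 1}, CN3 gives {0, 1/3, 2/3, 1})
#' plus truncated-normal noise on [0, 1], with homozygous bands getting one
#' quarter of the heterozygous-band noise. CN0 BAF is uniform (no allelic
#' signal). A GC wave of the requested amplitude times the standardized local
#' GC is added to every LRR track. Carriers of each locus are drawn
#' independently per sample at the phenotype-specific design frequency.
#'
#' @param map A `snp_map` from [build_snp_map()].
#' @param loci A locus table from [cnv_locus()] (zero rows allowed).
#' @param n_cases,n_controls Cohort sizes.
#' @param sd_lrr Gaussian noise SD added to LRR (>= 0).
#' @param baf_noise Heterozygous-band BAF noise SD.
#' @param gc_wave_amplitude GC-wave amplitude (LRR units per SD of local GC).
#' @param seed Integer seed; cohorts are bit-identical for identical inputs.
#' @return A list of class `cnv_cohort`: `map`, `samples` (data.frame with
#'   `sample_id`, `phenotype`), `lrr` and `baf` (marker x sample matrices) and
#'   `truth` (class `cohort_truth`: `loci`, `carriers` — one character vector
#'   of sample ids per locus — and `seed`).
#' @export
simulate_cohort <- function(map, loci, n_cases, n_controls, sd_lrr = 0.2,
                            baf_noise = 0.03, gc_wave_amplitude = 0,
                            seed = 1L) {
  validate_snp_map(map)
  if (n_cases < 0 || n_controls < 0 || n_cases + n_controls < 1) {
    stop_invalid("cohort must contain at least one sample")
  }
  if (sd_lrr < 0 || baf_noise < 0) stop_invalid("noise SDs must be >= 0")
  loci <- if (is.null(loci) || nrow(loci) == 0) cnv_locus(1, 1, 1, 1, 0, 0)[0, ] else loci
  chr_max <- tapply(map$pos, map$chr, max)
  for (i in seq_len(nrow(loci))) {
    lc <- as.character(loci$chr[i])
    if (!lc %in% names(chr_max) || loci$start[i] < 1 || loci$end[i] > chr_max[[lc]]) {
      stop_invalid("locus ", i, " lies outside the map bounds")
    }
  }

  n <- n_cases + n_controls
  samples <- data.frame(
    sample_id = c(sprintf("case_%04d", seq_len(n_cases)),
                  sprintf("ctrl_%04d", seq_len(n_controls))),
    phenotype = rep(c("case", "control"), c(n_cases, n_controls)),
    stringsAsFactors = FALSE
  )
  n_mark <- nrow(map)
  gcz <- standardized_gc(map)
  locus_idx <- lapply(seq_len(nrow(loci)), function(i) {
    which(map$chr == loci$chr[i] & map$pos >= loci$start[i] & map$pos <= loci$end[i])
  })

  with_seed(seed, {
    carrier_mat <- matrix(FALSE, nrow = nrow(loci), ncol = n)
    for (i in seq_len(nrow(loci))) {
      freq <- ifelse(samples$phenotype == "case", loci$case_freq[i], loci$control_freq[i])
      carrier_mat[i, ] <- runif(n) < freq
    }
    lrr <- matrix(0, n_mark, n, dimnames = list(map$marker, samples$sample_id))
    baf <- matrix(0, n_mark, n, dimnames = list(map$marker, samples$sample_id))
    for (j in seq_len(n)) {
      cn <- rep(2L, n_mark)
      for (i in seq_len(nrow(loci))) {
        if (carrier_mat[i, j]) cn[locus_idx[[i]]] <- loci$copy_number[i]
      }
      b <- integer(n_mark)
      pos_cn <- cn > 0L
      b[pos_cn] <- rbinom(sum(pos_cn), cn[pos_cn], map$pbaf[pos_cn])
      ratio <- ifelse(pos_cn, b / pmax(cn, 1L), 0.5)
      het <- ratio > 0 & ratio < 1
      sd_b <- ifelse(het, baf_noise, baf_noise / 4)
      bafj <- rtruncnorm01(n_mark, ratio, sd_b)
      if (any(!pos_cn)) bafj[!pos_cn] <- runif(sum(!pos_cn))
      mu <- STATE_LRR_MEAN[match(cn, STATE_CN)] + gc_wave_amplitude * gcz
      lrrj <- if (sd_lrr > 0) rnorm(n_mark, mu, sd_lrr) else mu
      lrr[, j] <- lrrj
      baf[, j] <- bafj
    }
    carriers <- lapply(seq_len(nrow(loci)), function(i) samples$sample_id[carrier_mat[i, ]])
    truth <- structure(
      list(loci = loci, carriers = carriers, seed = as.integer(seed)),
      class = "cohort_truth"
    )
    structure(
      list(map = map, samples = samples, lrr = lrr, baf = baf, truth = truth),
      class = "cnv_cohort"
    )
  })
}

#' Extract one sample's signal track from a cohort
#'
#' @param cohort A `cnv_cohort`.
#' @param sample Sample id or column index.
#' @return A list of class `signal_track`: `sample_id`, `phenotype`, `lrr`,
#'   `baf` (vectors aligned to `cohort$map`).
#' @export
get_track <- function(cohort, sample) {
  j <- if (is.character(sample)) match(sample, cohort$samples$sample_id) else sample
  if (is.na(j) || j < 1 || j > nrow(cohort$samples)) stop_invalid("unknown sample: ", sample)
  structure(
    list(
      sample_id = cohort$samples$sample_id[j],
      phenotype = cohort$samples$phenotype[j],
      lrr = cohort$lrr[, j], baf = cohort$baf[, j]
    ),
    class = "signal_track"
  )
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat(sprintf(
    "cnv_cohort: %d markers x %d samples (%d cases, %d controls), %d implanted loci\n",
    nrow(x$map), nrow(x$samples), sum(x$samples$phenotype == "case"),
    sum(x$samples$phenotype == "control"), nrow(x$truth$loci)
  ))
  invisible(x)
}
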
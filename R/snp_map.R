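#' Build a synthetic ordered SNP map
#'
#' Generates an ordered autosomal marker map of the kind a genotyping array
#' export provides: marker identifiers, chromosome, physical position, the
#' population frequency of the B allele, and local GC content. Inter-marker
#' gaps are exponential with the given mean (an idealisation of real array
#' spacing), GC content follows a smooth sinusoid plus noise so that GC-wave
#' artifacts can be injected and corrected, and population B-allele
#' frequencies are uniform on (0.05, 0.95).
#'
#' @param n_chromosomes Number of autosomes to generate (1..22).
#' @param markers_per_chromosome Markers per chromosome (>= 10).
#' @param mean_spacing Mean inter-marker gap in base pairs.
#' @param gc_wavelength Wavelength (bp) of the sinusoidal GC profile.
#' @param seed Integer seed; identical arguments give identical maps.
#' @return A `data.frame` of class `snp_map` with columns `marker`, `chr`,
#'   `pos`, `pbaf` (population B-allele frequency) and `gc` (local GC
#'   fraction), ordered by chromosome then position (strictly increasing
#'   within a chromosome).
#' @export
build_snp_map <- function(n_chromosomes, markers_per_chromosome, mean_spacing,
                          gc_wavelength = 1e6, seed = 1L) {
  if (n_chromosomes < 1 || n_chromosomes > 22) {
    stop_invalid("n_chromosomes must be in 1..22, got ", n_chromosomes)
  }
  if (markers_per_chromosome < 10) {
    stop_invalid("markers_per_chromosome must be >= 10, got ", markers_per_chromosome)
  }
  if (mean_spacing <= 0 || gc_wavelength <= 0) {
    stop_invalid("mean_spacing and gc_wavelength must be positive")
  }
  with_seed(seed, {
    per_chr <- lapply(seq_len(n_chromosomes), function(chr) {
      gaps <- pmax(1, round(rexp(markers_per_chromosome, rate = 1 / mean_spacing)))
      pos <- cumsum(gaps)
      phase <- runif(1, 0, 2 * pi)
      gc <- 0.45 + 0.08 * sin(2 * pi * pos / gc_wavelength + phase) +
        rnorm(markers_per_chromosome, 0, 0.01)
      data.frame(
        marker = sprintf("rs%d_%06d", chr, seq_len(markers_per_chromosome)),
        chr = as.integer(chr),
        pos = as.integer(pos),
        pbaf = runif(markers_per_chromosome, 0.05, 0.95),
        gc = pmin(1, pmax(0, gc)),
        stringsAsFactors = FALSE
      )
    })
    map <- do.call(rbind, per_chr)
    rownames(map) <- NULL
    class(map) <- c("snp_map", "data.frame")
    map
  })
}

validate_snp_map <- function(map) {
  stopifnot(all(c("marker", "chr", "pos", "pbaf", "gc") %in% names(map)))
  ok <- tapply(map$pos, map$chr, function(p) all(diff(p) > 0))
  if (!all(unlist(ok))) stop_invalid("positions must be strictly increasing within a chromosome")
  if (any(map$chr < 1 | map$chr > 22)) stop_invalid("map must be autosomal (chr 1..22)")
  if (any(map$pbaf < 0 | map$pbaf > 1) || any(map$gc < 0 | map$gc > 1)) {
    stop_invalid("pbaf and gc must lie in [0, 1]")
  }
  invisible(map)
}

# Local GC standardized over the whole map; the shared covariate for GC-wave
# injection (simulation), estimation (QC) and removal (correction).
standardized_gc <- function(map) {
  s <- sd(map$gc)
  if (s == 0) return(rep(0, nrow(map)))
  (map$gc - mean(map$gc)) / s
}

#' Build an exclusion-region set (telomeres, centromeres, extra intervals)
#'
#' Calls overlapping telomeric, centromeric, immunoglobulin or
#' segmental-duplication regions are spurious-call hotspots and are removed
#' when at least half the call overlaps such a region. This helper assembles
#' the region set for a synthetic map: a fixed-width band at both ends of each
#' chromosome, per-chromosome centromere intervals, and arbitrary extra
#' intervals. Regions are returned as a `GRanges` (1-based, as GenomicRanges
#' stores them); [write_bed()]/[read_bed()] convert to and from the 0-based
#' half-open BED convention.
#'
#' @param map A `snp_map`; chromosome extents are taken from its positions.
#' @param telomere_bp Width of the telomeric band at each chromosome end (0
#'   for none).
#' @param centromere Optional `data.frame` with columns `chr`, `start`, `end`
#'   (1-based inclusive).
#' @param extra_regions Optional `data.frame` with columns `chr`, `start`,
#'   `end` (1-based inclusive), e.g. immunoglobulin loci or segmental
#'   duplications.
#' @return A `GRanges` of exclusion regions (possibly empty), reduced to a
#'   disjoint union.
#' @export
make_exclusion_bed <- function(map, telomere_bp = 0, centromere = NULL,
                               extra_regions = NULL) {
  validate_snp_map(map)
  pieces <- list()
  chr_ends <- tapply(map$pos, map$chr, max)
  if (telomere_bp < 0) stop_invalid("telomere_bp must be >= 0")
  if (telomere_bp > 0) {
    chrs <- as.integer(names(chr_ends))
    pieces$telomere <- data.frame(
      chr = rep(chrs, 2L),
      start = c(rep(1L, length(chrs)), as.integer(chr_ends - telomere_bp + 1)),
      end = c(rep(as.integer(telomere_bp), length(chrs)), as.integer(chr_ends))
    )
  }
  add <- function(df, what) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    if (any(df$start > df$end)) stop_invalid("inverted interval in ", what)
    df[, c("chr", "start", "end")]
  }
  pieces$centromere <- add(centromere, "centromere")
  pieces$extra <- add(extra_regions, "extra_regions")
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0) {
    return(GenomicRanges::GRanges())
  }
  df <- do.call(rbind, pieces)
  gr <- GenomicRanges::GRanges(
    seqnames = paste0("chr", df$chr),
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  )
  GenomicRanges::reduce(sort(gr))
}

#' Write / read exclusion regions as BED
#'
#' BED files are 0-based half-open; internal coordinates are 1-based
#' inclusive. `rtracklayer` performs the conversion.
#'
#' @param regions A `GRanges`.
#' @param path Output file path.
#' @return `read_bed` returns a `GRanges`.
#' @export
write_bed <- function(regions, path) {
  rtracklayer::export(regions, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  S4Vectors::mcols(gr) <- NULL
  GenomicRanges::reduce(sort(gr))
}

# Calls (1-based inclusive, integer chr) -> GRanges
calls_to_granges <- function(calls) {
  GenomicRanges::GRanges(
    seqnames = paste0("chr", calls$chr),
    ranges = IRanges::IRanges(start = calls$start, end = calls$end)
  )
}
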
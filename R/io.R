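# File formats: final-report-like signal TSV, rawcnv-like call lines, YAML
# pipeline configuration. All internal coordinates are 1-based inclusive;
# only BED files (snp_map.R) use the 0-based half-open convention.

#' Write / read a cohort signal TSV (final-report-like)
#'
#' Layout: header `Name Chr Position <sample>.LRR <sample>.BAF ...`, one row
#' per marker, tab-delimited. The map's `pbaf` and `gc` columns ride along as
#' `PopBAF` / `GC` so a written cohort can be re-read losslessly (phenotypes
#' are recovered from the sample-id prefix).
#'
#' @param cohort A `cnv_cohort`.
#' @param path Output path.
#' @return `read_signal_tsv` returns a `cnv_cohort` (without truth).
#' @export
write_signal_tsv <- function(cohort, path) {
  sig <- matrix(NA_real_, nrow(cohort$map), 2L * nrow(cohort$samples))
  sig[, seq(1, ncol(sig), 2)] <- cohort$lrr
  sig[, seq(2, ncol(sig), 2)] <- cohort$baf
  colnames(sig) <- as.vector(rbind(paste0(cohort$samples$sample_id, ".LRR"),
                                   paste0(cohort$samples$sample_id, ".BAF")))
  df <- cbind(
    data.frame(Name = cohort$map$marker, Chr = cohort$map$chr,
               Position = cohort$map$pos, PopBAF = cohort$map$pbaf,
               GC = cohort$map$gc, stringsAsFactors = FALSE),
    as.data.frame(sig)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_tsv
#' @param phenotypes Optional named vector sample_id -> phenotype; by default
#'   ids starting with `case` are cases and the rest controls.
#' @export
read_signal_tsv <- function(path, phenotypes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Name", "Chr", "Position")
  if (!all(need %in% names(df))) {
    stop_invalid("signal TSV must carry columns ", paste(need, collapse = ", "))
  }
  sig_cols <- setdiff(names(df), c(need, "PopBAF", "GC"))
  lrr_cols <- grep("\\.LRR$", sig_cols, value = TRUE)
  samples <- sub("\\.LRR$", "", lrr_cols)
  missing_baf <- setdiff(paste0(samples, ".BAF"), sig_cols)
  extra_baf <- setdiff(grep("\\.BAF$", sig_cols, value = TRUE), paste0(samples, ".BAF"))
  if (length(missing_baf) || length(extra_baf)) {
    stop_invalid("unpaired LRR/BAF columns: ",
                 paste(c(missing_baf, extra_baf), collapse = ", "))
  }
  for (cl in sig_cols) {
    if (!is.numeric(df[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cl]]))))[1]
      stop_invalid("non-numeric value in column ", cl, " at line ", bad + 1L)
    }
  }
  ord <- order(df$Chr, df$Position)
  df <- df[ord, , drop = FALSE]
  bad <- unlist(tapply(df$Position, df$Chr, function(p) any(diff(p) <= 0)))
  if (any(bad)) stop_invalid("duplicate positions within a chromosome")
  map <- data.frame(
    marker = df$Name, chr = as.integer(df$Chr), pos = as.integer(df$Position),
    pbaf = if ("PopBAF" %in% names(df)) df$PopBAF else rep(0.5, nrow(df)),
    gc = if ("GC" %in% names(df)) df$GC else rep(0.5, nrow(df)),
    stringsAsFactors = FALSE
  )
  class(map) <- c("snp_map", "data.frame")
  validate_snp_map(map)
  baf <- as.matrix(df[, paste0(samples, ".BAF"), drop = FALSE])
  if (any(baf < 0 | baf > 1)) {
    stop_invalid("BAF out of [0, 1] at line ",
                 which(rowSums(baf < 0 | baf > 1) > 0)[1] + 1L)
  }
  pheno <- if (is.null(phenotypes)) {
    ifelse(startsWith(samples, "case"), "case", "control")
  } else {
    unname(phenotypes[samples])
  }
  structure(
    list(
      map = map,
      samples = data.frame(sample_id = samples, phenotype = pheno,
                           stringsAsFactors = FALSE),
      lrr = `dimnames<-`(as.matrix(df[, paste0(samples, ".LRR"), drop = FALSE]),
                         list(map$marker, samples)),
      baf = `dimnames<-`(baf, list(map$marker, samples)),
      truth = NULL
    ),
    class = "cnv_cohort"
  )
}

#' Write / read CNV calls as rawcnv-like text
#'
#' One call per line:
#' `chr1:100-200  numsnp=5  length=101  state,cn=1  s1  conf=12.5  caller=hmm`
#' (1-based inclusive coordinates; `length = end - start + 1`). Diploid
#' (`cn=2`) lines are rejected: diploid is not a call.
#'
#' @param calls CNV-call `data.frame`.
#' @param path File path.
#' @return `read_calls` returns the calls `data.frame`.
#' @export
write_calls <- function(calls, path) {
  lines <- sprintf(
    "chr%d:%d-%d\tnumsnp=%d\tlength=%d\tstate,cn=%d\t%s\tconf=%.6g\tcaller=%s",
    calls$chr, calls$start, calls$end, calls$n_probes, call_length(calls),
    calls$copy_number, calls$sample_id, calls$confidence, calls$caller
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_calls())
  pat <- paste0(
    "^chr([0-9]+):([0-9]+)-([0-9]+)\\s+numsnp=([0-9]+)\\s+length=([0-9]+)\\s+",
    "state,cn=([0-9]+)\\s+(\\S+)\\s+conf=(-?[0-9.eE+-]+)\\s+caller=(\\S+)$"
  )
  m <- regmatches(lines, regexec(pat, lines))
  bad <- which(vapply(m, length, integer(1)) == 0)
  if (length(bad)) stop_invalid("malformed call line ", bad[1], ": ", lines[bad[1]])
  f <- function(i) vapply(m, `[[`, character(1), i + 1L)
  cn <- as.integer(f(6))
  if (any(cn == 2L)) stop_invalid("cn=2 is not a call (line ", which(cn == 2L)[1], ")")
  out <- data.frame(
    sample_id = f(7), chr = as.integer(f(1)), start = as.integer(f(2)),
    end = as.integer(f(3)), copy_number = cn, copy_type = copy_type_of(cn),
    n_probes = as.integer(f(4)), confidence = as.numeric(f(8)), caller = f(9),
    stringsAsFactors = FALSE
  )
  if (any(out$start > out$end)) stop_invalid("inverted call interval")
  out
}

#' Read and validate a pipeline configuration
#'
#' YAML with top-level blocks `simulation`, `caller`, `qc`, `consensus`,
#' `association`, `paths` and a global `seed`; unknown top-level keys are
#' rejected and missing values take the package defaults.
#'
#' @param path YAML file path.
#' @return Validated configuration list (class `pipeline_config`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("simulation", "caller", "qc", "consensus", "association",
             "paths", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop_invalid("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults <- list(
    simulation = list(n_chromosomes = 1, markers_per_chromosome = 2000,
                      mean_spacing = 3000, n_cases = 300, n_controls = 300,
                      sd_lrr = 0.2, baf_noise = 0.03, gc_wave_amplitude = 0,
                      loci = list()),
    caller = caller_params(),
    qc = qc_thresholds(),
    consensus = list(reciprocal_overlap = 0.5, min_freq = 0.01),
    association = list(n_perm = 10000, alpha = 0.05),
    paths = list(out_dir = "results"),
    seed = 1L
  )
  merge2 <- function(d, u) {
    if (is.null(names(u))) return(u) # unnamed blocks (e.g. loci) replace wholesale
    for (k in names(u)) {
      d[[k]] <- if (is.list(d[[k]]) && is.list(u[[k]])) merge2(d[[k]], u[[k]]) else u[[k]]
    }
    d
  }
  # a simulation block may be a single cohort or a named list of cohort
  # blocks (two-cohort study design); defaults apply per block
  sim_fields <- names(defaults$simulation)
  user_sim <- cfg$simulation
  multi <- is.list(user_sim) && length(user_sim) > 0 &&
    !any(names(user_sim) %in% sim_fields) &&
    all(vapply(user_sim, function(b) is.list(b) && any(names(b) %in% sim_fields),
               logical(1)))
  if (multi) {
    cfg$simulation <- NULL
    out <- merge2(defaults, cfg)
    out$simulation <- lapply(user_sim, function(b) merge2(defaults$simulation, b))
  } else {
    out <- merge2(defaults, cfg)
  }
  class(out) <- c("pipeline_config", "list")
  out
}

# p-value formatting used by all result tables: scientific, 3 significant
# digits.
format_p <- function(p) formatC(p, format = "e", digits = 2)

write_result_tsv <- function(df, path) {
  pcols <- grep("p_value|adjusted", names(df), value = TRUE)
  for (cl in pcols) df[[cl]] <- format_p(df[[cl]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
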
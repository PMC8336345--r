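#' @keywords internal
"_PACKAGE"

#' @useDynLib cnvrassoc, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
# All exported stochastic operations funnel their seed through here so that a
# call never perturbs the session RNG and is bit-reproducible.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("cnvrassoc_invalid_argument", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Truncated-normal draws on [lo, hi] via inverse-CDF; vectorized over mean.
rtruncnorm01 <- function(n, mean, sd, lo = 0, hi = 1) {
  if (all(sd == 0)) return(pmin(hi, pmax(lo, rep_len(mean, n))))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  u <- runif(n, plo, phi)
  qnorm(u, mean, sd)
}

# Truncated-normal log-density on [0, 1]
dtruncnorm01 <- function(x, mean, sd, log = FALSE) {
  z <- pnorm(1, mean, sd) - pnorm(0, mean, sd)
  d <- dnorm(x, mean, sd, log = TRUE) - log(z)
  d[x < 0 | x > 1] <- -Inf
  if (log) d else exp(d)
}

# An empty CNV-call table with the canonical column set.
empty_calls <- function() {
  data.frame(
    sample_id = character(), chr = integer(), start = integer(), end = integer(),
    copy_number = integer(), copy_type = character(), n_probes = integer(),
    confidence = numeric(), caller = character(), stringsAsFactors = FALSE
  )
}

call_length <- function(calls) calls$end - calls$start + 1L

copy_type_of <- function(cn) ifelse(cn < 2, "loss", ifelse(cn > 2, "gain", NA_character_))
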
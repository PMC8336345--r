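# Shared emission model: every caller scores markers with the same per-state
# log-likelihood so that multi-caller consensus reflects decision structure,
# not incompatible signal models.
#
# LRR term: Normal(state mean, sd_lrr).  BAF term: mixture over B-allele
# counts b = 0..cn with Binomial(cn, population BAF) weights; each component
# is a truncated Normal on [0,1] centred at the allelic ratio b/cn, with the
# homozygous bands (ratio 0 or 1) at a quarter of the heterozygous-band SD.
# CN0 carries no allelic signal: BAF ~ Uniform(0,1).
#
# The BAF term depends only on (baf, pbaf, baf_sd) and is therefore computed
# once per track and shared by all three callers (GC correction only alters
# LRR); the Binomial mixture weights depend only on the map and are
# precomputed per cohort.

#' Default caller parameters
#'
#' @param sd_lrr Emission LRR standard deviation; `NULL` to estimate robustly
#'   per track (1.4826 x median absolute deviation, floored at 0.01).
#' @param baf_sd Heterozygous-band BAF standard deviation.
#' @param p_stay Long-range self-transition probability of the HMM.
#' @param D Distance scale (bp) of the distance-dependent transition.
#' @param prior_diploid Initial-state probability of CN2; the remainder is
#'   uniform over the four non-diploid states.
#' @param gaussian_threshold Cumulative log10-likelihood advantage a segment
#'   must reach to be emitted by the Gaussian-partition caller.
#' @return Parameter list consumed by the callers.
#' @export
caller_params <- function(sd_lrr = NULL, baf_sd = 0.03, p_stay = 0.999,
                          D = 1e5, prior_diploid = 0.999,
                          gaussian_threshold = 35) {
  if (p_stay <= 0 || p_stay >= 1 || prior_diploid <= 0 || prior_diploid >= 1) {
    stop_invalid("p_stay and prior_diploid must lie strictly in (0, 1)")
  }
  if (D <= 0) stop_invalid("D must be positive")
  list(
    sd_lrr = sd_lrr, baf_sd = baf_sd, p_stay = p_stay, D = D,
    prior_diploid = prior_diploid, gaussian_threshold = gaussian_threshold
  )
}

# Robust per-track LRR noise estimate for the emission model.
estimate_sd_lrr <- function(lrr) max(stats::mad(lrr), 0.01)

# Per-map log Binomial(cn, pbaf) mixture weights: a list over states, each an
# n x (cn + 1) matrix (NULL entry for CN0).
baf_logweights <- function(pbaf) {
  lapply(seq_along(STATE_CN), function(s) {
    cn <- STATE_CN[s]
    if (cn == 0L) return(NULL)
    w <- vapply(0:cn, function(b) dbinom(b, cn, pbaf, log = TRUE),
                numeric(length(pbaf)))
    matrix(w, ncol = cn + 1L)
  })
}

# n x 5 matrix of log BAF mixture densities for states CN0..CN4.
baf_mixture_loglik <- function(baf, pbaf, baf_sd, logw = baf_logweights(pbaf)) {
  n <- length(baf)
  out <- matrix(0, n, 5L) # CN0 column stays 0 (Uniform(0,1))
  for (s in seq_along(STATE_CN)) {
    cn <- STATE_CN[s]
    if (cn == 0L) next
    comp <- matrix(-Inf, n, cn + 1L)
    for (b in 0:cn) {
      ratio <- b / cn
      sd_b <- if (ratio > 0 && ratio < 1) baf_sd else baf_sd / 4
      comp[, b + 1L] <- logw[[s]][, b + 1L] + dtruncnorm01(baf, ratio, sd_b, log = TRUE)
    }
    m <- comp[, 1L]
    for (b in seq_len(cn)) m <- pmax(m, comp[, b + 1L])
    acc <- exp(comp[, 1L] - m)
    for (b in seq_len(cn)) acc <- acc + exp(comp[, b + 1L] - m)
    ll <- m + log(acc)
    ll[!is.finite(m)] <- -Inf
    out[, s] <- ll
  }
  out
}

# n x 5 matrix of log Normal LRR densities for states CN0..CN4.
lrr_gauss_loglik <- function(lrr, sd_lrr) {
  vapply(STATE_LRR_MEAN, function(mu) dnorm(lrr, mu, sd_lrr, log = TRUE),
         numeric(length(lrr)))
}

# Full emission matrix; `baf_ll` may be precomputed with baf_mixture_loglik.
emission_loglik <- function(lrr, baf, pbaf, sd_lrr, baf_sd, baf_ll = NULL) {
  baf_ll <- baf_ll %||% baf_mixture_loglik(baf, pbaf, baf_sd)
  lrr_gauss_loglik(lrr, sd_lrr) + baf_ll
}
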
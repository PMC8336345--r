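# Independent oracles used by the unit and acceptance tests. Each one is a
# direct, brute-force evaluation of a definition, deliberately sharing no
# code with the package implementation it checks.

# Exhaustive maximum-likelihood path over all k^n state sequences under the
# distance-dependent transition model. Grows the full path table column by
# column; feasible for n <= 8 with k = 5.
brute_force_viterbi <- function(emis, dist, log_init, p_stay, D) {
  n <- nrow(emis)
  k <- ncol(emis)
  paths <- matrix(seq_len(k), ncol = 1)
  scores <- log_init + emis[1, ]
  for (i in seq_len(n - 1)) {
    stay <- 1 - (1 - p_stay) * (1 - exp(-dist[i] / D))
    m <- nrow(paths)
    new_paths <- cbind(paths[rep(seq_len(m), each = k), , drop = FALSE],
                       rep(seq_len(k), m))
    prev <- new_paths[, i]
    cur <- new_paths[, i + 1]
    trans <- ifelse(prev == cur, log(stay), log((1 - stay) / (k - 1)))
    scores <- rep(scores, each = k) + trans + emis[i + 1, cur]
    paths <- new_paths
  }
  paths[which.max(scores), ]
}

# Two-tailed Fisher p by explicit enumeration with choose(); margins fixed.
enum_fisher_two_tailed <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b; N <- m + n
  support <- max(0, k - n):min(k, m)
  prob <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(N, k))
  }, numeric(1))
  obs <- prob[match(a, support)]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# One-sided hypergeometric tails by explicit summation with choose().
enum_hyper_upper <- function(q, m, N, Q) {
  # P(X >= q) drawing Q from N with m marked
  x <- q:min(Q, m)
  sum(vapply(x, function(v) {
    exp(lchoose(m, v) + lchoose(N - m, Q - v) - lchoose(N, Q))
  }, numeric(1)))
}

enum_hyper_lower <- function(q, m, N, Q) {
  x <- max(0, Q - (N - m)):q
  sum(vapply(x, function(v) {
    exp(lchoose(m, v) + lchoose(N - m, Q - v) - lchoose(N, Q))
  }, numeric(1)))
}

# Best (maximum-sum) contiguous segment by O(n^2) enumeration.
brute_force_best_segment <- function(x) {
  best <- -Inf; b0 <- NA; b1 <- NA
  for (i in seq_along(x)) {
    s <- 0
    for (j in i:length(x)) {
      s <- s + x[j]
      if (s > best) { best <- s; b0 <- i; b1 <- j }
    }
  }
  list(start = b0, end = b1, score = best)
}

# Benjamini-Hochberg step-up computed directly from the definition.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}
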
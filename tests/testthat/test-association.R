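test_that("two-tailed Fisher exact follows the probability-mass rule", {
  expect_equal(fisher_exact_two_tailed(1, 1, 1, 1), 1.0)
  # full enumeration over a in 0..5 of C(5,a)C(5,5-a)/C(10,5): every table is
  # at most as probable as (2,3,3,2), so the two-tailed sum is 1
  expect_equal(fisher_exact_two_tailed(2, 3, 3, 2), 1.0)
  expect_error(fisher_exact_two_tailed(-1, 1, 1, 1),
               class = "cnvrassoc_invalid_argument")
  expect_error(fisher_exact_two_tailed(0, 0, 0, 0),
               class = "cnvrassoc_invalid_argument")
})

test_that("Fisher exact equals hypergeometric enumeration and fisher.test", {
  tables <- withr::with_seed(101, {
    lapply(1:40, function(i) {
      n <- sample(4:60, 1)
      a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
      c <- sample(0:(n - a - b), 1); d <- n - a - b - c
      c(a, b, c, d)
    })
  })
  for (tb in tables) {
    if (sum(tb) == 0 || (tb[1] + tb[3]) == 0 || (tb[2] + tb[4]) == 0) next
    got <- fisher_exact_two_tailed(tb[1], tb[2], tb[3], tb[4])
    expect_equal(got, enum_fisher_two_tailed(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    want <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value
    expect_equal(got, want, tolerance = 1e-7)
  }
})

test_that("per-CNVR association applies BH over all tested regions", {
  tab <- data.frame(a = c(10, 3, 6, 2), b = c(90, 97, 94, 98),
                    c = c(1, 2, 5, 2), d = c(99, 98, 95, 98))
  res <- cnvr_association(tab)
  expect_equal(res$p_value, sort(res$p_value))
  expect_equal(res$fdr_adjusted_p, bh_stepup(res$p_value))
  expect_true(all(res$fdr_adjusted_p >= res$p_value))

  single <- cnvr_association(tab[1, ])
  expect_equal(single$fdr_adjusted_p, single$p_value)
})

test_that("Fisher's combined probability test matches its closed form", {
  expect_equal(fisher_combine(0.2), 0.2, tolerance = 1e-12) # k = 1 identity
  # k = 2 closed form: exp(-X/2) * (1 + X/2), X = -2 sum log p
  X <- -2 * sum(log(c(0.05, 0.05)))
  expect_equal(fisher_combine(c(0.05, 0.05)), exp(-X / 2) * (1 + X / 2),
               tolerance = 1e-12)
  expect_equal(round(fisher_combine(c(0.05, 0.05)), 4), 0.0175)
  # monotone in each argument
  expect_lt(fisher_combine(c(0.01, 0.2)), fisher_combine(c(0.02, 0.2)))
  expect_error(fisher_combine(c(0, 0.5)), class = "cnvrassoc_invalid_argument")
  expect_error(fisher_combine(numeric(0)), class = "cnvrassoc_invalid_argument")
})

make_summaries <- function(case_calls, control_calls) {
  n1 <- length(case_calls); n0 <- length(control_calls)
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n1 + n0)),
    phenotype = rep(c("case", "control"), c(n1, n0)),
    n_cnvs = c(case_calls, control_calls),
    any_cnv = as.numeric(c(case_calls, control_calls) > 0),
    total_kb = 10 * c(case_calls, control_calls),
    stringsAsFactors = FALSE
  )
}

test_that("burden test is exchangeable under identical groups and seeded", {
  s <- make_summaries(rep(c(0, 1, 2, 3), 5), rep(c(0, 1, 2, 3), 5))
  res <- burden_test(s, n_perm = 400, seed = 11)
  expect_true(all(res$p_value >= 0.5))
  expect_identical(res, burden_test(s, n_perm = 400, seed = 11))
  expect_false(identical(res$p_value,
                         burden_test(s, n_perm = 400, seed = 12)$p_value))
})

test_that("an extreme case excess reaches the permutation tail bound", {
  s <- make_summaries(rep(5, 20), rep(0, 20))
  res <- burden_test(s, n_perm = 10000, seed = 4)
  expect_true(all(res$p_value <= 0.001))
  expect_true(all(res$p_value >= 1 / 10001))
  expect_error(burden_test(make_summaries(rep(1, 5), numeric(0)), n_perm = 10),
               class = "cnvrassoc_invalid_argument")
})

test_that("pathway enrichment statistic normalizes per sample", {
  map <- tiny_map(100)
  genes <- data.frame(name = c("G1", "G2", "G3", "G4"), chr = 1L,
                      start = map$pos[c(10, 30, 50, 70)],
                      end = map$pos[c(15, 35, 55, 75)],
                      stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("s%02d", 1:20),
                        phenotype = rep(c("case", "control"), each = 10),
                        stringsAsFactors = FALSE)
  mk <- function(ids, i0, i1) {
    data.frame(sample_id = ids, chr = 1L, start = map$pos[i0], end = map$pos[i1],
               copy_number = 1L, copy_type = "loss", n_probes = 5L,
               confidence = 20, caller = "hmm", stringsAsFactors = FALSE)
  }
  # cases hit pathway genes (G1, G2), controls hit off-pathway genes (G3, G4)
  calls <- rbind(mk(sprintf("s%02d", 1:10), 10, 35),
                 mk(sprintf("s%02d", 11:20), 50, 75))
  res <- cnv_enrichment_test(calls, samples, genes, c("G1", "G2"),
                             n_perm = 10000, seed = 2)
  expect_equal(res$observed, 1)
  expect_lte(res$p_value, 0.001)
  # pathway covering all genes: ratio is identically 1, difference 0, p = 1
  res_all <- cnv_enrichment_test(calls, samples, genes,
                                 c("G1", "G2", "G3", "G4"),
                                 n_perm = 200, seed = 2)
  expect_equal(res_all$observed, 0)
  expect_equal(res_all$p_value, 1)
  expect_identical(
    cnv_enrichment_test(calls, samples, genes, "G1", n_perm = 100, seed = 5),
    cnv_enrichment_test(calls, samples, genes, "G1", n_perm = 100, seed = 5)
  )
  expect_error(cnv_enrichment_test(calls, samples, genes, character(0)),
               class = "cnvrassoc_invalid_argument")
})

test_that("chi-squared goodness-of-fit power matches the noncentral tail", {
  expect_equal(power_chi2_gof(0, 100, 1, 0.05), 0.05, tolerance = 1e-12)
  # normal-approximation oracle at w = 0.1, n = 1292, df = 1
  lambda <- 1292 * 0.1^2
  approx <- pnorm(sqrt(lambda) - qnorm(0.975))
  got <- power_chi2_gof(0.1, 1292, 1, 0.05)
  expect_equal(got, approx, tolerance = 0.02)
  expect_equal(round(got, 3), 0.949)
  # monotone in n
  powers <- vapply(c(100, 500, 1000, 2000), power_chi2_gof, numeric(1),
                   w = 0.1, df = 1, alpha = 0.05)
  expect_true(all(diff(powers) > 0))
  expect_error(power_chi2_gof(0.1, 100, 1, 1.5),
               class = "cnvrassoc_invalid_argument")
})

test_that("meta-analysis combines shared significant genes by Fisher's method", {
  assoc <- function(p, genes) {
    data.frame(p_value = p, genes = genes, stringsAsFactors = FALSE)
  }
  a <- assoc(c(6.22e-4, 0.2), c("SDHB", "OTHER"))
  b <- assoc(c(4.70e-2, 0.01), c("SDHB", "NOTSHARED"))
  meta <- meta_combine(a, b)
  expect_equal(meta$gene, "SDHB")
  expect_equal(meta$combined_p, fisher_combine(c(6.22e-4, 4.70e-2)))
  # combining two p-values below exp(-1) improves on both
  expect_lt(meta$combined_p, 4.70e-2)
  # non-significant rows never enter
  expect_equal(nrow(meta_combine(assoc(0.2, "G"), assoc(0.01, "G"))), 0)
})
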
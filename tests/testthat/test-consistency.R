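# Ensemble sign probabilities, consistency categories, mixture moments,
# attribution aggregation, correlations and rank tests.

test_that("ensemble_sign_probability counts strictly positive deltas", {
  expect_equal(ensemble_sign_probability(c(0.5, 0.2, 0.1, 0.3, 0.4)), 1)
  expect_equal(ensemble_sign_probability(c(0.5, -0.2, 0.1, -0.3, 0.4)), 0.6)
  expect_equal(ensemble_sign_probability(c(0, 0, 0, 0, 0)), 0)  # strict >
  expect_error(ensemble_sign_probability(c(1, NaN, 2)), "replicate 2")
  expect_error(ensemble_sign_probability(0.5), "2 replicates")
})

test_that("classify_consistency implements the three-category rule", {
  expect_identical(classify_consistency(c(1, 1, 1, 1, 1), truth = 1)$category,
                   "CONSISTENT_CORRECT")
  expect_identical(classify_consistency(c(1, 1, 1, 0, 1), truth = 0)$category,
                   "INCONSISTENT")
  expect_identical(classify_consistency(c(0, 0, 0, 0, 0), truth = 1)$category,
                   "CONSISTENT_INCORRECT")
  expect_identical(classify_consistency(c(1, 1, 1))$category,
                   "CONSISTENT_NO_TRUTH")
  rec <- classify_consistency(c(1, 0, 1, 1, 1), truth = 1)
  expect_equal(rec$sign_probability, 0.8)
  expect_equal(rec$n_replicates, 5L)
})

test_that("classification is invariant to replicate order", {
  set.seed(42)
  for (i in 1:50) {
    labels <- sample(0:1, 5, replace = TRUE)
    truth <- sample(0:1, 1)
    ref <- classify_consistency(labels, truth)$category
    expect_identical(classify_consistency(sample(labels), truth)$category, ref)
  }
})

test_that("vectorized classification agrees with the scalar rule", {
  set.seed(7)
  labels <- matrix(sample(0:1, 200, replace = TRUE), 40, 5)
  truth <- sample(c(0L, 1L, NA), 40, replace = TRUE)
  recs <- enseq:::classify_consistency_matrix(labels, truth)
  for (i in seq_len(40)) {
    expect_identical(recs$category[i],
                     classify_consistency(labels[i, ],
                                          truth = truth[i])$category)
  }
})

test_that("poisson mixture moments follow the law of total variance", {
  mm <- poisson_mixture_moments(rep(2, 5))
  expect_equal(mm$mean, 2)
  expect_equal(mm$variance, 2)  # identical components: equidispersed

  mm2 <- poisson_mixture_moments(c(1, 3), c(0.5, 0.5))
  expect_equal(mm2$mean, 2)
  expect_equal(mm2$variance, 3)  # E[lambda] + Var(lambda) = 2 + 1

  expect_error(poisson_mixture_moments(c(1, 2), c(0.7, 0.7)), "simplex|sum")
  expect_error(poisson_mixture_moments(c(-1, 2), c(0.5, 0.5)))
  # M = 1 reduces to the single Poisson
  one <- poisson_mixture_moments(3.7, 1)
  expect_equal(one$mean, 3.7)
  expect_equal(one$variance, 3.7)
})

test_that("saliency window scores sum absolute attributions per bin", {
  expect_equal(saliency_window_scores(numeric(256)), c(0, 0))
  expect_equal(saliency_window_scores(rep(c(1, -1), 64)), 128)
  set.seed(1)
  at <- rnorm(640)
  oracle <- vapply(1:5, function(b) {
    s <- 0
    for (i in ((b - 1) * 128 + 1):(b * 128)) s <- s + abs(at[i])
    s
  }, numeric(1))
  expect_equal(saliency_window_scores(at), oracle)
  expect_error(saliency_window_scores(numeric(100)), "multiple")
})

test_that("pairwise correlations match the textbook formula", {
  set.seed(2)
  mat <- matrix(rnorm(40), 10, 4)
  out <- pairwise_correlation(mat, "pearson")
  expect_equal(nrow(out), 6L)  # M(M-1)/2
  manual <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (k in seq_len(nrow(out))) {
    expect_equal(out$correlation[k],
                 manual(mat[, out$rep_i[k]], mat[, out$rep_j[k]]),
                 tolerance = 1e-12)
  }
  expect_equal(pairwise_correlation(cbind(1:5, 1:5))$correlation, 1)
  expect_equal(pairwise_correlation(cbind(1:5, 5:1))$correlation, -1)
  # constant column reported as NA, not dropped
  out2 <- pairwise_correlation(cbind(1:5, rep(2, 5), 5:1))
  expect_equal(nrow(out2), 3L)
  expect_true(is.na(out2$correlation[out2$rep_i == 2 | out2$rep_j == 2][1]))
})

test_that("group_compare gives exact small-sample rank p-values", {
  # all 3 of a below all 3 of b: p = 1 / C(6,3) = 0.05 one-sided
  expect_equal(group_compare(c(1, 2, 3), c(4, 5, 6), "less")$p_value, 0.05)
  expect_equal(group_compare(c(4, 5, 6), c(1, 2, 3), "greater")$p_value, 0.05)
  # identical groups: no shift, p >= 0.5
  expect_gte(group_compare(c(1, 2, 7), c(1, 2, 7), "greater")$p_value, 0.5)
  expect_error(group_compare(numeric(0), 1:3), "empty")
  # large/tied samples fall back to the normal approximation without error
  set.seed(1)
  p <- group_compare(rnorm(30), rnorm(30) + 1, "less")$p_value
  expect_lt(p, 0.01)
})

test_that("BH adjustment over a family matches the hand recursion", {
  pairs <- list(list(a = c(1, 2, 3), b = c(4, 5, 6), name = "x"),
                list(a = c(1, 2), b = c(3, 4), name = "y"))
  fam <- group_compare_family(pairs, "less")
  # raw: 1/20 and 1/6 (exact enumeration); step-up by hand:
  # sorted (0.05, 1/6): adj_2 = 1/6, adj_1 = min(2*0.05, 1/6) = 0.1
  expect_equal(fam$p_raw, c(0.05, 1 / 6))
  expect_equal(fam$p_adjusted, c(0.1, 1 / 6))
  # hand-derived step-up: (0.01, 0.02, 0.03) over m = 3 -> all 0.03
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
})
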
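# Haplotype construction, individual prediction, gene uncertainty and drivers.

test_that("build_haplotypes substitutes phased alleles", {
  w <- random_window(2048, seed = 51)
  pos0 <- c(400L, 900L)
  ref <- vapply(pos0, function(p) substr(w$sequence, p + 1, p + 1), character(1))
  alt <- ifelse(ref == "G", "A", "G")
  variants <- data.frame(pos0 = pos0, ref = ref, alt = alt)

  # all-reference genotype: both haplotypes equal the reference
  h0 <- build_haplotypes(w, matrix(0L, 2, 2), variants)
  expect_identical(h0$hap1$sequence, w$sequence)
  expect_identical(h0$hap2$sequence, w$sequence)

  # het 1|0 at the first variant: haplotypes differ at exactly one position
  h1 <- build_haplotypes(w, rbind(c(1L, 0L), c(0L, 0L)), variants)
  d <- which(strsplit(h1$hap1$sequence, "")[[1]] !=
               strsplit(h1$hap2$sequence, "")[[1]])
  expect_equal(d, 401L)

  # two variants phased onto hap1 for GT 1|0, 1|0
  h2 <- build_haplotypes(w, rbind(c(1L, 0L), c(1L, 0L)), variants)
  expect_identical(substr(h2$hap1$sequence, 401, 401), alt[1])
  expect_identical(substr(h2$hap1$sequence, 901, 901), alt[2])
  expect_identical(h2$hap2$sequence, w$sequence)

  bad <- variants
  bad$ref[1] <- setdiff(c("A", "C", "G", "T"), ref[1])[1]
  expect_error(build_haplotypes(w, matrix(0L, 2, 2), bad), "mismatch")
})

test_that("predict_individual averages ten central bins then two haplotypes", {
  # mock whose output we can slice by hand
  vals <- matrix(seq_len(16), 16, 1)
  mock_a <- function(w) vals
  mock_b <- function(w) vals + 16
  w <- random_window(2048, seed = 52)
  # 16 bins: central ten are bins 4..13
  expect_equal(predict_individual(mock_a, w, w), mean(vals[4:13, 1]))
  # hap values 2 and 4 average to 3
  m2 <- function(w) matrix(2, 16, 1)
  m4 <- function(w) matrix(4, 16, 1)
  hap_pair <- predict_individual(m2, w, w)
  expect_equal(hap_pair, 2)
  mixed <- (predict_individual(m2, w, w) + predict_individual(m4, w, w)) / 2
  expect_equal(mixed, 3)

  short <- function(w) matrix(1, 8, 1)
  expect_error(predict_individual(short, w, w), "10 bins")
})

test_that("predict_population equals the per-individual definitional path", {
  model <- default_ground_truth()
  sim <- simulate_regulatory_genome(model, 1, seed = 61)
  w <- sim$windows[[1]]
  panel <- draw_variant_panel(w, sim$sites, n_variants = 6, n_planted = 2,
                              seed = 62)
  pop <- simulate_population(model, w, panel, n_individuals = 8,
                             allele_freq = 0.4, h2 = 0.5, seed = 63)
  ens <- make_replicate_ensemble(model, M = 3, sigma = 0.3)
  bulk <- predict_population(ens, w, panel, pop$haplotypes)
  for (i in 1:8) {
    haps <- build_haplotypes(w, pop$haplotypes[i, , ], panel)
    direct <- predict_individual(ens, haps$hap1, haps$hap2)
    expect_equal(unname(bulk[i, ]), unname(direct), tolerance = 1e-8)
  }
})

test_that("cross-individual correlation is a rank statistic", {
  x <- c(1, 3, 2, 5, 4)
  y <- c(10, 30, 20, 50, 40)
  expect_equal(cross_individual_correlation(x, y), 1)
  expect_equal(cross_individual_correlation(x, -y), -1)
  expect_equal(cross_individual_correlation(exp(x), y), 1)  # monotone invariance
  expect_warning(out <- cross_individual_correlation(rep(1, 5), y), "constant")
  expect_true(is.na(out))
  expect_error(cross_individual_correlation(1:4, 1:5), "mismatch")
  expect_error(cross_individual_correlation(1:2, 1:2), "3 individuals")
})

test_that("gene uncertainty table computes variance, magnitude and counts", {
  rho <- rbind(rep(0.4, 5),
               c(0.3, -0.3, 0.3, -0.3, 0.3),
               c(0.05, -0.05, 0.02, 0.01, -0.03))
  tab <- gene_uncertainty_table(rho, c("g1", "g2", "g3"))
  expect_equal(tab$variance_rho[1], 0)
  expect_equal(tab$n_positive, c(5L, 3L, 3L))
  expect_equal(tab$mean_abs_rho[2], 0.3)
  expect_true(tab$eligible[2])
  expect_false(tab$eligible[3])  # mean |rho| = 0.032 < 0.1
  expect_equal(tab$uncertainty_class, rep("UNCLASSIFIED", 3))
})

test_that("uncertainty extremes are selected among eligible genes only", {
  tab <- gene_uncertainty_table(
    rbind(c(0.5, 0.5), c(0.2, 0.6), c(0.1, 0.9), c(0.45, 0.55),
          c(0.01, -0.01)),
    c("g1", "g2", "g3", "g4", "g5"))
  expect_false(tab$eligible[5])
  out <- select_uncertainty_extremes(tab, n = 1)
  expect_equal(out$high, "g3")  # largest variance
  expect_equal(out$low, "g1")   # variance 0
  expect_false("g5" %in% c(out$high, out$low))
  expect_equal(out$table$uncertainty_class[out$table$gene_id == "g3"], "HIGH")

  expect_warning(big <- select_uncertainty_extremes(tab, n = 5), "splitting")
  expect_equal(sort(c(big$high, big$low)), c("g1", "g2", "g3", "g4"))
  expect_length(intersect(big$high, big$low), 0L)
})

test_that("ensemble_mean_rank averages within-replicate ranks", {
  pred <- cbind(c(1, 2, 3), c(30, 10, 20))
  expect_equal(ensemble_mean_rank(pred), c(2, 1.5, 2.5))
})

test_that("identify_drivers recovers a single dominant signal", {
  set.seed(71)
  dosage <- matrix(rbinom(100 * 10, 2, 0.4), 100, 10,
                   dimnames = list(NULL, sprintf("v%02d", 1:10)))
  pred <- 2 * dosage[, 4]
  dr <- identify_drivers(pred, dosage)
  expect_equal(dr$variant_id[1], "v04")
  expect_equal(dr$variance_explained[1], 1)
  expect_true(all(diff(dr$variance_explained) <= 1e-12))
})

test_that("uncorrelated variants are never drivers and the cap holds", {
  set.seed(72)
  n <- 200
  dosage <- matrix(rbinom(n * 12, 2, 0.5), n, 12,
                   dimnames = list(NULL, sprintf("v%02d", 1:12)))
  # orthogonalize v12 against the prediction by construction
  pred <- rowSums(dosage[, 1:8]) + rnorm(n, sd = 0.1)
  dosage[, 12] <- sample(rep(0:2, length.out = n))  # permuted: r2 ~ 0
  dr <- identify_drivers(pred, dosage, delta = 0.01)
  expect_lte(nrow(dr), 6L)  # cap
  expect_false("v12" %in% dr$variant_id[1])

  # constant predictions yield no drivers, with a warning
  expect_warning(none <- identify_drivers(rep(1, n), dosage), "constant")
  expect_equal(nrow(none), 0L)
})

test_that("driver concordance counts reproducibility and sign agreement", {
  drivers <- data.frame(
    gene_id = c("g1", "g1", "g1", "g1", "g2"),
    replicate = c(1, 2, 3, 1, 2),
    variant_id = c("a", "a", "a", "b", "c"))
  sad_signs <- data.frame(
    gene_id = rep(c("g1", "g1", "g2"), each = 3),
    variant_id = rep(c("a", "b", "c"), each = 3),
    replicate = rep(1:3, 3),
    sign = c(1, 1, -1, 1, 1, 1, -1, -1, -1))
  classes <- data.frame(gene_id = c("g1", "g2"),
                        uncertainty_class = c("LOW", "HIGH"))
  out <- driver_concordance(drivers, sad_signs, classes, M = 3)
  rep_a <- out$reproducibility[out$reproducibility$variant_id == "a", ]
  expect_equal(rep_a$n_replicates, 3L)
  expect_equal(rep_a$uncertainty_class, "LOW")
  rep_c <- out$reproducibility[out$reproducibility$variant_id == "c", ]
  expect_equal(rep_c$n_replicates, 1L)
  # only "a" reaches the min_found threshold; 2 of 3 replicates agree on sign
  expect_equal(out$sign_agreement$variant_id, "a")
  expect_equal(out$sign_agreement$n_sign_agree, 2L)
})

test_that("a zero-noise ensemble gives identical driver sets and zero variance", {
  model <- default_ground_truth()
  sim <- simulate_regulatory_genome(model, 1, seed = 81)
  w <- sim$windows[[1]]
  panel <- draw_variant_panel(w, sim$sites, n_variants = 8, n_planted = 3,
                              seed = 82)
  pop <- simulate_population(model, w, panel, n_individuals = 30,
                             allele_freq = 0.4, h2 = 1, seed = 83)
  ens0 <- make_replicate_ensemble(model, M = 3, sigma = 0)
  preds <- predict_population(ens0, w, panel, pop$haplotypes)
  rhos <- vapply(1:3, function(m)
    cross_individual_correlation(preds[, m], pop$measured), numeric(1))
  expect_equal(var(rhos), 0)
  sets <- lapply(1:3, function(m)
    identify_drivers(preds[, m], pop$dosage, panel$variant_id)$variant_id)
  expect_identical(sets[[1]], sets[[2]])
  expect_identical(sets[[1]], sets[[3]])
})
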
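# Motif insertion, background selection and activity-score machinery.

test_that("insert_motif substitutes in place at the documented interval", {
  # all-A window, anchor 1024; offset 10, L = 8 -> [anchor-18, anchor-10)
  w <- genomic_window("chrT", 0, strrep("A", 2048), 1024)
  out <- insert_motif(w, "CCCCCCCC", 10)
  expect_equal(out$length, w$length)
  cpos <- which(strsplit(out$sequence, "")[[1]] == "C") - 1L  # 0-based
  expect_equal(cpos, 1006:1013)  # [anchor-18, anchor-10) = [1006, 1014)

  # inserting the reference substring is the identity
  w2 <- random_window(2048, seed = 6)
  sub <- substr(w2$sequence, 1024 - 18 + 1, 1024 - 10)
  expect_identical(insert_motif(w2, sub, 10)$sequence, w2$sequence)

  expect_error(insert_motif(w, "CCCC", 0), "overlap")
  expect_error(insert_motif(w, strrep("C", 100), 1030), "exit")
})

test_that("select_backgrounds ranks genes by consistently-correct tracks", {
  tab <- data.frame(
    gene_id = rep(c("gB", "gA", "gC"), each = 3),
    track_id = rep(c("t1", "t2", "t3"), 3),
    category = c("CONSISTENT_CORRECT", "CONSISTENT_CORRECT", "CONSISTENT_CORRECT",
                 "CONSISTENT_CORRECT", "INCONSISTENT", "CONSISTENT_INCORRECT",
                 "INCONSISTENT", "INCONSISTENT", "INCONSISTENT"))
  expect_equal(select_backgrounds(tab, 1), "gB")
  expect_equal(select_backgrounds(tab, 2), c("gB", "gA"))
  expect_equal(select_backgrounds(tab, 0), character(0))
  expect_warning(out <- select_backgrounds(tab, 10), "only 3")
  expect_equal(out, c("gB", "gA", "gC"))
  # full tie: lexicographic order
  tie <- tab
  tie$category <- "CONSISTENT_CORRECT"
  expect_equal(select_backgrounds(tie, 2), c("gA", "gB"))
})

test_that("a content-blind model scores every insertion at zero", {
  blind <- toy_model()
  blind$weights[] <- 0
  w <- random_window(2048, seed = 3)
  sc <- tf_activity_score(blind, list(w), toy_motifs()[[1]], offset = 10,
                          mode = "consensus")
  expect_equal(as.numeric(sc$scores), 0)
})

test_that("inserting a planted activator yields a positive score", {
  model <- toy_model()
  w <- toy_null_window()
  sc <- tf_activity_score(model, list(w), model$motifs[[1]], offset = 10,
                          mode = "consensus")
  expect_gt(sc$scores[1, 1], 0)
  # repressor insertion is negative
  sc2 <- tf_activity_score(model, list(w), model$motifs[[2]], offset = 10,
                           mode = "consensus")
  expect_lt(sc2$scores[1, 1], 0)
})

test_that("single-background scores equal a direct two-call subtraction", {
  model <- toy_model()
  w <- random_window(2048, seed = 17)
  motif <- model$motifs[[1]]
  sc <- tf_activity_score(model, list(w), motif, offset = 100,
                          mode = "consensus")
  ins <- insert_motif(w, consensus_sequence(motif), 100)
  p_ins <- robust_predict(model, ins)
  p_bg <- robust_predict(model, w)
  direct <- sum(p_ins[8:9, 1]) - sum(p_bg[8:9, 1])
  expect_equal(unname(sc$scores[1, 1]), direct, tolerance = 1e-9)

  # and the mutation score equals the direct mutated-vs-canonical difference
  msc <- tf_mutation_activity_score(model, list(w), motif, offset = 100,
                                    mode = "consensus")
  mut_seq <- mutate_motif_sequence(motif, consensus_sequence(motif))
  p_mut <- robust_predict(model, insert_motif(w, mut_seq, 100))
  expect_equal(unname(msc$scores[1, 1]),
               sum(p_mut[8:9, 1]) - sum(p_ins[8:9, 1]), tolerance = 1e-9)
  # algebraic identity: score(mut vs bg) = score(mut vs canon) + score(canon vs bg)
  direct_mut_bg <- sum(p_mut[8:9, 1]) - sum(p_bg[8:9, 1])
  expect_equal(unname(msc$scores[1, 1] + sc$scores[1, 1]), direct_mut_bg,
               tolerance = 1e-9)
})

test_that("disruptive mutation of a planted activator scores negative", {
  model <- toy_model()
  w <- toy_null_window()
  msc <- tf_mutation_activity_score(model, list(w), model$motifs[[1]],
                                    offset = 10, mode = "consensus")
  expect_lt(msc$scores[1, 1], 0)
})

test_that("a motif outside the model vocabulary scores exactly zero", {
  model <- toy_model()
  w <- toy_null_window()  # AT-repeat: no G/C anywhere
  # an A/T-only motif cannot create or destroy any toy-motif match
  at_motif <- pwm_motif("AT", {
    m <- matrix(0.01, 8, 4)
    m[, 1] <- 0.49
    m[, 4] <- 0.49
    m / rowSums(m)
  })
  sc <- tf_activity_score(model, list(w), at_motif, offset = 10,
                          mode = "consensus")
  expect_equal(as.numeric(sc$scores), 0)
})

test_that("odd bin counts have no central junction", {
  model <- toy_model()
  w <- genomic_window("chrT", 0, strrep("AT", 1920 / 2), 960)  # 15 bins
  expect_error(tf_activity_score(model, list(w), model$motifs[[1]], 10,
                                 mode = "consensus"), "odd|junction")
})

test_that("inconsistency_fraction counts non-unanimous sign rows", {
  unanimous <- rbind(c(1, 2, 3), c(-1, -2, -0.5))
  expect_equal(inconsistency_fraction(unanimous), 0)
  mixed <- rbind(matrix(1, 9, 3), c(1, -1, 1))
  expect_equal(inconsistency_fraction(mixed), 0.1)
  # zero counts as non-positive: (0, 1) rows are inconsistent
  expect_equal(inconsistency_fraction(rbind(c(0, 1))), 1)
  expect_equal(inconsistency_fraction(rbind(c(0, 0, 0))), 0)
})

test_that("a zero-noise ensemble has zero inconsistency everywhere", {
  model <- toy_model()
  ens0 <- make_replicate_ensemble(model, M = 3, sigma = 0)
  w <- random_window(2048, seed = 23)
  ma <- motif_activity_analysis(ens0, list(w), model$motifs,
                                offsets = c(10, 100), seed = 5)
  for (i in seq_along(ma$scores)) {
    for (kind in c("CANONICAL", "MUTATION")) {
      sc <- ma$scores[[i]][[kind]]$scores  # replicates x tracks
      expect_equal(inconsistency_fraction(matrix(sc[, 1], nrow = 1)), 0)
    }
  }
})

test_that("motif realizations are fixed per (motif, background) across replicates", {
  model <- toy_model()
  ens <- make_replicate_ensemble(model, M = 3, sigma = 0.3)
  w <- random_window(2048, seed = 29)
  a <- motif_activity_analysis(ens, list(w), model$motifs[1], offsets = 10,
                               seed = 77)
  b <- motif_activity_analysis(ens, list(w), model$motifs[1], offsets = 10,
                               seed = 77)
  expect_identical(a$long, b$long)
})
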
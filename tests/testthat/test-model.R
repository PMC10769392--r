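# Ground-truth prediction engine: oracle equality, locality, augmentation
# averaging, incremental substitution updates.

test_that("a window without motif matches predicts the baseline everywhere", {
  model <- toy_model()
  p <- predict_tracks(model, toy_null_window())
  expect_equal(as.numeric(p), rep(0.5, 16), tolerance = 1e-10)
})

test_that("planting an activator at the anchor raises the anchor bin rate", {
  model <- toy_model()
  w0 <- toy_null_window()
  p0 <- predict_tracks(model, w0)
  cons <- consensus_sequence(model$motifs[[1]])
  w1 <- substitute_bases(w0, 1024:(1024 + 7), strsplit(cons, "")[[1]])
  p1 <- predict_tracks(model, w1)
  expect_gt(p1[9, 1], p0[9, 1])  # bin containing offset 1024
  # and a repressor lowers it
  rep_cons <- consensus_sequence(model$motifs[[2]])
  w2 <- substitute_bases(w0, 1024:(1024 + 7), strsplit(rep_cons, "")[[1]])
  expect_lt(predict_tracks(model, w2)[9, 1], p0[9, 1])
})

test_that("engine predictions equal the brute-force oracle", {
  model <- toy_model()
  for (seed in 1:3) {
    w <- random_window(2048, seed = seed)
    expect_equal(as.numeric(predict_tracks(model, w)),
                 as.numeric(oracle_predict(model, w)), tolerance = 1e-8)
  }
  # including a hand-planted two-site window
  w <- toy_null_window()
  w <- substitute_bases(w, 300:307,
                        strsplit(consensus_sequence(toy_motifs()[[1]]), "")[[1]])
  w <- substitute_bases(w, 1500:1507,
                        strsplit(consensus_sequence(toy_motifs()[[2]]), "")[[1]])
  expect_equal(as.numeric(predict_tracks(model, w)),
               as.numeric(oracle_predict(model, w)), tolerance = 1e-8)
})

test_that("bins are invariant to edits outside their receptive field", {
  model <- toy_model()
  w <- random_window(2048, seed = 5)
  p0 <- predict_tracks(model, w)
  # bin 1 center is at 64 bp; edit at 1600 bp, far beyond rf/2 + motif length
  w2 <- substitute_bases(w, 1600, "A")
  if (substr(w$sequence, 1601, 1601) == "A") w2 <- substitute_bases(w, 1600, "C")
  p2 <- predict_tracks(model, w2)
  expect_identical(p0[1, 1], p2[1, 1])
  expect_identical(p0[2, 1], p2[2, 1])
})

test_that("N bases contribute nothing", {
  model <- toy_model()
  w <- toy_null_window()
  cons <- consensus_sequence(model$motifs[[1]])
  w1 <- substitute_bases(w, 1024:(1024 + 7), strsplit(cons, "")[[1]])
  # breaking the site with N returns the window to baseline
  w2 <- substitute_bases(w1, 1027, "N")
  expect_equal(as.numeric(predict_tracks(model, w2)), rep(0.5, 16),
               tolerance = 1e-10)
})

test_that("robust_predict averages the six augmentations of a function", {
  nb <- 16L
  mock <- function(w) {
    ints <- match(strsplit(w$sequence, "")[[1]], c("A", "C", "G", "T"))
    ints[is.na(ints)] <- 0
    matrix(vapply(seq_len(nb), function(b)
      sum(ints[((b - 1) * 128 + 1):(b * 128)]), numeric(1)), ncol = 1)
  }
  w <- random_window(2048, seed = 9)
  # hand enumeration of the six calls
  acc <- matrix(0, nb, 1)
  for (shift in c(-1L, 0L, 1L)) {
    ws <- enseq:::shift_window(w, shift)
    acc <- acc + mock(ws)
    wrc <- reverse_complement(ws)
    acc <- acc + mock(wrc)[nb:1, , drop = FALSE]
  }
  expect_equal(robust_predict(mock, w), acc / 6)
})

test_that("strand-symmetric shift-invariant predictors pass through robust_predict", {
  const <- function(w) matrix(7, 16, 1)
  w <- random_window(2048, seed = 2)
  expect_equal(robust_predict(const, w), predict_tracks(const, w))
})

test_that("strand-antisymmetric predictors cancel to zero", {
  # +1 when the window carries more C than G, -1 otherwise; the probe
  # sequence holds its single C away from the edges so shifts preserve it
  mock <- function(w) {
    chars <- strsplit(w$sequence, "")[[1]]
    matrix(sign(sum(chars == "C") - sum(chars == "G")), 16, 1)
  }
  seq <- paste0(strrep("A", 100), "C", strrep("A", 2048 - 101))
  w <- genomic_window("chrT", 0, seq, 1024)
  expect_equal(as.numeric(robust_predict(mock, w)), rep(0, 16))
})

test_that("robust_predict on the reverse complement yields reversed bins", {
  model <- toy_model()
  w <- random_window(2048, seed = 13)
  fwd <- robust_predict(model, w)
  rev_ <- robust_predict(model, reverse_complement(w))
  expect_equal(as.numeric(rev_), as.numeric(fwd[16:1, , drop = FALSE]),
               tolerance = 1e-10)
})

test_that("ensemble predictions share the contract and collapse at sigma 0", {
  model <- toy_model()
  ens0 <- make_replicate_ensemble(model, M = 3, sigma = 0)
  w <- random_window(2048, seed = 3)
  p <- robust_predict(ens0, w)
  expect_equal(dim(p), c(16L, 1L, 3L))
  expect_identical(p[, , 1], p[, , 2])
  expect_identical(p[, , 1], p[, , 3])
  expect_equal(p[, , 1], robust_predict(model, w)[, 1], tolerance = 1e-12,
               ignore_attr = TRUE)

  ens <- make_replicate_ensemble(model, M = 3, sigma = 0.5)
  p2 <- robust_predict(ens, w)
  expect_false(identical(p2[, , 1], p2[, , 2]))
  # member extraction matches the ensemble slice
  m2 <- ensemble_member(ens, 2)
  expect_equal(robust_predict(m2, w)[, 1], p2[, , 2], tolerance = 1e-12)
})

test_that("incremental substitution predictions match full rescans", {
  model <- toy_model()
  ens <- make_replicate_ensemble(model, M = 3, sigma = 0.4)
  w <- random_window(2048, seed = 21)
  set.seed(99)
  for (i in 1:5) {
    pos0 <- sample(200:1800, 3)
    bases <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
    w2 <- substitute_bases(w, pos0, bases)
    full <- robust_predict(ens, w2)
    ints <- enseq:::seq_to_int(w$sequence)
    subs <- data.frame(pos0 = pos0, base = match(bases, c("A", "C", "G", "T")))
    inc <- enseq:::.bulk_robust(model, ens$members, ints,
                                subs_list = list(subs))$subs[[1]]
    expect_equal(as.numeric(inc), as.numeric(full), tolerance = 1e-9)
  }
})

test_that("ISM attributions highlight planted sites and respect N", {
  model <- toy_model()
  w <- toy_null_window()
  cons <- consensus_sequence(model$motifs[[1]])
  w <- substitute_bases(w, 1000:1007, strsplit(cons, "")[[1]])
  at <- ism_attributions(model, w, track = 1)
  expect_equal(dim(at), c(2048L, 1L))
  expect_true(all(at >= 0))
  # attribution mass concentrates on the planted site
  expect_gt(mean(at[1001:1008, 1]), 10 * mean(at[1:500, 1]) + 1e-12)
})

test_that("function-predictor ISM agrees with the model-backed fast path", {
  model <- toy_model()
  w <- substitute_bases(toy_null_window(1280, anchor = 640), 600:607,
                        strsplit(consensus_sequence(toy_motifs()[[1]]), "")[[1]])
  fast <- ism_attributions(model, w, track = 1)
  slow <- ism_attributions(function(win) predict_tracks(model, win), w,
                           track = 1)
  expect_equal(as.numeric(fast), as.numeric(slow), tolerance = 1e-8)
})
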
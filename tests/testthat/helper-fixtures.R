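# Shared fixtures: a small hand-specified model for oracle tests and a
# desk-scale model for integration-style tests. Everything is built in code.

# Two hand-written sharp PWMs: an activator and a repressor.
toy_motifs <- function() {
  act <- matrix(0.02, 8, 4)
  act[cbind(1:8, c(1, 2, 3, 4, 1, 2, 3, 4))] <- 0.94  # consensus ACGTACGT
  rep_ <- matrix(0.02, 8, 4)
  rep_[cbind(1:8, c(3, 3, 3, 3, 2, 2, 2, 2))] <- 0.94  # consensus GGGGCCCC
  list(pwm_motif("ACT", act / rowSums(act)),
       pwm_motif("REP", rep_ / rowSums(rep_)))
}

# 2048 bp / 16-bin single-track toy model with known weights.
toy_model <- function(...) {
  ground_truth_model(toy_motifs(), weights = c(4, -3),
                     baseline_rate = 0.5, decay_scale = 256,
                     receptive_field = 1024, window_length = 2048,
                     bin_width = 128, ...)
}

# A background window guaranteed to contain no toy-motif match: alternating
# AT carries no G or C, which every toy consensus requires.
toy_null_window <- function(len = 2048, anchor = len %/% 2) {
  genomic_window("chrT", 0, strrep("AT", len / 2), anchor = anchor, id = "null")
}

random_window <- function(len = 2048, seed = 1, anchor = len %/% 2) {
  set.seed(seed)
  genomic_window("chrT", 0, paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = ""),
                 anchor = anchor, id = sprintf("rw%d", seed))
}

# Independent brute-force reimplementation of the ground-truth rate model:
# nested loops over positions, motifs and strands, no shared code with the
# package engine.
oracle_predict <- function(model, window) {
  seqc <- strsplit(window$sequence, "", fixed = TRUE)[[1L]]
  base_idx <- match(seqc, c("A", "C", "G", "T"))
  n <- length(base_idx)
  nb <- n / model$bin_width
  bin_centers <- (seq_len(nb) - 0.5) * model$bin_width
  pre <- matrix(rep(log(expm1(model$link_sharpness * model$baseline_rate)) /
                      model$link_sharpness, each = nb), nb, model$n_tracks)
  rc_of <- c(4L, 3L, 2L, 1L)
  for (mi in seq_along(model$motifs)) {
    pm <- model$motifs[[mi]]$matrix
    L <- nrow(pm)
    lo <- log(pmax(pm, 1e-9) / 0.25)
    tau <- model$match_threshold_frac * sum(apply(lo, 1, max))
    for (s in 1:(n - L + 1)) {
      for (strand in c("+", "-")) {
        sc <- 0
        for (j in 1:L) {
          b <- base_idx[s + j - 1]
          if (is.na(b)) { sc <- -Inf; break }
          sc <- sc + if (strand == "+") lo[j, b] else lo[L - j + 1, rc_of[b]]
        }
        sc <- sc - tau
        if (is.finite(sc) && sc > 0) {
          contrib <- min(sc, model$site_saturation)
          center <- (s - 1) + L / 2
          for (b in seq_len(nb)) {
            d <- abs(center - bin_centers[b])
            if (d <= model$receptive_field / 2) {
              pre[b, ] <- pre[b, ] +
                model$weights[mi, ] * contrib * exp(-d / model$decay_scale)
            }
          }
        }
      }
    }
  }
  log1p(exp(model$link_sharpness * pre)) / model$link_sharpness
}
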
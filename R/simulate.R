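# Synthetic regulatory genome, experimental counts, eQTL panels and diploid
# populations with known ground truth. Everything here is bitwise reproducible
# from (arguments, seed).

#' Default motif library for the synthetic regulatory genome
#'
#' Generates sharp, information-rich PWMs (consensus probability 0.95 at most
#' positions, two degenerate positions per motif), the regulatory vocabulary
#' of the default ground-truth model. Sharp motifs of 10-12 bp keep chance
#' matches rare at the default match threshold while letting PWM-sampled
#' realizations stay above it.
#'
#' @param n_motifs number of motifs.
#' @param lengths motif lengths to cycle through.
#' @param seed integer seed.
#' @return A list of [pwm_motif()] objects.
#' @export
default_motif_library <- function(n_motifs = 8L, lengths = c(12L, 11L, 12L, 10L),
                                  seed = 42L) {
  with_seed(seed, {
    lapply(seq_len(n_motifs), function(i) {
      L <- lengths[(i - 1L) %% length(lengths) + 1L]
      m <- matrix(0, L, 4L)
      soft <- sample(seq_len(L), 2L)  # two degenerate positions per motif
      for (j in seq_len(L)) {
        cons <- sample.int(4L, 1L)
        if (j %in% soft) {
          p <- rep(0.1, 4L)
          p[cons] <- 0.45
          p[sample(setdiff(1:4, cons), 1L)] <- 0.35
        } else {
          # sharp position with jittered consensus probability and an uneven
          # split of the residual mass, so single-base log-odds drops vary
          # continuously across motifs
          pc <- stats::runif(1L, 0.88, 0.97)
          r <- stats::runif(3L, 0.2, 1)
          p <- rep(0, 4L)
          p[cons] <- pc
          p[setdiff(1:4, cons)] <- (1 - pc) * r / sum(r)
        }
        m[j, ] <- p / sum(p)
      }
      pwm_motif(sprintf("M%02d", i), m)
    })
  })
}

#' Default ground-truth model
#'
#' A desk-scale ground truth: 4,096 bp windows with 32 x 128 bp bins, a
#' 2,048 bp receptive field, exponential distance decay over 512 bp, and a
#' motif library of activators (first 5 motifs) and repressors (last 3) with
#' per-track effect multipliers across 4 tracks (one per assay class).
#'
#' @param n_tracks number of tracks.
#' @param seed integer seed for library and weights.
#' @param ... overrides passed on to [ground_truth_model()].
#' @return A `gt_model`.
#' @export
default_ground_truth <- function(n_tracks = 4L, seed = 42L, ...) {
  motifs <- default_motif_library(seed = seed)
  n_m <- length(motifs)
  n_act <- ceiling(n_m * 5 / 8)
  with_seed(derive_seed(seed, 1L), {
    # one strong anchor activator (planted at every TSS) plus a spread of
    # weaker effects whose sign the ensemble members can disagree about
    base_w <- c(6, exp(stats::runif(n_act - 1L, log(0.8), log(6))),
                -exp(stats::runif(n_m - n_act, log(0.8), log(6))))
    mult <- matrix(stats::runif(n_m * n_tracks, 0.6, 1.4), n_m, n_tracks)
    W <- base_w * mult
  })
  ground_truth_model(motifs, W, ...)
}

#' Simulate a synthetic regulatory genome
#'
#' Generates `n_windows` background windows with i.i.d. bases at the given GC
#' fraction, plants Poisson-distributed motif instances (sequence sampled
#' from the PWM, random strand and position), and optionally plants one
#' strong activator consensus just upstream of the central TSS anchor of
#' every window so that windows carry promoter-like signal.
#'
#' @param model a `gt_model` supplying the motif vocabulary.
#' @param n_windows number of windows.
#' @param length window length in bp (multiple of the model's bin width).
#' @param gc GC fraction of the background, in (0, 1).
#' @param motif_density expected planted instances per kb.
#' @param seed integer seed.
#' @param tss_motif plant an activator consensus ending 24 bp upstream of the
#'   TSS anchor in every window (default TRUE).
#' @return A list with `windows` (list of [genomic_window()], TSS anchor at
#'   the window center) and `sites` (data.frame of planted instances).
#' @export
simulate_regulatory_genome <- function(model, n_windows, length = NULL,
                                       gc = 0.41, motif_density = 0.5,
                                       seed = 1L, tss_motif = TRUE) {
  stopifnot(inherits(model, "gt_model"))
  length <- as.integer(length %||% model$window_length)
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)", call. = FALSE)
  if (length %% model$bin_width != 0L) {
    stop("length must be a multiple of the model bin width", call. = FALSE)
  }
  if (model$max_motif_len > length) stop("motif longer than window", call. = FALSE)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  anchor <- length %/% 2L
  windows <- vector("list", n_windows)
  sites <- list()
  with_seed(seed, {
    for (i in seq_len(n_windows)) {
      chars <- sample(BASES, length, replace = TRUE, prob = probs)
      wid <- sprintf("w%04d", i)
      add_site <- function(midx, start0, strand, mseq) {
        ins <- strsplit(if (strand == "-") rc_seq(mseq) else mseq, "",
                        fixed = TRUE)[[1L]]
        chars[(start0 + 1L):(start0 + base::length(ins))] <<- ins
        sites[[base::length(sites) + 1L]] <<- data.frame(
          window_id = wid, motif_id = model$motifs[[midx]]$motif_id,
          motif_idx = midx, start0 = start0, strand = strand,
          length = base::length(ins), sequence = mseq,
          stringsAsFactors = FALSE)
      }
      n_sites <- if (motif_density > 0) {
        stats::rpois(1L, motif_density * length / 1000)
      } else 0L
      for (s in seq_len(n_sites)) {
        midx <- sample.int(model$n_motifs, 1L)
        L <- model$motifs[[midx]]$length
        start0 <- sample.int(length - L + 1L, 1L) - 1L
        strand <- sample(c("+", "-"), 1L)
        mseq <- sample_motif(model$motifs[[midx]],
                             seed = stats::runif(1L) * 1e9, mode = "sample")
        add_site(midx, start0, strand, mseq)
      }
      if (isTRUE(tss_motif)) {
        midx <- 1L  # strongest-by-convention activator
        L <- model$motifs[[midx]]$length
        start0 <- anchor - 24L - L
        if (start0 >= 0L) {
          add_site(midx, start0, "+", consensus_sequence(model$motifs[[midx]]))
        }
      }
      windows[[i]] <- genomic_window("chrS", (i - 1L) * length,
                                     paste(chars, collapse = ""),
                                     anchor = anchor, id = wid)
    }
  })
  sites <- if (base::length(sites)) do.call(rbind, sites) else
    data.frame(window_id = character(0), motif_id = character(0),
               motif_idx = integer(0), start0 = integer(0),
               strand = character(0), length = integer(0),
               sequence = character(0), stringsAsFactors = FALSE)
  list(windows = windows, sites = sites)
}

#' Sample Poisson experimental counts from true rates
#'
#' Each bin is drawn independently as Poisson with the given rate, the
#' generative model of the experimental readout.
#'
#' @param rates nonnegative matrix (bins x tracks) or vector of true rates.
#' @param seed integer seed.
#' @return Integer counts with the same shape as `rates`.
#' @export
simulate_track_counts <- function(rates, seed = 1L) {
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  with_seed(seed, {
    counts <- stats::rpois(base::length(rates), as.numeric(rates))
  })
  if (!is.null(dim(rates))) {
    counts <- array(counts, dim = dim(rates), dimnames = dimnames(rates))
  }
  counts
}

#' Simulate an eQTL panel with known true effect signs
#'
#' Positive variants are single-base substitutions inside planted motif
#' instances; their true sign is the sign of the ground-truth SAD score
#' (alternate minus reference, summed over the three bins centered at the
#' variant, on the first track). Negatives are substitutions at background
#' positions with unknown truth. TSS distances (variant offset minus anchor)
#' are recorded for both.
#'
#' @param model the ground-truth `gt_model`.
#' @param windows list of [genomic_window()] from
#'   [simulate_regulatory_genome()].
#' @param sites planted-site table from the same call.
#' @param n_pos,n_neg numbers of positive / negative variants.
#' @param seed integer seed.
#' @return data.frame of variants: variant_id, window_id, gene_id, chrom,
#'   pos (1-based), pos0, ref, alt, tss_distance, true_sign (+1/-1/NA),
#'   is_positive.
#' @export
simulate_eqtls <- function(model, windows, sites, n_pos, n_neg, seed = 1L) {
  stopifnot(inherits(model, "gt_model"))
  if (n_pos > 0L && nrow(sites) == 0L) {
    stop("not enough planted sites to draw positive variants", call. = FALSE)
  }
  win_by_id <- stats::setNames(windows, vapply(windows, function(w) w$id,
                                               character(1)))
  bw <- model$bin_width
  out <- list()
  with_seed(seed, {
    # positives: substitutions inside planted motifs, truth from the oracle.
    # candidates are drawn in batches and evaluated with shared window scans.
    n_drawn <- 0L
    rounds <- 0L
    while (n_drawn < n_pos) {
      rounds <- rounds + 1L
      if (rounds > 40L) {
        stop("could not draw enough positive variants with nonzero ground-truth effect",
             call. = FALSE)
      }
      batch <- list()
      for (k in seq_len(2L * (n_pos - n_drawn))) {
        s <- sites[sample.int(nrow(sites), 1L), ]
        w <- win_by_id[[s$window_id]]
        pos0 <- s$start0 + sample.int(s$length, 1L) - 1L
        # keep the variant clear of the first/last bin (SAD needs neighbors)
        if (pos0 < bw || pos0 >= w$length - bw) next
        ref <- substr(w$sequence, pos0 + 1L, pos0 + 1L)
        if (ref == "N") next
        alt <- sample(setdiff(BASES, ref), 1L)
        batch[[base::length(batch) + 1L]] <- data.frame(
          window_id = w$id, pos0 = pos0, ref = ref, alt = alt,
          stringsAsFactors = FALSE)
      }
      if (base::length(batch) == 0L) next
      batch <- do.call(rbind, batch)
      for (wid in unique(batch$window_id)) {
        rows <- batch[batch$window_id == wid, , drop = FALSE]
        w <- win_by_id[[wid]]
        sads <- .gt_sad_bulk(model, w, rows)
        for (j in seq_len(nrow(rows))) {
          if (sads[j] == 0 || n_drawn >= n_pos) next
          n_drawn <- n_drawn + 1L
          out[[base::length(out) + 1L]] <- data.frame(
            window_id = wid, gene_id = wid, chrom = w$chrom,
            pos = w$start + rows$pos0[j] + 1L, pos0 = rows$pos0[j],
            ref = rows$ref[j], alt = rows$alt[j],
            tss_distance = rows$pos0[j] - w$anchor,
            true_sign = sign(sads[j]), is_positive = TRUE,
            stringsAsFactors = FALSE)
        }
      }
    }
    # negatives: background substitutions (outside planted sites), no truth
    planted <- split(sites, sites$window_id)
    n_drawn <- 0L
    attempts <- 0L
    while (n_drawn < n_neg) {
      attempts <- attempts + 1L
      if (attempts > 500L * max(n_neg, 1L)) {
        stop("could not draw enough negative variants", call. = FALSE)
      }
      w <- windows[[sample.int(base::length(windows), 1L)]]
      pos0 <- sample.int(w$length - 2L * bw, 1L) - 1L + bw
      ps <- planted[[w$id]]
      if (!is.null(ps) &&
          any(pos0 >= ps$start0 & pos0 < ps$start0 + ps$length)) next
      ref <- substr(w$sequence, pos0 + 1L, pos0 + 1L)
      if (ref == "N") next
      alt <- sample(setdiff(BASES, ref), 1L)
      n_drawn <- n_drawn + 1L
      out[[base::length(out) + 1L]] <- data.frame(
        window_id = w$id, gene_id = w$id, chrom = w$chrom,
        pos = w$start + pos0 + 1L, pos0 = pos0, ref = ref, alt = alt,
        tss_distance = pos0 - w$anchor,
        true_sign = NA_real_, is_positive = FALSE, stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, out)
  df <- cbind(variant_id = sprintf("v%04d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  df
}

# Ground-truth SAD scores (robust 6-augmentation, first track) for a batch
# of candidate substitutions in one window, sharing the window scans.
.gt_sad_bulk <- function(model, window, cand) {
  ints <- seq_to_int(window$sequence)
  subs <- lapply(seq_len(nrow(cand)), function(j) {
    stopifnot(BASES[ints[cand$pos0[j] + 1L]] == cand$ref[j])
    list(pos0 = cand$pos0[j], base = match(cand$alt[j], BASES))
  })
  res <- .bulk_robust(model, list(.gt_member(model)), ints, subs_list = subs)
  bw <- window$length %/% res$nb
  vapply(seq_len(nrow(cand)), function(j) {
    i0 <- cand$pos0[j] %/% bw + 1L
    bins <- (i0 - 1L):(i0 + 1L)
    sum(res$subs[[j]][bins, 1L, 1L] - res$base[bins, 1L, 1L])
  }, numeric(1))
}

#' Simulate a phased diploid population with measured expression
#'
#' Haplotype alleles are drawn independently at the stated frequencies (no
#' linkage disequilibrium). Measured expression is the standardized
#' ground-truth individual prediction scaled to variance `h2`, plus Gaussian
#' noise of variance `1 - h2`.
#'
#' @param model the ground-truth `gt_model`.
#' @param window the gene's [genomic_window()] (TSS at the anchor).
#' @param variants data.frame with pos0, ref, alt for the variant panel.
#' @param n_individuals population size.
#' @param allele_freq alternate-allele frequency, scalar or per-variant,
#'   each in (0, 1).
#' @param h2 fraction of expression variance explained by the genetic
#'   prediction, in \[0, 1\].
#' @param seed integer seed.
#' @param track track index used for the expression readout.
#' @return A list with `haplotypes` (individuals x variants x 2 array of 0/1),
#'   `dosage`, `measured` (expression vector) and `truth_prediction` (the
#'   noiseless ground-truth individual predictions).
#' @export
simulate_population <- function(model, window, variants, n_individuals,
                                allele_freq = 0.3, h2 = 0.3, seed = 1L,
                                track = 1L) {
  stopifnot(inherits(model, "gt_model"))
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]", call. = FALSE)
  n_var <- nrow(variants)
  f <- rep_len(allele_freq, n_var)
  if (any(f <= 0 | f >= 1)) stop("allele frequencies must be in (0, 1)",
                                 call. = FALSE)
  with_seed(seed, {
    hap <- array(stats::rbinom(n_individuals * n_var * 2L, 1L,
                               rep(f, each = n_individuals)),
                 dim = c(n_individuals, n_var, 2L))
    noise <- stats::rnorm(n_individuals)
  })
  truth <- predict_population(model, window, variants, hap, track = track)[, 1L]
  s <- stats::sd(truth)
  genetic <- if (is.na(s) || s == 0) {
    if (h2 > 0) warning("ground-truth predictions are constant; genetic component is 0")
    rep(0, n_individuals)
  } else {
    (truth - mean(truth)) / s
  }
  measured <- sqrt(h2) * genetic + sqrt(1 - h2) * noise
  dimnames(hap) <- list(sprintf("ind%03d", seq_len(n_individuals)),
                        variants$variant_id %||% sprintf("v%03d", seq_len(n_var)),
                        c("hap1", "hap2"))
  list(haplotypes = hap, dosage = hap[, , 1L] + hap[, , 2L],
       measured = measured, truth_prediction = truth)
}

#' Draw a variant panel for one gene window
#'
#' Mixes substitutions inside planted motif instances (large true effects)
#' with background substitutions (little or no true effect), yielding genes
#' whose genetic signal strength varies with the planted content sampled.
#' Alternate-allele frequencies are drawn uniformly in the given range.
#'
#' @param window the gene's [genomic_window()].
#' @param sites planted-site table from [simulate_regulatory_genome()]
#'   (rows for other windows are ignored).
#' @param n_variants panel size.
#' @param n_planted maximum number of variants placed inside planted sites
#'   (capped by availability).
#' @param seed integer seed.
#' @param freq_range range of alternate-allele frequencies.
#' @return data.frame with variant_id, window_id, pos0, ref, alt, freq.
#' @export
draw_variant_panel <- function(window, sites, n_variants, n_planted = 2L,
                               seed = 1L, freq_range = c(0.05, 0.5)) {
  stopifnot(inherits(window, "genomic_window"))
  ws <- sites[sites$window_id == window$id, , drop = FALSE]
  with_seed(seed, {
    pos0 <- integer(0)
    if (n_planted > 0L && nrow(ws) > 0L) {
      cand <- unique(unlist(lapply(seq_len(nrow(ws)), function(i)
        ws$start0[i]:(ws$start0[i] + ws$length[i] - 1L))))
      cand <- cand[cand >= 2L * 128L & cand < window$length - 2L * 128L]
      if (base::length(cand)) {
        pos0 <- sample(cand, min(n_planted, base::length(cand)))
      }
    }
    n_bg <- n_variants - base::length(pos0)
    bg_cand <- setdiff((2L * 128L):(window$length - 2L * 128L - 1L), pos0)
    pos0 <- sort(c(pos0, sample(bg_cand, n_bg)))
    ref <- vapply(pos0, function(p) substr(window$sequence, p + 1L, p + 1L),
                  character(1))
    keep <- ref != "N"
    pos0 <- pos0[keep]; ref <- ref[keep]
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
    data.frame(variant_id = sprintf("%s_v%02d", window$id, seq_along(pos0)),
               window_id = window$id, pos0 = pos0, ref = ref, alt = alt,
               freq = stats::runif(base::length(pos0), freq_range[1L],
                                   freq_range[2L]),
               stringsAsFactors = FALSE)
  })
}
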
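# Ground-truth sequence->activity model and its prediction engine.
#
# The model maps a nucleotide window to per-bin, per-track nonnegative
# activity rates:
#
#   rate(bin b, track t) = softplus( s0_t
#        + sum_{PWM matches s} W[motif(s), t] * min(score(s), sat) * exp(-d(s,b)/decay)
#        + idiosyncratic k-mer response (ensemble members only)
#        + smooth positional bias (ensemble members only) )
#
# where matches are PWM hits scored by centered log-odds (log-odds vs the
# background base frequencies minus a per-motif threshold tau_m =
# match_threshold_frac * maximum achievable log-odds; only sites with
# positive centered score contribute) on both strands, and d(s,b) is the bp
# distance from the match center to the bin center; matches farther than
# receptive_field/2 from a bin center contribute nothing to that bin, so
# bases outside a bin's receptive field cannot affect it. s0_t is chosen so
# that softplus(s0_t) equals the baseline rate.

#' Construct a ground-truth regulatory activity model
#'
#' @param motifs list of [pwm_motif()] objects (the regulatory vocabulary).
#' @param weights numeric matrix n_motifs x n_tracks of signed effect weights
#'   (positive = activator, negative = repressor); a vector is treated as a
#'   single-track model.
#' @param baseline_rate expected activity (counts per bin) of motif-free
#'   sequence; scalar or per-track vector.
#' @param decay_scale exponential distance-decay scale in bp for match-to-bin
#'   contributions.
#' @param receptive_field total receptive field per bin in bp; sequence
#'   farther than `receptive_field/2` from a bin center cannot affect it.
#' @param window_length default window length in bp (multiple of `bin_width`).
#' @param bin_width output bin width in bp.
#' @param link_sharpness softplus sharpness beta.
#' @param background background base frequencies (A,C,G,T) for the log-odds.
#' @param kmer_k k-mer order of the ensemble members' idiosyncratic response.
#' @param kmer_amp amplitude multiplier of the idiosyncratic k-mer response
#'   (per unit of ensemble perturbation scale sigma).
#' @param kmer_active number of active k-mers per track in each member's
#'   idiosyncratic response (sparse; the rest have weight 0).
#' @param weight_add_amp standard deviation (per unit sigma) of the additive
#'   component of member weight noise; weights of small magnitude can change
#'   sign between members, emulating replicate disagreement about weak
#'   regulatory effects.
#' @param weak_site_amp standard deviation (per unit sigma) of the members'
#'   gated weak-site response: a site with centered score s below
#'   `site_saturation` additionally contributes
#'   `eta[motif, track] * (1 - s/site_saturation)` for member-specific eta,
#'   so replicates agree on strong (saturated) sites but hold idiosyncratic
#'   opinions about weak or degraded matches.
#' @param match_threshold_frac fraction of a motif's maximum achievable
#'   log-odds used as its match threshold; a site contributes its centered
#'   score (log-odds minus threshold) only when positive.
#' @param site_saturation cap on a site's centered score contribution
#'   (occupancy saturation): strong sites contribute `site_saturation`
#'   regardless of how far above threshold they score, so small changes to a
#'   strong site produce small predicted changes.
#' @param bias_amp amplitude multiplier of the members' smooth positional bias
#'   (per unit of sigma).
#' @param track_ids optional track identifiers.
#' @param assay_class optional per-track assay classes (CAGE, DNASE_ATAC,
#'   TF_CHIP, HISTONE_CHIP).
#' @return An object of class `gt_model`.
#' @export
ground_truth_model <- function(motifs, weights, baseline_rate = 0.5,
                               decay_scale = 384, receptive_field = 2048,
                               window_length = 4096, bin_width = 128,
                               link_sharpness = 1,
                               background = c(0.25, 0.25, 0.25, 0.25),
                               kmer_k = 4L, kmer_amp = 0.6, kmer_active = 12L,
                               weight_add_amp = 1.2, weak_site_amp = 8,
                               bias_amp = 0.1, match_threshold_frac = 0.6,
                               site_saturation = 2.0,
                               track_ids = NULL, assay_class = NULL) {
  stopifnot(length(motifs) >= 1L)
  for (m in motifs) stopifnot(inherits(m, "pwm_motif"))
  if (is.null(dim(weights))) weights <- matrix(weights, ncol = 1L)
  weights <- as.matrix(weights)
  if (nrow(weights) != length(motifs)) {
    stop("weights must have one row per motif", call. = FALSE)
  }
  n_tracks <- ncol(weights)
  if (window_length %% bin_width != 0L) {
    stop("window_length must be a multiple of bin_width", call. = FALSE)
  }
  if (receptive_field > window_length) {
    stop("receptive_field must not exceed window_length", call. = FALSE)
  }
  stopifnot(decay_scale > 0, all(baseline_rate > 0), link_sharpness > 0,
            abs(sum(background) - 1) < 1e-6)
  baseline_rate <- rep_len(baseline_rate, n_tracks)
  track_ids <- track_ids %||% sprintf("track%02d", seq_len(n_tracks))
  assay_class <- assay_class %||%
    rep_len(c("CAGE", "DNASE_ATAC", "TF_CHIP", "HISTONE_CHIP"), n_tracks)
  max_len <- max(vapply(motifs, function(m) m$length, integer(1)))
  if (max_len > window_length) stop("motif longer than window", call. = FALSE)

  # Precompute per-motif log-odds lookup tables (5th column handles N: a huge
  # penalty so any N inside a match window keeps the site below threshold, i.e.
  # N contributes nothing).
  floor_p <- 1e-9
  stopifnot(match_threshold_frac >= 0, match_threshold_frac < 1)
  lo_tabs <- lapply(motifs, function(m) {
    lo <- log(pmax(m$matrix, floor_p)) -
      matrix(log(background), m$length, 4L, byrow = TRUE)
    tau <- match_threshold_frac * sum(apply(lo, 1L, max))
    lo5 <- cbind(lo, rep(-1e9, m$length))
    lo_rc <- lo[m$length:1L, 4L:1L, drop = FALSE]
    lo5_rc <- cbind(lo_rc, rep(-1e9, m$length))
    list(fwd = lo5, rc = lo5_rc, L = m$length, tau = tau)
  })

  structure(list(
    motifs = motifs, weights = weights, baseline_rate = baseline_rate,
    decay_scale = decay_scale, receptive_field = receptive_field,
    window_length = as.integer(window_length), bin_width = as.integer(bin_width),
    link_sharpness = link_sharpness, background = background,
    kmer_k = as.integer(kmer_k), kmer_amp = kmer_amp,
    kmer_active = as.integer(kmer_active), bias_amp = bias_amp,
    weight_add_amp = weight_add_amp, weak_site_amp = weak_site_amp,
    match_threshold_frac = match_threshold_frac,
    site_saturation = site_saturation,
    n_tracks = n_tracks, n_motifs = length(motifs),
    track_ids = track_ids, assay_class = assay_class,
    s0 = inv_softplus(baseline_rate, link_sharpness),
    lo_tabs = lo_tabs, max_motif_len = max_len
  ), class = "gt_model")
}

#' @export
print.gt_model <- function(x, ...) {
  cat(sprintf("<gt_model> %d motifs, %d tracks, window %d bp (%d x %d bp bins)\n",
              x$n_motifs, x$n_tracks, x$window_length,
              x$window_length %/% x$bin_width, x$bin_width))
  cat(sprintf("  receptive field %d bp, decay scale %g bp, baseline rate %s\n",
              x$receptive_field, x$decay_scale,
              paste(signif(x$baseline_rate, 3), collapse = "/")))
  invisible(x)
}

# ---- internal engine -------------------------------------------------------

# Score a motif at the given 1-based starts of an N-extended integer sequence.
.score_starts <- function(lo5, idx5, starts, L) {
  if (length(starts) == 0L) return(numeric(0))
  s <- numeric(length(starts))
  for (j in seq_len(L)) s <- s + lo5[j, idx5[starts + j - 1L]]
  s
}

# Full scan + per-bin summaries for one integer-encoded sequence.
# Returns CT (n_bins x n_motifs motif contribution), KT (n_bins x 4^k k-mer
# counts, NULL when k-mer response is disabled), and the encoded sequence.
.window_cache <- function(model, ints, need_kmer = TRUE) {
  n <- length(ints)
  bw <- model$bin_width
  if (n %% bw != 0L) stop("sequence length must be a multiple of bin_width",
                          call. = FALSE)
  nb <- n %/% bw
  bc <- (seq_len(nb) - 0.5) * bw          # bin centers, bp
  half_rf <- model$receptive_field / 2
  idx5 <- ints
  idx5[is.na(idx5)] <- 5L
  CT <- matrix(0, nb, model$n_motifs)
  GT <- matrix(0, nb, model$n_motifs)   # gated weak-site exposure
  sc_cache <- vector("list", model$n_motifs)  # centered scores at all starts
  for (m in seq_len(model$n_motifs)) {
    tab <- model$lo_tabs[[m]]
    L <- tab$L
    nst <- n - L + 1L
    if (nst < 1L) next
    starts <- seq_len(nst)
    sc_cache[[m]] <- list()
    for (strand in c("fwd", "rc")) {
      sc <- .score_starts(tab[[strand]], idx5, starts, L) - tab$tau
      sc_cache[[m]][[strand]] <- sc
      keep <- which(sc > 0)
      if (length(keep) == 0L) next
      sat <- pmin(sc[keep], model$site_saturation)
      gate <- pmax(0, 1 - sc[keep] / model$site_saturation)
      centers <- (keep - 1L) + L / 2
      D <- abs(outer(centers, bc, "-"))
      Wd <- exp(-D / model$decay_scale) * (D <= half_rf)
      CT[, m] <- CT[, m] + colSums(Wd * sat)
      GT[, m] <- GT[, m] + colSums(Wd * gate)
    }
  }
  KT <- NULL
  kidx <- NULL
  if (need_kmer) {
    k <- model$kmer_k
    nk <- 4L^k
    nks <- n - k + 1L
    kidx <- rep(1L, nks)
    ok <- rep(TRUE, nks)
    for (j in seq_len(k)) {
      b <- ints[j:(j + nks - 1L)]
      ok <- ok & !is.na(b)
      kidx <- kidx + ifelse(is.na(b), 0L, (b - 1L)) * 4L^(k - j)
    }
    kidx[!ok] <- NA_integer_
    anchors <- (seq_len(nks) - 1L) + k %/% 2L
    KT <- matrix(0, nb, nk)
    for (b in seq_len(nb)) {
      sel <- kidx[abs(anchors - bc[b]) <= half_rf]
      sel <- sel[!is.na(sel)]
      if (length(sel)) KT[b, ] <- tabulate(sel, nbins = nk)
    }
  }
  list(ints = ints, idx5 = idx5, n = n, nb = nb, bc = bc, CT = CT, GT = GT,
       KT = KT, kidx = kidx, sc = sc_cache)
}

# Delta summaries for a set of substitutions (pos0 0-based, base integer code;
# NA base = N). Returns dCT (n_bins x n_motifs) and kdelta (data.frame of
# k-mer count changes with the contiguous bin range each affects).
.subs_delta <- function(model, cache, pos0, base) {
  n <- cache$n
  nb <- cache$nb
  bc <- cache$bc
  half_rf <- model$receptive_field / 2
  ints2 <- cache$ints
  ints2[pos0 + 1L] <- base
  idx5_new <- ints2
  idx5_new[is.na(idx5_new)] <- 5L
  dCT <- matrix(0, nb, model$n_motifs)
  dGT <- matrix(0, nb, model$n_motifs)
  for (m in seq_len(model$n_motifs)) {
    tab <- model$lo_tabs[[m]]
    L <- tab$L
    nst <- n - L + 1L
    lo_rng <- pmax(1L, pos0 - L + 2L)
    hi_rng <- pmin(nst, pos0 + 1L)
    ok <- lo_rng <= hi_rng
    if (!any(ok)) next
    starts <- if (length(pos0) == 1L) {
      lo_rng:hi_rng
    } else {
      sort(unique(unlist(mapply(seq.int, lo_rng[ok], hi_rng[ok],
                                SIMPLIFY = FALSE))))
    }
    for (strand in c("fwd", "rc")) {
      # old scores come from the full-scan cache; new scores differ only by
      # the log-odds difference at each substituted motif position
      old <- cache$sc[[m]][[strand]][starts]
      new <- old
      lo5 <- tab[[strand]]
      for (q in seq_along(pos0)) {
        p <- pos0[q]
        j <- p - starts + 2L             # 1-based motif position per start
        hit <- j >= 1L & j <= L
        if (!any(hit)) next
        ob <- cache$idx5[p + 1L]
        nbase <- base[q]
        nb5 <- if (is.na(nbase)) 5L else nbase
        jj <- j[hit]
        new[hit] <- new[hit] + lo5[cbind(jj, rep(nb5, length(jj)))] -
          lo5[cbind(jj, rep(ob, length(jj)))]
      }
      for (which_set in list(list(sc = old, sgn = -1), list(sc = new, sgn = 1))) {
        keep <- which(which_set$sc > 0)
        if (length(keep) == 0L) next
        sat <- pmin(which_set$sc[keep], model$site_saturation)
        gate <- pmax(0, 1 - which_set$sc[keep] / model$site_saturation)
        centers <- (starts[keep] - 1L) + L / 2
        D <- abs(outer(centers, bc, "-"))
        Wd <- exp(-D / model$decay_scale) * (D <= half_rf)
        dCT[, m] <- dCT[, m] + which_set$sgn * colSums(Wd * sat)
        dGT[, m] <- dGT[, m] + which_set$sgn * colSums(Wd * gate)
      }
    }
  }
  dKT <- NULL
  if (!is.null(cache$KT)) {
    k <- model$kmer_k
    nks <- n - k + 1L
    ks <- unique(unlist(lapply(pos0, function(p) {
      lo <- max(1L, p - k + 2L)
      hi <- min(nks, p + 1L)
      if (lo > hi) integer(0) else lo:hi
    })))
    if (length(ks)) {
      old_idx <- cache$kidx[ks]
      new_idx <- vapply(ks, function(s) {
        b <- ints2[s:(s + k - 1L)]
        if (anyNA(b)) NA_integer_ else
          as.integer(1L + sum((b - 1L) * 4L^((k - 1L):0L)))
      }, integer(1))
      anchors <- (ks - 1L) + k %/% 2L
      # contiguous bin range whose center lies within half_rf of the anchor
      blo <- pmax(1L, ceiling((anchors - half_rf) / model$bin_width + 0.5))
      bhi <- pmin(nb, floor((anchors + half_rf) / model$bin_width + 0.5))
      dKT <- matrix(0, nb, 4L^k)
      for (i in seq_along(ks)) {
        if (blo[i] > bhi[i]) next
        rng <- blo[i]:bhi[i]
        if (!is.na(old_idx[i])) dKT[rng, old_idx[i]] <- dKT[rng, old_idx[i]] - 1
        if (!is.na(new_idx[i])) dKT[rng, new_idx[i]] <- dKT[rng, new_idx[i]] + 1
      }
    }
  }
  list(dCT = dCT, dGT = dGT, dKT = dKT, ints = ints2)
}

# Pre-link member score for one cache: s0 + CT %*% W [+ KT %*% eps + bias].
.member_prelink <- function(model, cache, member) {
  nb <- cache$nb
  S <- matrix(model$s0, nb, model$n_tracks, byrow = TRUE) +
    cache$CT %*% member$W
  if (!is.null(member$eta)) S <- S + cache$GT %*% member$eta
  if (!is.null(member$eps) && !is.null(cache$KT)) {
    S <- S + cache$KT %*% member$eps
  }
  if (!is.null(member$bias)) {
    if (nrow(member$bias) != nb) {
      stop("member positional bias was built for a different bin count",
           call. = FALSE)
    }
    S <- S + member$bias
  }
  S
}

# Adjust a pre-link score matrix for a substitution delta.
.apply_delta <- function(S, delta, member) {
  S2 <- S + delta$dCT %*% member$W
  if (!is.null(member$eta)) S2 <- S2 + delta$dGT %*% member$eta
  if (!is.null(member$eps) && !is.null(delta$dKT)) {
    S2 <- S2 + delta$dKT %*% member$eps
  }
  S2
}

.gt_member <- function(model) {
  list(W = model$weights, eps = NULL, eta = NULL, bias = NULL, index = 0L)
}

# The six augmentations: {shift -1, 0, +1} x {forward, reverse complement}.
.augmentations <- function() {
  list(list(shift = -1L, rc = FALSE), list(shift = 0L, rc = FALSE),
       list(shift = 1L, rc = FALSE), list(shift = -1L, rc = TRUE),
       list(shift = 0L, rc = TRUE), list(shift = 1L, rc = TRUE))
}

.shift_ints <- function(ints, shift) {
  n <- length(ints)
  if (shift == 0L) return(ints)
  out <- rep(NA_integer_, n)
  if (shift > 0L) out[(1L + shift):n] <- ints[1L:(n - shift)]
  else out[1L:(n + shift)] <- ints[(1L - shift):n]
  out
}

# Map substitutions (0-based pos, int base) into an augmented frame; drops
# positions shifted off the edge.
.map_subs <- function(pos0, base, n, shift, rc) {
  p <- pos0 + shift
  keep <- p >= 0L & p <= n - 1L
  p <- p[keep]
  b <- base[keep]
  if (rc) {
    p <- n - 1L - p
    b <- ifelse(is.na(b), NA_integer_, 5L - b)
  }
  list(pos0 = p, base = b)
}

# Core bulk predictor. For one window: builds the six augmentation caches,
# evaluates every member on the unmodified window and on each substitution
# set, and returns augmentation-averaged rates. Member parameters are
# concatenated column-wise so that all members are evaluated with single
# matrix products per augmentation.
#
# subs_list: list of data.frames with columns pos0 (0-based) and base
# (integer code, NA = N). Returns list(base = nb x T x M array,
# subs = list of nb x T x M arrays).
.bulk_robust <- function(model, members, ints, subs_list = list(),
                         augment = TRUE) {
  need_kmer <- any(vapply(members, function(m) !is.null(m$eps), logical(1)))
  need_eta <- any(vapply(members, function(m) !is.null(m$eta), logical(1)))
  augs <- if (augment) .augmentations() else list(list(shift = 0L, rc = FALSE))
  n <- length(ints)
  M <- length(members)
  Tn <- model$n_tracks
  nk <- 4L^model$kmer_k
  zW <- function(x, nr) if (is.null(x)) matrix(0, nr, Tn) else x
  Wc <- do.call(cbind, lapply(members, `[[`, "W"))
  etac <- if (need_eta) {
    do.call(cbind, lapply(members, function(m) zW(m$eta, model$n_motifs)))
  } else NULL
  epsc <- if (need_kmer) {
    do.call(cbind, lapply(members, function(m) zW(m$eps, nk)))
  } else NULL
  s0c <- rep(model$s0, M)
  beta <- model$link_sharpness

  caches <- vector("list", length(augs))
  Sbase <- vector("list", length(augs))
  nb <- NULL
  for (a in seq_along(augs)) {
    ai <- .shift_ints(ints, augs[[a]]$shift)
    if (augs[[a]]$rc) ai <- rc_int(ai)
    cache <- .window_cache(model, ai, need_kmer = need_kmer)
    nb <- cache$nb
    S <- matrix(s0c, nb, Tn * M, byrow = TRUE) + cache$CT %*% Wc
    if (!is.null(etac)) S <- S + cache$GT %*% etac
    if (!is.null(epsc)) S <- S + cache$KT %*% epsc
    biasc <- lapply(members, function(m) m$bias)
    if (any(!vapply(biasc, is.null, logical(1)))) {
      if (nrow(biasc[[which(!vapply(biasc, is.null, logical(1)))[1L]]]) != nb) {
        stop("member positional bias was built for a different bin count",
             call. = FALSE)
      }
      S <- S + do.call(cbind, lapply(biasc, function(b)
        if (is.null(b)) matrix(0, nb, Tn) else b))
    }
    caches[[a]] <- cache
    Sbase[[a]] <- S
  }
  to_array <- function(S, rc) {
    r <- softplus(S, beta)
    if (rc) r <- r[nb:1L, , drop = FALSE]
    array(r, dim = c(nb, Tn, M))
  }
  avg_rates <- function(S_by_aug) {
    out <- array(0, dim = c(nb, Tn, M))
    for (a in seq_along(augs)) {
      out <- out + to_array(S_by_aug[[a]], augs[[a]]$rc)
    }
    out / length(augs)
  }
  base <- avg_rates(Sbase)
  subs_out <- vector("list", length(subs_list))
  for (s in seq_along(subs_list)) {
    sb <- subs_list[[s]]
    S_by_aug <- vector("list", length(augs))
    for (a in seq_along(augs)) {
      mp <- .map_subs(sb$pos0, sb$base, n, augs[[a]]$shift, augs[[a]]$rc)
      if (length(mp$pos0) == 0L) {
        S_by_aug[[a]] <- Sbase[[a]]
        next
      }
      delta <- .subs_delta(model, caches[[a]], mp$pos0, mp$base)
      S2 <- Sbase[[a]] + delta$dCT %*% Wc
      if (!is.null(etac)) S2 <- S2 + delta$dGT %*% etac
      if (!is.null(epsc) && !is.null(delta$dKT)) {
        S2 <- S2 + delta$dKT %*% epsc
      }
      S_by_aug[[a]] <- S2
    }
    subs_out[[s]] <- avg_rates(S_by_aug)
  }
  dimnames(base) <- list(NULL, model$track_ids, NULL)
  list(base = base, subs = subs_out, nb = nb)
}

# Variant-set bulk predictor: evaluates many substitution SETS drawn from a
# small pool of single-base variants (personal haplotypes). Per augmentation,
# the prediction delta of each pool variant is computed once; a set's pre-link
# score is the base score plus the sum of its variants' deltas, which is exact
# whenever the set's variants are farther apart than the longest motif (no
# shared site or k-mer window). Sets containing clustered variants fall back
# to a joint recomputation.
.bulk_robust_sets <- function(model, members, ints, var_pos0, var_base, sets,
                              augment = TRUE) {
  need_kmer <- any(vapply(members, function(m) !is.null(m$eps), logical(1)))
  need_eta <- any(vapply(members, function(m) !is.null(m$eta), logical(1)))
  augs <- if (augment) .augmentations() else list(list(shift = 0L, rc = FALSE))
  n <- length(ints)
  M <- length(members)
  Tn <- model$n_tracks
  nk <- 4L^model$kmer_k
  zW <- function(x, nr) if (is.null(x)) matrix(0, nr, Tn) else x
  Wc <- do.call(cbind, lapply(members, `[[`, "W"))
  etac <- if (need_eta) {
    do.call(cbind, lapply(members, function(m) zW(m$eta, model$n_motifs)))
  } else NULL
  epsc <- if (need_kmer) {
    do.call(cbind, lapply(members, function(m) zW(m$eps, nk)))
  } else NULL
  s0c <- rep(model$s0, M)
  beta <- model$link_sharpness

  # interaction clusters: variants closer than the longest motif can share a
  # site window, so their deltas are not additive
  ord <- order(var_pos0)
  cluster <- integer(length(var_pos0))
  cid <- 0L
  last <- -Inf
  for (i in ord) {
    if (var_pos0[i] - last > model$max_motif_len) cid <- cid + 1L
    cluster[i] <- cid
    last <- var_pos0[i]
  }
  set_joint <- vapply(sets, function(idx) anyDuplicated(cluster[idx]) > 0L,
                      logical(1))

  nb <- NULL
  base_acc <- NULL
  subs_acc <- NULL
  for (a in seq_along(augs)) {
    aug <- augs[[a]]
    ai <- .shift_ints(ints, aug$shift)
    if (aug$rc) ai <- rc_int(ai)
    cache <- .window_cache(model, ai, need_kmer = need_kmer)
    nb <- cache$nb
    S <- matrix(s0c, nb, Tn * M, byrow = TRUE) + cache$CT %*% Wc
    if (!is.null(etac)) S <- S + cache$GT %*% etac
    if (!is.null(epsc)) S <- S + cache$KT %*% epsc
    biasc <- lapply(members, function(m) m$bias)
    if (any(!vapply(biasc, is.null, logical(1)))) {
      S <- S + do.call(cbind, lapply(biasc, function(b)
        if (is.null(b)) matrix(0, nb, Tn) else b))
    }
    if (is.null(base_acc)) {
      base_acc <- array(0, dim = c(nb, Tn, M))
      subs_acc <- lapply(sets, function(x) array(0, dim = c(nb, Tn, M)))
    }
    to_arr <- function(Sx) {
      r <- softplus(Sx, beta)
      if (aug$rc) r <- r[nb:1L, , drop = FALSE]
      array(r, dim = c(nb, Tn, M))
    }
    base_acc <- base_acc + to_arr(S)
    # per-variant pre-link deltas in this augmentation frame
    dS_v <- vector("list", length(var_pos0))
    for (v in seq_along(var_pos0)) {
      mp <- .map_subs(var_pos0[v], var_base[v], n, aug$shift, aug$rc)
      if (length(mp$pos0) == 0L) {
        dS_v[[v]] <- 0
        next
      }
      delta <- .subs_delta(model, cache, mp$pos0, mp$base)
      d <- delta$dCT %*% Wc
      if (!is.null(etac)) d <- d + delta$dGT %*% etac
      if (!is.null(epsc) && !is.null(delta$dKT)) d <- d + delta$dKT %*% epsc
      dS_v[[v]] <- d
    }
    for (si in seq_along(sets)) {
      idx <- sets[[si]]
      if (length(idx) == 0L) {
        subs_acc[[si]] <- subs_acc[[si]] + to_arr(S)
        next
      }
      if (set_joint[si]) {
        mp <- .map_subs(var_pos0[idx], var_base[idx], n, aug$shift, aug$rc)
        if (length(mp$pos0) == 0L) {
          subs_acc[[si]] <- subs_acc[[si]] + to_arr(S)
          next
        }
        delta <- .subs_delta(model, cache, mp$pos0, mp$base)
        S2 <- S + delta$dCT %*% Wc
        if (!is.null(etac)) S2 <- S2 + delta$dGT %*% etac
        if (!is.null(epsc) && !is.null(delta$dKT)) {
          S2 <- S2 + delta$dKT %*% epsc
        }
      } else {
        S2 <- S
        for (v in idx) S2 <- S2 + dS_v[[v]]
      }
      subs_acc[[si]] <- subs_acc[[si]] + to_arr(S2)
    }
  }
  na <- length(augs)
  dimnames(base_acc) <- list(NULL, model$track_ids, NULL)
  list(base = base_acc / na, subs = lapply(subs_acc, function(x) x / na),
       nb = nb)
}

# ---- user-facing prediction ------------------------------------------------

#' Predict per-bin activity rates for a window
#'
#' Single forward-strand prediction (no augmentation averaging); see
#' [robust_predict()] for the augmentation-averaged version used throughout
#' the analyses.
#'
#' @param object a predictor: a `gt_model`, an `ensemble_member`, a
#'   `replicate_ensemble`, or a function mapping a [genomic_window()] to a
#'   bins x tracks matrix.
#' @param window a [genomic_window()].
#' @param ... unused.
#' @return bins x tracks matrix of nonnegative rates (for an ensemble, a
#'   bins x tracks x M array).
#' @export
predict_tracks <- function(object, window, ...) UseMethod("predict_tracks")

#' @export
predict_tracks.gt_model <- function(object, window, ...) {
  ints <- seq_to_int(window$sequence)
  res <- .bulk_robust(object, list(.gt_member(object)), ints, augment = FALSE)
  out <- res$base[, , 1L, drop = FALSE]
  dim(out) <- dim(res$base)[1:2]
  colnames(out) <- object$track_ids
  attr(out, "bin_width") <- object$bin_width
  out
}

#' @export
predict_tracks.ensemble_member <- function(object, window, ...) {
  model <- object$model
  ints <- seq_to_int(window$sequence)
  res <- .bulk_robust(model, list(object$params), ints, augment = FALSE)
  out <- res$base[, , 1L, drop = FALSE]
  dim(out) <- dim(res$base)[1:2]
  colnames(out) <- model$track_ids
  attr(out, "bin_width") <- model$bin_width
  out
}

#' @export
predict_tracks.replicate_ensemble <- function(object, window, ...) {
  ints <- seq_to_int(window$sequence)
  res <- .bulk_robust(object$model, object$members, ints, augment = FALSE)
  attr(res$base, "bin_width") <- object$model$bin_width
  res$base
}

#' @export
predict_tracks.function <- function(object, window, ...) {
  out <- object(window)
  if (is.null(dim(out))) out <- matrix(out, ncol = 1L)
  out
}

#' Ground-truth activity prediction for a window
#'
#' Convenience wrapper around [predict_tracks()] for the ground-truth model.
#'
#' @param model a `gt_model`.
#' @param window a [genomic_window()].
#' @return bins x tracks matrix of strictly positive rates.
#' @export
ground_truth_predict <- function(model, window) {
  stopifnot(inherits(model, "gt_model"))
  predict_tracks(model, window)
}

#' @export
predict.gt_model <- function(object, window, ...) predict_tracks(object, window)

#' Augmentation-averaged prediction
#'
#' Averages six predictions: sequence shifts of -1, 0 and +1 bp, each on the
#' forward and the reverse-complement strand. Reverse-complement outputs are
#' returned to forward bin order before averaging; shifted windows are padded
#' with N at the vacated edge.
#'
#' @param predictor a `gt_model`, `ensemble_member`, `replicate_ensemble`, or
#'   a function mapping a [genomic_window()] to a bins x tracks matrix.
#' @param window a [genomic_window()].
#' @param ... unused.
#' @return bins x tracks matrix (bins x tracks x M array for an ensemble).
#' @export
robust_predict <- function(predictor, window, ...) UseMethod("robust_predict")

#' @export
robust_predict.gt_model <- function(predictor, window, ...) {
  ints <- seq_to_int(window$sequence)
  res <- .bulk_robust(predictor, list(.gt_member(predictor)), ints)
  out <- res$base[, , 1L, drop = FALSE]
  dim(out) <- dim(res$base)[1:2]
  colnames(out) <- predictor$track_ids
  attr(out, "bin_width") <- predictor$bin_width
  out
}

#' @export
robust_predict.ensemble_member <- function(predictor, window, ...) {
  model <- predictor$model
  ints <- seq_to_int(window$sequence)
  res <- .bulk_robust(model, list(predictor$params), ints)
  out <- res$base[, , 1L, drop = FALSE]
  dim(out) <- dim(res$base)[1:2]
  colnames(out) <- model$track_ids
  attr(out, "bin_width") <- model$bin_width
  out
}

#' @export
robust_predict.replicate_ensemble <- function(predictor, window, ...) {
  ints <- seq_to_int(window$sequence)
  res <- .bulk_robust(predictor$model, predictor$members, ints)
  attr(res$base, "bin_width") <- predictor$model$bin_width
  res$base
}

#' @export
robust_predict.function <- function(predictor, window, ...) {
  acc <- NULL
  n_aug <- 0L
  for (aug in .augmentations()) {
    w <- shift_window(window, aug$shift)
    if (aug$rc) w <- reverse_complement(w)
    p <- predict_tracks(predictor, w)
    if (aug$rc) p <- p[nrow(p):1L, , drop = FALSE]
    acc <- if (is.null(acc)) p else acc + p
    n_aug <- n_aug + 1L
  }
  acc / n_aug
}

#' In-silico substitution attributions for a predictor
#'
#' Per-nucleotide attribution by substitution: for each position, the mean
#' absolute change in the anchor-proximal output (the mean of the ten central
#' bins of the chosen track) over the three alternative bases. This is the
#' mock-predictor analogue of a gradient saliency map; positions holding N
#' get attribution 0.
#'
#' @param predictor a model-backed predictor or a plain function.
#' @param window a [genomic_window()].
#' @param track track index for the output statistic.
#' @return A positions x members matrix of nonnegative attributions (one
#'   column for non-ensemble predictors).
#' @export
ism_attributions <- function(predictor, window, track = 1L) {
  UseMethod("ism_attributions")
}

.central10_stat <- function(rates, track) {
  nb <- nrow(rates)
  if (nb < 10L) stop("need at least 10 bins for the central-ten statistic",
                     call. = FALSE)
  lo <- nb %/% 2L - 4L
  mean(rates[lo:(lo + 9L), track])
}

.ism_model_backed <- function(model, members, window, track) {
  ints <- seq_to_int(window$sequence)
  cache <- .window_cache(model, ints,
                         need_kmer = any(vapply(members, function(m)
                           !is.null(m$eps), logical(1))))
  beta <- model$link_sharpness
  Sbase <- lapply(members, function(mem) .member_prelink(model, cache, mem))
  stat0 <- vapply(Sbase, function(S) .central10_stat(softplus(S, beta), track),
                  numeric(1))
  n <- length(ints)
  M <- length(members)
  out <- matrix(0, n, M)
  for (p in seq_len(n)) {
    b0 <- ints[p]
    if (is.na(b0)) next
    alts <- setdiff(1:4, b0)
    for (b in alts) {
      delta <- .subs_delta(model, cache, p - 1L, b)
      for (m in seq_len(M)) {
        S2 <- .apply_delta(Sbase[[m]], delta, members[[m]])
        out[p, m] <- out[p, m] +
          abs(.central10_stat(softplus(S2, beta), track) - stat0[m])
      }
    }
  }
  out / 3
}

#' @export
ism_attributions.gt_model <- function(predictor, window, track = 1L) {
  .ism_model_backed(predictor, list(.gt_member(predictor)), window, track)
}

#' @export
ism_attributions.replicate_ensemble <- function(predictor, window, track = 1L) {
  .ism_model_backed(predictor$model, predictor$members, window, track)
}

#' @export
ism_attributions.ensemble_member <- function(predictor, window, track = 1L) {
  .ism_model_backed(predictor$model, list(predictor$params), window, track)
}

#' @export
ism_attributions.function <- function(predictor, window, track = 1L) {
  chars <- strsplit(window$sequence, "", fixed = TRUE)[[1L]]
  stat0 <- .central10_stat(predict_tracks(predictor, window), track)
  out <- numeric(window$length)
  for (p in seq_along(chars)) {
    if (chars[p] == "N") next
    alts <- setdiff(BASES, chars[p])
    acc <- 0
    for (b in alts) {
      w2 <- substitute_bases(window, p - 1L, b)
      acc <- acc + abs(.central10_stat(predict_tracks(predictor, w2), track) - stat0)
    }
    out[p] <- acc / 3
  }
  matrix(out, ncol = 1L)
}
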
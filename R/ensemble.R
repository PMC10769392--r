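# Seed-perturbed replicate predictors emulating a deep ensemble trained with
# different random seeds: all members share the ground-truth motif vocabulary
# but differ in (i) multiplicative lognormal noise on effect weights,
# (ii) a sparse idiosyncratic k-mer response (each member responds to a small
# random set of k-mers no other member cares about - the analogue of
# replicate-specific spurious features learned from the same data), and
# (iii) a smooth positional bias. All three components scale with sigma and
# vanish exactly at sigma = 0, so a zero-noise ensemble collapses to M
# identical copies of the ground truth.

#' Build an ensemble of seed-perturbed replicate predictors
#'
#' Member i replaces each ground-truth effect weight w by
#' `w * exp(sigma * z1) + sigma * weight_add_amp * z2` with z1, z2 standard
#' normal drawn from seed i (the additive part lets members disagree on the
#' sign of weak effects), adds an independently seeded
#' idiosyncratic k-mer response (a sparse random set of k-mers per track with
#' weight standard deviation `sigma * kmer_amp`, additive pre-link and not decayed
#' within the receptive field), and a low-amplitude smooth positional bias
#' (sinusoidal, amplitude `sigma * bias_amp`). Members are pure functions:
#' the same input always yields the same output.
#'
#' @param model a [ground_truth_model()].
#' @param M number of replicates (>= 2).
#' @param sigma perturbation scale (>= 0); 0 makes every member identical to
#'   the ground truth.
#' @param seeds optional vector of M distinct integer seeds (default
#'   `1:M` offset by 1000).
#' @return An object of class `replicate_ensemble`.
#' @export
make_replicate_ensemble <- function(model, M = 5L, sigma = 0.25, seeds = NULL) {
  stopifnot(inherits(model, "gt_model"))
  if (M < 2L) stop("consistency analysis requires M >= 2 replicates", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  seeds <- seeds %||% (1000L + seq_len(M))
  if (length(seeds) != M) stop("need one seed per replicate", call. = FALSE)
  if (anyDuplicated(seeds)) stop("duplicate replicate seeds", call. = FALSE)
  nb <- model$window_length %/% model$bin_width
  nk <- 4L^model$kmer_k
  members <- lapply(seq_len(M), function(i) {
    with_seed(seeds[i], {
      Z <- matrix(stats::rnorm(model$n_motifs * model$n_tracks),
                  model$n_motifs, model$n_tracks)
      Z2 <- matrix(stats::rnorm(model$n_motifs * model$n_tracks),
                   model$n_motifs, model$n_tracks)
      W <- model$weights * exp(sigma * Z) +
        sigma * model$weight_add_amp * Z2
      eps <- NULL
      bias <- NULL
      eta <- NULL
      if (sigma > 0) {
        eta <- matrix(stats::rnorm(model$n_motifs * model$n_tracks),
                      model$n_motifs, model$n_tracks) *
          (sigma * model$weak_site_amp)
        # sparse idiosyncratic response: kmer_active k-mers per track, weights
        # centered to zero mean so members mostly differ in shape, not level
        eps <- matrix(0, nk, model$n_tracks)
        for (t in seq_len(model$n_tracks)) {
          act <- sample.int(nk, min(model$kmer_active, nk))
          wgt <- stats::rnorm(base::length(act)) * (sigma * model$kmer_amp)
          eps[act, t] <- wgt - mean(wgt)
        }
        freq <- sample(1:3, model$n_tracks, replace = TRUE)
        phase <- stats::runif(model$n_tracks)
        bias <- sapply(seq_len(model$n_tracks), function(t) {
          sigma * model$bias_amp *
            sin(2 * pi * (freq[t] * seq_len(nb) / nb + phase[t]))
        })
        bias <- matrix(bias, nb, model$n_tracks)
      }
      list(W = W, eps = eps, eta = eta, bias = bias, index = i,
           seed = seeds[i])
    })
  })
  structure(list(model = model, M = as.integer(M), sigma = sigma,
                 seeds = as.integer(seeds), members = members),
            class = "replicate_ensemble")
}

#' @export
print.replicate_ensemble <- function(x, ...) {
  cat(sprintf("<replicate_ensemble> M = %d, sigma = %g, seeds = %s\n",
              x$M, x$sigma, paste(x$seeds, collapse = ",")))
  print(x$model)
  invisible(x)
}

#' Extract one replicate as a standalone predictor
#'
#' @param ensemble a [make_replicate_ensemble()] object.
#' @param i replicate index in `1:M`.
#' @return An object of class `ensemble_member` usable wherever a predictor
#'   is expected.
#' @export
ensemble_member <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "replicate_ensemble"),
            i >= 1L, i <= ensemble$M)
  structure(list(model = ensemble$model, params = ensemble$members[[i]],
                 index = as.integer(i), seed = ensemble$seeds[i]),
            class = "ensemble_member")
}

#' @export
print.ensemble_member <- function(x, ...) {
  cat(sprintf("<ensemble_member> replicate %d (seed %d)\n", x$index, x$seed))
  invisible(x)
}

#' @export
predict.replicate_ensemble <- function(object, window, ...) {
  predict_tracks(object, window)
}

#' Simulate experimental counts from a model's predicted rates
#'
#' `simulate()` for a ground-truth model: Poisson counts at the model's
#' predicted per-bin rates for a window.
#'
#' @param object a `gt_model`.
#' @param nsim number of count matrices to draw.
#' @param seed integer seed.
#' @param window a [genomic_window()].
#' @param ... unused.
#' @return A list of `nsim` integer matrices (bins x tracks).
#' @export
simulate.gt_model <- function(object, nsim = 1, seed = 1L, window, ...) {
  rates <- predict_tracks(object, window)
  lapply(seq_len(nsim), function(i)
    simulate_track_counts(rates, seed = derive_seed(seed, i)))
}
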
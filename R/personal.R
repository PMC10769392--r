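# Personal-genome analysis: haplotype construction, per-individual expression
# prediction, cross-individual correlations, gene-uncertainty ranking and
# driver-variant identification.

#' Build the two personal haplotype windows for one individual
#'
#' Each haplotype is the reference window with that haplotype's phased
#' alternate alleles substituted (SNVs only, so lengths are unchanged).
#'
#' @param reference_window the reference [genomic_window()].
#' @param hap_alleles variants x 2 matrix of 0/1 alternate-allele indicators
#'   (phased; column 1 = hap1).
#' @param variants data.frame with pos0 (0-based offset), ref, alt.
#' @return A list with `hap1` and `hap2` [genomic_window()] objects.
#' @export
build_haplotypes <- function(reference_window, hap_alleles, variants) {
  stopifnot(inherits(reference_window, "genomic_window"))
  hap_alleles <- matrix(hap_alleles, ncol = 2L)
  stopifnot(nrow(hap_alleles) == nrow(variants))
  for (i in seq_len(nrow(variants))) {
    have <- substr(reference_window$sequence, variants$pos0[i] + 1L,
                   variants$pos0[i] + 1L)
    if (have != variants$ref[i]) {
      stop(sprintf("reference mismatch at offset %d: window has %s, expected %s",
                   variants$pos0[i], have, variants$ref[i]), call. = FALSE)
    }
  }
  make_hap <- function(col) {
    idx <- which(hap_alleles[, col] == 1L)
    w <- substitute_bases(reference_window, variants$pos0[idx],
                          variants$alt[idx])
    w$id <- sprintf("%s_hap%d", reference_window$id, col)
    w
  }
  list(hap1 = make_hap(1L), hap2 = make_hap(2L))
}

#' Predict an individual's expression from its two haplotypes
#'
#' Per haplotype, the augmentation-averaged prediction is averaged over the
#' ten central bins surrounding the TSS junction (five on each side); the
#' individual value is the mean of the two haplotype values.
#'
#' @param predictor a predictor (see [robust_predict()]).
#' @param hap1,hap2 haplotype [genomic_window()] objects.
#' @param track track index of the expression readout.
#' @return A single value, or a vector of M values for a
#'   `replicate_ensemble`.
#' @export
predict_individual <- function(predictor, hap1, hap2, track = 1L) {
  hap_value <- function(w) {
    p <- robust_predict(predictor, w)
    nb <- dim(p)[1L]
    if (nb < 10L) stop("need at least 10 bins", call. = FALSE)
    lo <- nb %/% 2L - 4L
    bins <- lo:(lo + 9L)
    if (base::length(dim(p)) == 3L) {
      apply(p[bins, track, , drop = FALSE], 3L, mean)
    } else {
      mean(p[bins, track])
    }
  }
  (hap_value(hap1) + hap_value(hap2)) / 2
}

#' Per-individual predictions for a whole population
#'
#' Batch equivalent of [build_haplotypes()] + [predict_individual()]:
#' reference augmentation scans are computed once and each distinct haplotype
#' is applied as an incremental substitution set, shared across replicates.
#'
#' @param predictor a `replicate_ensemble` or `gt_model`.
#' @param window the reference [genomic_window()].
#' @param variants data.frame with pos0, ref, alt.
#' @param haplotypes individuals x variants x 2 array of 0/1 alternate-allele
#'   indicators.
#' @param track track index of the expression readout.
#' @return individuals x replicates matrix of predicted expression.
#' @export
predict_population <- function(predictor, window, variants, haplotypes,
                               track = 1L) {
  if (inherits(predictor, "replicate_ensemble")) {
    model <- predictor$model
    members <- predictor$members
  } else if (inherits(predictor, "gt_model")) {
    model <- predictor
    members <- list(.gt_member(predictor))
  } else stop("predictor must be a replicate_ensemble or gt_model", call. = FALSE)
  n_ind <- dim(haplotypes)[1L]
  n_var <- dim(haplotypes)[2L]
  stopifnot(n_var == nrow(variants))
  ints <- seq_to_int(window$sequence)
  for (i in seq_len(n_var)) {
    if (BASES[ints[variants$pos0[i] + 1L]] != variants$ref[i]) {
      stop(sprintf("reference mismatch at offset %d", variants$pos0[i]),
           call. = FALSE)
    }
  }
  alt_base <- match(variants$alt, BASES)
  # deduplicate haplotype patterns across individuals and chromosome copies
  pat <- matrix(NA_character_, n_ind, 2L)
  for (h in 1:2) {
    pat[, h] <- apply(matrix(haplotypes[, , h], n_ind, n_var), 1L, paste,
                      collapse = "")
  }
  uniq <- unique(as.vector(pat))
  sets <- lapply(uniq, function(key) {
    which(strsplit(key, "", fixed = TRUE)[[1L]] == "1")
  })
  res <- .bulk_robust_sets(model, members, ints, variants$pos0, alt_base,
                           sets)
  nb <- res$nb
  if (nb < 10L) stop("need at least 10 bins", call. = FALSE)
  lo <- nb %/% 2L - 4L
  bins <- lo:(lo + 9L)
  M <- base::length(members)
  hap_values <- matrix(NA_real_, base::length(uniq), M)
  for (u in seq_along(uniq)) {
    hap_values[u, ] <- apply(res$subs[[u]][bins, track, , drop = FALSE], 3L, mean)
  }
  rownames(hap_values) <- uniq
  (hap_values[pat[, 1L], , drop = FALSE] +
      hap_values[pat[, 2L], , drop = FALSE]) / 2
}

#' Cross-individual correlation
#'
#' Spearman correlation (average ranks for ties) between predicted and
#' measured expression across individuals. Returns NA with a warning when
#' either vector is constant.
#'
#' @param predicted,measured numeric vectors over the same >= 3 individuals.
#' @return Spearman rho in \[-1, 1\], or NA.
#' @export
cross_individual_correlation <- function(predicted, measured) {
  if (base::length(predicted) != base::length(measured)) {
    stop("length mismatch between predictions and measurements", call. = FALSE)
  }
  if (base::length(predicted) < 3L) stop("need at least 3 individuals", call. = FALSE)
  if (stats::sd(predicted) == 0 || stats::sd(measured) == 0) {
    warning("constant vector; cross-individual correlation undefined")
    return(NA_real_)
  }
  stats::cor(predicted, measured, method = "spearman")
}

#' Gene uncertainty from replicate cross-individual correlations
#'
#' For each gene, the variance and mean magnitude of the M replicate
#' correlations, the eligibility gate (mean magnitude >= `min_abs_rho`), and
#' the count of replicates with positive correlation. Genes with undefined
#' correlations are ineligible and UNCLASSIFIED.
#'
#' @param rho genes x replicates matrix of Spearman correlations.
#' @param gene_ids optional identifiers.
#' @param min_abs_rho eligibility threshold on mean |rho| (default 0.1).
#' @return data.frame with gene_id, per-replicate rhos, variance_rho,
#'   mean_abs_rho, n_positive, eligible and uncertainty_class.
#' @export
gene_uncertainty_table <- function(rho, gene_ids = NULL, min_abs_rho = 0.1) {
  rho <- as.matrix(rho)
  if (ncol(rho) < 2L) stop("need at least 2 replicates", call. = FALSE)
  gene_ids <- gene_ids %||% rownames(rho) %||% sprintf("g%04d", seq_len(nrow(rho)))
  variance_rho <- apply(rho, 1L, stats::var)
  mean_abs_rho <- rowMeans(abs(rho))
  ok <- !apply(rho, 1L, anyNA)
  out <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  colnames(rho) <- sprintf("rho_rep%d", seq_len(ncol(rho)))
  out <- cbind(out, rho)
  out$variance_rho <- ifelse(ok, variance_rho, NA_real_)
  out$mean_abs_rho <- ifelse(ok, mean_abs_rho, NA_real_)
  out$n_positive <- rowSums(rho > 0, na.rm = TRUE)
  out$eligible <- ok & !is.na(mean_abs_rho) & mean_abs_rho >= min_abs_rho
  out$uncertainty_class <- "UNCLASSIFIED"
  rownames(out) <- NULL
  out
}

#' Select highest- and lowest-uncertainty genes
#'
#' Among eligible genes only, the top and bottom `n` by correlation variance
#' (ties broken by gene id). If fewer than `2n` genes are eligible, the pool
#' is split in half with a warning.
#'
#' @param table a [gene_uncertainty_table()] result.
#' @param n genes per extreme (default 100).
#' @return A list with `high` and `low` gene-id vectors and `table` with
#'   `uncertainty_class` filled in (HIGH / LOW / UNCLASSIFIED).
#' @export
select_uncertainty_extremes <- function(table, n = 100L) {
  el <- table[table$eligible, , drop = FALSE]
  pool <- nrow(el)
  if (pool < 2L * n) {
    warning(sprintf("only %d eligible genes for 2 x %d requested; splitting the pool",
                    pool, n))
    n_high <- pool %/% 2L
    n_low <- pool - n_high
  } else {
    n_high <- n_low <- n
  }
  ord_desc <- order(-el$variance_rho, el$gene_id)
  ord_asc <- order(el$variance_rho, el$gene_id)
  high <- el$gene_id[ord_desc][seq_len(n_high)]
  low <- el$gene_id[ord_asc][seq_len(n_low)]
  table$uncertainty_class[table$gene_id %in% high] <- "HIGH"
  table$uncertainty_class[table$gene_id %in% low] <- "LOW"
  list(high = high, low = low, table = table)
}

#' Ensemble prediction by mean expression rank
#'
#' Averages an individual's within-replicate prediction rank across all
#' replicates, the rank-based ensemble used for cross-individual comparison.
#'
#' @param predictions individuals x replicates matrix.
#' @return Numeric vector of mean ranks per individual.
#' @export
ensemble_mean_rank <- function(predictions) {
  predictions <- as.matrix(predictions)
  rowMeans(apply(predictions, 2L, rank))
}

#' Identify driver variants for one gene and one replicate
#'
#' Ranks variants by the squared Pearson correlation between allele dosage
#' and the replicate's individual predictions, then greedily accepts them in
#' rank order while the cumulative explained variance (R-squared of the
#' regression of predictions on the accepted dosages) grows by at least
#' `delta`, up to `max_drivers`. This reconstructs a forward-selection
#' variance-decomposition driver definition; `delta` and the cap are exposed
#' because the criterion admits variants.
#'
#' @param predictions numeric vector of per-individual predictions (>= 3).
#' @param dosage individuals x variants matrix of allele dosages (0/1/2).
#' @param variant_ids optional identifiers (default column names).
#' @param delta minimum increment in explained variance to accept a driver.
#' @param max_drivers cap on drivers per gene (default 6).
#' @return data.frame with variant_id, rank, variance_explained (marginal
#'   r-squared, non-increasing in rank) and cumulative_r2; zero rows when the
#'   predictions are constant (flagged with a warning).
#' @export
identify_drivers <- function(predictions, dosage, variant_ids = NULL,
                             delta = 0.05, max_drivers = 6L) {
  dosage <- as.matrix(dosage)
  if (base::length(predictions) < 3L) stop("need at least 3 individuals", call. = FALSE)
  stopifnot(nrow(dosage) == base::length(predictions))
  variant_ids <- variant_ids %||% colnames(dosage) %||%
    sprintf("v%03d", seq_len(ncol(dosage)))
  empty <- data.frame(variant_id = character(0), rank = integer(0),
                      variance_explained = numeric(0),
                      cumulative_r2 = numeric(0), stringsAsFactors = FALSE)
  if (stats::sd(predictions) == 0) {
    warning("constant prediction vector; no drivers identified")
    return(empty)
  }
  r2 <- apply(dosage, 2L, function(d) {
    if (stats::sd(d) == 0) return(0)
    stats::cor(d, predictions)^2
  })
  ord <- order(-r2, variant_ids)
  accepted <- integer(0)
  cum <- numeric(0)
  r2_cur <- 0
  for (j in ord) {
    if (base::length(accepted) >= max_drivers) break
    X <- dosage[, c(accepted, j), drop = FALSE]
    fit <- stats::lm.fit(cbind(1, X), predictions)
    r2_new <- 1 - sum(fit$residuals^2) /
      sum((predictions - mean(predictions))^2)
    if (r2_new - r2_cur >= delta) {
      accepted <- c(accepted, j)
      cum <- c(cum, r2_new)
      r2_cur <- r2_new
    } else break
  }
  if (base::length(accepted) == 0L) return(empty)
  data.frame(variant_id = variant_ids[accepted],
             rank = seq_along(accepted),
             variance_explained = r2[accepted],
             cumulative_r2 = cum, stringsAsFactors = FALSE)
}

#' Driver reproducibility and sign concordance across replicates
#'
#' A driver's reproducibility is the number of replicates whose driver set
#' contains it (matched by variant identity). For drivers found by at least
#' `min_found` replicates, the sign-agreement table counts how many of the M
#' replicates agree on the variant's SAD score sign (the modal sign count).
#' Both tables are stratified by the gene's uncertainty class.
#'
#' @param drivers data.frame with columns gene_id, replicate, variant_id
#'   (one row per driver per replicate).
#' @param sad_signs data.frame with columns gene_id, variant_id, replicate,
#'   sign (per-replicate SAD signs of the candidate variants).
#' @param gene_classes data.frame with gene_id and uncertainty_class.
#' @param M number of replicates.
#' @param min_found minimum replicates identifying a driver for the
#'   sign-agreement table (default 3).
#' @return A list with `reproducibility` (gene_id, variant_id, n_replicates,
#'   uncertainty_class) and `sign_agreement` (adds n_sign_agree).
#' @export
driver_concordance <- function(drivers, sad_signs, gene_classes, M,
                               min_found = 3L) {
  cls <- stats::setNames(gene_classes$uncertainty_class, gene_classes$gene_id)
  key <- paste(drivers$gene_id, drivers$variant_id, sep = "\r")
  reps_per <- tapply(drivers$replicate, key, function(r)
    base::length(unique(r)))
  parts <- strsplit(names(reps_per), "\r", fixed = TRUE)
  repro <- data.frame(
    gene_id = vapply(parts, `[`, character(1), 1L),
    variant_id = vapply(parts, `[`, character(1), 2L),
    n_replicates = as.integer(reps_per), stringsAsFactors = FALSE)
  repro$uncertainty_class <- unname(cls[repro$gene_id])
  rownames(repro) <- NULL
  sel <- repro[repro$n_replicates >= min_found, , drop = FALSE]
  agree <- integer(nrow(sel))
  for (i in seq_len(nrow(sel))) {
    s <- sad_signs$sign[sad_signs$gene_id == sel$gene_id[i] &
                          sad_signs$variant_id == sel$variant_id[i]]
    agree[i] <- if (base::length(s)) max(table(sign(s))) else NA_integer_
  }
  sign_agreement <- cbind(sel, n_sign_agree = agree)
  rownames(sign_agreement) <- NULL
  list(reproducibility = repro, sign_agreement = sign_agreement)
}
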
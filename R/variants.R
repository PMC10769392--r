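# eQTL-style variant effect analysis: SAD scoring, variant filtering,
# sign-consistency tables, stratification and majority-vote accuracy.

#' SNP activity difference (SAD) score
#'
#' Builds the alternate window by substituting the alternate allele at the
#' window anchor, makes augmentation-averaged predictions for both alleles,
#' and sums the alternate-minus-reference difference over the three bins
#' centered at the variant (the bin containing it plus both neighbors).
#' Swapping the alleles negates the score exactly.
#'
#' @param predictor a `gt_model`, `ensemble_member`, `replicate_ensemble` or
#'   predictor function.
#' @param window a [genomic_window()] whose anchor marks the variant; the
#'   reference base at the anchor must equal `ref_allele`.
#' @param ref_allele,alt_allele single reference / alternate bases.
#' @return For a single predictor, a named vector of per-track scores; for a
#'   `replicate_ensemble`, an M x tracks matrix.
#' @export
sad_score <- function(predictor, window, ref_allele, alt_allele) {
  stopifnot(inherits(window, "genomic_window"))
  anchor <- window$anchor
  have <- substr(window$sequence, anchor + 1L, anchor + 1L)
  if (have != toupper(ref_allele)) {
    stop(sprintf("reference mismatch at anchor: window has %s, expected %s",
                 have, ref_allele), call. = FALSE)
  }
  alt_win <- substitute_bases(window, anchor, alt_allele)
  p_ref <- robust_predict(predictor, window)
  p_alt <- robust_predict(predictor, alt_win)
  nb <- dim(p_ref)[1L]
  bw <- window$length %/% nb
  i0 <- anchor %/% bw + 1L
  if (i0 <= 1L || i0 >= nb) {
    stop("variant lies within one bin of the window edge", call. = FALSE)
  }
  bins <- (i0 - 1L):(i0 + 1L)
  if (base::length(dim(p_ref)) == 3L) {
    M <- dim(p_ref)[3L]
    Tn <- dim(p_ref)[2L]
    out <- matrix(NA_real_, M, Tn)
    for (m in seq_len(M)) {
      out[m, ] <- colSums(p_alt[bins, , m, drop = FALSE][, , 1L, drop = FALSE] -
                            p_ref[bins, , m, drop = FALSE][, , 1L, drop = FALSE])
    }
    colnames(out) <- dimnames(p_ref)[[2L]]
    out
  } else {
    colSums(p_alt[bins, , drop = FALSE] - p_ref[bins, , drop = FALSE])
  }
}

#' Bulk SAD scores for a variant panel
#'
#' Efficient batch scorer: reference-window augmentation scans are shared
#' across the variants of a window and across replicates, and each variant is
#' applied as an incremental substitution. Agrees with [sad_score()] up to
#' floating-point reassociation.
#'
#' @param predictor a `replicate_ensemble` or `gt_model`.
#' @param windows list of [genomic_window()] objects.
#' @param variants data.frame with columns variant_id, window_id, pos0, ref,
#'   alt and optionally true_sign, gene_id, tss_distance.
#' @param track track index used for the per-variant summary columns.
#' @return A list with `sad` (variants x replicates matrix on `track`),
#'   `sad_all` (variants x replicates x tracks array) and `table` (per-variant
#'   data.frame with sign_probability, mean_abs_sad and consistency category
#'   when true signs are present).
#' @export
variant_effect_table <- function(predictor, windows, variants, track = 1L) {
  if (inherits(predictor, "replicate_ensemble")) {
    model <- predictor$model
    members <- predictor$members
  } else if (inherits(predictor, "gt_model")) {
    model <- predictor
    members <- list(.gt_member(predictor))
  } else stop("predictor must be a replicate_ensemble or gt_model", call. = FALSE)
  M <- base::length(members)
  win_by_id <- stats::setNames(windows, vapply(windows, function(w) w$id,
                                               character(1)))
  n_var <- nrow(variants)
  sad_all <- array(NA_real_, dim = c(n_var, M, model$n_tracks),
                   dimnames = list(variants$variant_id, NULL, model$track_ids))
  for (wid in unique(variants$window_id)) {
    w <- win_by_id[[wid]]
    if (is.null(w)) stop(sprintf("window '%s' not found", wid), call. = FALSE)
    idx <- which(variants$window_id == wid)
    ints <- seq_to_int(w$sequence)
    nb <- w$length %/% model$bin_width
    subs <- lapply(idx, function(i) {
      p0 <- variants$pos0[i]
      if (BASES[ints[p0 + 1L]] != variants$ref[i]) {
        stop(sprintf("reference mismatch for %s at offset %d",
                     variants$variant_id[i], p0), call. = FALSE)
      }
      i0 <- p0 %/% model$bin_width + 1L
      if (i0 <= 1L || i0 >= nb) {
        stop(sprintf("variant %s lies within one bin of the window edge",
                     variants$variant_id[i]), call. = FALSE)
      }
      list(pos0 = p0, base = match(variants$alt[i], BASES))
    })
    res <- .bulk_robust(model, members, ints, subs_list = subs)
    for (k in seq_along(idx)) {
      i <- idx[k]
      i0 <- variants$pos0[i] %/% model$bin_width + 1L
      bins <- (i0 - 1L):(i0 + 1L)
      delta <- res$subs[[k]][bins, , , drop = FALSE] -
        res$base[bins, , , drop = FALSE]
      sad_all[i, , ] <- t(apply(delta, c(2L, 3L), sum))[, , drop = FALSE]
    }
  }
  sad <- matrix(sad_all[, , track], n_var, M)
  rownames(sad) <- variants$variant_id
  truth <- if ("true_sign" %in% names(variants)) variants$true_sign else
    rep(NA_real_, n_var)
  rec <- classify_consistency_matrix(sad > 0,
                                     truth = ifelse(is.na(truth), NA_integer_,
                                                    as.integer(truth > 0)),
                                     unit_ids = variants$variant_id)
  table <- data.frame(
    variant_id = variants$variant_id,
    gene_id = variants$gene_id %||% variants$window_id,
    tss_distance = variants$tss_distance %||% NA_integer_,
    true_sign = truth,
    sign_probability = rec$sign_probability,
    mean_abs_sad = rowMeans(abs(sad)),
    category = rec$category,
    stringsAsFactors = FALSE)
  list(sad = sad, sad_all = sad_all, table = table)
}

#' Filter a variant-gene table for sign analysis
#'
#' Applies, in order: (1) remove variants with opposite true effect signs on
#' different genes; (2) remove pairs farther from the TSS than the receptive
#' field; (3) keep only the closest gene per variant.
#'
#' @param variant_gene data.frame with columns variant_id, gene_id,
#'   tss_distance and sign (per-gene true effect sign; NA = unknown).
#' @param receptive_field distance threshold in bp.
#' @return The filtered data.frame, one row per surviving variant.
#' @export
filter_variants <- function(variant_gene, receptive_field) {
  df <- variant_gene
  # (1) opposite signs on different genes
  by_var <- split(df$sign, df$variant_id)
  bad <- names(by_var)[vapply(by_var, function(s) {
    s <- s[!is.na(s)]
    base::length(unique(sign(s))) > 1L
  }, logical(1))]
  df <- df[!df$variant_id %in% bad, , drop = FALSE]
  # (2) beyond the receptive field
  df <- df[abs(df$tss_distance) <= receptive_field, , drop = FALSE]
  # (3) closest gene per variant
  df <- df[order(df$variant_id, abs(df$tss_distance)), , drop = FALSE]
  df <- df[!duplicated(df$variant_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' eQTL sign-consistency table
#'
#' Per-replicate sign labels (SAD > 0) are classified against the true sign,
#' and proportions over the three categories are reported.
#'
#' @param sad variants x replicates matrix of signed SAD scores.
#' @param true_sign vector of true effect signs (+1/-1), known for all rows.
#' @param variant_ids optional identifiers.
#' @return A list with `records` (per-variant data.frame) and `proportions`
#'   (named numeric over CONSISTENT_CORRECT, INCONSISTENT,
#'   CONSISTENT_INCORRECT, summing to 1).
#' @export
eqtl_consistency_table <- function(sad, true_sign, variant_ids = NULL) {
  sad <- as.matrix(sad)
  if (anyNA(true_sign)) stop("true_sign must be known for all rows", call. = FALSE)
  rec <- classify_consistency_matrix(sad > 0, truth = as.integer(true_sign > 0),
                                     unit_ids = variant_ids %||%
                                       rownames(sad) %||%
                                       as.character(seq_len(nrow(sad))))
  cats <- c("CONSISTENT_CORRECT", "INCONSISTENT", "CONSISTENT_INCORRECT")
  prop <- as.numeric(table(factor(rec$category, levels = cats))) / nrow(rec)
  names(prop) <- cats
  list(records = rec, proportions = prop)
}

#' Ensemble majority vote versus a single replicate
#'
#' Majority sign is positive when the ensemble sign probability exceeds 0.5;
#' an exact 0.5 tie is broken toward "non-positive".
#'
#' @param sad variants x replicates matrix of signed SAD scores.
#' @param true_sign vector of true signs (+1/-1).
#' @param single_index replicate used for the single-model accuracy.
#' @return A list with `accuracy_single` and `accuracy_majority`.
#' @export
ensemble_vs_single_accuracy <- function(sad, true_sign, single_index = 1L) {
  sad <- as.matrix(sad)
  truth_pos <- true_sign > 0
  p <- rowMeans(sad > 0)
  majority_pos <- p > 0.5
  single_pos <- sad[, single_index] > 0
  list(accuracy_single = mean(single_pos == truth_pos),
       accuracy_majority = mean(majority_pos == truth_pos))
}

#' Per-stratum consistency proportions
#'
#' @param records per-unit data.frame with a `category` column (e.g. from
#'   [variant_effect_table()] or [eqtl_consistency_table()]).
#' @param strata factor or character vector aligned with `records` assigning
#'   each unit to a stratum.
#' @return data.frame of per-stratum category proportions and sizes.
#' @export
stratify_consistency <- function(records, strata) {
  stopifnot(nrow(records) == base::length(strata))
  cats <- c("CONSISTENT_CORRECT", "INCONSISTENT", "CONSISTENT_INCORRECT")
  strata <- as.character(strata)
  out <- lapply(unique(strata), function(s) {
    idx <- which(strata == s)
    tab <- table(factor(records$category[idx], levels = cats))
    data.frame(stratum = s, t(as.numeric(tab) / base::length(idx)),
               n = base::length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  names(out)[2:4] <- cats
  out
}

#' Effect-size strata from mean absolute SAD
#'
#' Quantile bins of the predicted effect size.
#'
#' @param mean_abs_sad vector of per-variant mean |SAD|.
#' @param n_bins number of quantile bins (default 3).
#' @return Character vector of stratum labels (`"Q1"` = smallest effects).
#' @export
effect_size_strata <- function(mean_abs_sad, n_bins = 3L) {
  qs <- stats::quantile(mean_abs_sad, probs = seq(0, 1, length.out = n_bins + 1L))
  qs[1L] <- -Inf
  qs[base::length(qs)] <- Inf
  paste0("Q", as.integer(cut(mean_abs_sad, qs, labels = FALSE)))
}

#' Assign variants to annotation intervals
#'
#' Each variant is assigned the name of the first BED interval containing its
#' position; variants outside every interval get the stratum "unannotated".
#'
#' @param chrom,pos vectors of variant chromosome and 1-based position.
#' @param bed data.frame from [read_bed()] (0-based half-open intervals).
#' @return Character vector of interval names.
#' @export
annotate_variants <- function(chrom, pos, bed) {
  if (!all(c("chrom", "start", "end") %in% names(bed))) {
    stop("malformed BED annotation table", call. = FALSE)
  }
  pos0 <- pos - 1L
  vapply(seq_along(pos0), function(i) {
    hit <- which(bed$chrom == chrom[i] & bed$start <= pos0[i] & bed$end > pos0[i])
    if (base::length(hit) == 0L) "unannotated" else
      (bed$name[hit[1L]] %||% sprintf("interval%d", hit[1L]))
  }, character(1))
}
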
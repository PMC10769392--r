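# TF motif insertion and mutagenesis: background selection, fixed-offset
# insertion upstream of the TSS, activity and mutation-activity scores, and
# per-track inconsistency fractions.

#' Insert a motif sequence upstream of the TSS
#'
#' In-place substitution: the L reference bases ending `offset_upstream` bp
#' before the TSS anchor are replaced by `motif_seq`; window length and all
#' other bases are unchanged. In 0-based half-open coordinates the replaced
#' interval is `[anchor - offset - L, anchor - offset)`.
#'
#' @param background a [genomic_window()] with the TSS at its anchor.
#' @param motif_seq motif sequence to insert.
#' @param offset_upstream gap in bp between the motif's TSS-proximal end and
#'   the TSS (>= 1).
#' @return The motif-inserted `genomic_window`.
#' @export
insert_motif <- function(background, motif_seq, offset_upstream) {
  stopifnot(inherits(background, "genomic_window"))
  L <- nchar(motif_seq)
  if (offset_upstream < 1L) {
    stop("offset must be >= 1 bp (the motif may not overlap the TSS)",
         call. = FALSE)
  }
  start0 <- background$anchor - offset_upstream - L
  if (start0 < 0L) stop("motif insertion would exit the window", call. = FALSE)
  substitute_bases(background, start0:(start0 + L - 1L),
                   strsplit(toupper(motif_seq), "", fixed = TRUE)[[1L]])
}

#' Select background genes for motif insertion
#'
#' Ranks genes by the number of tracks on which the ensemble predicts them
#' consistently correctly, and returns the top `n` (ties broken by gene id).
#'
#' @param consistency_table data.frame with columns gene_id, track_id and
#'   category (one row per gene x track).
#' @param n number of backgrounds (default 100).
#' @return Character vector of gene ids.
#' @export
select_backgrounds <- function(consistency_table, n = 100L) {
  if (nrow(consistency_table) == 0L) stop("empty consistency table", call. = FALSE)
  if (n == 0L) return(character(0))
  counts <- tapply(consistency_table$category == "CONSISTENT_CORRECT",
                   consistency_table$gene_id, sum)
  df <- data.frame(gene_id = names(counts), n_correct = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n_correct, df$gene_id), , drop = FALSE]
  if (n > nrow(df)) {
    warning(sprintf("requested %d backgrounds but only %d genes available",
                    n, nrow(df)))
    n <- nrow(df)
  }
  df$gene_id[seq_len(n)]
}

# Central-two-bin activity statistic (the bins flanking the TSS junction),
# per member and track, from a bulk-prediction array.
.central2_stat <- function(rates_array) {
  nb <- dim(rates_array)[1L]
  if (nb %% 2L != 0L) {
    stop("odd bin count: no central bin junction for the TSS", call. = FALSE)
  }
  bins <- c(nb %/% 2L, nb %/% 2L + 1L)
  apply(rates_array[bins, , , drop = FALSE], c(2L, 3L), sum)  # tracks x M
}

.motif_subs <- function(window, motif_seq, offset) {
  L <- nchar(motif_seq)
  if (offset < 1L) stop("offset must be >= 1 bp", call. = FALSE)
  start0 <- window$anchor - offset - L
  if (start0 < 0L) stop("motif insertion would exit the window", call. = FALSE)
  list(pos0 = start0:(start0 + L - 1L),
       base = match(strsplit(motif_seq, "", fixed = TRUE)[[1L]], BASES))
}

#' TF activity and mutation-activity scores
#'
#' For each replicate, the TF activity score is the mean over backgrounds of
#' the difference in the central-two-bin activity between the motif-inserted
#' and the unmodified background window (`kind = "CANONICAL"`). The mutation
#' activity score compares the disruptively mutated motif against the
#' canonical motif (`kind = "MUTATION"`): mean over backgrounds of
#' \[inserted-mutated - inserted-canonical\]. One motif realization is drawn
#' per (motif, background) pair, fixed across replicates; `mode =
#' "consensus"` gives a deterministic variant.
#'
#' @param ensemble a `replicate_ensemble` (a `gt_model` is treated as a
#'   single-member ensemble).
#' @param backgrounds list of background [genomic_window()] objects.
#' @param motif a [pwm_motif()].
#' @param offset insertion offset in bp upstream of the TSS.
#' @param kind `"CANONICAL"` or `"MUTATION"`.
#' @param mode motif realization mode, `"sample"` or `"consensus"`.
#' @param seed seed for the per-background motif realizations.
#' @return An object of class `activity_score` with `motif_id`, `offset`,
#'   `kind` and `scores` (replicates x tracks matrix).
#' @export
tf_activity_score <- function(ensemble, backgrounds, motif, offset,
                              kind = c("CANONICAL", "MUTATION"),
                              mode = c("sample", "consensus"), seed = 1L) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  res <- motif_activity_analysis(ensemble, backgrounds, list(motif),
                                 offsets = offset, mode = mode, seed = seed)
  res$scores[[1L]][[kind]]
}

#' @rdname tf_activity_score
#' @export
tf_mutation_activity_score <- function(ensemble, backgrounds, motif, offset,
                                       mode = c("sample", "consensus"),
                                       seed = 1L) {
  tf_activity_score(ensemble, backgrounds, motif, offset, kind = "MUTATION",
                    mode = mode, seed = seed)
}

#' Batch motif insertion analysis
#'
#' Computes canonical and mutation activity scores for every motif x offset
#' combination, sharing the background window scans across all combinations
#' and replicates.
#'
#' @inheritParams tf_activity_score
#' @param motifs list of [pwm_motif()] objects.
#' @param offsets vector of insertion offsets in bp.
#' @return A list with `scores` (nested list indexed by \[combo\]\[kind\] of
#'   `activity_score` objects) and `long` (data.frame: motif_id, offset,
#'   kind, replicate, track_id, score).
#' @export
motif_activity_analysis <- function(ensemble, backgrounds, motifs, offsets,
                                    mode = c("sample", "consensus"),
                                    seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(ensemble, "gt_model")) {
    model <- ensemble
    members <- list(.gt_member(ensemble))
  } else {
    stopifnot(inherits(ensemble, "replicate_ensemble"))
    model <- ensemble$model
    members <- ensemble$members
  }
  if (base::length(backgrounds) == 0L) stop("need at least one background",
                                            call. = FALSE)
  M <- base::length(members)
  Tn <- model$n_tracks
  combos <- expand.grid(motif = seq_along(motifs), offset = offsets,
                        KEEP.OUT.ATTRS = FALSE)
  # accumulators: [combo] -> tracks x M
  acc_canon <- lapply(seq_len(nrow(combos)), function(i) matrix(0, Tn, M))
  acc_mut <- lapply(seq_len(nrow(combos)), function(i) matrix(0, Tn, M))
  for (b in seq_along(backgrounds)) {
    w <- backgrounds[[b]]
    ints <- seq_to_int(w$sequence)
    # one realization per (motif, background), fixed across replicates
    canon_seqs <- vapply(seq_along(motifs), function(mi) {
      sample_motif(motifs[[mi]], seed = derive_seed(seed, 1000L * mi + b),
                   mode = mode)
    }, character(1))
    mut_seqs <- vapply(seq_along(motifs), function(mi) {
      mutate_motif_sequence(motifs[[mi]], canon_seqs[mi])
    }, character(1))
    subs_list <- vector("list", 2L * nrow(combos))
    for (i in seq_len(nrow(combos))) {
      mi <- combos$motif[i]
      subs_list[[2L * i - 1L]] <- .motif_subs(w, canon_seqs[mi], combos$offset[i])
      subs_list[[2L * i]] <- .motif_subs(w, mut_seqs[mi], combos$offset[i])
    }
    res <- .bulk_robust(model, members, ints, subs_list = subs_list)
    stat_bg <- .central2_stat(res$base)
    for (i in seq_len(nrow(combos))) {
      stat_canon <- .central2_stat(res$subs[[2L * i - 1L]])
      stat_mut <- .central2_stat(res$subs[[2L * i]])
      acc_canon[[i]] <- acc_canon[[i]] + (stat_canon - stat_bg)
      acc_mut[[i]] <- acc_mut[[i]] + (stat_mut - stat_canon)
    }
  }
  nB <- base::length(backgrounds)
  scores <- vector("list", nrow(combos))
  long <- list()
  for (i in seq_len(nrow(combos))) {
    mi <- combos$motif[i]
    mk <- function(kind, acc) {
      structure(list(motif_id = motifs[[mi]]$motif_id,
                     offset = combos$offset[i], kind = kind,
                     scores = t(acc / nB),  # replicates x tracks
                     track_ids = model$track_ids),
                class = "activity_score")
    }
    scores[[i]] <- list(CANONICAL = mk("CANONICAL", acc_canon[[i]]),
                        MUTATION = mk("MUTATION", acc_mut[[i]]))
    for (kind in c("CANONICAL", "MUTATION")) {
      sc <- scores[[i]][[kind]]$scores
      long[[base::length(long) + 1L]] <- data.frame(
        motif_id = motifs[[mi]]$motif_id, offset = combos$offset[i],
        kind = kind, replicate = rep(seq_len(M), Tn),
        track_id = rep(model$track_ids, each = M),
        score = as.vector(sc), stringsAsFactors = FALSE)
    }
  }
  list(scores = scores, long = do.call(rbind, long), combos = combos)
}

#' @export
print.activity_score <- function(x, ...) {
  cat(sprintf("<activity_score> %s  offset %d bp  %s  (M = %d x %d tracks)\n",
              x$motif_id, x$offset, x$kind, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Fraction of motifs with inconsistent directional effects
#'
#' A motif is inconsistent when its per-replicate score signs are not
#' unanimous; a score of exactly 0 counts as non-positive (the strict-sign
#' rule of the ensemble sign probability).
#'
#' @param scores a motifs x replicates matrix of scores for one track, or a
#'   list of `activity_score` objects (one kind/offset/track).
#' @param track track index used when `scores` is a list.
#' @return Fraction in \[0, 1\].
#' @export
inconsistency_fraction <- function(scores, track = 1L) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- t(vapply(scores, function(s) s$scores[, track],
                       numeric(nrow(scores[[1L]]$scores))))
  }
  scores <- as.matrix(scores)
  if (nrow(scores) == 0L) stop("need at least one motif", call. = FALSE)
  pos <- scores > 0
  mean(rowSums(pos) %% ncol(scores) != 0L)
}
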
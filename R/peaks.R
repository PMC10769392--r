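# Poisson-null peak calling and the reference-sequence consistency breakdown.

#' Call peaks on a track with a Poisson null
#'
#' The null rate lambda is the arithmetic mean over all bins. Each bin's
#' p-value is the upper Poisson tail `P(X >= round(value))` (values are
#' rounded half-up, the Poisson pmf being integer-valued), and peaks are the
#' bins whose Benjamini-Hochberg adjusted p-value is at most `fdr`. An
#' all-zero track has lambda 0 and no peaks (p = 1 everywhere).
#'
#' @param values nonnegative per-bin activity values (>= 2 bins).
#' @param fdr false discovery rate cutoff (default 0.01).
#' @return An object of class `peak_calls` with fields `lambda`, `p_value`,
#'   `p_adjusted`, `is_peak` and `fdr`.
#' @export
call_peaks <- function(values, fdr = 0.01) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 bins", call. = FALSE)
  if (any(values < 0)) stop("track values must be >= 0", call. = FALSE)
  lambda <- mean(values)
  if (lambda == 0) {
    p <- rep(1, length(values))
  } else {
    k <- floor(values + 0.5)  # round half-up to integer counts
    p <- stats::ppois(k - 1, lambda, lower.tail = FALSE)
  }
  padj <- stats::p.adjust(p, method = "BH")
  structure(list(lambda = lambda, values = values, p_value = p,
                 p_adjusted = padj, is_peak = padj <= fdr & lambda > 0,
                 fdr = fdr, n_bins = length(values)),
            class = "peak_calls")
}

#' @export
print.peak_calls <- function(x, ...) {
  cat(sprintf("<peak_calls> %d bins, lambda = %.4g, %d peak(s) at FDR %.3g\n",
              x$n_bins, x$lambda, sum(x$is_peak), x$fdr))
  invisible(x)
}

#' Consistency breakdown of binary peak predictions
#'
#' Classifies every bin by the agreement of the M replicate peak calls with
#' the experimental call (the truth), and reports category proportions in
#' three strata: all bins, experimental-peak bins, and TSS bins that are also
#' experimental peaks.
#'
#' @param experimental a [call_peaks()] result for the experimental track.
#' @param predicted list of M [call_peaks()] results, one per replicate.
#' @param tss_bins integer indices of TSS-containing bins (optional).
#' @return A list with `records` (per-bin classification data.frame) and
#'   `proportions` (strata x categories data.frame; each row sums to 1; an
#'   empty stratum is reported as NA).
#' @export
bin_consistency_breakdown <- function(experimental, predicted,
                                      tss_bins = integer(0)) {
  stopifnot(inherits(experimental, "peak_calls"))
  for (p in predicted) stopifnot(inherits(p, "peak_calls"))
  nb <- experimental$n_bins
  if (any(vapply(predicted, function(p) p$n_bins, integer(1)) != nb)) {
    stop("bin-count mismatch between experimental and predicted tracks",
         call. = FALSE)
  }
  labels <- sapply(predicted, function(p) as.integer(p$is_peak))
  labels <- matrix(labels, nrow = nb)
  truth <- as.integer(experimental$is_peak)
  records <- classify_consistency_matrix(labels, truth,
                                         unit_ids = as.character(seq_len(nb)))
  strata <- list(
    all_bins = seq_len(nb),
    peak_bins = which(truth == 1L),
    tss_peak_bins = intersect(tss_bins, which(truth == 1L))
  )
  cats <- c("CONSISTENT_CORRECT", "INCONSISTENT", "CONSISTENT_INCORRECT")
  prop <- t(vapply(strata, function(idx) {
    if (length(idx) == 0L) return(rep(NA_real_, 3L))
    tab <- table(factor(records$category[idx], levels = cats))
    as.numeric(tab) / length(idx)
  }, numeric(3)))
  proportions <- data.frame(stratum = names(strata), prop,
                            n = vapply(strata, length, integer(1)),
                            row.names = NULL, stringsAsFactors = FALSE)
  names(proportions)[2:4] <- cats
  list(records = records, proportions = proportions)
}

#' Peak intervals as a BED-style table
#'
#' @param peaks a [call_peaks()] result.
#' @param chrom chromosome name for the output intervals.
#' @param start 0-based coordinate of the first bin.
#' @param bin_width bin width in bp.
#' @return data.frame with chrom, start, end, p_value for each peak bin.
#' @export
peaks_to_bed <- function(peaks, chrom = "chrS", start = 0L, bin_width = 128L) {
  idx <- which(peaks$is_peak)
  data.frame(chrom = chrom,
             start = start + (idx - 1L) * bin_width,
             end = start + idx * bin_width,
             p_value = peaks$p_value[idx],
             stringsAsFactors = FALSE)
}

#' @export
plot.peak_calls <- function(x, ...) {
  graphics::plot(seq_len(x$n_bins), x$values, type = "h",
                 col = ifelse(x$is_peak, "firebrick", "grey40"),
                 xlab = "bin", ylab = "activity",
                 main = sprintf("Poisson-null peaks (lambda = %.3g, FDR %.3g)",
                                x$lambda, x$fdr), ...)
  graphics::abline(h = x$lambda, lty = 2, col = "grey60")
  invisible(x)
}
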
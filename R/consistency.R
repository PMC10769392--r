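# Ensemble uncertainty machinery: sign probabilities, consistency categories,
# Poisson-mixture moments, attribution aggregation and group comparisons.

CONSISTENCY_CATEGORIES <- c("CONSISTENT_CORRECT", "CONSISTENT_INCORRECT",
                            "INCONSISTENT", "CONSISTENT_NO_TRUTH")

#' Ensemble sign probability
#'
#' The fraction of replicates whose prediction difference is strictly
#' positive. A difference of exactly 0 counts as "not increased" (strict
#' inequality), so an all-zero vector yields probability 0.
#'
#' @param deltas numeric vector of M per-replicate differences (M >= 2).
#' @return A value in \[0, 1\].
#' @export
ensemble_sign_probability <- function(deltas) {
  if (length(deltas) < 2L) stop("need at least 2 replicates", call. = FALSE)
  bad <- which(is.na(deltas) | is.nan(deltas))
  if (length(bad)) {
    stop(sprintf("non-finite delta for replicate %d", bad[1L]), call. = FALSE)
  }
  mean(deltas > 0)
}

#' Classify replicate agreement into consistency categories
#'
#' Unanimous replicate labels matching the truth are CONSISTENT_CORRECT;
#' unanimous labels contradicting the truth are CONSISTENT_INCORRECT;
#' unanimous labels without truth are CONSISTENT_NO_TRUTH; any disagreement
#' is INCONSISTENT.
#'
#' @param labels binary (0/1 or logical) vector of M replicate labels.
#' @param truth optional binary truth label.
#' @param unit_id optional identifier carried through to the record.
#' @return A list of class `consistency_record` with fields `unit_id`,
#'   `sign_probability` (fraction of positive labels), `category`,
#'   `n_replicates` and `truth`.
#' @export
classify_consistency <- function(labels, truth = NULL, unit_id = NA_character_) {
  labels <- as.integer(as.logical(labels))
  if (length(labels) < 2L) stop("need at least 2 replicates", call. = FALSE)
  p <- mean(labels == 1L)
  category <- if (p > 0 && p < 1) {
    "INCONSISTENT"
  } else if (is.null(truth) || is.na(truth)) {
    "CONSISTENT_NO_TRUTH"
  } else if (labels[1L] == as.integer(as.logical(truth))) {
    "CONSISTENT_CORRECT"
  } else {
    "CONSISTENT_INCORRECT"
  }
  structure(list(unit_id = unit_id, sign_probability = p, category = category,
                 n_replicates = length(labels),
                 truth = if (is.null(truth)) NA else as.integer(as.logical(truth))),
            class = "consistency_record")
}

#' @export
print.consistency_record <- function(x, ...) {
  cat(sprintf("<consistency_record> %s  p=%.2f (M=%d)  %s\n",
              x$unit_id, x$sign_probability, x$n_replicates, x$category))
  invisible(x)
}

# Vectorized classification over a units x M label matrix.
classify_consistency_matrix <- function(label_matrix, truth = NULL,
                                        unit_ids = NULL) {
  label_matrix <- matrix(as.integer(label_matrix > 0), nrow(label_matrix))
  p <- rowMeans(label_matrix)
  n <- nrow(label_matrix)
  unit_ids <- unit_ids %||% as.character(seq_len(n))
  category <- rep("INCONSISTENT", n)
  unanim <- p == 0 | p == 1
  if (is.null(truth)) {
    category[unanim] <- "CONSISTENT_NO_TRUTH"
    truth_vec <- rep(NA_integer_, n)
  } else {
    truth_vec <- as.integer(truth > 0)
    known <- !is.na(truth_vec)
    match_truth <- (p == 1 & truth_vec == 1L) | (p == 0 & truth_vec == 0L)
    match_truth[!known] <- FALSE
    category[unanim & known & match_truth] <- "CONSISTENT_CORRECT"
    category[unanim & known & !match_truth] <- "CONSISTENT_INCORRECT"
    category[unanim & !known] <- "CONSISTENT_NO_TRUTH"
  }
  data.frame(unit_id = unit_ids, sign_probability = p, category = category,
             truth = truth_vec, stringsAsFactors = FALSE)
}

#' Moments of a Poisson mixture
#'
#' For a convex combination of Poisson components with means `lambda_i` and
#' weights `w_i`, the mixture mean is `sum(w * lambda)` and the variance is
#' `sum(w * lambda) + sum(w * (lambda - mean)^2)` (law of total variance).
#' The variance always exceeds the mean unless all component means are equal
#' (a Poisson mixture is overdispersed).
#'
#' @param component_means nonnegative component means.
#' @param weights mixture weights; nonnegative, summing to 1 within 1e-9
#'   (default uniform).
#' @return A list of class `mixture_moments` with `mean` and `variance`.
#' @export
poisson_mixture_moments <- function(component_means,
                                    weights = rep(1 / length(component_means),
                                                  length(component_means))) {
  if (any(component_means < 0)) stop("component means must be >= 0", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be nonnegative and sum to 1 within 1e-9", call. = FALSE)
  }
  mu <- sum(weights * component_means)
  v <- mu + sum(weights * (component_means - mu)^2)
  structure(list(mean = mu, variance = v), class = "mixture_moments")
}

#' @export
print.mixture_moments <- function(x, ...) {
  cat(sprintf("<mixture_moments> mean %.6g, variance %.6g\n", x$mean, x$variance))
  invisible(x)
}

#' Aggregate per-nucleotide attributions into per-bin scores
#'
#' Sums the absolute attribution values within consecutive windows of
#' `window` bp, the binning used to compare saliency maps between replicates.
#'
#' @param attributions numeric vector of per-nucleotide attributions; its
#'   length must be a multiple of `window`.
#' @param window bin width in bp (default 128).
#' @return Numeric vector of nonnegative per-bin scores.
#' @export
saliency_window_scores <- function(attributions, window = 128L) {
  n <- length(attributions)
  if (n %% window != 0L) {
    stop("attribution length must be a multiple of the window size", call. = FALSE)
  }
  colSums(matrix(abs(attributions), nrow = window))
}

#' Pairwise correlations between replicate columns
#'
#' @param mat numeric units x replicates matrix with at least 3 rows.
#' @param method `"pearson"` or `"spearman"`.
#' @return data.frame with one row per unordered replicate pair (`rep_i` <
#'   `rep_j`) and the correlation; a pair involving a constant column is
#'   reported with `correlation = NA` rather than dropped.
#' @export
pairwise_correlation <- function(mat, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (nrow(mat) < 3L) stop("need at least 3 units", call. = FALSE)
  M <- ncol(mat)
  if (M < 2L) stop("need at least 2 replicate columns", call. = FALSE)
  const <- apply(mat, 2L, function(x) stats::sd(x) == 0)
  pairs <- utils::combn(M, 2L)
  out <- data.frame(rep_i = pairs[1L, ], rep_j = pairs[2L, ],
                    correlation = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    if (const[i] || const[j]) next
    out$correlation[k] <- stats::cor(mat[, i], mat[, j], method = method)
  }
  out
}

#' One-sided two-group rank comparison
#'
#' Mann-Whitney U test comparing `a` against `b`. The exact null
#' distribution is used when both groups have at most 8 observations and
#' there are no ties; otherwise the normal approximation with tie correction
#' is used.
#'
#' @param a,b numeric vectors (nonempty).
#' @param alternative `"greater"` (a shifted above b) or `"less"`.
#' @return A list with `statistic` (U for group a) and `p_value`.
#' @export
group_compare <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) == 0L || length(b) == 0L) stop("empty group", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- length(a) <= 8L && length(b) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = !exact)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' A family of one-sided rank comparisons with BH correction
#'
#' Runs [group_compare()] for each (a, b) pair and applies Benjamini-Hochberg
#' step-up correction over the family.
#'
#' @param pairs list of lists, each with elements `a` and `b` (and optionally
#'   `name`).
#' @param alternative passed to [group_compare()].
#' @return data.frame with columns name, p_raw, p_adjusted.
#' @export
group_compare_family <- function(pairs, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  p <- vapply(pairs, function(pr) group_compare(pr$a, pr$b, alternative)$p_value,
              numeric(1))
  nm <- vapply(seq_along(pairs), function(i) pairs[[i]]$name %||% as.character(i),
               character(1))
  data.frame(name = nm, p_raw = p,
             p_adjusted = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}
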
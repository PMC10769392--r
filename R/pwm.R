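#' Position weight matrix motif
#'
#' A transcription-factor binding motif as an L x 4 matrix of per-position base
#' probabilities (columns in A, C, G, T order). Each row must sum to 1 within
#' 1e-6; zero probabilities are allowed and preserved.
#'
#' @param motif_id motif identifier.
#' @param matrix numeric L x 4 matrix of probabilities.
#' @return An object of class `pwm_motif`.
#' @export
pwm_motif <- function(motif_id, matrix) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) stop("PWM must have 4 columns (A,C,G,T)", call. = FALSE)
  if (any(matrix < 0)) stop("PWM probabilities must be nonnegative", call. = FALSE)
  rs <- rowSums(matrix)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("PWM rows must sum to 1 within 1e-6", call. = FALSE)
  }
  dimnames(matrix) <- list(NULL, BASES)
  structure(list(motif_id = as.character(motif_id), matrix = matrix,
                 length = nrow(matrix)),
            class = "pwm_motif")
}

#' @export
print.pwm_motif <- function(x, ...) {
  cat(sprintf("<pwm_motif> %s  length %d  consensus %s\n",
              x$motif_id, x$length, consensus_sequence(x)))
  invisible(x)
}

#' Per-position Shannon entropy of a PWM
#'
#' Entropy in bits per motif position, with the convention 0*log2(0) = 0.
#' A uniform position has entropy 2 bits; a one-hot position has entropy 0.
#'
#' @param pwm a [pwm_motif()].
#' @return Numeric vector of length L, entropies in bits.
#' @export
column_entropy <- function(pwm) {
  stopifnot(inherits(pwm, "pwm_motif"))
  p <- pwm$matrix
  terms <- ifelse(p > 0, -p * log2(p), 0)
  rowSums(terms)
}

#' Consensus sequence of a PWM
#'
#' Per-position highest-probability base; ties broken alphabetically
#' (A < C < G < T).
#'
#' @param pwm a [pwm_motif()].
#' @return A character string of length L.
#' @export
consensus_sequence <- function(pwm) {
  stopifnot(inherits(pwm, "pwm_motif"))
  idx <- apply(pwm$matrix, 1L, which.max)  # which.max takes the first maximum
  paste(BASES[idx], collapse = "")
}

#' Design the maximally disruptive single-base mutation for a motif
#'
#' Selects the lowest-entropy (most information-rich) PWM position and the
#' lowest-probability base at that position. Ties are broken toward the
#' leftmost position and the alphabetically first base. The returned base
#' always differs from the consensus base at that position.
#'
#' @param pwm a [pwm_motif()].
#' @return A list with `position` (1-based motif position) and `base`.
#' @export
design_disruptive_mutation <- function(pwm) {
  stopifnot(inherits(pwm, "pwm_motif"))
  ent <- column_entropy(pwm)
  pos <- which.min(ent)  # leftmost minimum
  probs <- pwm$matrix[pos, ]
  base <- BASES[which.min(probs)]  # alphabetically first minimum
  cons <- BASES[which.max(probs)]
  if (base == cons) {
    # Only possible when all four probabilities are tied; argmin and argmax
    # both resolve to A, so step to the next base.
    base <- BASES[2L]
  }
  list(position = as.integer(pos), base = base)
}

#' Probability of a mutant base under the PWM
#'
#' @param pwm a [pwm_motif()].
#' @param position 1-based motif position.
#' @param base mutant base, one of A/C/G/T.
#' @return The PWM probability of `base` at `position`.
#' @export
mutation_probability <- function(pwm, position, base) {
  stopifnot(inherits(pwm, "pwm_motif"))
  if (position < 1L || position > pwm$length) stop("position out of range", call. = FALSE)
  b <- match(toupper(base), BASES)
  if (is.na(b)) stop("base must be one of A/C/G/T", call. = FALSE)
  unname(pwm$matrix[position, b])
}

#' Sample or take the consensus of a motif sequence
#'
#' `mode = "sample"` draws each position independently from its probability
#' row (seeded); `mode = "consensus"` returns the per-position argmax with
#' alphabetical tie-breaking.
#'
#' @param pwm a [pwm_motif()].
#' @param seed integer seed (used for `mode = "sample"`).
#' @param mode `"sample"` or `"consensus"`.
#' @return A character string of length L.
#' @export
sample_motif <- function(pwm, seed = 1L, mode = c("sample", "consensus")) {
  stopifnot(inherits(pwm, "pwm_motif"))
  mode <- match.arg(mode)
  if (mode == "consensus") return(consensus_sequence(pwm))
  with_seed(seed, {
    idx <- apply(pwm$matrix, 1L, function(p) sample.int(4L, 1L, prob = p))
    paste(BASES[idx], collapse = "")
  })
}

#' Apply the designed disruptive mutation to a motif sequence
#'
#' @param pwm a [pwm_motif()].
#' @param motif_seq a realized motif sequence of length L (e.g. from
#'   [sample_motif()]).
#' @return The mutated sequence.
#' @export
mutate_motif_sequence <- function(pwm, motif_seq) {
  stopifnot(inherits(pwm, "pwm_motif"), nchar(motif_seq) == pwm$length)
  mut <- design_disruptive_mutation(pwm)
  chars <- strsplit(motif_seq, "", fixed = TRUE)[[1L]]
  chars[mut$position] <- mut$base
  paste(chars, collapse = "")
}
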
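#' Genomic sequence window
#'
#' A fixed-length nucleotide sequence anchored at a genome coordinate, with a
#' designated anchor offset (a TSS or a variant position) inside the window.
#' Coordinates are 0-based, half-open; the anchor is a 0-based offset into the
#' sequence.
#'
#' @param chrom chromosome name.
#' @param start 0-based start coordinate of the window on `chrom`.
#' @param sequence nucleotide string over A/C/G/T/N (case-insensitive).
#' @param anchor 0-based offset of the TSS or variant within the window.
#' @param strand `"+"` or `"-"`.
#' @param id optional window identifier.
#' @return An object of class `genomic_window`.
#' @export
genomic_window <- function(chrom, start, sequence, anchor, strand = "+",
                           id = NULL) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains non-ACGTN characters", call. = FALSE)
  }
  len <- nchar(sequence)
  start <- as.integer(start)
  anchor <- as.integer(anchor)
  if (start < 0) stop("start must be >= 0", call. = FALSE)
  if (anchor < 0 || anchor >= len) {
    stop("anchor must lie inside the window (0 <= anchor < length)",
         call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  structure(
    list(chrom = as.character(chrom), start = start, length = len,
         sequence = sequence, anchor = anchor, strand = strand,
         id = id %||% sprintf("%s:%d-%d", chrom, start, start + len)),
    class = "genomic_window"
  )
}

#' @export
print.genomic_window <- function(x, ...) {
  cat(sprintf("<genomic_window> %s  %s:%d-%d (%s)  anchor=%d\n",
              x$id, x$chrom, x$start, x$start + x$length, x$strand, x$anchor))
  head_seq <- substr(x$sequence, 1, 60)
  cat(sprintf("  %s%s\n", head_seq, if (x$length > 60) "..." else ""))
  invisible(x)
}

#' Substitute bases in a window
#'
#' Returns a copy of `window` with the bases at the given 0-based offsets
#' replaced. Window length and all coordinates are preserved (substitution
#' semantics; no indels).
#'
#' @param window a [genomic_window()].
#' @param pos0 integer vector of 0-based offsets within the window.
#' @param bases character vector of replacement bases (single characters).
#' @return A `genomic_window`.
#' @export
substitute_bases <- function(window, pos0, bases) {
  stopifnot(inherits(window, "genomic_window"), length(pos0) == length(bases))
  if (length(pos0) == 0L) return(window)
  if (any(pos0 < 0 | pos0 >= window$length)) {
    stop("substitution position outside window", call. = FALSE)
  }
  if (any(!toupper(bases) %in% c(BASES, "N"))) {
    stop("replacement bases must be A/C/G/T/N", call. = FALSE)
  }
  chars <- strsplit(window$sequence, "", fixed = TRUE)[[1L]]
  chars[pos0 + 1L] <- toupper(bases)
  window$sequence <- paste(chars, collapse = "")
  window
}

#' Reverse complement of a window
#'
#' The anchor is mirrored so that it designates the same physical position.
#'
#' @param window a [genomic_window()].
#' @return A `genomic_window`.
#' @export
reverse_complement <- function(window) {
  stopifnot(inherits(window, "genomic_window"))
  window$sequence <- rc_seq(window$sequence)
  window$anchor <- window$length - 1L - window$anchor
  window$strand <- if (window$strand == "+") "-" else "+"
  window
}

# Shift the window content by `shift` bases (content moves right for +1);
# vacated edge positions are filled with N. Anchor offset is unchanged: the
# anchor tracks the window frame, not the content (this is the convention for
# shift augmentation, where the output binning stays fixed).
shift_window <- function(window, shift) {
  if (shift == 0L) return(window)
  ints <- seq_to_int(window$sequence)
  n <- length(ints)
  out <- rep(NA_integer_, n)
  if (shift > 0L) out[(1L + shift):n] <- ints[1L:(n - shift)]
  else out[1L:(n + shift)] <- ints[(1L - shift):n]
  window$sequence <- int_to_seq(out)
  window
}

#' Deterministic ten-fold downsampling of windows
#'
#' Sorts windows by (chrom, start) and keeps every `stride`-th one, starting
#' from the first. Deterministic by construction, so repeated runs analyse the
#' same subset.
#'
#' @param windows list of [genomic_window()] objects.
#' @param stride keep one window in every `stride` (default 10).
#' @return A list of `genomic_window` objects.
#' @export
downsample_windows <- function(windows, stride = 10L) {
  stopifnot(stride >= 1L)
  if (length(windows) == 0L) return(windows)
  ord <- order(vapply(windows, function(w) w$chrom, character(1)),
               vapply(windows, function(w) w$start, integer(1)))
  windows[ord][seq(1L, length(windows), by = stride)]
}
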
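# Readers and writers for the standard formats the pipeline touches: FASTA,
# minimal phased VCF, MEME-like PWM files, BED3/4 and TSV tables.

#' Read a FASTA file
#'
#' @param path path to a FASTA file.
#' @return A named character vector of uppercased sequences, in file order.
#'   An empty file yields an empty vector.
#' @export
read_fasta <- function(path) {
  if (file.size(path) %in% c(0L, NA)) return(stats::setNames(character(0), character(0)))
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e) stop(sprintf("failed to parse FASTA '%s': %s",
                                       path, conditionMessage(e)), call. = FALSE)
    ),
    warning = function(w) {
      # readDNAStringSet downgrades invalid sequence codes to a warning;
      # treat them as the parse errors they are
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop(sprintf("FASTA '%s' contains invalid sequence characters", path),
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop(sprintf("FASTA record '%s' contains bases outside A/C/G/T/N",
                 names(seqs)[which(bad)[1L]]), call. = FALSE)
  }
  # Keep only the first whitespace-delimited token of each header.
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences, or a list of
#'   [genomic_window()] objects (window ids become record names).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs) && length(seqs) && inherits(seqs[[1L]], "genomic_window")) {
    nm <- vapply(seqs, function(w) w$id, character(1))
    seqs <- stats::setNames(vapply(seqs, function(w) w$sequence, character(1)), nm)
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a phased VCF of SNVs
#'
#' Parses a minimal VCF (CHROM POS ID REF ALT QUAL FILTER INFO FORMAT + GT
#' columns) with phased genotypes. Non-SNV records (indels, multi-allelic
#' sites) are skipped with a message; unphased genotypes are an error, since
#' haplotype construction requires phasing.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @return A list with `variants` (data.frame: chrom, pos (1-based), id, ref,
#'   alt), `haplotypes` (integer array individuals x variants x 2, values 0/1
#'   indicating the alternate allele), `dosage` (individuals x variants) and
#'   `n_skipped` (count of non-SNV records dropped).
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_total <- nrow(fix)
  is_snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% BASES & fix$ALT %in% BASES
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0L) {
    message(sprintf("read_phased_vcf: skipped %d non-SNV record(s)", n_skipped))
  }
  gt <- vcfR::extract.gt(v)
  if (is.null(gt) || ncol(gt) == 0L) {
    stop("VCF has no genotype columns", call. = FALSE)
  }
  gt <- gt[is_snv, , drop = FALSE]
  fix <- fix[is_snv, , drop = FALSE]
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop("unphased genotype found ('/'); phased genotypes ('|') are required",
         call. = FALSE)
  }
  n_var <- nrow(fix)
  n_ind <- ncol(gt)
  hap <- array(0L, dim = c(n_ind, n_var, 2L),
               dimnames = list(colnames(gt), fix$ID, c("hap1", "hap2")))
  if (n_var > 0L) {
    parts <- strsplit(as.vector(gt), "|", fixed = TRUE)
    a1 <- matrix(as.integer(vapply(parts, `[`, character(1), 1L)), n_var, n_ind)
    a2 <- matrix(as.integer(vapply(parts, `[`, character(1), 2L)), n_var, n_ind)
    hap[, , 1L] <- t(a1)
    hap[, , 2L] <- t(a2)
  }
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = fix$ID, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  list(variants = variants, haplotypes = hap,
       dosage = hap[, , 1L, drop = FALSE][, , 1L] + hap[, , 2L, drop = FALSE][, , 1L],
       n_skipped = n_skipped)
}

#' Write a minimal phased VCF
#'
#' @param variants data.frame with columns chrom, pos (1-based), id, ref, alt.
#' @param haplotypes integer array individuals x variants x 2 of 0/1 alternate
#'   allele indicators (optional; omitted columns produce a site-only VCF).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(variants, haplotypes = NULL, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  ind <- if (is.null(haplotypes)) character(0) else dimnames(haplotypes)[[1L]] %||%
    paste0("ind", seq_len(dim(haplotypes)[1L]))
  header <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(haplotypes)) header <- c(header, "FORMAT", ind)
  writeLines(paste(header, collapse = "\t"), con)
  for (i in seq_len(nrow(variants))) {
    fields <- c(variants$chrom[i], variants$pos[i],
                variants$id[i] %||% ".", variants$ref[i], variants$alt[i],
                ".", "PASS", ".")
    if (!is.null(haplotypes)) {
      gts <- paste(haplotypes[, i, 1L], haplotypes[, i, 2L], sep = "|")
      fields <- c(fields, "GT", gts)
    }
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a MEME-like PWM file
#'
#' Parses the probability-matrix subset of the MEME format: `MOTIF <name>`
#' lines, each followed by L rows of 4 probabilities (an optional
#' `letter-probability matrix` header line is tolerated). Rows are
#' renormalized to sum exactly to 1; a row summing outside [0.9, 1.1] before
#' normalization is rejected as a likely counts matrix.
#'
#' @param path path to the PWM file.
#' @return A list of [pwm_motif()] objects.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  motifs <- list()
  name <- NULL
  rows <- list()
  flush <- function() {
    if (!is.null(name)) {
      if (length(rows) == 0L) stop(sprintf("motif '%s' has no matrix rows", name),
                                   call. = FALSE)
      m <- do.call(rbind, rows)
      motifs[[length(motifs) + 1L]] <<- pwm_motif(name, m)
    }
    name <<- NULL
    rows <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (grepl("^MOTIF\\b", ln)) {
      flush()
      name <- strsplit(ln, "\\s+")[[1L]][2L]
      if (is.na(name)) stop(sprintf("line %d: MOTIF line without a name", i),
                            call. = FALSE)
      next
    }
    if (grepl("^letter-probability", ln) || grepl("^[A-Za-z]", ln)) next
    vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
    if (length(vals) != 4L || anyNA(vals)) {
      stop(sprintf("line %d: expected 4 numeric probabilities", i), call. = FALSE)
    }
    s <- sum(vals)
    if (s < 0.9 || s > 1.1) {
      stop(sprintf("line %d: row sums to %.4g; expected probabilities (is this a counts matrix?)",
                   i, s), call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- vals / s
  }
  flush()
  motifs
}

#' Convert a 4-column TSV matrix to a PWM motif
#'
#' Reads a tab-separated file of L rows x 4 columns (A, C, G, T) of
#' probabilities or counts (counts are normalized per row).
#'
#' @param path path to the TSV file.
#' @param motif_id identifier for the resulting motif.
#' @return A [pwm_motif()].
#' @export
pwm_from_tsv <- function(path, motif_id = basename(path)) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  if (ncol(m) != 4L) stop("expected 4 columns (A,C,G,T)", call. = FALSE)
  m <- m / rowSums(m)
  pwm_motif(motif_id, m)
}

#' Read a BED3/BED4 interval file
#'
#' Minimal reader for the plain-text BED subset used here (chrom, start, end
#' and an optional name column); coordinates are kept 0-based half-open.
#'
#' @param path path to the BED file.
#' @return data.frame with columns chrom, start, end, name.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file must have at least 3 columns", call. = FALSE)
  out <- data.frame(chrom = as.character(df[[1L]]), start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    name = if (ncol(df) >= 4L) as.character(df[[4L]]) else NA_character_,
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("malformed BED: end <= start", call. = FALSE)
  out
}

#' Write a BED file
#' @param df data.frame with chrom, start, end and optional further columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a TSV table (tab-separated, header row, '.' decimal)
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_tsv()]
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
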
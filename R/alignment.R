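# Core alignment container: a named character vector of equal-length
# upper-case sequences over {A,C,G,T,N,-,?}, plus marker metadata.

UNAMBIG_BASES <- c("A", "C", "G", "T")
MISSING_CHARS <- c("N", "-", "?")
ALN_ALPHABET <- c(UNAMBIG_BASES, MISSING_CHARS)
MARKER_CLASSES <- c("exon", "intron", "uce", "gene", "unified")

#' Construct a marker alignment
#'
#' An `phf_alignment` stores one multiple sequence alignment for a single
#' marker: an ordered set of taxa, each with a gap-aware sequence over the
#' nucleotide alphabet `A,C,G,T,N,-,?`. Sequences are normalized on
#' construction: upper-cased, with `U` converted to `T`. `?` is treated as
#' equivalent to `N` (both denote missing data) by every statistic in the
#' package.
#'
#' @param marker_id Character scalar identifying the marker (usually the
#'   file stem of the alignment on disk).
#' @param seqs Named character vector, one equal-length sequence per taxon.
#' @param marker_class One of `"exon"`, `"intron"`, `"uce"`, `"gene"`,
#'   `"unified"`.
#' @param frame Optional verified reading-frame offset (1, 2 or 3) set by
#'   [select_reading_frame()]. `NA` means the frame has not been verified;
#'   codon partitioning then falls back to a per-marker partition.
#' @return An object of class `phf_alignment`.
#' @seealso [read_alignment()], [summarize_alignment()]
#' @export
alignment <- function(marker_id, seqs, marker_class = "unified", frame = NA_integer_) {
  marker_class <- match.arg(marker_class, MARKER_CLASSES)
  if (!is.character(marker_id) || length(marker_id) != 1L || !nzchar(marker_id))
    stop("marker_id must be a non-empty character scalar")
  if (length(seqs) < 1L) stop("alignment '", marker_id, "' has no sequences")
  taxa <- names(seqs)
  if (is.null(taxa) || any(!nzchar(taxa)))
    stop("all sequences must be named by taxon")
  dup <- unique(taxa[duplicated(taxa)])
  if (length(dup))
    stop("duplicate taxon name(s) in alignment '", marker_id, "': ",
         paste(dup, collapse = ", "))
  seqs <- normalize_sequences(seqs)
  lens <- nchar(seqs)
  if (any(lens != lens[1L])) {
    bad <- taxa[lens != lens[1L]][1L]
    stop("ragged alignment '", marker_id, "': taxon '", bad, "' has length ",
         nchar(seqs[[bad]]), ", expected ", lens[1L])
  }
  if (lens[1L] < 1L) stop("alignment '", marker_id, "' has zero length")
  structure(
    list(marker_id = marker_id, marker_class = marker_class,
         seqs = seqs, frame = as.integer(frame)),
    class = "phf_alignment")
}

normalize_sequences <- function(seqs) {
  out <- chartr("u", "T", toupper(seqs))  # toupper first, then stray 'u' safety
  out <- chartr("U", "T", out)
  bad <- grepl(sprintf("[^%s]", paste(c("ACGTN?", "\\-"), collapse = "")), out)
  if (any(bad)) {
    tax <- names(seqs)[bad][1L]
    chars <- setdiff(unique(strsplit(out[bad][1L], "")[[1L]]), ALN_ALPHABET)
    stop("invalid character(s) ", paste(chars, collapse = ""),
         " in sequence for taxon '", tax, "'")
  }
  out
}

#' @export
print.phf_alignment <- function(x, ...) {
  cat(sprintf("<alignment '%s'> class=%s  %d taxa x %d bp%s\n",
              x$marker_id, x$marker_class, n_taxa(x), aln_length(x),
              if (!is.na(x$frame)) sprintf("  frame=%d", x$frame) else ""))
  invisible(x)
}

#' Alignment dimensions and taxa
#'
#' @param aln A `phf_alignment`.
#' @return `aln_length()` the number of columns; `n_taxa()` the number of
#'   rows; `taxa()` the taxon names in row order.
#' @export
aln_length <- function(aln) nchar(aln$seqs[[1L]])

#' @rdname aln_length
#' @export
n_taxa <- function(aln) length(aln$seqs)

#' @rdname aln_length
#' @export
taxa <- function(aln) names(aln$seqs)

# Character-matrix view (rows = taxa) used by column-wise operators.
aln_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seqs, ""), use.names = FALSE),
              nrow = length(aln$seqs), byrow = TRUE)
  rownames(m) <- names(aln$seqs)
  m
}

# Rebuild an alignment from a character matrix, keeping metadata.
aln_from_matrix <- function(m, template) {
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- rownames(m)
  alignment(template$marker_id, seqs, template$marker_class,
            frame = template$frame)
}

#' @export
`==.phf_alignment` <- function(e1, e2) {
  identical(e1$marker_id, e2$marker_id) &&
    identical(e1$marker_class, e2$marker_class) &&
    identical(unname(e1$seqs), unname(e2$seqs)) &&
    identical(names(e1$seqs), names(e2$seqs))
}

is_unambiguous <- function(chars) chars %in% UNAMBIG_BASES
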
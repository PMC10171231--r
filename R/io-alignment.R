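# Alignment file IO: FASTA (via Biostrings) and relaxed sequential Phylip.
# Relaxed Phylip here means: a "<ntaxa> <nchar>" header followed by one
# "name whitespace sequence" record per line, names of arbitrary length.

#' Read a marker alignment from FASTA or relaxed Phylip
#'
#' The format is auto-detected from the first non-blank character (`>` for
#' FASTA, a digit for Phylip). Sequences are normalized (upper case, `U`
#' to `T`) and validated against the alphabet `A,C,G,T,N,-,?`. The marker
#' id is the file stem.
#'
#' @param path Path to the alignment file.
#' @param marker_class Marker class to record; see [alignment()].
#' @return A `phf_alignment`.
#' @export
read_alignment <- function(path, marker_class = "unified") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (!length(nonblank)) stop("empty alignment file: ", path)
  first <- substr(trimws(nonblank[1L]), 1L, 1L)
  seqs <- if (first == ">") {
    read_fasta_seqs(path)
  } else if (grepl("[0-9]", first)) {
    read_phylip_seqs(nonblank)
  } else {
    stop("cannot detect alignment format of ", path,
         " (first character '", first, "')")
  }
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup))
    stop("duplicate record name(s) in ", path, ": ", paste(dup, collapse = ", "))
  lens <- nchar(seqs)
  if (any(lens != lens[1L])) {
    bad <- names(seqs)[lens != lens[1L]][1L]
    stop("ragged alignment in ", path, ": taxon '", bad, "'")
  }
  alignment(tools::file_path_sans_ext(basename(path)), seqs, marker_class)
}

read_fasta_seqs <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

read_phylip_seqs <- function(nonblank) {
  hdr <- strsplit(trimws(nonblank[1L]), "\\s+")[[1L]]
  if (length(hdr) < 2L) stop("malformed phylip header: ", nonblank[1L])
  ntax <- as.integer(hdr[1L])
  nchr <- as.integer(hdr[2L])
  body <- nonblank[-1L]
  if (length(body) != ntax)
    stop("phylip header declares ", ntax, " taxa but file has ",
         length(body), " records (interleaved phylip is not supported)")
  parts <- strsplit(trimws(body), "\\s+")
  nm <- vapply(parts, `[[`, "", 1L)
  sq <- vapply(parts, function(p) paste(p[-1L], collapse = ""), "")
  if (any(nchar(sq) != nchr))
    stop("phylip sequence length disagrees with header (expected ", nchr, ")")
  names(sq) <- nm
  sq
}

#' Write an alignment to FASTA or relaxed Phylip
#'
#' Writing then re-reading reproduces the alignment exactly (taxon names,
#' order, sequences).
#'
#' @param aln A `phf_alignment`.
#' @param path Output path.
#' @param format `"fasta"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "phf_alignment"))
  if (aln_length(aln) < 1L)
    stop("refusing to write zero-length alignment '", aln$marker_id, "'")
  if (format == "fasta") {
    ss <- Biostrings::BStringSet(aln$seqs)
    Biostrings::writeXStringSet(ss, path, width = 80L)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", n_taxa(aln), aln_length(aln)), con)
    writeLines(sprintf("%s  %s", names(aln$seqs), aln$seqs), con)
  }
  invisible(path)
}

#' Read all alignments in a directory
#'
#' @param dir Directory containing `.fa`/`.fasta`/`.phy`/`.phylip` files.
#' @param marker_class Marker class applied to every file.
#' @return Named list of `phf_alignment` keyed by marker id.
#' @export
read_alignment_dir <- function(dir, marker_class = "unified") {
  files <- list.files(dir, pattern = "\\.(fa|fasta|fas|phy|phylip)$",
                      full.names = TRUE)
  alns <- lapply(files, read_alignment, marker_class = marker_class)
  names(alns) <- vapply(alns, `[[`, "", "marker_id")
  alns
}
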
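# Post-alignment quality control: reference-divergence screening,
# minimum-size keep rule, external trimming, window-based misalignment
# masking and reading-frame selection.

#' Quality-control configuration
#'
#' Defaults reproduce the capture-pipeline screening rules: drop samples
#' more than 40% divergent from the reference, keep alignments with more
#' than 3 taxa and more than 100 bp, trim alignment ends until at least
#' 50% of rows carry sequence data, mask 100-bp windows more than 40%
#' divergent from the consensus, and require a reading frame that keeps
#' more than 90% of rows stop-free.
#'
#' @param ref_divergence_max Fraction; rows with p-distance to the
#'   reference strictly greater than this are removed.
#' @param min_taxa_exclusive Alignments must have strictly more taxa.
#' @param min_len_exclusive Alignments must be strictly longer (bp).
#' @param end_coverage_min Minimum fraction of rows with an unambiguous
#'   base for a terminal column to survive external trimming (inclusive).
#' @param window_len Masking window width in bp (non-overlapping windows).
#' @param window_divergence_max Fraction; a row window strictly more
#'   divergent than this from the consensus is replaced with `N`.
#' @param orf_inclusion_min Fraction of rows a reading frame must
#'   (strictly) exceed to be accepted.
#' @return An object of class `phf_qc_config`.
#' @export
qc_config <- function(ref_divergence_max = 0.40, min_taxa_exclusive = 3L,
                      min_len_exclusive = 100L, end_coverage_min = 0.50,
                      window_len = 100L, window_divergence_max = 0.40,
                      orf_inclusion_min = 0.90) {
  fr <- c(ref_divergence_max, end_coverage_min, window_divergence_max,
          orf_inclusion_min)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0,1]")
  if (window_len < 1L || min_len_exclusive < 0L)
    stop("lengths must be positive")
  structure(list(ref_divergence_max = ref_divergence_max,
                 min_taxa_exclusive = as.integer(min_taxa_exclusive),
                 min_len_exclusive = as.integer(min_len_exclusive),
                 end_coverage_min = end_coverage_min,
                 window_len = as.integer(window_len),
                 window_divergence_max = window_divergence_max,
                 orf_inclusion_min = orf_inclusion_min),
            class = "phf_qc_config")
}

#' Uncorrected pairwise distance
#'
#' Proportion of mismatching positions among positions where *both*
#' sequences carry an unambiguous nucleotide. Returns `NA` when no
#' position is comparable.
#'
#' @param s1,s2 Equal-length sequences, as strings or character vectors.
#' @return Fraction in \[0,1\], or `NA_real_`.
#' @export
pdistance <- function(s1, s2) {
  c1 <- if (length(s1) == 1L) strsplit(s1, "")[[1L]] else s1
  c2 <- if (length(s2) == 1L) strsplit(s2, "")[[1L]] else s2
  if (length(c1) != length(c2))
    stop("sequence length mismatch: ", length(c1), " vs ", length(c2))
  cmp <- is_unambiguous(c1) & is_unambiguous(c2)
  n <- sum(cmp)
  if (n == 0L) return(NA_real_)
  sum(c1[cmp] != c2[cmp]) / n
}

#' Remove samples too divergent from the reference sequence
#'
#' Rows with p-distance to `ref_taxon` strictly greater than
#' `cfg$ref_divergence_max` are removed, as is the reference row itself
#' (it is a design aid, not a sample). Removals are recorded in the
#' `"removed"` attribute. Rows sharing no comparable site with the
#' reference are retained and flagged in the attribute as
#' `"no_overlap"`.
#'
#' @param aln A `phf_alignment` containing `ref_taxon`.
#' @param ref_taxon Name of the reference row.
#' @param cfg A [qc_config()].
#' @return The screened alignment, with attribute `removed` (data.frame
#'   of taxon, divergence, action).
#' @export
screen_reference_divergence <- function(aln, ref_taxon, cfg = qc_config()) {
  if (!ref_taxon %in% taxa(aln))
    stop("reference taxon '", ref_taxon, "' absent from alignment '",
         aln$marker_id, "'")
  m <- aln_matrix(aln)
  ref <- m[ref_taxon, ]
  others <- setdiff(rownames(m), ref_taxon)
  div <- vapply(others, function(tx) pdistance(m[tx, ], ref), 0)
  drop <- !is.na(div) & div > cfg$ref_divergence_max
  log <- data.frame(
    taxon = c(others[drop], others[is.na(div)]),
    divergence = c(div[drop], div[is.na(div)]),
    action = c(rep("removed", sum(drop)),
               rep("no_overlap", sum(is.na(div)))),
    stringsAsFactors = FALSE)
  keep <- others[!drop]
  if (!length(keep))
    stop("screening removed every sample of '", aln$marker_id, "'")
  out <- alignment(aln$marker_id, aln$seqs[keep], aln$marker_class,
                   frame = aln$frame)
  attr(out, "removed") <- log
  out
}

#' Minimum-size keep rule
#'
#' `TRUE` iff the alignment has strictly more than `min_taxa_exclusive`
#' taxa and is strictly longer than `min_len_exclusive` bp.
#'
#' @inheritParams screen_reference_divergence
#' @return Logical scalar.
#' @export
qc_keep <- function(aln, cfg = qc_config()) {
  n_taxa(aln) > cfg$min_taxa_exclusive &&
    aln_length(aln) > cfg$min_len_exclusive
}

#' Trim alignment ends to a minimum row coverage
#'
#' Leading columns are removed up to the first column where the fraction
#' of rows carrying an unambiguous nucleotide is at least
#' `cfg$end_coverage_min`; trailing columns likewise from the right.
#' Interior columns are untouched.
#'
#' @inheritParams screen_reference_divergence
#' @return The trimmed alignment.
#' @export
trim_external <- function(aln, cfg = qc_config()) {
  m <- aln_matrix(aln)
  cov <- colMeans(matrix(m %in% UNAMBIG_BASES, nrow = nrow(m)))
  ok <- which(cov >= cfg$end_coverage_min)
  if (!length(ok))
    stop("external trimming would empty alignment '", aln$marker_id,
         "': no column reaches coverage ", cfg$end_coverage_min)
  first <- ok[1L]; last <- ok[length(ok)]
  if (first == 1L && last == ncol(m)) return(aln)
  aln_from_matrix(m[, first:last, drop = FALSE], aln)
}

# Majority-rule consensus over unambiguous states; alphabetical
# tie-break; 'N' where a column has no unambiguous state.
consensus_sequence <- function(aln) {
  m <- aln_matrix(aln)
  counts <- vapply(UNAMBIG_BASES, function(b) colSums(m == b),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(NULL, UNAMBIG_BASES))
  apply(counts, 1L, function(ct) {
    if (all(ct == 0)) "N" else UNAMBIG_BASES[which.max(ct)]
  })
}

# Non-overlapping window boundaries over L columns: full windows of
# `win`; a final partial window is kept separate when it spans at least
# win/2 columns, otherwise merged into the previous window.
window_bounds <- function(L, win) {
  if (L <= win) return(matrix(c(1L, L), ncol = 2L))
  n_full <- L %/% win
  rem <- L %% win
  starts <- seq.int(1L, by = win, length.out = n_full)
  ends <- starts + win - 1L
  if (rem > 0L) {
    if (rem >= win / 2) {
      starts <- c(starts, n_full * win + 1L)
      ends <- c(ends, L)
    } else {
      ends[n_full] <- L
    }
  }
  cbind(starts, ends)
}

#' Mask misaligned windows against the consensus
#'
#' The alignment is scanned in non-overlapping windows of
#' `cfg$window_len` columns (a final partial window at least half a
#' window wide is processed on its own; a shorter remainder is merged
#' into the preceding window). For every row, any window whose
#' p-distance to the majority-rule consensus is strictly greater than
#' `cfg$window_divergence_max` is replaced with `N`. Alignment
#' dimensions never change.
#'
#' @inheritParams screen_reference_divergence
#' @return The masked alignment, with attribute `masked` (data.frame of
#'   taxon, window start/end, divergence).
#' @export
mask_divergent_windows <- function(aln, cfg = qc_config()) {
  m <- aln_matrix(aln)
  cons <- consensus_sequence(aln)
  bounds <- window_bounds(ncol(m), cfg$window_len)
  log <- list()
  for (tx in rownames(m)) {
    for (w in seq_len(nrow(bounds))) {
      idx <- bounds[w, 1L]:bounds[w, 2L]
      d <- pdistance(m[tx, idx], cons[idx])
      if (!is.na(d) && d > cfg$window_divergence_max) {
        m[tx, idx] <- "N"
        log[[length(log) + 1L]] <- data.frame(
          taxon = tx, start = bounds[w, 1L], end = bounds[w, 2L],
          divergence = d, stringsAsFactors = FALSE)
      }
    }
  }
  out <- aln_from_matrix(m, aln)
  attr(out, "masked") <- if (length(log)) do.call(rbind, log) else
    data.frame(taxon = character(), start = integer(), end = integer(),
               divergence = numeric())
  out
}

#' Select an open reading frame and trim to whole codons
#'
#' For each offset 1-3 the alignment is notionally trimmed from the
#' offset to the last full codon; a row is "included" under that frame
#' when none of its fully unambiguous codons is a stop (`TAA`, `TAG`,
#' `TGA`; codons containing gaps or ambiguity are skipped). The frame
#' including the most rows wins, ties going to the smaller offset. The
#' returned alignment is trimmed to whole codons of the chosen frame and
#' carries `frame = 1` relative to its own columns (column 1 is codon
#' position 1), flagging it for codon partitioning.
#'
#' @inheritParams screen_reference_divergence
#' @return List with elements `frame` (offset 1, 2 or 3 in the input
#'   coordinates) and `alignment` (trimmed, frame-verified).
#' @export
select_reading_frame <- function(aln, cfg = qc_config()) {
  m <- aln_matrix(aln)
  L <- ncol(m)
  stops <- c("TAA", "TAG", "TGA")
  incl <- integer(3L)
  for (off in 1:3) {
    ncod <- (L - off + 1L) %/% 3L
    if (ncod < 1L) { incl[off] <- 0L; next }
    cols <- off:(off + 3L * ncod - 1L)
    sub <- m[, cols, drop = FALSE]
    ok <- vapply(seq_len(nrow(sub)), function(r) {
      cod <- matrix(sub[r, ], nrow = 3L)
      full <- colSums(matrix(cod %in% UNAMBIG_BASES, nrow = 3L)) == 3L
      if (!any(full)) return(TRUE)
      codons <- apply(cod[, full, drop = FALSE], 2L, paste, collapse = "")
      !any(codons %in% stops)
    }, NA)
    incl[off] <- sum(ok)
  }
  best <- which.max(incl)  # ties -> smallest offset
  if (incl[best] / nrow(m) <= cfg$orf_inclusion_min)
    stop("no reading frame of '", aln$marker_id, "' includes more than ",
         round(100 * cfg$orf_inclusion_min), "% of rows (best: ",
         incl[best], "/", nrow(m), ")")
  ncod <- (L - best + 1L) %/% 3L
  cols <- best:(best + 3L * ncod - 1L)
  trimmed <- aln_from_matrix(m[, cols, drop = FALSE], aln)
  trimmed$frame <- 1L
  list(frame = as.integer(best), alignment = trimmed)
}
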
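# Per-alignment summary statistics driving filtration: parsimony-
# informative sites, taxon sampling against a fixed study roster, and
# missing-data proportions.

#' Define the study-wide taxon roster
#'
#' The roster fixes the denominator of the sampling proportion: the study
#' samples that *could* appear in any alignment, not the union of taxa
#' actually observed.
#'
#' @param taxa Character vector of unique taxon names.
#' @return An object of class `phf_roster`.
#' @export
taxon_roster <- function(taxa) {
  taxa <- as.character(taxa)
  if (!length(taxa)) stop("roster must be non-empty")
  if (anyDuplicated(taxa)) stop("roster taxa must be unique")
  structure(list(taxa = taxa), class = "phf_roster")
}

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative when at least two distinct
#' unambiguous states (`A`, `C`, `G`, `T`) are each present in at least
#' two rows. Gaps, `N` and `?` never count as states.
#'
#' @param aln A `phf_alignment`.
#' @return Integer count of informative columns.
#' @export
count_pis <- function(aln) {
  m <- aln_matrix(aln)
  counts <- vapply(UNAMBIG_BASES, function(b) colSums(m == b),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)
  sum(rowSums(counts >= 2L) >= 2L)
}

#' Summarize one alignment against a roster
#'
#' Computes the four filtration statistics (sampling proportion,
#' number and proportion of parsimony-informative sites, alignment
#' length) plus the missing-data proportion: the fraction of cells in the
#' alignment that are `N`, `?` or `-`.
#'
#' @param aln A `phf_alignment` whose taxa are all roster members.
#' @param roster A [taxon_roster()].
#' @return A one-row data.frame with columns `marker_id`, `marker_class`,
#'   `length_bp`, `n_samples`, `sampling_prop`, `n_pis`, `prop_pis`,
#'   `missing_bp_prop`.
#' @export
summarize_alignment <- function(aln, roster) {
  stopifnot(inherits(aln, "phf_alignment"), inherits(roster, "phf_roster"))
  stray <- setdiff(taxa(aln), roster$taxa)
  if (length(stray))
    stop("alignment '", aln$marker_id, "' has taxa absent from roster: ",
         paste(stray, collapse = ", "))
  len <- aln_length(aln)
  ns <- n_taxa(aln)
  np <- count_pis(aln)
  m <- aln_matrix(aln)
  miss <- sum(m %in% MISSING_CHARS) / (ns * len)
  data.frame(marker_id = aln$marker_id, marker_class = aln$marker_class,
             length_bp = len, n_samples = ns,
             sampling_prop = ns / length(roster$taxa),
             n_pis = np, prop_pis = np / len,
             missing_bp_prop = miss, stringsAsFactors = FALSE)
}

#' Summarize a set of alignments
#'
#' Produces the per-marker statistics table (one row per alignment, TSV
#' serializable) together with set-level aggregates: mean, sd, min and
#' max per statistic plus total base pairs and total informative sites.
#'
#' @param alns List of `phf_alignment` with unique marker ids.
#' @param roster A [taxon_roster()].
#' @return List with elements `stats` (data.frame) and `aggregates`
#'   (data.frame of mean/sd/min/max rows per statistic, plus `total_bp`,
#'   `total_pis` attributes columns).
#' @export
summarize_set <- function(alns, roster) {
  if (!length(alns)) {
    empty <- summarize_alignment(
      alignment("x", c(t1 = "A")), taxon_roster("t1"))[0L, ]
    return(list(stats = empty, aggregates = set_aggregates(empty)))
  }
  ids <- vapply(alns, `[[`, "", "marker_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate marker_id(s): ", paste(dup, collapse = ", "))
  stats <- do.call(rbind, lapply(alns, summarize_alignment, roster = roster))
  rownames(stats) <- NULL
  list(stats = stats, aggregates = set_aggregates(stats))
}

set_aggregates <- function(stats) {
  vars <- c("length_bp", "n_samples", "sampling_prop", "n_pis", "prop_pis",
            "missing_bp_prop")
  if (!nrow(stats)) {
    return(data.frame(statistic = vars, mean = NA_real_, sd = NA_real_,
                      min = NA_real_, max = NA_real_,
                      total_bp = NA_real_, total_pis = NA_real_))
  }
  agg <- data.frame(
    statistic = vars,
    mean = vapply(vars, function(v) mean(stats[[v]]), 0),
    sd   = vapply(vars, function(v) stats::sd(stats[[v]]), 0),
    min  = vapply(vars, function(v) min(stats[[v]]), 0),
    max  = vapply(vars, function(v) max(stats[[v]]), 0),
    row.names = NULL)
  agg$total_bp <- sum(stats$length_bp)
  agg$total_pis <- sum(stats$n_pis)
  agg
}

#' Write / read an alignment statistics table as TSV
#'
#' @param stats Data.frame from [summarize_set()]`$stats`.
#' @param path TSV path.
#' @return `path` (write) or the stats data.frame (read).
#' @export
write_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_stats
#' @export
read_stats <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
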
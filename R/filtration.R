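# Threshold-series filtration of alignments and their paired gene trees.
# A filter keeps a marker when the chosen statistic is at or above the
# threshold, so threshold 0 is the identity and survivor sets are nested
# as the threshold rises.

FILTER_STATISTICS <- c("sampling_prop", "prop_pis", "n_pis", "length_bp")
FILTER_MODES <- c("summary_tree", "concatenation")

#' Build a filtration scheme with the standard threshold series
#'
#' The two modes carry the sweep series used for summary/site-based
#' species-tree inputs (dense series) and for concatenation (sparser,
#' compute-bound series):
#'
#' * `summary_tree`: sampling and proportion-informative 0.05-1.00 in
#'   0.05 steps; informative-site counts 10-100 by 10 then 200-700 by
#'   100; lengths 100-3,000 bp by 100.
#' * `concatenation`: sampling and proportion-informative 0.1-1.0 in 0.1
#'   steps; informative-site counts 10, 30, 50, 70, 100, 200, 500, 700,
#'   1,000; lengths 200, 500, 700, 1,000, 1,200, 1,500, 1,700, 2,000,
#'   2,200, 2,500 bp.
#'
#' Proportion series start at 0.05 (or 0.1), not 0: a zero threshold
#' filters nothing.
#'
#' @param statistic One of `"sampling_prop"`, `"prop_pis"`, `"n_pis"`,
#'   `"length_bp"`.
#' @param mode `"summary_tree"` or `"concatenation"`.
#' @return An object of class `phf_filter_scheme` with fields
#'   `statistic`, `mode`, `thresholds` (strictly ascending).
#' @export
make_threshold_series <- function(statistic = FILTER_STATISTICS,
                                  mode = FILTER_MODES) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  thresholds <- if (mode == "summary_tree") {
    switch(statistic,
           sampling_prop = seq(0.05, 1, by = 0.05),
           prop_pis      = seq(0.05, 1, by = 0.05),
           n_pis         = c(seq(10, 100, by = 10), seq(200, 700, by = 100)),
           length_bp     = seq(100, 3000, by = 100))
  } else {
    switch(statistic,
           sampling_prop = seq(0.1, 1, by = 0.1),
           prop_pis      = seq(0.1, 1, by = 0.1),
           n_pis         = c(10, 30, 50, 70, 100, 200, 500, 700, 1000),
           length_bp     = c(200, 500, 700, 1000, 1200, 1500, 1700,
                             2000, 2200, 2500))
  }
  filter_scheme(statistic, thresholds, mode)
}

#' @rdname make_threshold_series
#' @param thresholds Strictly ascending numeric vector of thresholds
#'   (all non-negative).
#' @export
filter_scheme <- function(statistic, thresholds, mode = "summary_tree") {
  statistic <- match.arg(statistic, FILTER_STATISTICS)
  mode <- match.arg(mode, FILTER_MODES)
  if (!length(thresholds) || any(diff(thresholds) <= 0) || any(thresholds < 0))
    stop("thresholds must be strictly ascending and non-negative")
  structure(list(statistic = statistic, thresholds = as.numeric(thresholds),
                 mode = mode),
            class = "phf_filter_scheme")
}

#' Filter alignments by a summary statistic
#'
#' Keeps markers whose statistic is greater than or equal to the
#' threshold.
#'
#' @param stats Statistics data.frame from [summarize_set()]`$stats`.
#' @param statistic Column to filter on (one of the four filtration
#'   statistics).
#' @param threshold Numeric threshold (keep if at least).
#' @return Character vector of surviving `marker_id`s, in table order.
#' @export
filter_alignments <- function(stats, statistic, threshold) {
  statistic <- match.arg(statistic, FILTER_STATISTICS)
  if (!statistic %in% names(stats))
    stop("statistic '", statistic, "' not present in stats table")
  stats$marker_id[stats[[statistic]] >= threshold]
}

#' Filter gene trees through their paired alignment statistics
#'
#' Gene trees are paired to alignments by `marker_id` (file stem). A
#' tree passes when its alignment passes [filter_alignments()]; input
#' order is preserved.
#'
#' @param trees List of `phf_gene_tree`.
#' @param stats Statistics table covering every tree's marker id.
#' @param statistic,threshold As in [filter_alignments()].
#' @param strict When `TRUE` (default) trees without a statistics row
#'   are an error; when `FALSE` they are dropped with a warning.
#' @return The surviving trees, original order.
#' @export
filter_gene_trees <- function(trees, stats, statistic, threshold,
                              strict = TRUE) {
  ids <- vapply(trees, `[[`, "", "marker_id")
  orphans <- setdiff(ids, stats$marker_id)
  if (length(orphans)) {
    msg <- paste0("gene tree(s) without a statistics row: ",
                  paste(orphans, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
    trees <- trees[!ids %in% orphans]
    ids <- ids[!ids %in% orphans]
  }
  keep <- filter_alignments(stats, statistic, threshold)
  trees[ids %in% keep]
}

#' Sweep a filtration scheme across its thresholds
#'
#' Applies every threshold of the scheme, recording survivor counts and
#' survivor totals; optionally writes one multi-tree Newick file per
#' threshold (survivor gene trees, one per line) for downstream
#' summary-tree programs.
#'
#' @param stats Statistics table.
#' @param scheme A [filter_scheme()].
#' @param trees Optional list of `phf_gene_tree` to filter alongside.
#' @param outdir Optional directory for per-threshold survivor tree
#'   files (`<statistic>_<threshold>.trees`).
#' @return A `phf_filter_report`: data.frame with columns `statistic`,
#'   `threshold`, `n_survivors`, `total_bp`, `total_pis`, `survivors`
#'   (comma-joined marker ids).
#' @export
filter_sweep <- function(stats, scheme, trees = NULL, outdir = NULL) {
  stopifnot(inherits(scheme, "phf_filter_scheme"))
  rows <- lapply(scheme$thresholds, function(th) {
    ids <- filter_alignments(stats, scheme$statistic, th)
    sub <- stats[stats$marker_id %in% ids, , drop = FALSE]
    if (!is.null(trees) && !is.null(outdir)) {
      surv <- filter_gene_trees(trees, stats, scheme$statistic, th)
      if (length(surv)) {
        fn <- file.path(outdir, sprintf("%s_%s.trees", scheme$statistic,
                                        format(th, trim = TRUE)))
        write_tree_lines(surv, fn)
      }
    }
    data.frame(statistic = scheme$statistic, threshold = th,
               n_survivors = length(ids),
               total_bp = sum(sub$length_bp), total_pis = sum(sub$n_pis),
               survivors = paste(ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("phf_filter_report", class(out))
  out
}
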
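# Supermatrix concatenation with codon-aware partitions, gene-jackknife
# resampling, and bipartition frequency summaries of replicate trees.

#' Construct a partition scheme
#'
#' A partition scheme is a list of entries `(name, start, end,
#' codon_offset)` over a matrix of `total_length` columns; codon entries
#' cover every third site of their interval starting at
#' `start + codon_offset - 1`. The expanded sites of all entries must
#' tile `1..total_length` exactly once.
#'
#' @param entries Data.frame with columns `name`, `start`, `end`,
#'   `codon_offset` (`NA` for contiguous entries).
#' @param total_length Number of matrix columns.
#' @return An object of class `phf_partition_scheme`.
#' @export
partition_scheme <- function(entries, total_length) {
  stopifnot(all(c("name", "start", "end", "codon_offset") %in% names(entries)))
  sites <- unlist(lapply(seq_len(nrow(entries)), function(i)
    partition_sites(entries[i, ])))
  if (length(sites) != total_length || anyDuplicated(sites) ||
      !setequal(sites, seq_len(total_length)))
    stop("partition entries must tile 1..", total_length, " exactly once")
  structure(list(entries = entries, total_length = as.integer(total_length)),
            class = "phf_partition_scheme")
}

partition_sites <- function(entry) {
  if (is.na(entry$codon_offset)) {
    seq.int(entry$start, entry$end)
  } else {
    seq.int(entry$start + entry$codon_offset - 1L, entry$end, by = 3L)
  }
}

#' Concatenate marker alignments into a partitioned supermatrix
#'
#' Markers are laid left to right in input order; every roster taxon
#' gets a row, with `-` filling the span of markers it is absent from.
#' Exon-class markers with a verified reading frame (see
#' [select_reading_frame()]) contribute three codon-position partition
#' entries; all other markers contribute one per-marker entry
#' (non-frame-verified exons fall back with a warning).
#'
#' @param alns List of `phf_alignment` with unique marker ids.
#' @param roster A [taxon_roster()]; all alignment taxa must be members.
#' @return A `phf_supermatrix`: list with `alignment` (the concatenated
#'   `phf_alignment`), `scheme` (a [partition_scheme()]) and
#'   `source_ids`.
#' @export
concatenate_alignments <- function(alns, roster) {
  stopifnot(length(alns) >= 1L, inherits(roster, "phf_roster"))
  ids <- vapply(alns, `[[`, "", "marker_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate marker_id(s): ", paste(dup, collapse = ", "))
  stray <- setdiff(unique(unlist(lapply(alns, taxa))), roster$taxa)
  if (length(stray))
    stop("alignment taxa absent from roster: ", paste(stray, collapse = ", "))
  lens <- vapply(alns, aln_length, 0L)
  pieces <- lapply(alns, function(a) {
    s <- a$seqs[roster$taxa]
    s[is.na(s)] <- strrep("-", aln_length(a))
    names(s) <- roster$taxa
    s
  })
  seqs <- do.call(function(...) paste0(...), pieces)
  names(seqs) <- roster$taxa
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  entries <- do.call(rbind, lapply(seq_along(alns), function(i) {
    a <- alns[[i]]
    if (a$marker_class == "exon" && !is.na(a$frame)) {
      data.frame(name = paste0(a$marker_id, "_pos", 1:3),
                 start = starts[i], end = ends[i], codon_offset = 1:3,
                 stringsAsFactors = FALSE)
    } else {
      if (a$marker_class == "exon")
        warning("exon marker '", a$marker_id,
                "' has no verified frame; using a per-marker partition")
      data.frame(name = a$marker_id, start = starts[i], end = ends[i],
                 codon_offset = NA_integer_, stringsAsFactors = FALSE)
    }
  }))
  structure(
    list(alignment = alignment("supermatrix", seqs, "unified"),
         scheme = partition_scheme(entries, sum(lens)),
         source_ids = ids),
    class = "phf_supermatrix")
}

#' @export
print.phf_supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d bp, %d markers, %d partitions\n",
              n_taxa(x$alignment), aln_length(x$alignment),
              length(x$source_ids), nrow(x$scheme$entries)))
  invisible(x)
}

#' Write a partition scheme
#'
#' `format = "raxml"` writes `DNA, name = start-end` lines (codon
#' entries as `start-end\3` beginning at the codon position's first
#' site); `format = "nexus"` writes a SETS block of charsets.
#'
#' @param scheme A [partition_scheme()].
#' @param path Output path.
#' @param format `"raxml"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(scheme, path, format = c("raxml", "nexus")) {
  format <- match.arg(format)
  e <- scheme$entries
  rng <- ifelse(is.na(e$codon_offset),
                sprintf("%d-%d", e$start, e$end),
                sprintf("%d-%d\\3", e$start + ifelse(is.na(e$codon_offset),
                                                     0L, e$codon_offset) - 1L,
                        e$end))
  lines <- if (format == "raxml") {
    sprintf("DNA, %s = %s", e$name, rng)
  } else {
    c("begin sets;", sprintf("    charset %s = %s;", e$name, rng), "end;")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Gene-jackknife resampling of markers to a base-pair target
#'
#' Each replicate draws markers sequentially without replacement (a
#' fresh random permutation per replicate) until the cumulative length
#' first reaches `target_bp`; the final marker may overshoot, so
#' replicate matrices are "nearly the same size". With `target_bp = 0`
#' a replicate contains exactly one marker.
#'
#' @param alns List of `phf_alignment`.
#' @param target_bp Cumulative length target in bp (default 200,000).
#' @param n_replicates Number of replicates.
#' @param seed Integer seed; identical seeds give identical replicate
#'   compositions.
#' @param roster Optional [taxon_roster()] used when `materialize =
#'   TRUE` (defaults to the union of taxa).
#' @param materialize When `TRUE`, each replicate record also carries a
#'   concatenated `phf_supermatrix` in `$matrix`.
#' @return List of replicate records: `replicate_index`, `marker_ids`,
#'   `total_bp`, `seed`, and optionally `matrix`.
#' @export
gene_jackknife <- function(alns, target_bp = 200000L, n_replicates,
                           seed = NULL, roster = NULL, materialize = FALSE) {
  stopifnot(n_replicates >= 1L, target_bp >= 0)
  lens <- vapply(alns, aln_length, 0L)
  if (sum(lens) < target_bp)
    stop("total available ", sum(lens), " bp < target ", target_bp, " bp")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(roster))
    roster <- taxon_roster(sort(unique(unlist(lapply(alns, taxa)))))
  lapply(seq_len(n_replicates), function(r) {
    perm <- sample.int(length(alns))
    cum <- cumsum(lens[perm])
    k <- if (target_bp == 0) 1L else which(cum >= target_bp)[1L]
    sel <- perm[seq_len(k)]
    rec <- list(replicate_index = r,
                marker_ids = vapply(alns[sel], `[[`, "", "marker_id"),
                total_bp = as.integer(cum[k]),
                seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
    if (materialize)
      rec$matrix <- concatenate_alignments(alns[sel], roster)
    rec
  })
}

#' Bipartition frequencies across a set of trees
#'
#' Summarizes replicate (e.g. jackknife) trees by the frequency of each
#' observed non-trivial bipartition. Trees may have unequal leaf sets:
#' a bipartition `A|B` is *observable* in a tree when at least two
#' members of each side are among its leaves, and *present* when the
#' tree, restricted to the shared members, displays the split. The
#' frequency denominator counts only observable trees.
#'
#' @param trees List of `phf_gene_tree` (at least one).
#' @return Data.frame with columns `bipartition` (smaller side,
#'   comma-joined), `n_present`, `n_observable`, `frequency`.
#' @export
clade_frequencies <- function(trees) {
  stopifnot(length(trees) >= 1L)
  tr <- lapply(trees, `[[`, "tree")
  sides_list <- lapply(tr, tree_split_sides)
  tips_list <- lapply(tr, `[[`, "tip.label")
  # collect distinct bipartitions, keyed over the union taxon set
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(tr)) {
    tips <- tips_list[[i]]
    for (side in sides_list[[i]]) {
      A <- sort(side); B <- sort(setdiff(tips, side))
      # canonical order: smaller side first, ties lexicographic
      if (length(B) < length(A) ||
          (length(B) == length(A) && paste(B, collapse = ",") <
             paste(A, collapse = ","))) { tmp <- A; A <- B; B <- tmp }
      key <- paste(paste(A, collapse = ","), paste(B, collapse = ","),
                   sep = " | ")
      if (is.null(seen[[key]])) seen[[key]] <- list(A = A, B = B)
    }
  }
  keys <- ls(seen)
  rows <- lapply(keys, function(key) {
    A <- seen[[key]]$A; B <- seen[[key]]$B
    pres <- obs <- 0L
    for (i in seq_along(tr)) {
      As <- intersect(A, tips_list[[i]])
      Bs <- intersect(B, tips_list[[i]])
      if (length(As) < 2L || length(Bs) < 2L) next
      obs <- obs + 1L
      if (tree_displays_split(sides_list[[i]], As, Bs)) pres <- pres + 1L
    }
    data.frame(bipartition = paste(A, collapse = ","),
               n_present = pres, n_observable = obs,
               frequency = pres / obs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$frequency, out$bipartition), , drop = FALSE]
}
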
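# Synthetic marker-set generator: a random species tree, gene trees
# whose topological error grows as alignment length shrinks (NNI noise
# with Poisson rate proportional to 1/length), and Jukes-Cantor
# sequence alignments. Together these emulate the statistical structure
# a filtration experiment assumes -- short markers carry more gene tree
# estimation error -- without re-estimating trees from sequence.

#' Simulation configuration
#'
#' Defaults mirror a sequence-capture study regime: 26 study taxa,
#' marker lengths log-uniform between 100 and 5,000 bp (median a few
#' hundred bp), modest per-taxon dropout, and branch lengths of a few
#' hundredths of a substitution per site.
#'
#' @param n_taxa Number of study taxa (at least 4; default 26).
#' @param n_markers Number of markers (default 200).
#' @param min_bp,max_bp Bounds of the log-uniform marker length
#'   distribution (defaults 100 and 5,000).
#' @param error_rate_scale `c`: expected number of NNI perturbations in
#'   a gene tree is `c * ref_len / length`, so shorter alignments get
#'   noisier trees. `c = 0` disables gene tree error.
#' @param ref_len Reference length at which the expected perturbation
#'   count equals `c` (default 1,000 bp).
#' @param substitution_scale Mean of the exponential branch-length
#'   distribution, substitutions/site (default 0.05).
#' @param dropout Per-taxon probability of being absent from a marker
#'   (default 0.1).
#' @param length_independent When `TRUE`, perturbation counts ignore
#'   alignment length (`K ~ Poisson(c)`), emulating ILS-like
#'   discordance that filtration cannot remove.
#' @param seed Integer seed for reproducibility.
#' @return An object of class `phf_sim_config`.
#' @export
sim_config <- function(n_taxa = 26L, n_markers = 200L, min_bp = 100L,
                       max_bp = 5000L, error_rate_scale = 1,
                       ref_len = 1000L, substitution_scale = 0.05,
                       dropout = 0.1, length_independent = FALSE,
                       seed = NULL) {
  if (n_taxa < 4L) stop("n_taxa must be at least 4")
  if (dropout < 0 || dropout > 1) stop("dropout must be in [0,1]")
  if (error_rate_scale < 0) stop("error_rate_scale must be non-negative")
  structure(list(n_taxa = as.integer(n_taxa),
                 n_markers = as.integer(n_markers),
                 min_bp = as.integer(min_bp), max_bp = as.integer(max_bp),
                 error_rate_scale = error_rate_scale,
                 ref_len = as.integer(ref_len),
                 substitution_scale = substitution_scale,
                 dropout = dropout,
                 length_independent = isTRUE(length_independent),
                 seed = seed),
            class = "phf_sim_config")
}

#' Simulate a random species tree
#'
#' Random unrooted binary topology over `cfg$n_taxa` labelled taxa with
#' exponential branch lengths (mean `cfg$substitution_scale`).
#'
#' @param cfg A [sim_config()].
#' @return A `phf_gene_tree` with marker id `"species_tree"`.
#' @export
simulate_species_tree <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tree <- ape::rtopology(cfg$n_taxa, rooted = FALSE,
                         tip.label = sprintf("t%02d", seq_len(cfg$n_taxa)))
  tree$edge.length <- stats::rexp(nrow(tree$edge),
                                  rate = 1 / cfg$substitution_scale)
  gene_tree("species_tree", tree)
}

#' Simulate gene trees with length-dependent topological error
#'
#' Each gene tree starts from the species tree, receives
#' `K ~ Poisson(c * ref_len / length)` random NNI rearrangements
#' (`K ~ Poisson(c)` in length-independent mode), and then loses each
#' taxon independently with probability `cfg$dropout` (at least four
#' leaves always remain). Support labels are assigned 100 on edges
#' whose bipartition agrees with the (pruned) species tree and a random
#' integer in 0-70 on discordant edges.
#'
#' @param sp Species tree (`phf_gene_tree`).
#' @param lengths Integer vector of marker lengths in bp.
#' @param cfg A [sim_config()]. The RNG is *not* reseeded here; seed
#'   once via [simulate_species_tree()] or [generate_study()].
#' @return List of `phf_gene_tree` (marker ids `m0001`, `m0002`, ...)
#'   with attribute `n_nni` (the drawn K per marker).
#' @export
simulate_gene_trees <- function(sp, lengths, cfg) {
  stopifnot(all(lengths >= 1L))
  sp_tree <- sp$tree
  ntip <- ape::Ntip(sp_tree)
  out <- vector("list", length(lengths))
  ks <- integer(length(lengths))
  for (i in seq_along(lengths)) {
    lambda <- if (cfg$length_independent) cfg$error_rate_scale
      else cfg$error_rate_scale * cfg$ref_len / lengths[i]
    K <- stats::rpois(1L, lambda)
    ks[i] <- K
    gt <- if (K > 0L) phangorn::rNNI(sp_tree, moves = K, n = 1L) else sp_tree
    keep <- sp_tree$tip.label[stats::runif(ntip) >= cfg$dropout]
    if (length(keep) < 4L)
      keep <- sample(sp_tree$tip.label, 4L)
    if (length(keep) < ntip) gt <- ape::keep.tip(gt, keep)
    gt <- label_against_species(gt, sp_tree)
    out[[i]] <- gene_tree(sprintf("m%04d", i), gt)
  }
  attr(out, "n_nni") <- ks
  out
}

# Support labels: 100 where the edge's bipartition is displayed by the
# species tree restricted to the gene tree's leaves, random 0-70 where
# not (a discordant edge would not attract high bootstrap in practice).
label_against_species <- function(gt, sp_tree) {
  gt <- safe_unroot(gt)
  ntip <- ape::Ntip(gt)
  sp_sides <- tree_split_sides(sp_tree)
  lab <- rep("", gt$Nnode)
  sp <- tree_splits(gt)
  for (s in sp) {
    side <- s$side
    other <- setdiff(gt$tip.label, side)
    concordant <- tree_displays_split(sp_sides, side, other)
    lab[s$node - ntip] <- if (concordant) "100"
      else as.character(sample.int(71L, 1L) - 1L)
  }
  gt$node.label <- lab
  gt
}

#' Simulate a Jukes-Cantor alignment along a tree
#'
#' Sites evolve independently under JC69 from a uniform root state, so
#' two leaves at path distance `d` have expected p-distance
#' `3/4 * (1 - exp(-4d/3))`.
#'
#' @param record A `phf_gene_tree` with branch lengths.
#' @param length Alignment length in bp (positive).
#' @param seed Optional integer seed.
#' @param marker_class Marker class recorded on the alignment.
#' @return A `phf_alignment` with the tree's leaves as taxa.
#' @export
simulate_sequences <- function(record, length, seed = NULL,
                               marker_class = "unified") {
  if (length < 1L) stop("alignment length must be positive")
  if (!is.null(seed)) set.seed(seed)
  tree <- record$tree
  dat <- phangorn::simSeq(tree, l = length, type = "DNA")
  m <- toupper(as.character(dat))
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- rownames(m)
  alignment(record$marker_id, seqs[tree$tip.label], marker_class)
}

#' Generate a complete synthetic study
#'
#' Draws marker lengths log-uniformly, simulates the species tree, the
#' per-marker gene trees (length-dependent NNI error, taxon dropout)
#' and JC69 alignments on each gene tree, and writes everything to
#' disk: `alignments/<id>.fasta`, `gene_trees/<id>.nwk`,
#' `species_tree.nwk` and a `manifest.tsv` with one row per marker
#' (`marker_id`, `length_bp`, `n_nni`, `n_taxa`, `dropped`).
#'
#' @param cfg A [sim_config()] (its `seed` drives all randomness).
#' @param outdir Output directory; created if needed. When `NULL`,
#'   nothing is written and the objects are only returned.
#' @return Invisible list: `alignments` (named list), `gene_trees`
#'   (named list), `species_tree`, `manifest` (data.frame), `dirs`.
#' @export
generate_study <- function(cfg, outdir = NULL) {
  sp <- simulate_species_tree(cfg)  # seeds the RNG
  lengths <- as.integer(round(exp(stats::runif(
    cfg$n_markers, log(cfg$min_bp), log(cfg$max_bp)))))
  trees <- simulate_gene_trees(sp, lengths, cfg)
  alns <- vector("list", length(trees))
  for (i in seq_along(trees))
    alns[[i]] <- simulate_sequences(trees[[i]], lengths[i])
  names(alns) <- vapply(alns, `[[`, "", "marker_id")
  names(trees) <- names(alns)
  manifest <- data.frame(
    marker_id = names(alns),
    length_bp = lengths,
    n_nni = attr(trees, "n_nni"),
    n_taxa = vapply(trees, function(g) ape::Ntip(g$tree), 0L),
    dropped = vapply(trees, function(g)
      paste(setdiff(sp$tree$tip.label, g$tree$tip.label), collapse = ","),
      ""),
    stringsAsFactors = FALSE)
  dirs <- NULL
  if (!is.null(outdir)) {
    aln_dir <- file.path(outdir, "alignments")
    tree_dir <- file.path(outdir, "gene_trees")
    dir.create(aln_dir, showWarnings = FALSE, recursive = TRUE)
    dir.create(tree_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(alns)) {
      write_alignment(alns[[id]], file.path(aln_dir, paste0(id, ".fasta")))
      ape::write.tree(trees[[id]]$tree,
                      file.path(tree_dir, paste0(id, ".nwk")))
    }
    ape::write.tree(sp$tree, file.path(outdir, "species_tree.nwk"))
    utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dirs <- list(alignments = aln_dir, gene_trees = tree_dir)
  }
  invisible(list(alignments = alns, gene_trees = trees, species_tree = sp,
                 manifest = manifest, dirs = dirs))
}
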
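# Generation of input/configuration files for the external species-tree
# programs: BPP (A01 species-tree estimation), SVDquartets (PAUP* NEXUS)
# and ASTRAL-III (collapsed multi-tree Newick). All writers are
# deterministic: identical inputs give byte-identical files.

#' BPP control-file settings
#'
#' Defaults are the species-tree (A01) run configuration used for
#' target-capture data sets: `burnin = 10000`, `sampfreq = 2`,
#' `nsample = 100000`, inverse-gamma-style `gamma(3, 0.004)` priors on
#' both the population-size (theta) and divergence-time (tau)
#' parameters, and one population per sample.
#'
#' @param burnin,sampfreq,nsample Positive integer MCMC settings.
#' @param theta_prior,tau_prior Numeric `c(alpha, beta)` gamma
#'   parameters.
#' @param species_map Optional named character vector mapping each
#'   sample to a population; defaults to one population per sample.
#' @return An object of class `phf_bpp_settings`.
#' @export
bpp_settings <- function(burnin = 10000L, sampfreq = 2L, nsample = 100000L,
                         theta_prior = c(3, 0.004), tau_prior = c(3, 0.004),
                         species_map = NULL) {
  if (any(c(burnin, sampfreq, nsample) <= 0))
    stop("MCMC settings must be positive integers")
  structure(list(burnin = as.integer(burnin), sampfreq = as.integer(sampfreq),
                 nsample = as.integer(nsample),
                 theta_prior = theta_prior, tau_prior = tau_prior,
                 species_map = species_map),
            class = "phf_bpp_settings")
}

#' Write BPP (A01) control, sequence and Imap files
#'
#' Serializes the alignments as BPP multi-locus Phylip-like blocks (one
#' block per alignment; sequence labels carry the `^individual` tag),
#' writes the Imap mapping each individual to its population, and a
#' control file for the "species tree estimation" mode
#' (`speciestree = 1`, `speciesdelimitation = 0`) with
#' `nloci` equal to the number of alignments. Keys not covered by
#' `settings` are written explicitly with their documented defaults so
#' the generated file is auditable.
#'
#' @param alns List of `phf_alignment` (at least one).
#' @param settings A [bpp_settings()].
#' @param outdir Output directory (created if needed).
#' @param guide_tree Optional Newick string for the starting species
#'   tree; defaults to a ladder over the populations.
#' @return Named character vector of the three file paths
#'   (`control`, `seqs`, `imap`), invisibly.
#' @export
write_bpp <- function(alns, settings = bpp_settings(), outdir,
                      guide_tree = NULL) {
  stopifnot(length(alns) >= 1L, inherits(settings, "phf_bpp_settings"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  all_taxa <- sort(unique(unlist(lapply(alns, taxa))))
  smap <- settings$species_map
  if (is.null(smap)) smap <- stats::setNames(all_taxa, all_taxa)
  missing <- setdiff(all_taxa, names(smap))
  if (length(missing))
    stop("taxa missing from species_map: ", paste(missing, collapse = ", "))
  pops <- unique(unname(smap[all_taxa]))

  seq_path <- file.path(outdir, "seqs.txt")
  con <- file(seq_path, "w")
  for (a in alns) {
    writeLines(sprintf("%d %d", n_taxa(a), aln_length(a)), con)
    writeLines(sprintf("%s^%s  %s", names(a$seqs), names(a$seqs), a$seqs),
               con)
    writeLines("", con)
  }
  close(con)

  imap_path <- file.path(outdir, "imap.txt")
  writeLines(sprintf("%s %s", all_taxa, unname(smap[all_taxa])), imap_path)

  if (is.null(guide_tree))
    guide_tree <- ladder_newick(pops)
  ctl_path <- file.path(outdir, "bpp.ctl")
  # max samples per population across loci
  counts <- vapply(pops, function(p) {
    max(vapply(alns, function(a) sum(smap[taxa(a)] == p), 0L))
  }, 0L)
  counts[counts == 0L] <- 1L
  lines <- c(
    "seed = -1",
    sprintf("seqfile = %s", basename(seq_path)),
    sprintf("Imapfile = %s", basename(imap_path)),
    "outfile = out.txt",
    "mcmcfile = mcmc.txt",
    "speciesdelimitation = 0",
    "speciestree = 1",
    sprintf("species&tree = %d  %s", length(pops), paste(pops, collapse = " ")),
    sprintf("                   %s", paste(counts, collapse = " ")),
    sprintf("                   %s", guide_tree),
    "usedata = 1",
    sprintf("nloci = %d", length(alns)),
    "cleandata = 0",
    sprintf("thetaprior = %g %g", settings$theta_prior[1L],
            settings$theta_prior[2L]),
    sprintf("tauprior = %g %g", settings$tau_prior[1L],
            settings$tau_prior[2L]),
    "finetune = 1: .01 .0001 .005 .0005 .2 .01 .01 .01",
    "print = 1 0 0 0",
    sprintf("burnin = %d", settings$burnin),
    sprintf("sampfreq = %d", settings$sampfreq),
    sprintf("nsample = %d", settings$nsample))
  writeLines(lines, ctl_path)
  invisible(c(control = ctl_path, seqs = seq_path, imap = imap_path))
}

ladder_newick <- function(labels) {
  if (length(labels) == 1L) return(paste0("(", labels, ");"))
  out <- labels[length(labels)]
  for (i in rev(seq_len(length(labels) - 1L)))
    out <- paste0("(", labels[i], ", ", out, ")")
  paste0(out, ";")
}

#' Write an SVDquartets NEXUS file
#'
#' Emits a NEXUS file with the supermatrix DATA block, a SETS block of
#' charsets from the partition scheme, and a PAUP block invoking
#' SVDquartets with exhaustive quartet evaluation (`evalq=all`) and
#' multi-locus bootstrapping.
#'
#' @param supermatrix A `phf_supermatrix` from
#'   [concatenate_alignments()].
#' @param outpath Output path.
#' @param nreps Bootstrap replicate count (default 1000).
#' @return `outpath`, invisibly.
#' @export
write_svdq_nexus <- function(supermatrix, outpath, nreps = 1000L) {
  stopifnot(inherits(supermatrix, "phf_supermatrix"))
  a <- supermatrix$alignment
  e <- supermatrix$scheme$entries
  rng <- ifelse(is.na(e$codon_offset),
                sprintf("%d-%d", e$start, e$end),
                sprintf("%d-%d\\3",
                        e$start + ifelse(is.na(e$codon_offset), 0L,
                                         e$codon_offset) - 1L, e$end))
  lines <- c(
    "#NEXUS",
    "begin data;",
    sprintf("    dimensions ntax=%d nchar=%d;", n_taxa(a), aln_length(a)),
    "    format datatype=dna missing=? gap=-;",
    "    matrix",
    sprintf("    %s  %s", names(a$seqs), a$seqs),
    "    ;",
    "end;",
    "begin sets;",
    sprintf("    charset %s = %s;", e$name, rng),
    "end;",
    "begin paup;",
    sprintf("    svdquartets evalq=all bootstrap=multilocus nreps=%d;",
            as.integer(nreps)),
    "    savetrees file=svdq.tre format=newick;",
    "end;")
  writeLines(lines, outpath)
  invisible(outpath)
}

#' Prepare the ASTRAL-III gene tree input file
#'
#' Applies [collapse_low_support()] to every gene tree (default: drop
#' branches below 10% bootstrap) and writes one Newick string per line,
#' in input order.
#'
#' @param trees List of `phf_gene_tree`.
#' @param collapse_threshold Integer support cutoff (strictly below
#'   collapses).
#' @param outpath Output path.
#' @return `outpath`, invisibly.
#' @export
prepare_astral_input <- function(trees, collapse_threshold = 10L, outpath) {
  stopifnot(length(trees) >= 1L)
  collapsed <- lapply(trees, collapse_low_support,
                      threshold = collapse_threshold)
  write_tree_lines(collapsed, outpath)
  invisible(outpath)
}
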
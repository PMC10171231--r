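# Gene tree records and Newick IO. Internal-node labels that are fully
# numeric integers are interpreted as bootstrap support in [0,100]
# (the IQ-Tree ultrafast-bootstrap convention); any other label is kept
# verbatim but ignored by support-aware operations.

#' Construct a gene tree record
#'
#' Pairs a marker id with an `ape::phylo` tree. Trees are treated as
#' unrooted throughout the package; integer internal-node labels are
#' bootstrap support values.
#'
#' @param marker_id Character scalar (usually the tree file stem).
#' @param tree An `ape::phylo` object.
#' @return An object of class `phf_gene_tree`.
#' @export
gene_tree <- function(marker_id, tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate leaf label(s) in tree '", marker_id, "': ",
         paste(dup, collapse = ", "))
  if (!is.null(tree$edge.length)) {
    tree$edge.length[is.na(tree$edge.length)] <- 0
    if (any(tree$edge.length < 0))
      stop("negative branch length in tree '", marker_id, "'")
  }
  sup <- node_supports(tree)
  if (any(!is.na(sup) & (sup < 0 | sup > 100)))
    stop("support outside [0,100] in tree '", marker_id, "'")
  structure(list(marker_id = marker_id, tree = tree), class = "phf_gene_tree")
}

#' @export
print.phf_gene_tree <- function(x, ...) {
  cat(sprintf("<gene tree '%s'> %d leaves, %d internal nodes\n",
              x$marker_id, ape::Ntip(x$tree), x$tree$Nnode))
  invisible(x)
}

# Integer-valued support per internal node (NA where the label is absent
# or not a plain integer, e.g. "0.95" or a clade name).
node_supports <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  sup <- rep(NA_real_, tree$Nnode)
  ok <- grepl("^[0-9]+$", lab)
  sup[ok] <- as.numeric(lab[ok])
  sup
}

#' Read a Newick gene tree
#'
#' Internal-node labels are parsed as integer support when fully numeric;
#' other labels (for instance SH-aLRT fractions such as `0.95`) are kept
#' as plain labels and excluded from support-aware computations, with a
#' message. Missing branch lengths default to 0.
#'
#' @param path Path to a file containing one Newick string.
#' @return A `phf_gene_tree`.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_balance(txt, path)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  lab <- tree$node.label
  if (!is.null(lab)) {
    odd <- nzchar(lab) & !grepl("^[0-9]+$", lab)
    if (any(odd))
      message("tree ", basename(path), ": ", sum(odd),
              " non-integer internal label(s) kept but not treated as support")
  }
  gene_tree(tools::file_path_sans_ext(basename(path)), tree)
}

check_newick_balance <- function(txt, path = "<string>") {
  chars <- strsplit(txt, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("unbalanced parentheses in ", path, " at character ", i)
  }
  if (depth != 0L)
    stop("unbalanced parentheses in ", path,
         ": ", depth, " unclosed '(' at end of input")
  invisible(TRUE)
}

#' Read every Newick tree in a directory as gene tree records
#'
#' @param dir Directory of `.nwk`/`.tre`/`.treefile`/`.newick` files.
#' @return Named list of `phf_gene_tree` keyed by marker id (file stem).
#' @export
read_tree_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(nwk|tre|tree|treefile|newick)$",
                      full.names = TRUE)
  trees <- lapply(files, read_tree)
  names(trees) <- vapply(trees, `[[`, "", "marker_id")
  trees
}

#' Write gene trees as a multi-tree Newick file (one tree per line)
#'
#' @param trees List of `phf_gene_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_lines <- function(trees, path) {
  txt <- vapply(trees, function(gt) ape::write.tree(gt$tree), "")
  writeLines(txt, path)
  invisible(path)
}

#' Read clade definitions from a TSV file
#'
#' Expected columns: `name`, `member`, optional `role` (rows with
#' `role == "outgroup"` define the clade's outgroup set).
#'
#' @param path TSV path.
#' @return Named list of [clade_definition()] objects.
#' @export
read_clades <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("name", "member") %in% names(df)))
    stop("clade file must have columns 'name' and 'member'")
  if (!"role" %in% names(df)) df$role <- ""
  out <- lapply(split(df, df$name), function(d) {
    clade_definition(d$name[1L],
                     members = d$member[d$role != "outgroup"],
                     outgroup = d$member[d$role == "outgroup"])
  })
  out[unique(df$name)]
}
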
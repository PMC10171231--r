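# Internal split (bipartition) machinery shared by the monophyly,
# branch-collapsing and concordance-factor code. A split of an unrooted
# tree is represented by the set of tip labels on one side; keys are
# canonicalized against the tree's own leaf set so the two sides of an
# edge hash identically.

# Enumerate the non-trivial splits of a tree (treated as unrooted).
# Returns a list of entries: side (character vector of tips on the
# descendant side), support (numeric or NA), node (internal node id in
# the unrooted tree). Splits of size < 2 or > ntip-2 are dropped.
tree_splits <- function(tree) {
  tree <- safe_unroot(tree)
  ntip <- ape::Ntip(tree)
  if (tree$Nnode < 2L) return(list())
  sup <- node_supports(tree)
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  out <- vector("list", length(pp) - 1L)
  k <- 0L
  for (i in seq_along(pp)) {
    if (i == 1L) next  # root: all tips
    side <- labels[pp[[i]]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    k <- k + 1L
    out[[k]] <- list(side = side, support = sup[i], node = ntip + i)
  }
  out[seq_len(k)]
}

safe_unroot <- function(tree) {
  if (ape::Ntip(tree) > 2L && ape::is.rooted(tree)) ape::unroot(tree) else tree
}

# Canonical key for the split side|rest over leaf set `tips`: the side not
# containing the lexicographically smallest tip, sorted and pasted.
split_key <- function(side, tips) {
  anchor <- min(tips)
  if (anchor %in% side) side <- setdiff(tips, side)
  paste(sort(side), collapse = "\r")
}

# Keys of all non-trivial splits of a tree.
tree_split_keys <- function(tree) {
  sp <- tree_splits(tree)
  tips <- tree$tip.label
  vapply(sp, function(s) split_key(s$side, tips), "")
}

# Does `tree` (unrooted) contain the split side|complement over its own
# leaf set?
has_split <- function(tree, side) {
  split_key(side, tree$tip.label) %in% tree_split_keys(tree)
}

# Restriction test used by concordance factors and cross-leafset clade
# frequencies: given candidate sides P and Q (subsets of the tree's leaf
# set, disjoint, each of size >= 2), does some edge of the tree induce
# P|Q on P united Q?  Splits of an induced subtree are exactly the
# non-trivial restrictions of the full tree's splits.
tree_displays_split <- function(split_sides, P, Q) {
  for (side in split_sides) {
    p_in <- sum(P %in% side)
    q_in <- sum(Q %in% side)
    # side must contain all of P and none of Q, or vice versa
    if ((p_in == length(P) && q_in == 0L) ||
        (q_in == length(Q) && p_in == 0L)) return(TRUE)
  }
  FALSE
}

# Raw split sides of a tree (list of character vectors), for repeated
# restriction tests against the same tree.
tree_split_sides <- function(tree) lapply(tree_splits(tree), `[[`, "side")
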
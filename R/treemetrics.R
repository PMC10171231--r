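# Clade monophyly and support scoring across gene tree sets, low-support
# branch collapsing, gene concordance factors, and the branch-length vs.
# support regression.

#' Define a named clade
#'
#' @param name Clade name (e.g. a subfamily).
#' @param members Taxon names belonging to the clade.
#' @param outgroup Optional taxon names usable for rooting; must be
#'   disjoint from `members`.
#' @return An object of class `phf_clade`.
#' @export
clade_definition <- function(name, members, outgroup = character()) {
  members <- unique(as.character(members))
  outgroup <- unique(as.character(outgroup))
  if (!length(members)) stop("clade '", name, "' has no members")
  if (length(intersect(members, outgroup)))
    stop("clade '", name, "': outgroup overlaps members")
  structure(list(name = name, members = members, outgroup = outgroup),
            class = "phf_clade")
}

#' Test clade monophyly on an unrooted gene tree
#'
#' Monophyly is evaluated on the taxa actually present: with
#' `M = members` intersected with the leaves and `O` the remaining
#' leaves, the clade is monophyletic iff `M|O` is a bipartition of the
#' unrooted tree. When fewer than two members or fewer than two
#' non-members are present, monophyly is undefined and the result is
#' `"not_evaluable"`.
#'
#' @param record A `phf_gene_tree`.
#' @param clade A [clade_definition()].
#' @return `"yes"`, `"no"` or `"not_evaluable"`.
#' @export
is_monophyletic <- function(record, clade) {
  tree <- record$tree
  M <- intersect(clade$members, tree$tip.label)
  O <- setdiff(tree$tip.label, M)
  if (length(M) < 2L || length(O) < 2L) return("not_evaluable")
  if (has_split(tree, M)) "yes" else "no"
}

#' Score clade monophyly and strong support across gene trees
#'
#' For each evaluable tree (see [is_monophyletic()]) the clade counts as
#' monophyletic when its bipartition is displayed, and as strongly
#' supported when that bipartition's edge additionally carries integer
#' bootstrap support at or above `support_threshold`. Edges without an
#' integer support label never count as strong. Proportions use the
#' number of evaluable trees as denominator; with zero evaluable trees
#' both proportions are `NA`.
#'
#' @param trees List of `phf_gene_tree`.
#' @param clade A [clade_definition()].
#' @param support_threshold Integer bootstrap cutoff (default 90,
#'   inclusive).
#' @return One-row data.frame: `clade`, `n_trees`, `n_evaluable`,
#'   `n_monophyletic`, `n_strong`, `prop_monophyletic`, `prop_strong`,
#'   `support_threshold`.
#' @export
clade_support <- function(trees, clade, support_threshold = 90L) {
  stopifnot(length(trees) >= 1L)
  n_eval <- n_mono <- n_strong <- 0L
  for (rec in trees) {
    tree <- rec$tree
    M <- intersect(clade$members, tree$tip.label)
    O <- setdiff(tree$tip.label, M)
    if (length(M) < 2L || length(O) < 2L) next
    n_eval <- n_eval + 1L
    key <- split_key(M, tree$tip.label)
    sp <- tree_splits(tree)
    hit <- NULL
    for (s in sp) if (split_key(s$side, tree$tip.label) == key) { hit <- s; break }
    if (is.null(hit)) next
    n_mono <- n_mono + 1L
    if (!is.na(hit$support) && hit$support >= support_threshold)
      n_strong <- n_strong + 1L
  }
  data.frame(clade = clade$name, n_trees = length(trees),
             n_evaluable = n_eval, n_monophyletic = n_mono,
             n_strong = n_strong,
             prop_monophyletic = if (n_eval) n_mono / n_eval else NA_real_,
             prop_strong = if (n_eval) n_strong / n_eval else NA_real_,
             support_threshold = as.integer(support_threshold),
             stringsAsFactors = FALSE)
}

#' Collapse poorly supported branches into polytomies
#'
#' Internal edges whose integer bootstrap support is strictly below
#' `threshold` are contracted (their length is discarded). Leaf edges
#' and edges without an integer support label are never contracted:
#' absence of a label is treated as support-unknown, not as low
#' support. Support exactly at the threshold is retained.
#'
#' @param record A `phf_gene_tree`.
#' @param threshold Integer support cutoff (default 10; collapse when
#'   strictly below).
#' @return A `phf_gene_tree` with the same leaves.
#' @export
collapse_low_support <- function(record, threshold = 10L) {
  tree <- safe_unroot(record$tree)
  sup <- node_supports(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  nodes <- ntip + which(!is.na(sup) & sup < threshold)
  nodes <- setdiff(nodes, root)
  if (!length(nodes)) return(gene_tree(record$marker_id, tree))
  gene_tree(record$marker_id, contract_nodes(tree, nodes))
}

# Contract the edges above the given internal nodes: each node's
# children are reattached to its nearest non-contracted ancestor.
contract_nodes <- function(tree, nodes) {
  edge <- tree$edge
  elen <- tree$edge.length
  ntip <- ape::Ntip(tree)
  parent <- integer(max(edge))
  parent[edge[, 2L]] <- edge[, 1L]
  eff <- function(v) { while (v %in% nodes) v <- parent[v]; v }
  keep <- !(edge[, 2L] %in% nodes)
  new_edge <- edge[keep, , drop = FALSE]
  new_edge[, 1L] <- vapply(new_edge[, 1L], eff, 0L)
  if (!is.null(elen)) elen <- elen[keep]
  # renumber: tips keep 1..ntip; surviving internals get ntip+1.. in
  # old-number order with the root first
  old_int <- sort(unique(new_edge[, 1L]))
  root <- ntip + 1L
  old_int <- c(root, setdiff(old_int, root))
  map <- integer(max(edge))
  map[seq_len(ntip)] <- seq_len(ntip)
  map[old_int] <- ntip + seq_along(old_int)
  out <- list(edge = cbind(map[new_edge[, 1L]], map[new_edge[, 2L]]),
              tip.label = tree$tip.label,
              Nnode = length(old_int))
  if (!is.null(elen)) out$edge.length <- elen
  if (!is.null(tree$node.label))
    out$node.label <- tree$node.label[old_int - ntip]
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}

#' Gene concordance factors for a species tree
#'
#' For every internal branch of the species tree (bipartition `P|Q`), a
#' gene tree is *decisive* when it contains at least two leaves from
#' each side, and *concordant* when, restricted to the shared leaves,
#' it displays the branch's bipartition. The gene concordance factor is
#' `100 * n_concordant / n_decisive` (reported as a percentage;
#' `NA` when no gene tree is decisive).
#'
#' @param species_tree A `phf_gene_tree` (or `phylo`) with at least one
#'   internal branch.
#' @param trees List of `phf_gene_tree`.
#' @return A data.frame with one row per internal species-tree branch:
#'   `bipartition` (smaller side, comma-joined), `gcf_percent`,
#'   `n_concordant`, `n_decisive`.
#' @export
gene_concordance <- function(species_tree, trees) {
  sp_tree <- if (inherits(species_tree, "phf_gene_tree"))
    species_tree$tree else species_tree
  branches <- tree_splits(sp_tree)
  if (!length(branches))
    stop("species tree has no internal branch")
  tips_sp <- sp_tree$tip.label
  gt <- lapply(trees, `[[`, "tree")
  gt_sides <- lapply(gt, tree_split_sides)
  gt_tips <- lapply(gt, `[[`, "tip.label")
  rows <- lapply(branches, function(br) {
    P <- br$side
    Q <- setdiff(tips_sp, P)
    conc <- dec <- 0L
    for (i in seq_along(gt)) {
      Ps <- intersect(P, gt_tips[[i]])
      Qs <- intersect(Q, gt_tips[[i]])
      if (length(Ps) < 2L || length(Qs) < 2L) next
      dec <- dec + 1L
      if (tree_displays_split(gt_sides[[i]], Ps, Qs)) conc <- conc + 1L
    }
    small <- if (length(P) <= length(Q)) P else Q
    data.frame(bipartition = paste(sort(small), collapse = ","),
               gcf_percent = if (dec) 100 * conc / dec else NA_real_,
               n_concordant = conc, n_decisive = dec,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ordinary least squares regression of support on branch length
#'
#' Fits `y ~ x` by OLS and reports the slope, intercept, coefficient of
#' determination and the two-sided t-test p-value for the slope. Used
#' to test whether shorter branches (substitutions/site) are associated
#' with lower clade monophyly or bootstrap-support proportions.
#'
#' @param x Numeric predictor (branch lengths), length at least 3, not
#'   constant.
#' @param y Numeric response (proportions), same length.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`.
#' @export
ols_support_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0)
    stop("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- stats::coef(sm)
  list(slope = unname(co["x", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = sm$r.squared,
       p_value = unname(co["x", "Pr(>|t|)"]))
}
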
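# Fixture builders and independent oracle implementations used by the
# unit and acceptance suites. Oracles deliberately take a different
# computational route than the package code they check.

make_aln <- function(..., id = "m1", class = "unified") {
  alignment(id, c(...), marker_class = class)
}

random_aln <- function(n_taxa, len, missing_frac = 0.1, id = "m1") {
  pool <- c("A", "C", "G", "T")
  miss <- c("N", "-", "?")
  seqs <- vapply(seq_len(n_taxa), function(i) {
    ch <- sample(pool, len, replace = TRUE)
    k <- rbinom(1L, len, missing_frac)
    if (k > 0) ch[sample.int(len, k)] <- sample(miss, k, replace = TRUE)
    paste(ch, collapse = "")
  }, "")
  names(seqs) <- sprintf("tax%02d", seq_len(n_taxa))
  alignment(id, seqs)
}

# A biologically "clean" alignment: every row is a lightly mutated copy
# of one base sequence, so consensus divergence stays far below any
# masking/screening threshold.
family_aln <- function(n_taxa, len, div = 0.05, id = "fam") {
  pool <- c("A", "C", "G", "T")
  base <- sample(pool, len, replace = TRUE)
  seqs <- vapply(seq_len(n_taxa), function(i) {
    ch <- base
    k <- rbinom(1L, len, div)
    if (k > 0) {
      at <- sample.int(len, k)
      ch[at] <- vapply(ch[at], function(x) sample(setdiff(pool, x), 1L), "")
    }
    paste(ch, collapse = "")
  }, "")
  names(seqs) <- sprintf("tax%02d", seq_len(n_taxa))
  alignment(id, seqs)
}

random_gene_tree <- function(n_taxa, id = "g1", supports = TRUE) {
  tree <- ape::rtree(n_taxa, tip.label = sprintf("t%02d", seq_len(n_taxa)))
  tree <- ape::unroot(tree)
  if (supports)
    tree$node.label <- as.character(sample(0:100, tree$Nnode, replace = TRUE))
  gene_tree(id, tree)
}

# --- count_pis oracle: explicit per-column loop with table() ------------
oracle_count_pis <- function(aln) {
  m <- phylofiltr:::aln_matrix(aln)
  n <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    tb <- table(col)
    if (sum(tb >= 2) >= 2) n <- n + 1L
  }
  n
}

# --- monophyly oracle: edge-removal component enumeration ---------------
# For every edge of the unrooted tree, delete it and read off the two
# leaf components by breadth-first search over the remaining edges.
oracle_bipartitions <- function(tree) {
  tree <- if (ape::Ntip(tree) > 2 && ape::is.rooted(tree))
    ape::unroot(tree) else tree
  edges <- tree$edge
  nv <- max(edges)
  out <- list()
  for (e in seq_len(nrow(edges))) {
    adj <- edges[-e, , drop = FALSE]
    comp <- rep(NA_integer_, nv)
    frontier <- edges[e, 1L]
    comp[frontier] <- 1L
    while (length(frontier)) {
      nxt <- c(adj[adj[, 1L] %in% frontier, 2L],
               adj[adj[, 2L] %in% frontier, 1L])
      nxt <- nxt[is.na(comp[nxt])]
      comp[nxt] <- 1L
      frontier <- unique(nxt)
    }
    side <- tree$tip.label[which(comp[seq_len(ape::Ntip(tree))] == 1L)]
    if (length(side) >= 2 && length(side) <= ape::Ntip(tree) - 2)
      out[[length(out) + 1L]] <- sort(side)
  }
  unique(out)
}

oracle_is_monophyletic <- function(record, clade) {
  tree <- record$tree
  M <- sort(intersect(clade$members, tree$tip.label))
  O <- setdiff(tree$tip.label, M)
  if (length(M) < 2 || length(O) < 2) return("not_evaluable")
  bips <- oracle_bipartitions(tree)
  for (b in bips)
    if (identical(b, M) || identical(sort(setdiff(tree$tip.label, b)), M))
      return("yes")
  "no"
}

# --- OLS oracle: normal equations + t distribution ----------------------
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept,
       r_squared = 1 - rss / tss,
       p_value = 2 * stats::pt(-abs(tval), df = n - 2))
}
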
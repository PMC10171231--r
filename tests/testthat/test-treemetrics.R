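# Monophyly, clade support, branch collapsing, gene concordance
# factors, OLS regression.

gt_txt <- function(s, id = "g") gene_tree(id, ape::read.tree(text = s))

test_that("is_monophyletic evaluates bipartitions on present taxa", {
  gt <- gt_txt("((A,B),(C,D));")
  expect_equal(is_monophyletic(gt, clade_definition("x", c("A", "B"))), "yes")
  expect_equal(is_monophyletic(gt, clade_definition("x", c("A", "C"))), "no")
  # absent member E ignored: evaluated on {A,B}
  expect_equal(is_monophyletic(gt, clade_definition("x", c("A", "B", "E"))),
               "yes")
  # fewer than 2 members or non-members present
  expect_equal(is_monophyletic(gt, clade_definition("x", c("A"))),
               "not_evaluable")
  expect_equal(is_monophyletic(gt, clade_definition("x", c("A", "B", "C"))),
               "not_evaluable")
})

test_that("is_monophyletic agrees with the edge-removal oracle", {
  set.seed(17)
  for (i in 1:120) {
    n <- sample(4:10, 1)
    gt <- random_gene_tree(n, supports = FALSE)
    k <- sample(2:(n - 1), 1)
    clade <- clade_definition("r", sample(gt$tree$tip.label, k))
    expect_equal(is_monophyletic(gt, clade),
                 oracle_is_monophyletic(gt, clade))
  }
})

test_that("clade_support counts monophyly and strong support separately", {
  # trifurcating roots: each internal edge carries exactly one label
  mono_hi <- "((A:1,B:1)95:1,(C:1,D:1)99:1,E:1);"
  mono_lo <- "((A:1,B:1)60:1,(C:1,D:1)99:1,E:1);"
  not_mono <- "((A:1,C:1)99:1,(B:1,D:1)99:1,E:1);"
  trees <- c(lapply(1:4, function(i) gt_txt(mono_hi, paste0("h", i))),
             lapply(1:3, function(i) gt_txt(mono_lo, paste0("l", i))),
             lapply(1:3, function(i) gt_txt(not_mono, paste0("n", i))))
  rep <- clade_support(trees, clade_definition("AB", c("A", "B")))
  expect_equal(rep$n_evaluable, 10L)
  expect_equal(rep$prop_monophyletic, 0.7)
  expect_equal(rep$prop_strong, 0.4)
  # identical trees, support 100 everywhere
  all100 <- lapply(1:5, function(i)
    gt_txt("((A:1,B:1)100:1,(C:1,D:1)100:1,E:1);", paste0("x", i)))
  rep2 <- clade_support(all100, clade_definition("AB", c("A", "B")))
  expect_equal(rep2$prop_monophyletic, 1)
  expect_equal(rep2$prop_strong, 1)
  # clade evaluable in no tree
  rep3 <- clade_support(all100, clade_definition("ZZ", c("Z1", "Z2")))
  expect_equal(rep3$n_evaluable, 0L)
  expect_true(is.na(rep3$prop_monophyletic))
  # prop_strong never exceeds prop_monophyletic, monotone in threshold
  set.seed(18)
  trs <- lapply(1:20, function(i) random_gene_tree(8, paste0("m", i)))
  cl <- clade_definition("c", sprintf("t%02d", 1:3))
  prev <- 1
  for (th in c(0, 50, 90, 101)) {
    r <- clade_support(trs, cl, th)
    expect_lte(r$prop_strong, r$prop_monophyletic)
    expect_lte(r$prop_strong, prev)
    prev <- r$prop_strong
  }
})

test_that("collapse_low_support contracts exactly the weak labelled edges", {
  gt <- gt_txt("((A:1,B:1)5:1,((C:1,D:1)95:2,E:1)50:1,F:1);")
  before <- length(phylofiltr:::tree_splits(gt$tree))
  out <- collapse_low_support(gt, 10)
  expect_equal(length(phylofiltr:::tree_splits(out$tree)), before - 1L)
  expect_setequal(out$tree$tip.label, gt$tree$tip.label)
  expect_equal(is_monophyletic(out, clade_definition("ab", c("A", "B"))), "no")
  expect_equal(is_monophyletic(out, clade_definition("cd", c("C", "D"))),
               "yes")
  # surviving branch lengths are preserved
  sp <- phylofiltr:::tree_splits(out$tree)
  cd_node <- NULL
  for (s in sp) if (setequal(s$side, c("C", "D"))) cd_node <- s$node
  expect_equal(out$tree$edge.length[out$tree$edge[, 2] == cd_node], 2)
  # all supports at/above threshold -> identical topology
  hi <- gt_txt("((A:1,B:1)10:1,((C:1,D:1)95:1,E:1)50:1,F:1);")
  expect_equal(length(phylofiltr:::tree_splits(
    collapse_low_support(hi, 10)$tree)), 3L)
  # unlabeled edges are never contracted
  nolab <- gene_tree("n", ape::read.tree(text = "((A,B),(C,D),E);"))
  expect_equal(length(phylofiltr:::tree_splits(
    collapse_low_support(nolab, 10)$tree)), 2L)
})

test_that("collapse_low_support is idempotent and validates on random trees", {
  set.seed(19)
  for (i in 1:25) {
    gt <- random_gene_tree(sample(5:12, 1))
    out <- collapse_low_support(gt, 30)
    sup <- phylofiltr:::node_supports(out$tree)
    kept <- sup[!is.na(sup)]
    # only edges with support >= threshold (or root/unlabelled) survive
    keys <- phylofiltr:::tree_splits(out$tree)
    for (s in keys) if (!is.na(s$support)) expect_gte(s$support, 30)
    again <- collapse_low_support(out, 30)
    expect_setequal(phylofiltr:::tree_split_keys(again$tree),
                    phylofiltr:::tree_split_keys(out$tree))
    report <- capture.output(ape::checkValidPhylo(out$tree))
    expect_false(any(grepl("FATAL|MODERATE", report)))
  }
})

test_that("gene concordance factors follow the decisiveness rule", {
  sp <- gt_txt("((A,B),(C,D),(E,F));", "sp")
  identical10 <- lapply(1:10, function(i) gt_txt("((A,B),(C,D),(E,F));",
                                                 paste0("i", i)))
  gcf <- gene_concordance(sp, identical10)
  expect_true(all(gcf$gcf_percent == 100))
  expect_true(all(gcf$n_decisive == 10))

  # 4 decisive, 2 concordant for the AB branch
  disc <- "((A,C),(B,D),(E,F));"
  conc <- "((A,B),(C,D),(E,F));"
  # a tree missing B is non-decisive for AB|rest
  nodec <- ape::drop.tip(ape::read.tree(text = conc), "B")
  mixed <- c(lapply(1:2, function(i) gt_txt(conc, paste0("c", i))),
             lapply(1:2, function(i) gt_txt(disc, paste0("d", i))),
             list(gene_tree("nd", nodec)))
  gcf2 <- gene_concordance(sp, mixed)
  ab <- gcf2[gcf2$bipartition == "A,B", ]
  expect_equal(ab$n_decisive, 4L)
  expect_equal(ab$n_concordant, 2L)
  expect_equal(ab$gcf_percent, 50)

  # zero decisive trees -> NA with n_decisive 0
  tiny <- list(gene_tree("t", ape::read.tree(text = "((A,C),(E,F));")))
  gcf3 <- gene_concordance(sp, tiny)
  ab3 <- gcf3[gcf3$bipartition == "A,B", ]
  expect_equal(ab3$n_decisive, 0L)
  expect_true(is.na(ab3$gcf_percent))
})

test_that("random gene trees approach the random-resolution baseline", {
  set.seed(20)
  sp <- random_gene_tree(10, "sp", supports = FALSE)
  rand <- lapply(1:100, function(i) random_gene_tree(10, paste0("r", i),
                                                     supports = FALSE))
  gcf <- gene_concordance(sp, rand)
  # wide sanity band: random trees agree with any given branch rarely
  expect_lt(mean(gcf$gcf_percent), 50)
})

test_that("OLS regression matches the closed-form normal equations", {
  x <- c(1, 2, 3, 4, 5)
  # exact fits trigger summary.lm's "essentially perfect fit" warning
  fit <- suppressWarnings(ols_support_regression(x, 2 * x))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  fit0 <- suppressWarnings(ols_support_regression(x, rep(0.5, 5)))
  expect_equal(fit0$slope, 0, tolerance = 1e-12)
  expect_error(ols_support_regression(rep(1, 5), x), "constant")
  expect_error(ols_support_regression(1:2, 1:2), "at least 3")
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- runif(n); y <- 0.3 + 1.7 * x + rnorm(n, sd = 0.2)
    got <- ols_support_regression(x, y)
    want <- oracle_ols(x, y)
    for (f in names(want))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-10)
  }
})
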
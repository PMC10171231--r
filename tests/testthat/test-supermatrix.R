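# Concatenation, partition schemes, gene jackknifing, bipartition
# frequencies.

test_that("concatenation lays markers in order and gap-fills absentees", {
  roster <- taxon_roster(c("a", "b", "c"))
  a1 <- alignment("m1", c(a = strrep("A", 100), b = strrep("C", 100),
                          c = strrep("G", 100)))
  a2 <- alignment("m2", c(a = strrep("T", 200), b = strrep("G", 200)))
  sm <- concatenate_alignments(list(a1, a2), roster)
  expect_equal(aln_length(sm$alignment), 300L)
  expect_equal(sm$source_ids, c("m1", "m2"))
  e <- sm$scheme$entries
  expect_equal(e$start, c(1L, 101L))
  expect_equal(e$end, c(100L, 300L))
  # taxon c absent from m2 -> gap fill across its span
  expect_equal(substr(sm$alignment$seqs[["c"]], 101, 300), strrep("-", 200))
  expect_equal(substr(sm$alignment$seqs[["a"]], 101, 300), strrep("T", 200))
  expect_error(concatenate_alignments(list(a1, a1), roster), "duplicate")
})

test_that("frame-verified exons get three codon partitions", {
  roster <- taxon_roster(c("a", "b"))
  ex <- alignment("ex1", c(a = strrep("ATG", 100), b = strrep("ATG", 100)),
                  marker_class = "exon", frame = 1L)
  sm <- concatenate_alignments(list(ex), roster)
  e <- sm$scheme$entries
  expect_equal(nrow(e), 3L)
  expect_equal(e$codon_offset, 1:3)
  expect_equal(e$start, rep(1L, 3)); expect_equal(e$end, rep(300L, 3))
  f <- withr::local_tempfile()
  write_partitions(sm$scheme, f, "raxml")
  expect_equal(readLines(f),
               c("DNA, ex1_pos1 = 1-300\\3", "DNA, ex1_pos2 = 2-300\\3",
                 "DNA, ex1_pos3 = 3-300\\3"))
  # non-frame-verified exon falls back to a per-marker partition
  ex2 <- alignment("ex2", c(a = strrep("ATG", 10), b = strrep("ATG", 10)),
                   marker_class = "exon")
  expect_warning(sm2 <- concatenate_alignments(list(ex2), roster),
                 "no verified frame")
  expect_equal(nrow(sm2$scheme$entries), 1L)
})

test_that("partition intervals tile the matrix exactly once", {
  set.seed(88)
  roster <- taxon_roster(sprintf("tax%02d", 1:6))
  for (i in 1:5) {
    alns <- lapply(1:4, function(j) {
      cls <- sample(c("exon", "intron", "uce"), 1)
      len <- if (cls == "exon") 3L * sample(5:40, 1) else sample(20:200, 1)
      a <- random_aln(sample(3:6, 1), len, 0, id = sprintf("p%d_%d", i, j))
      a$marker_class <- cls
      if (cls == "exon") a$frame <- 1L
      a
    })
    sm <- concatenate_alignments(alns, roster)
    sites <- unlist(lapply(seq_len(nrow(sm$scheme$entries)), function(k)
      phylofiltr:::partition_sites(sm$scheme$entries[k, ])))
    expect_equal(sort(sites), seq_len(aln_length(sm$alignment)))
    # partition_scheme validates on construction; dropping an entry must fail
    bad <- sm$scheme$entries[-1L, , drop = FALSE]
    expect_error(partition_scheme(bad, aln_length(sm$alignment)), "tile")
  }
})

test_that("supermatrix PIS is additive over markers with a shared roster", {
  set.seed(99)
  roster <- taxon_roster(sprintf("tax%02d", 1:6))
  alns <- lapply(1:5, function(i) random_aln(6, sample(20:80, 1),
                                             id = paste0("q", i)))
  sm <- concatenate_alignments(alns, roster)
  expect_equal(count_pis(sm$alignment), sum(vapply(alns, count_pis, 0L)))
})

test_that("gene jackknife hits the target with minimal overshoot", {
  mk <- function(len, id) alignment(id, c(a = strrep("A", len),
                                          b = strrep("C", len)))
  # 10 markers x 50 kb, target 200 kb -> exactly 4 markers each replicate
  alns <- lapply(1:10, function(i) mk(50000L, sprintf("j%02d", i)))
  reps <- gene_jackknife(alns, target_bp = 200000L, n_replicates = 20,
                         seed = 7)
  for (r in reps) {
    expect_length(r$marker_ids, 4L)
    expect_equal(r$total_bp, 200000L)
  }
  # determinism: same seed, same compositions
  reps2 <- gene_jackknife(alns, target_bp = 200000L, n_replicates = 20,
                          seed = 7)
  expect_identical(lapply(reps, `[[`, "marker_ids"),
                   lapply(reps2, `[[`, "marker_ids"))
  # target 0 -> single-marker replicates
  r0 <- gene_jackknife(alns, target_bp = 0L, n_replicates = 3, seed = 1)
  expect_true(all(vapply(r0, function(r) length(r$marker_ids), 0L) == 1L))
  expect_error(gene_jackknife(alns[1:2], target_bp = 200000L,
                              n_replicates = 1, seed = 1), "total available")
})

test_that("jackknife minimality and near-uniform marker inclusion", {
  set.seed(13)
  lens <- sample(300:900, 60, replace = TRUE)
  alns <- lapply(seq_along(lens), function(i)
    alignment(sprintf("u%02d", i), c(a = strrep("A", lens[i]),
                                     b = strrep("C", lens[i]))))
  target <- 10000L
  reps <- gene_jackknife(alns, target_bp = target, n_replicates = 200,
                         seed = 3, materialize = FALSE)
  lens_by_id <- setNames(lens, vapply(alns, `[[`, "", "marker_id"))
  incl <- table(unlist(lapply(reps, `[[`, "marker_ids")))
  for (r in reps) {
    expect_gte(r$total_bp, target)
    last <- r$marker_ids[length(r$marker_ids)]
    expect_lt(r$total_bp - lens_by_id[[last]], target)  # minimality
    expect_equal(r$total_bp, sum(lens_by_id[r$marker_ids]))
  }
  # inclusion roughly uniform: each marker selected with similar frequency
  p_hat <- mean(incl) / 200
  expect_true(all(abs(incl / 200 - p_hat) < 5 * sqrt(p_hat * (1 - p_hat) / 200)))
})

test_that("materialized replicates concatenate their selected markers", {
  set.seed(14)
  alns <- lapply(1:6, function(i)
    random_aln(4, 200, 0, id = sprintf("w%d", i)))
  reps <- gene_jackknife(alns, target_bp = 500L, n_replicates = 2, seed = 9,
                         materialize = TRUE)
  for (r in reps) {
    expect_s3_class(r$matrix, "phf_supermatrix")
    expect_equal(aln_length(r$matrix$alignment), r$total_bp)
    expect_equal(r$matrix$source_ids, r$marker_ids)
  }
})

test_that("clade_frequencies counts presence over observable trees", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),(E,F));")
  same <- lapply(1:10, function(i) gene_tree(paste0("s", i), t1))
  cf <- clade_frequencies(same)
  expect_true(all(cf$frequency == 1))
  # 6 of 10 trees contain AB|rest, 4 have A,C swapped
  t2 <- ape::read.tree(text = "((C,B),(A,D),(E,F));")
  mix <- c(lapply(1:6, function(i) gene_tree(paste0("a", i), t1)),
           lapply(1:4, function(i) gene_tree(paste0("b", i), t2)))
  cf2 <- clade_frequencies(mix)
  ab <- cf2[cf2$bipartition == "A,B", ]
  expect_equal(ab$n_observable, 10L)
  expect_equal(ab$frequency, 0.6)
  # bipartition observable in a subset only: denominator shrinks
  t3 <- ape::drop.tip(t1, c("A", "B"))   # leaves C D E F
  part <- c(lapply(1:5, function(i) gene_tree(paste0("c", i), t1)),
            lapply(1:5, function(i) gene_tree(paste0("d", i), t3)))
  cf3 <- clade_frequencies(part)
  ab3 <- cf3[cf3$bipartition == "A,B", ]
  expect_equal(ab3$n_observable, 5L)
  expect_equal(ab3$frequency, 1)
})
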
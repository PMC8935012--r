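test_that("gap blocks are maximal runs with identical carrier sets", {
  aln <- gene_alignment(c(sp1 = "ATG---TAA", sp2 = "ATGGCGTAA"), "g")
  b <- find_gap_blocks(aln)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$col_start, b$col_end), c(4L, 6L))
  expect_equal(b$carriers, "sp1")

  aln2 <- gene_alignment(c(sp1 = "A--T", sp2 = "A--T", sp3 = "ACGT"), "g")
  b2 <- find_gap_blocks(aln2)
  expect_equal(nrow(b2), 1L)
  expect_equal(c(b2$col_start, b2$col_end), c(2L, 3L))
  expect_equal(b2$carriers, "sp1,sp2")

  expect_equal(nrow(find_gap_blocks(
    gene_alignment(c(a = "ACGT", b = "ACGT"), "g"))), 0L)

  # differing carrier sets split adjacent gapped columns into two blocks
  aln3 <- gene_alignment(c(a = "A--T", b = "A-CT", c = "ACCT"), "g")
  b3 <- find_gap_blocks(aln3)
  expect_equal(nrow(b3), 2L)

  # all-gap columns are dropped with a warning
  expect_warning(
    b4 <- find_gap_blocks(gene_alignment(c(a = "A-T", b = "A-T"), "g")),
    "all-gap")
  expect_equal(nrow(b4), 0L)
})

test_that("placement resolves terminal and clade gaps, discarding ties", {
  tr <- quartet_tree()
  # single-leaf carrier: terminal-edge deletion, complement is no clade
  ev <- place_event(list(col_start = 4L, col_end = 5L, carriers = "a"), tr)
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$descendants, "a")
  expect_true(ev$polarity_confident)

  # a clade strictly inside the tree: unambiguous stem deletion
  tr5 <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,(d:1,e:1):1);")
  ev5 <- place_event(list(col_start = 4L, col_end = 5L, carriers = "a,b"),
                     tr5)
  expect_equal(ev5$kind, "deletion")
  expect_equal(ev5$descendants, "a,b")

  # carriers forming one half of the root bipartition: the minimal
  # reconstruction exists with either root state (deletion below one
  # child or insertion below the other) -> polarity tie, discarded
  ev_tie <- place_event(list(col_start = 4L, col_end = 5L,
                             carriers = "a,b"), tr)
  expect_equal(nrow(ev_tie), 0L)
  expect_equal(attr(ev_tie, "reason"), "root_ambiguous")

  # two changes required: homoplastic
  ev2 <- place_event(list(col_start = 4L, col_end = 5L, carriers = "a,c"), tr)
  expect_equal(nrow(ev2), 0L)
  expect_equal(attr(ev2, "reason"), "homoplastic")

  # carriers {c,d}: both bipartition halves are clades -> root ambiguous
  ev3 <- place_event(list(col_start = 4L, col_end = 5L, carriers = "c,d"), tr)
  expect_equal(nrow(ev3), 0L)
  expect_equal(attr(ev3, "reason"), "root_ambiguous")

  expect_error(place_event(list(col_start = 1L, col_end = 1L,
                                carriers = "a,b,c,d"), tr),
               "uninformative")
})

test_that("placement agrees with exhaustive minimum-change search", {
  set.seed(101)
  for (n in 4:6) {
    for (rep in 1:6) {
      tr <- ape::rtree(n, tip.label = letters[1:n])
      subsets <- seq_len(2^n - 2)  # all nonempty proper carrier sets
      for (mask in subsets) {
        carriers <- letters[1:n][bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L]
        got <- place_event(list(col_start = 1L, col_end = 1L,
                                carriers = paste(carriers, collapse = ",")),
                           tr)
        want <- oracle_place(tr, carriers)
        if (is.null(want)) {
          expect_equal(nrow(got), 0L)
        } else {
          expect_equal(nrow(got), 1L)
          expect_equal(got$kind, want$kind)
          expect_equal(strsplit(got$descendants, ",")[[1]],
                       want$descendants)
        }
      }
    }
  }
})

test_that("indel inference assigns events to edges with correct polarity", {
  # single-leaf 2-nt gap: terminal deletion
  aln <- block_alignment("a", gap_len = 2L)
  ev <- infer_indels(aln, quartet_tree())
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$length_nt, 2L)
  expect_equal(ev$descendants, "a")

  # clade-shared 3-nt gap on an internal (non-root-child) edge:
  # stem deletion
  tr5 <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,(d:1,e:1):1);")
  aln2 <- block_alignment(c("a", "b"), tips = letters[1:5], gap_len = 3L)
  ev2 <- infer_indels(aln2, tr5)
  expect_equal(ev2$kind, "deletion")
  expect_equal(ev2$length_nt, 3L)
  expect_equal(ev2$descendants, "a,b")

  expect_equal(nrow(infer_indels(block_alignment(character(0)),
                                 quartet_tree())), 0L)
  expect_error(infer_indels(block_alignment("a"), quartet_tree(),
                            included_species = c("a", "b", "c")),
               "too few species")
})

test_that("event inference is invariant to row order and yields clades", {
  set.seed(77)
  tr <- ape::rtree(6, tip.label = letters[1:6])
  rows <- setNames(rep("ATGAAACCCGGGTTTAAATAA", 6), letters[1:6])
  substr(rows[["b"]], 7, 8) <- "--"
  substr(rows[["c"]], 7, 8) <- "--"   # may or may not be a clade
  substr(rows[["e"]], 13, 13) <- "-"
  aln <- gene_alignment(rows, "g")
  ev1 <- suppressMessages(infer_indels(aln, tr))
  aln_perm <- gene_alignment(rows[sample(names(rows))], "g")
  ev2 <- suppressMessages(infer_indels(aln_perm, tr))
  expect_equal(ev1[order(ev1$col_start), ], ev2[order(ev2$col_start), ],
               ignore_attr = TRUE)
  for (d in strsplit(ev1$descendants, ",")) {
    m <- if (length(d) == 1) match(d, tr$tip.label) else ape::getMRCA(tr, d)
    below <- if (m <= 6) tr$tip.label[m] else
      ape::extract.clade(tr, m)$tip.label
    expect_setequal(below, d)
  }
})
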
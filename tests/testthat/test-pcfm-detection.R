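# a 4-species alignment in which species "a" carries a deletion pair
pair_fixture <- function(len5 = 2L, len3 = 1L, spacer = 21L) {
  n_codons <- 40L
  set.seed(9)
  base <- pcfm:::random_cds(n_codons)
  rows <- setNames(rep(base, 4), c("a", "b", "c", "d"))
  p5 <- 10L
  p3 <- p5 + len5 + spacer
  substr(rows[["a"]], p5, p5 + len5 - 1L) <- strrep("-", len5)
  substr(rows[["a"]], p3, p3 + len3 - 1L) <- strrep("-", len3)
  list(aln = gene_alignment(rows, "gfix"), p5 = p5, p3 = p3)
}

detect_fixture <- function(fix) {
  ev <- infer_indels(fix$aln, quartet_tree())
  q <- quality_check_alignment(fix$aln)
  pair_pcfms(ev, q, fix$aln)
}

test_that("two frame-disrupting indels with net offset 0 mod 3 form one pair", {
  fix <- pair_fixture()
  # carrier must still encode a clean ORF for the fixture to be usable
  expect_true(quality_check(fix$aln$rows[["a"]])$passes)
  pairs <- detect_fixture(fix)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$combined_offset, -3L)
  expect_equal(pairs$carriers, "a")
  expect_equal(pairs$spacer_nt, 21L)
  expect_true(pairs$same_edge)
})

test_that("singletons and >2 frame-disrupting indels yield no pairs", {
  # one lone 1-nt deletion: nothing to pair (and carrier fails mod-3)
  rows <- setNames(rep("ATGAAACCCGGGTTTAAATAA", 4), c("a", "b", "c", "d"))
  substr(rows[["a"]], 8, 8) <- "-"
  aln <- gene_alignment(rows, "g1")
  ev <- infer_indels(aln, quartet_tree())
  expect_equal(nrow(pair_pcfms(ev, quality_check_alignment(aln), aln)), 0L)

  # three 1-nt deletions: net -3 keeps the frame but the species is excluded
  set.seed(4)
  rows2 <- setNames(rep(pcfm:::random_cds(40), 4), c("a", "b", "c", "d"))
  for (p in c(10L, 40L, 70L)) substr(rows2[["a"]], p, p) <- "-"
  aln2 <- gene_alignment(rows2, "g3")
  ev2 <- infer_indels(aln2, quartet_tree())
  q2 <- quality_check_alignment(aln2)
  expect_equal(nrow(pair_pcfms(ev2, q2, aln2)), 0L)
})

test_that("postfilter enforces length, combination, edge and carrier rules", {
  mk <- function(k5, l5, k3, l3, same_edge, n_carr) data.frame(
    gene_id = "g", kind_5p = k5, len_5p = l5, col_start_5p = 5L,
    col_end_5p = 5L + l5 - 1L, kind_3p = k3, len_3p = l3,
    col_start_3p = 30L, col_end_3p = 30L + l3 - 1L, spacer_nt = 20L,
    spacer_nt_anc = 20L, combined_offset = 0L, same_edge = same_edge,
    edge_label = "a", n_carriers = n_carr, carriers = "a",
    stringsAsFactors = FALSE)
  pairs <- rbind(
    mk("deletion", 2L, "deletion", 1L, TRUE, 1L),    # kept (low only)
    mk("deletion", 1L, "insertion", 1L, TRUE, 4L),   # kept in both
    mk("deletion", 4L, "insertion", 1L, TRUE, 3L),   # length > 2
    mk("deletion", 2L, "deletion", 1L, FALSE, 3L),   # cross-edge
    mk("deletion", 2L, "insertion", 1L, TRUE, 3L),   # disallowed combo
    mk("insertion", 2L, "deletion", 2L, TRUE, 2L))   # kept in both
  low <- postfilter_pcfms(pairs, "low_confidence")
  high <- postfilter_pcfms(pairs, "high_confidence")
  expect_equal(nrow(low), 3L)
  expect_equal(nrow(high), 2L)
  # high subset of low subset of input
  expect_true(all(rownames(high) %in% rownames(low)))
  expect_true(all(rownames(low) %in% rownames(pairs)))
  expect_error(postfilter_pcfms(pairs, "nonsense"))
})

test_that("relative position honors its boundary conditions", {
  expect_equal(relative_position(0, 30, 300), 0)
  expect_equal(relative_position(270, 300, 300), 1)
  expect_equal(relative_position(10, 20, 110), 0.1)
  expect_error(relative_position(0, 300, 300), "degenerate")
  # extending only the 3' flank strictly decreases P
  p <- vapply(c(0, 30, 90), function(add)
    relative_position(60, 90, 300 + add), numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("pair endpoints measured on a non-carrier row give P in [0,1]", {
  fix <- pair_fixture()
  pairs <- detect_fixture(fix)
  pos <- pcfm_positions(pairs[1, ], fix$aln)
  expect_equal(pos$p1, fix$p5 - 1L)
  expect_equal(pos$p2, fix$p3)       # 3' edge of the 3' indel
  expect_equal(pos$L, 120L)
  expect_equal(pos$P, pos$p1 / (pos$L - (pos$p2 - pos$p1)))
})

test_that("position-distribution comparison tests uniformity and reference", {
  set.seed(31)
  u <- runif(500)
  res <- compare_position_distributions(u, n_boot = 200, seed = 5)
  expect_gt(res$ks_uniform$p.value, 0.001)
  # identical observed and reference: two-sample D = 0
  res2 <- compare_position_distributions(u, u, n_boot = 50, seed = 5)
  expect_equal(unname(res2$ks_reference$statistic), 0)
  # mass clustered near 0: decisive rejection of uniformity
  res3 <- compare_position_distributions(runif(100, 0.01, 0.05),
                                         n_boot = 50, seed = 5)
  expect_lt(res3$ks_uniform$p.value, 0.001)
  expect_error(compare_position_distributions(u, n_boot = 0), "n_boot")
  # bootstrap density CIs bracket the point estimate
  expect_true(all(res$density$lower <= res$density$density + 1e-9))
  expect_true(all(res$density$upper >= res$density$density - 1e-9))
})
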
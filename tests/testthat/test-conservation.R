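test_that("per-site Shannon entropy hits its exact bounds", {
  rows <- c(s1 = "AAW", s2 = "AAW", s3 = "AWW", s4 = "AWW")
  ep <- entropy_profile(rows, window = 1)
  expect_equal(ep$H[1], 0)            # constant column
  expect_equal(ep$H[2], log(2))       # two equal classes
  expect_equal(ep$H[3], 0)
  # 20-way uniform column reaches ln 20
  aas <- rownames(miyata_matrix())
  rows20 <- setNames(paste0(aas, "A"), paste0("s", 1:20))
  ep20 <- entropy_profile(rows20, window = 2)
  expect_equal(ep20$H[1], log(20))
  expect_equal(length(ep20$window_scores), 1L)
  # bounds and row-permutation invariance on random alignments
  set.seed(3)
  for (i in 1:10) {
    m <- replicate(8, paste(sample(c(aas, "-"), 12, TRUE), collapse = ""))
    names(m) <- paste0("x", 1:8)
    H1 <- suppressMessages(entropy_profile(m, 1))$H
    H2 <- suppressMessages(entropy_profile(sample(m), 1))$H
    expect_equal(H1, H2)
    expect_true(all(is.na(H1) | (H1 >= 0 & H1 <= log(20) + 1e-12)))
  }
  expect_error(entropy_profile(rows, window = 10), "window")
})

test_that("region percentile ranks a span against same-length windows", {
  expect_equal(region_conservation_percentile(rep(2, 10), 3, 5), 1.0)
  # increasing profile, window 2, leftmost span is the unique minimum
  expect_equal(region_conservation_percentile(1:10, 1, 2), 1 / 9)
  # affine invariance
  sc <- c(5, 1, 4, 9, 2, 7, 3)
  expect_equal(region_conservation_percentile(sc, 2, 4),
               region_conservation_percentile(3 * sc - 11, 2, 4))
  expect_error(region_conservation_percentile(1:5, 2, 9), "span longer")
})

test_that("gene age measures root-to-MRCA distance in both modes", {
  tr <- ape::read.tree(text = "((a:1,b:1):2,c:3);")
  expect_equal(gene_age(tr, c("a", "b"), "branch_sum"), 2)
  expect_equal(gene_age(tr, c("a", "b"), "branch_count"), 1)
  expect_equal(gene_age(tr, "a", "branch_sum"), 3)   # MRCA of {a} is a
  expect_equal(gene_age(tr, c("a", "c"), "branch_sum"), 0)  # spans the root
  expect_error(gene_age(tr, "zz"), "not in tree")
  # both modes weakly decrease as the functional set grows
  tr2 <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,(d:1,e:1):2);")
  sets <- list("a", c("a", "b"), c("a", "b", "c"), c("a", "b", "c", "d"))
  for (mode in c("branch_sum", "branch_count")) {
    ages <- vapply(sets, gene_age, numeric(1), tree = tr2, mode = mode)
    expect_true(all(diff(ages) <= 0))
  }
})

test_that("functional fraction counts quality-passing rows", {
  aln <- gene_alignment(c(a = "ATGAAATAA", b = "ATGAAATAA",
                          c = "TTGAAATAA", d = "ATGTAATAA"), "g")
  expect_equal(functional_fraction(aln), 0.5)
})

test_that("paired Wilcoxon comparison handles signal, noise and degeneracy", {
  deg <- paired_comparison(rep(1, 6), rep(1, 6))
  expect_true(deg$degenerate)
  expect_null(deg$test)
  # all-positive distinct differences, n = 10: exact one-sided p = 1/2^10
  up <- paired_comparison(2:11 + seq(0.1, 1, 0.1), 2:11,
                          alternative = "greater")
  expect_equal(up$test$p.value, 1 / 2^10, tolerance = 1e-9)
  # alternating symmetric differences: no signal
  ctrl <- seq(10, 100, 10)
  alt <- paired_comparison(ctrl + c(1, -1), ctrl)
  expect_gt(alt$test$p.value, 0.5)
  expect_error(paired_comparison(1:3, 2:4), "insufficient")
  expect_error(paired_comparison(1:5, 1:6), "length")
})

test_that("likelihood-ratio arithmetic matches the chi-square df=1 null", {
  eq <- lrt_two_omega(-100, -100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  expect_equal(lrt_two_omega(-100, -100 + 3.84 / 2)$p, 0.05, tolerance = 0.003)
  expect_equal(round(lrt_two_omega(-500, -500 + 3.78 / 2)$p, 2), 0.05)
  expect_error(lrt_two_omega(-100, -101), "inconsistent")
  # TSV reader appends the test per gene
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlnL_1param\tlnL_2param",
               "g1\t-1000\t-998.11", "g2\t-800\t-800"), f)
  df <- read_omega_fits(f)
  expect_equal(df$lrt_statistic, c(3.78, 0))
  expect_equal(round(df$lrt_p, 2), c(0.05, 1))
})

test_that("matched controls are detectability-verified and reproducible", {
  tr <- quartet_tree()
  set.seed(500)
  pool <- lapply(1:6, function(i) {
    gene_alignment(setNames(rep(pcfm:::random_cds(60), 4),
                            c("a", "b", "c", "d")),
                   paste0("ctrl", i))
  })
  names(pool) <- vapply(pool, `[[`, character(1), "gene_id")
  # a case pair carried by leaf "a"
  case <- data.frame(
    gene_id = "case1", kind_5p = "deletion", len_5p = 2L,
    col_start_5p = 10L, col_end_5p = 11L, kind_3p = "deletion", len_3p = 1L,
    col_start_3p = 33L, col_end_3p = 33L, spacer_nt = 21L,
    spacer_nt_anc = 21L, combined_offset = -3L, same_edge = TRUE,
    edge_label = "a", n_carriers = 1L, carriers = "a",
    stringsAsFactors = FALSE)
  m1 <- build_matched_controls(case, pool, tr, max_attempts = 6, seed = 2)
  expect_false(is.na(m1$control_gene))
  expect_true(m1$control_gene %in% names(pool))
  # control pool genes contain no pair before planting
  expect_false(pcfm:::detects_any_pair(pool[[m1$control_gene]], tr))
  # fixed seed reproduces the pairing
  m2 <- build_matched_controls(case, pool, tr, max_attempts = 6, seed = 2)
  expect_identical(m1, m2)
})
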
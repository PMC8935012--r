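test_that("templates validate the frame-restoration arithmetic", {
  tpl <- pcfm_template("deletion", 2, "deletion", 1, 26)
  expect_equal(tpl$net_offset, -3L)
  expect_error(pcfm_template("deletion", 1, "insertion", 2, 5),
               "not divisible by 3")
  expect_equal(pcfm_template("insertion", 1, "deletion", 1, 0)$net_offset, 0L)
})

test_that("in-silico application edits exactly the spanned region", {
  # ATG AAA CCC GGG TAA: del-2 at nt 4, del-1 after a 2-nt spacer
  tpl <- pcfm_template("deletion", 2, "deletion", 1, 2)
  app <- apply_pcfm("ATGAAACCCGGGTAA", 4, tpl)
  expect_equal(app$nt, "ATGACCGGGTAA")
  expect_equal(app$net_offset, -3L)
  # downstream-of-span translation identical to the original
  ce <- app$codon_region[2]
  expect_equal(translate_nt(substr(app$nt, ce + 1 + app$net_offset,
                                   nchar(app$nt))),
               translate_nt(substr("ATGAAACCCGGGTAA", ce + 1, 15)))
  # net-zero template preserves length
  app0 <- apply_pcfm("ATGAAACCCGGGTAA", 5,
                     pcfm_template("insertion", 1, "deletion", 1, 0),
                     seed = 2)
  expect_equal(nchar(app0$nt), 15L)
  # placements touching start/stop codons are rejected
  expect_error(apply_pcfm("ATGAAACCCGGGTAA", 1, tpl), "placement")
  expect_error(apply_pcfm("ATGAAATAA", 4, tpl), "placement")
})

test_that("frame restoration holds for random draws of every template shape", {
  set.seed(20)
  shapes <- list(c("deletion", 2, "deletion", 1), c("deletion", 1, "deletion", 2),
                 c("insertion", 1, "insertion", 2), c("insertion", 2, "insertion", 1),
                 c("deletion", 1, "insertion", 1), c("deletion", 2, "insertion", 2),
                 c("insertion", 1, "deletion", 1), c("insertion", 2, "deletion", 2))
  for (i in 1:200) {
    sh <- shapes[[sample(length(shapes), 1)]]
    tpl <- pcfm_template(sh[1], as.integer(sh[2]), sh[3], as.integer(sh[4]),
                         sample(0:40, 1))
    g <- pcfm:::random_cds(sample(30:120, 1))
    ok <- pcfm:::valid_placements(nchar(g), tpl)
    if (length(ok) == 0) next
    pos <- if (length(ok) == 1) ok else sample(ok, 1)
    app <- apply_pcfm(g, pos, tpl)
    expect_equal(nchar(app$nt), nchar(g) + app$net_offset)
    ce <- app$codon_region[2]
    expect_identical(
      translate_nt(substr(app$nt, ce + 1 + app$net_offset, nchar(app$nt))),
      translate_nt(substr(g, ce + 1, nchar(g))))
  }
})

test_that("null distributions are reproducible with correct percentiles", {
  pool <- make_control_pool(40, mean_length_nt = 600, seed = 3)
  tpl <- pcfm_template("deletion", 2, "deletion", 1, 26)
  nl <- build_null(pool, tpl, "miyata", n_draws = 300, seed = 8)
  nl2 <- build_null(pool, tpl, "miyata", n_draws = 300, seed = 8)
  expect_identical(nl$draws, nl2$draws)
  expect_true(all(nl$draws >= 0 & nl$draws <= 5.13))
  # boundary of the percentile formula
  below <- min(nl$draws) - 1e-9
  expect_equal(percentile_pvalue(nl$draws, below), 1 / 301)
  expect_equal(percentile_pvalue(nl$draws, max(nl$draws)), 1)
  nl3 <- build_null(pool, tpl, "hydropathy", n_draws = 50, seed = 8,
                    observed = 0.5)
  expect_equal(nl3$percentile_p,
               (1 + sum(nl3$draws <= 0.5)) / 51)
  # an infeasible template (span longer than every pool gene) errors
  wide <- pcfm_template("deletion", 1, "deletion", 2, 2000)
  expect_error(build_null(pool, wide, "miyata", 10, 1), "infeasible")
})

test_that("Bonferroni control and KS combination of percentile p-values", {
  res <- combine_effect_pvalues(c(0.001, 0.2, 0.6, 0.9, 0.004), alpha = 0.05)
  expect_equal(res$per_gene$significant_bonferroni,
               c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_s3_class(res$ks, "htest")
})

# toy fixture with a known ancestral state: quartet tree, pair on leaf "a",
# optionally with one same-branch substitution inside the spanned region
quartet_case <- function(sub_to = NULL) {
  #            1   4   7   10  13  16  19  22
  base <- "ATGGGTACCCATGTTCCAGAATAA"  # M G T H V P E *
  rows <- setNames(rep(base, 4), c("a", "b", "c", "d"))
  # del-2 at cols 7-8, del-1 at col 16: spacer 7, net -3
  substr(rows[["a"]], 7, 8) <- "--"
  substr(rows[["a"]], 16, 16) <- "-"
  if (!is.null(sub_to)) substr(rows[["a"]], 10, 10) <- sub_to
  aln <- gene_alignment(rows, "q")
  ev <- infer_indels(aln, quartet_tree())
  pair <- pair_pcfms(ev, quality_check_alignment(aln), aln)
  list(aln = aln, pair = pair[1, ])
}

test_that("quartet states reconstruct ancestral and derived region peptides", {
  case <- quartet_case()
  expect_true(quality_check(case$aln$rows[["a"]])$passes)
  q <- ancestral_states(case$aln, quartet_tree(), case$pair)
  # no same-branch substitutions: intermediates omitted
  expect_false(q$has_substitutions)
  expect_setequal(q$defined_states, c("A", "E"))
  # ancestral region = sister-species codons 3..6 (T H V P)
  expect_equal(q$A, "THVP")
  # derived: carrier codons across the shifted region
  expect_equal(q$E, paste0(translate_nt(substr(gsub("-", "",
    case$aln$rows[["a"]]), 7, 15)), "-"))
  d <- quartet_distances(q, "miyata")
  expect_equal(d$distances$distance,
               miyata_mean(q$A, q$E))
  # carrier leaf equals E: distance matches and no compensation flagged
  traj <- descendant_trajectories(case$aln, quartet_tree(), case$pair,
                                  "miyata")
  expect_equal(traj$distance, traj$d_AE)
  expect_false(any(traj$compensated))
})

test_that("same-branch substitutions define or omit the intermediates", {
  # C->A at col 10 changes CAT(H) to AAT(N) ancestrally and CCA(P) to
  # CAA(Q) in the shifted frame: nonsynonymous in both frames
  case <- quartet_case(sub_to = "A")
  q <- ancestral_states(case$aln, quartet_tree(), case$pair)
  expect_true(q$has_substitutions)
  expect_setequal(q$defined_states, c("A", "A_mut", "A_fr", "E"))
  expect_equal(q$A, "THVP")
  expect_equal(q$A_mut, "TNVP")
  d <- quartet_distances(q, "miyata")
  expect_equal(nrow(d$distances), 6L)
  expect_false(is.na(d$substitutions_after_compensate))
  expect_false(is.na(d$substitutions_before_permit))
})
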
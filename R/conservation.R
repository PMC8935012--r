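#' Shannon entropy conservation profile of a protein alignment
#'
#' Per-site entropy `H = -sum(p_i * ln p_i)` over the amino-acid
#' frequencies at each column (gaps, stops and `X` excluded from the
#' frequencies), plus sliding-window means at a stated window length.
#' Sites that are all-gap have undefined entropy and are skipped inside
#' windows, with a message giving their count.
#'
#' @param pep_rows named character vector of equal-length peptide strings
#'   (one per species).
#' @param window window length in sites (>= 1, <= number of sites).
#' @return list of class `entropy_profile`: `H` (per-site entropy, NA at
#'   all-gap sites), `window_scores` (length `n_sites - window + 1`),
#'   `window`.
#' @export
entropy_profile <- function(pep_rows, window = 1L) {
  stopifnot(length(pep_rows) >= 1L)
  mat <- do.call(rbind, strsplit(toupper(pep_rows), "", fixed = TRUE))
  n_sites <- ncol(mat)
  if (window < 1L || window > n_sites)
    stop("window must be between 1 and the number of sites (", n_sites, ")")
  H <- apply(mat, 2L, function(col) {
    col <- col[!col %in% UNSCOREABLE]
    if (length(col) == 0L) return(NA_real_)
    p <- table(col) / length(col)
    -sum(p * log(p))
  })
  if (anyNA(H)) message(sum(is.na(H)), " all-gap site(s) skipped")
  ws <- vapply(seq_len(n_sites - window + 1L), function(i)
    mean(H[i:(i + window - 1L)], na.rm = TRUE), numeric(1L))
  structure(list(H = H, window_scores = ws, window = window),
            class = "entropy_profile")
}

#' Conservation percentile of a region within its gene
#'
#' The mean score over the region is compared against the means of all
#' windows of the same length in the gene; the returned value is the
#' fraction of windows whose mean is less than or equal to the region's
#' mean (ties count), so a low fraction marks a region less conserved than
#' the gene background. Invariant under affine transforms of the profile.
#'
#' @param scores per-site conservation scores (entropy, phastCons, ...).
#' @param span_start,span_end 1-based inclusive site interval.
#' @return Fraction in `(0, 1]`.
#' @export
region_conservation_percentile <- function(scores, span_start, span_end) {
  n <- length(scores)
  stopifnot(span_start >= 1L, span_end >= span_start)
  if (span_end > n) stop("span longer than gene profile")
  w <- span_end - span_start + 1L
  wm <- vapply(seq_len(n - w + 1L), function(i)
    mean(scores[i:(i + w - 1L)], na.rm = TRUE), numeric(1L))
  target <- wm[span_start]
  mean(wm <= target)
}

#' Gene age as root-to-MRCA distance of the functional species
#'
#' Locates the most recent common ancestor of the species with a likely
#' functional gene copy and returns the path length from the tree root to
#' it, either as the sum of branch lengths (substitutions/site) or as the
#' number of branches. Larger values mean a younger gene; the age of a set
#' spanning both root children is 0.
#'
#' @param tree rooted [ape::phylo].
#' @param functional_species nonempty subset of the leaf labels.
#' @param mode `"branch_sum"` or `"branch_count"`.
#' @return Nonnegative scalar.
#' @export
gene_age <- function(tree, functional_species,
                     mode = c("branch_sum", "branch_count")) {
  mode <- match.arg(mode)
  if (length(functional_species) == 0L) stop("no functional species")
  if (!all(functional_species %in% tree$tip.label))
    stop("species not in tree: ",
         paste(setdiff(functional_species, tree$tip.label), collapse = ", "))
  root <- length(tree$tip.label) + 1L
  mrca <- if (length(functional_species) == 1L)
    match(functional_species, tree$tip.label)
  else ape::getMRCA(tree, functional_species)
  if (mrca == root) return(0)
  path <- ape::nodepath(tree, root, mrca)
  if (mode == "branch_count") return(length(path) - 1L)
  sum(vapply(seq_len(length(path) - 1L), function(i) {
    e <- which(tree$edge[, 1L] == path[i] & tree$edge[, 2L] == path[i + 1L])
    tree$edge.length[e]
  }, numeric(1L)))
}

#' Fraction of species with a likely functional gene copy
#'
#' @param aln a [gene_alignment()].
#' @return `#rows passing [quality_check()] / #rows`.
#' @export
functional_fraction <- function(aln) {
  q <- quality_check_alignment(aln)
  mean(q$passes)
}

#' Matched detectability-verified controls for pair-carrying genes
#'
#' For each case (a gene carrying a compensatory pair), control candidates
#' are drawn at random from the pool of non-carrying gene alignments; the
#' case's pair template is planted into the candidate on the carrier
#' clade's edge, detection is re-run end to end
#' ([infer_indels()] + [pair_pcfms()] + [postfilter_pcfms()]), and the first
#' candidate in which the planted pair is recovered becomes the matched
#' control. Candidates already carrying a detected pair are rejected
#' outright. Cases exhausting `max_attempts` are reported unmatched with a
#' warning and should be excluded from paired tests.
#'
#' @param cases data.frame of pairs ([pair_pcfms()] rows, one per case
#'   gene).
#' @param pool named list of candidate [gene_alignment()] objects on the
#'   same tree.
#' @param tree rooted [ape::phylo].
#' @param max_attempts candidates tried per case.
#' @param seed integer seed; the pairing is reproducible under a fixed
#'   seed.
#' @return data.frame with `case_gene`, `control_gene` (NA when
#'   unmatched), `attempts`.
#' @export
build_matched_controls <- function(cases, pool, tree, max_attempts = 20L,
                                   seed = 1L) {
  stopifnot(length(pool) >= 1L)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    case <- cases[i, ]
    tpl <- template_from_pair(case)
    carr <- strsplit(case$carriers, ",", fixed = TRUE)[[1L]]
    control <- NA_character_
    attempts <- 0L
    order_idx <- sample(length(pool), min(max_attempts, length(pool)))
    for (j in order_idx) {
      attempts <- attempts + 1L
      cand <- pool[[j]]
      if (detects_any_pair(cand, tree)) next
      planted <- tryCatch(
        plant_pcfm_in_alignment(cand, tree, carr, tpl),
        error = function(e) NULL)
      if (is.null(planted)) next
      if (recovers_planted(planted$aln, tree, planted)) {
        control <- cand$gene_id
        break
      }
    }
    if (is.na(control))
      warning("case ", case$gene_id, " unmatched after ", attempts,
              " attempts")
    data.frame(case_gene = case$gene_id, control_gene = control,
               attempts = attempts, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

detects_any_pair <- function(aln, tree) {
  ev <- suppressMessages(infer_indels(aln, tree))
  q <- quality_check_alignment(aln)
  pr <- pair_pcfms(ev, q, aln)
  nrow(postfilter_pcfms(pr, "low_confidence")) > 0L
}

recovers_planted <- function(aln, tree, planted) {
  ev <- suppressMessages(infer_indels(aln, tree))
  q <- quality_check_alignment(aln)
  pr <- postfilter_pcfms(pair_pcfms(ev, q, aln), "low_confidence")
  if (nrow(pr) == 0L) return(FALSE)
  any(pr$col_start_5p == planted$col_start_5p &
        pr$col_end_3p == planted$col_end_3p &
        pr$kind_5p == planted$kind_5p & pr$kind_3p == planted$kind_3p &
        pr$edge_label == planted$edge_label)
}

#' Wilcoxon signed-rank comparison of paired case/control values
#'
#' Zero differences are dropped (the test's convention); the difference
#' distribution is returned for display alongside the test.
#'
#' @param values_case,values_control equal-length paired numeric vectors
#'   (n >= 5).
#' @param alternative passed to [stats::wilcox.test()].
#' @return list with `test` (htest or NULL when all differences are zero),
#'   `differences`, `degenerate` flag.
#' @export
paired_comparison <- function(values_case, values_control,
                              alternative = "two.sided") {
  if (length(values_case) != length(values_control))
    stop("paired vectors differ in length")
  if (length(values_case) < 5L)
    stop("insufficient pairs: n = ", length(values_case), " < 5")
  d <- values_case - values_control
  if (all(d == 0))
    return(list(test = NULL, differences = d, degenerate = TRUE))
  test <- suppressWarnings(
    stats::wilcox.test(values_case, values_control, paired = TRUE,
                       alternative = alternative))
  list(test = test, differences = d, degenerate = FALSE)
}

#' Likelihood-ratio test for a second dN/dS ratio
#'
#' Compares a single-ratio codon model with a two-ratio model (distinct
#' dN/dS on the pair-carrying clade versus the remaining branches) fitted
#' externally; the statistic is `2 * (lnL_2param - lnL_1param)` with a
#' chi-square null on 1 degree of freedom (one extra ratio parameter).
#'
#' @param lnL_1param,lnL_2param log-likelihoods of the nested fits.
#' @param tolerance slack allowed for `lnL_2param < lnL_1param` from
#'   numerical optimization.
#' @return list with `statistic` and `p`.
#' @export
lrt_two_omega <- function(lnL_1param, lnL_2param, tolerance = 1e-6) {
  stat <- 2 * (lnL_2param - lnL_1param)
  if (stat < -tolerance)
    stop("inconsistent likelihoods: two-parameter fit worse by ",
         format(-stat / 2))
  stat <- max(stat, 0)
  list(statistic = stat, p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Read a TSV of external codon-model fits
#'
#' Expected columns: `gene_id`, `lnL_1param`, `lnL_2param`, and optionally
#' `omega_single`, `omega_pre`, `omega_post`; the likelihood-ratio test is
#' appended per gene.
#'
#' @param path TSV path with a header row.
#' @return data.frame with added `lrt_statistic` and `lrt_p` columns.
#' @export
read_omega_fits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "lnL_1param", "lnL_2param")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  lrt <- lapply(seq_len(nrow(df)), function(i)
    lrt_two_omega(df$lnL_1param[i], df$lnL_2param[i]))
  df$lrt_statistic <- vapply(lrt, `[[`, numeric(1L), "statistic")
  df$lrt_p <- vapply(lrt, `[[`, numeric(1L), "p")
  df
}
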
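#' Compensatory frameshift template
#'
#' A template records the shape of a compensatory pair independent of where
#' it is applied: the kind and length of the 5' and 3' indels and the
#' number of nucleotides strictly between them (the spacer, which is
#' translated in the shifted frame). The signed net length change
#' (insertions positive, deletions negative) must be divisible by 3 so the
#' reading frame is restored downstream.
#'
#' @param kind_5p,kind_3p `"insertion"` or `"deletion"`.
#' @param len_5p,len_3p indel lengths in nucleotides (>= 1).
#' @param spacer_nt nucleotides strictly between the indels (>= 0).
#' @return list of class `pcfm_template`.
#' @export
pcfm_template <- function(kind_5p, len_5p, kind_3p, len_3p, spacer_nt) {
  kind_5p <- match.arg(kind_5p, c("insertion", "deletion"))
  kind_3p <- match.arg(kind_3p, c("insertion", "deletion"))
  stopifnot(len_5p >= 1L, len_3p >= 1L, spacer_nt >= 0L)
  off <- (if (kind_5p == "insertion") len_5p else -len_5p) +
    (if (kind_3p == "insertion") len_3p else -len_3p)
  if (off %% 3L != 0L)
    stop("net length change ", off, " is not divisible by 3: ",
         "the template does not restore the reading frame")
  structure(list(kind_5p = kind_5p, len_5p = as.integer(len_5p),
                 kind_3p = kind_3p, len_3p = as.integer(len_3p),
                 spacer_nt = as.integer(spacer_nt),
                 net_offset = as.integer(off)),
            class = "pcfm_template")
}

template_from_pair <- function(pair, derived_spacer = TRUE) {
  pcfm_template(pair$kind_5p, pair$len_5p, pair$kind_3p, pair$len_3p,
                if (derived_spacer) pair$spacer_nt else pair$spacer_nt_anc)
}

# original-sequence nucleotides consumed by the template (deletions + spacer)
template_consumed <- function(tpl) {
  (if (tpl$kind_5p == "deletion") tpl$len_5p else 0L) + tpl$spacer_nt +
    (if (tpl$kind_3p == "deletion") tpl$len_3p else 0L)
}

# 1-based positions at which the template can be applied to a CDS of n nt,
# keeping the start and stop codons untouched
valid_placements <- function(n, tpl) {
  consumed <- template_consumed(tpl)
  lo <- 4L
  hi <- n - 2L - consumed   # last touched nt must precede the stop codon
  if (hi < lo) integer(0) else lo:hi
}

#' Apply an in-silico compensatory frameshift to a coding sequence
#'
#' The 5' indel acts at `pos` (a deletion removes `len_5p` bases starting
#' there; an insertion adds `len_5p` bases drawn uniformly from A/C/G/T
#' just before it), and the 3' indel acts `spacer_nt` derived-sequence
#' nucleotides downstream. The sequence outside the affected span is
#' untouched, and because the net length change is divisible by 3 the
#' translation downstream of the 3' indel is identical to the original.
#'
#' @param nt ungapped CDS string.
#' @param pos 1-based position of the 5' indel; the span must fit inside
#'   the CDS excluding the start and stop codons (see errors).
#' @param template a [pcfm_template()].
#' @param seed optional integer seed for inserted bases (templates without
#'   insertions are deterministic).
#' @return list of class `pcfm_application`: `nt` (derived sequence),
#'   `span_orig` (first/last original coordinate touched), `codon_region`
#'   (codon-aligned original region enclosing the span), `net_offset`,
#'   `region_orig`/`region_derived` (nucleotides of the spanned region in
#'   both variants) and `pos`.
#' @export
apply_pcfm <- function(nt, pos, template, seed = NULL) {
  stopifnot(inherits(template, "pcfm_template"))
  nt <- toupper(nt)
  n <- nchar(nt)
  ok <- valid_placements(n, template)
  if (!pos %in% ok)
    stop("placement error: pos ", pos, " with this template overruns the ",
         "CDS or touches the start/stop codon (valid: ",
         if (length(ok)) paste0(min(ok), "..", max(ok)) else "none", ")")
  if (!is.null(seed)) set.seed(seed)
  rand_bases <- function(k) paste(sample(c("A", "C", "G", "T"), k,
                                         replace = TRUE), collapse = "")
  tpl <- template
  c5 <- if (tpl$kind_5p == "deletion") tpl$len_5p else 0L
  c3 <- if (tpl$kind_3p == "deletion") tpl$len_3p else 0L
  consumed <- c5 + tpl$spacer_nt + c3
  b0 <- pos + consumed - 1L                       # last original nt touched
  prefix <- substr(nt, 1L, pos - 1L)
  ins5 <- if (tpl$kind_5p == "insertion") rand_bases(tpl$len_5p) else ""
  spacer_seg <- if (tpl$spacer_nt > 0L)
    substr(nt, pos + c5, pos + c5 + tpl$spacer_nt - 1L) else ""
  ins3 <- if (tpl$kind_3p == "insertion") rand_bases(tpl$len_3p) else ""
  suffix <- substr(nt, b0 + 1L, n)
  derived <- paste0(prefix, ins5, spacer_seg, ins3, suffix)
  cs <- 3L * ((pos - 1L) %/% 3L) + 1L
  ce <- if (b0 >= pos) 3L * ((b0 + 2L) %/% 3L) else cs + 2L
  ce <- min(ce, n)
  net <- tpl$net_offset
  structure(list(
    nt = derived, pos = pos, span_orig = c(pos, max(b0, pos - 1L)),
    codon_region = c(cs, ce), net_offset = net,
    region_orig = substr(nt, cs, ce),
    region_derived = substr(derived, cs, ce + net)),
    class = "pcfm_application")
}

# pad the shorter peptide with gaps on the right so positions pair up
pad_peptides <- function(p1, p2) {
  n1 <- nchar(p1); n2 <- nchar(p2)
  if (n1 < n2) p1 <- paste0(p1, strrep("-", n2 - n1))
  if (n2 < n1) p2 <- paste0(p2, strrep("-", n1 - n2))
  list(p1, p2)
}

#' Peptides encoded by the spanned region before and after a frameshift
#'
#' Translates the codon-aligned region enclosing the pair in the ancestral
#' and the derived sequence; the shorter peptide is padded with gaps (which
#' score the maximum Miyata distance) so the two can be paired by position.
#'
#' @param app a `pcfm_application` from [apply_pcfm()].
#' @return list with elements `anc` and `der`, equal-length peptides.
#' @export
spanned_peptides <- function(app) {
  stopifnot(inherits(app, "pcfm_application"))
  p <- pad_peptides(translate_nt(app$region_orig),
                    translate_nt(app$region_derived))
  list(anc = p[[1L]], der = p[[2L]])
}

score_metric <- function(metric, pep1, pep2) {
  switch(metric,
         miyata = miyata_mean(pep1, pep2),
         hydropathy = hydropathy_diff(pep1, pep2),
         stop("unknown metric: ", metric))
}

#' Empirical null distribution of frameshift effect sizes
#'
#' Repeatedly plants the template at a random valid position of a random
#' control gene, translates the spanned region of both variants, and scores
#' their dissimilarity, yielding the distribution of effect sizes expected
#' for a compensatory pair of identical shape at a random position of a
#' random protein-coding gene. The observed value's percentile p-value is
#' `(1 + #(draws <= observed)) / (n_draws + 1)`; low values mean the
#' observed frameshifted region is unexpectedly similar to its ancestor.
#'
#' @param genes character vector (or list) of ungapped control CDS.
#' @param template a [pcfm_template()].
#' @param metric `"miyata"` or `"hydropathy"`.
#' @param n_draws number of null draws (the headline analyses use 10,000).
#' @param seed integer seed; draws are reproducible under a fixed seed.
#' @param observed optional observed effect size to be ranked.
#' @return list of class `pcfm_null` with `draws`, `n_draws`, `seed`,
#'   `template`, `metric`, `observed` and `percentile_p` (NA when no
#'   observation is supplied).
#' @export
build_null <- function(genes, template, metric = c("miyata", "hydropathy"),
                       n_draws = 10000L, seed = 1L, observed = NULL) {
  metric <- match.arg(metric)
  stopifnot(n_draws >= 1L)
  genes <- vapply(genes, toupper, character(1L), USE.NAMES = FALSE)
  feasible <- which(vapply(genes, function(g)
    length(valid_placements(nchar(g), template)) > 0L, logical(1L)))
  if (length(feasible) == 0L)
    stop("infeasible template: no valid placement in any control gene")
  set.seed(seed)
  draws <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    g <- genes[[sample(feasible, 1L)]]
    ok <- valid_placements(nchar(g), template)
    pos <- if (length(ok) == 1L) ok else sample(ok, 1L)
    app <- apply_pcfm(g, pos, template)
    pep <- spanned_peptides(app)
    draws[i] <- score_metric(metric, pep$anc, pep$der)
  }
  p <- if (is.null(observed)) NA_real_ else percentile_pvalue(draws, observed)
  structure(list(template = template, metric = metric, draws = draws,
                 n_draws = n_draws, seed = seed,
                 observed = if (is.null(observed)) NA_real_ else observed,
                 percentile_p = p),
            class = "pcfm_null")
}

#' Percentile p-value of an observation against null draws
#'
#' @param draws numeric vector of null draws.
#' @param observed observed value.
#' @return `(1 + #(draws <= observed)) / (length(draws) + 1)`, in `(0, 1]`.
#' @export
percentile_pvalue <- function(draws, observed) {
  (1 + sum(draws <= observed)) / (length(draws) + 1)
}

#' Combine per-gene percentile p-values and apply Bonferroni control
#'
#' The global signal across genes is tested with a one-sample
#' Kolmogorov-Smirnov test of the p-values against Uniform(0,1); per-gene
#' family-wise significance uses the Bonferroni-corrected level
#' `alpha / k` over the `k` genes.
#'
#' @param pvals numeric vector of per-gene percentile p-values.
#' @param alpha family-wise level (default 0.05).
#' @return list with `ks` (the KS test) and `per_gene` (data.frame with
#'   `p`, `significant_bonferroni`).
#' @export
combine_effect_pvalues <- function(pvals, alpha = 0.05) {
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  list(ks = ks,
       per_gene = data.frame(
         p = pvals,
         significant_bonferroni = pvals < alpha / length(pvals)))
}

# ---- parsimony reconstruction of nucleotide states ----

STATE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, `-` = 16L)

char_to_mask <- function(ch) {
  m <- STATE_BITS[ch]
  m[ch == "N"] <- 15L
  unname(m)
}

mask_to_char <- function(mask, prefer = 0L) {
  both <- bitwAnd(mask, prefer)
  if (both > 0L) mask <- both
  names(STATE_BITS)[which(bitwAnd(mask, STATE_BITS) > 0L)[1L]]
}

n_states <- function(mask) sum(bitwAnd(mask, STATE_BITS) > 0L)

# Fitch bottom-up + top-down refinement over all columns at once;
# states are 5-bit masks (A,C,G,T,gap), N = any base.
fitch_states <- function(aln, tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ncol <- aln$n_columns
  B <- matrix(0L, nrow = nnode, ncol = ncol)
  for (i in seq_len(ntip)) {
    ch <- strsplit(aln$rows[[tree$tip.label[i]]], "", fixed = TRUE)[[1L]]
    B[i, ] <- char_to_mask(ch)
  }
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1L]; v <- tree$edge[k, 2L]
    if (all(B[u, ] == 0L)) B[u, ] <- B[v, ]
    else {
      both <- bitwAnd(B[u, ], B[v, ])
      B[u, ] <- ifelse(both > 0L, both, bitwOr(B[u, ], B[v, ]))
    }
  }
  Fm <- B
  for (k in rev(seq_len(nrow(tree$edge)))) {   # preorder
    u <- tree$edge[k, 1L]; v <- tree$edge[k, 2L]
    both <- bitwAnd(B[v, ], Fm[u, ])
    Fm[v, ] <- ifelse(both > 0L, both, B[v, ])
  }
  list(tree = tree, F = Fm, ntip = ntip)
}

resolve_node_seq <- function(Fm, node, prefer_node = NULL) {
  ncol <- ncol(Fm)
  out <- character(ncol)
  for (j in seq_len(ncol)) {
    pref <- if (is.null(prefer_node)) 0L else Fm[prefer_node, j]
    out[j] <- mask_to_char(Fm[node, j], pref)
  }
  out
}

#' Ancestral, intermediate and derived region states for a compensatory pair
#'
#' Reconstructs nucleotide states at the two endpoints of the pair-carrying
#' edge by parsimony, then builds the four region peptides: the ancestral
#' state `A` (parent endpoint, ancestral frame), the derived state `E`
#' (child endpoint, shifted frame between the indels), the
#' substitution-first intermediate `A_mut` (same-branch substitutions
#' applied to `A`, ancestral frame) and the frameshift-first intermediate
#' `A_fr` (the pair applied to `A` without substitutions, shifted frame).
#' Intermediates are omitted when no same-branch substitutions fall in the
#' region, or when frame-dependent synonymity makes one protein-identical
#' to its neighboring endpoint (substitutions synonymous in one frame and
#' nonsynonymous in the other).
#'
#' @param aln a [gene_alignment()].
#' @param tree rooted [ape::phylo] covering the alignment species.
#' @param pair one row of [pair_pcfms()] output (same-edge pair).
#' @return list of class `state_quartet`: peptides `A`, `A_mut`, `A_fr`,
#'   `E` (all padded to equal length; undefined intermediates `NA`),
#'   `defined_states`, `has_substitutions`, `n_ambiguous_sites`.
#' @export
ancestral_states <- function(aln, tree, pair) {
  carr <- strsplit(pair$carriers, ",", fixed = TRUE)[[1L]]
  if (!all(carr %in% tree$tip.label)) stop("carriers missing from tree")
  sub <- ape::keep.tip(tree, intersect(tree$tip.label, aln$species_ids))
  fit <- fitch_states(aln, sub)
  tr <- fit$tree
  child <- if (length(carr) == 1L) match(carr, tr$tip.label)
           else ape::getMRCA(tr, carr)
  parent <- tr$edge[tr$edge[, 2L] == child, 1L]
  if (length(parent) != 1L) stop("pair edge has no parent (root-level clade)")
  span <- pair$col_start_5p:pair$col_end_3p
  ambig <- vapply(span, function(j)
    n_states(fit$F[parent, j]) > 1L || n_states(fit$F[child, j]) > 1L,
    logical(1L))
  if (mean(ambig) > 0.5)
    stop("low confidence: parsimony reconstruction ambiguous at ",
         sum(ambig), "/", length(span), " spanned sites")
  pstate <- resolve_node_seq(fit$F, parent)
  cstate <- resolve_node_seq(fit$F, child, prefer_node = parent)

  # ancestral-frame region: codon-extend in parent (ungapped) coordinates
  anc_region <- region_in_frame(pstate, pair$col_start_5p, pair$col_end_3p)
  # derived-frame region: codon-extend in child (ungapped) coordinates
  der_region <- region_in_frame(cstate, pair$col_start_5p, pair$col_end_3p)

  A_nt <- anc_region$nt
  E_nt <- der_region$nt
  # substitution-first intermediate: parent gap pattern, child bases where
  # both endpoints have a base and they differ
  mut_state <- ifelse(pstate != "-" & cstate != "-" & pstate != cstate,
                      cstate, pstate)
  Amut_nt <- region_in_frame(mut_state, pair$col_start_5p, pair$col_end_3p)$nt
  # frameshift-first intermediate: child gap pattern, parent bases where
  # available (inserted columns keep the child base: no ancestral state)
  fr_state <- ifelse(cstate == "-", "-", ifelse(pstate != "-", pstate, cstate))
  Afr_nt <- region_in_frame(fr_state, pair$col_start_5p, pair$col_end_3p)$nt

  peps <- lapply(list(A = A_nt, A_mut = Amut_nt, A_fr = Afr_nt, E = E_nt),
                 translate_nt)
  w <- max(nchar(unlist(peps)))
  peps <- lapply(peps, function(p) paste0(p, strrep("-", w - nchar(p))))

  has_subs <- Amut_nt != A_nt
  defined <- c("A", "E")
  if (has_subs) {
    defined <- c("A", "A_mut", "A_fr", "E")
    nonsyn_anc <- peps$A_mut != peps$A
    nonsyn_shift <- peps$E != peps$A_fr
    # frame-dependent synonymity: omit the intermediate that collapses
    # onto its neighboring endpoint at the protein level
    if (!nonsyn_anc && nonsyn_shift) defined <- setdiff(defined, "A_mut")
    if (nonsyn_anc && !nonsyn_shift) defined <- setdiff(defined, "A_fr")
  }
  structure(list(
    A = peps$A,
    A_mut = if ("A_mut" %in% defined) peps$A_mut else NA_character_,
    A_fr = if ("A_fr" %in% defined) peps$A_fr else NA_character_,
    E = peps$E,
    defined_states = sort(unique(defined)),
    has_substitutions = has_subs,
    n_ambiguous_sites = sum(ambig)),
    class = "state_quartet")
}

# codon-aligned ungapped region of a per-column state vector
region_in_frame <- function(state, col_from, col_to) {
  gapless <- state != "-"
  before <- if (col_from > 1L) sum(gapless[seq_len(col_from - 1L)]) else 0L
  through <- sum(gapless[seq_len(col_to)])
  seq_full <- paste(state[gapless], collapse = "")
  rs <- 3L * (before %/% 3L) + 1L
  re <- min(3L * ((through + 2L) %/% 3L), nchar(seq_full))
  list(nt = substr(seq_full, rs, re), start = rs, end = re)
}

#' Pairwise distances among the quartet states
#'
#' Distances between all defined pairs among `A`, `A_mut`, `A_fr`, `E`.
#' Supports two compensation hypotheses: substitutions occurring after the
#' pair compensate it when `d(A, E) < d(A, A_fr)`; substitutions occurring
#' before the pair make it permissible when `d(A_mut, E) < d(A, A_fr)`.
#'
#' @param q a `state_quartet` from [ancestral_states()].
#' @param metric `"miyata"` or `"hydropathy"`.
#' @return list with `distances` (data.frame `from`, `to`, `distance`) and
#'   logical flags `substitutions_after_compensate`,
#'   `substitutions_before_permit` (NA when the needed states are
#'   undefined).
#' @export
quartet_distances <- function(q, metric = c("miyata", "hydropathy")) {
  metric <- match.arg(metric)
  states <- q$defined_states
  peps <- lapply(states, function(s) q[[s]])
  names(peps) <- states
  combs <- utils::combn(states, 2L)
  d <- apply(combs, 2L, function(pr)
    score_metric(metric, peps[[pr[1L]]], peps[[pr[2L]]]))
  dist_df <- data.frame(from = combs[1L, ], to = combs[2L, ], distance = d,
                        stringsAsFactors = FALSE)
  getd <- function(a, b) {
    i <- which((dist_df$from == a & dist_df$to == b) |
                 (dist_df$from == b & dist_df$to == a))
    if (length(i)) dist_df$distance[i] else NA_real_
  }
  d_AE <- getd("A", "E"); d_AAfr <- getd("A", "A_fr")
  d_AmutE <- getd("A_mut", "E")
  list(distances = dist_df,
       substitutions_after_compensate =
         if (is.na(d_AAfr)) NA else d_AE < d_AAfr,
       substitutions_before_permit =
         if (is.na(d_AAfr) || is.na(d_AmutE)) NA else d_AmutE < d_AAfr)
}

#' Distances from the ancestral state to each carrier leaf
#'
#' For every species carrying the pair, the region peptide observed at the
#' leaf is compared with the reconstructed ancestral peptide `A`;
#' substitutions on branches descending from the pair are flagged as
#' compensatory when they bring the leaf closer to `A` than the derived
#' state `E` is.
#'
#' @inheritParams quartet_distances
#' @param aln a [gene_alignment()].
#' @param tree rooted [ape::phylo].
#' @param pair one row of [pair_pcfms()] output.
#' @return data.frame with `species`, `distance`, `d_AE`, `compensated`.
#' @export
descendant_trajectories <- function(aln, tree, pair,
                                    metric = c("miyata", "hydropathy")) {
  metric <- match.arg(metric)
  q <- ancestral_states(aln, tree, pair)
  d_AE <- score_metric(metric, q$A, q$E)
  carr <- strsplit(pair$carriers, ",", fixed = TRUE)[[1L]]
  rows <- lapply(carr, function(sp) {
    st <- strsplit(aln$rows[[sp]], "", fixed = TRUE)[[1L]]
    pep <- translate_nt(region_in_frame(st, pair$col_start_5p,
                                        pair$col_end_3p)$nt)
    pp <- pad_peptides(q$A, pep)
    d <- score_metric(metric, pp[[1L]], pp[[2L]])
    data.frame(species = sp, distance = d, d_AE = d_AE,
               compensated = d < d_AE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
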
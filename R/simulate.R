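# Synthetic ortholog alignments with a known indel history. Detection
# operates on gap structure, so a single-parameter equal-rates
# substitution process is sufficient; substitutions never touch the
# first/last codon and are rejected if they would create an in-frame stop
# in the reference frame (purifying selection against nonsense), so
# planted histories stay recoverable.

NON_STOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1L, paste, collapse = ""),
  STOP_CODONS)

random_cds <- function(n_codons) {
  stopifnot(n_codons >= 3L)
  paste0("ATG",
         paste(sample(NON_STOP_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

# per-site substitution process; keeps frame-0 codons stop-free and the
# terminal codons untouched
mutate_seq <- function(seq, p_site) {
  if (p_site <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  sites <- which(stats::runif(n) < p_site)
  sites <- sites[sites > 3L & sites <= n - 3L]
  for (s in sites) {
    new <- sample(setdiff(c("A", "C", "G", "T"), chars[s]), 1L)
    cod_start <- 3L * ((s - 1L) %/% 3L) + 1L
    codon <- chars[cod_start:(cod_start + 2L)]
    codon[s - cod_start + 1L] <- new
    if (paste(codon, collapse = "") %in% STOP_CODONS) next
    chars[s] <- new
  }
  paste(chars, collapse = "")
}

# evolve the root CDS down the tree; returns leaf sequences (no indels yet)
evolve_leaves <- function(tree, root_seq, subst_rate) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- root_seq
  for (k in rev(seq_len(nrow(tree$edge)))) {  # preorder
    u <- tree$edge[k, 1L]; v <- tree$edge[k, 2L]
    seqs[[v]] <- mutate_seq(seqs[[u]], subst_rate * tree$edge.length[k])
  }
  out <- seqs[seq_len(ntip)]
  names(out) <- tree$tip.label
  out
}

# nodes whose tip set gives an unambiguous single-change placement:
# not the root, and not a child of a binary root (whose complement is
# also a clade, leaving the polarity unresolved)
eligible_edge_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nodes <- setdiff(c(seq_len(ntip), (ntip + 2L):(ntip + tree$Nnode)), root)
  root_children <- tree$edge[tree$edge[, 1L] == root, 2L]
  if (length(root_children) == 2L) nodes <- setdiff(nodes, root_children)
  nodes
}

tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

# Plant a list of indel features into a species x column character matrix.
# Each feature: list(root_pos, kind, len, carriers). root_pos refers to the
# pre-planting (gap-free) coordinate system; features must be sorted by
# root_pos and non-overlapping. Returns the matrix plus per-feature
# alignment-column coordinates.
plant_features <- function(mat, features) {
  offset <- 0L
  coords <- vector("list", length(features))
  for (i in seq_along(features)) {
    f <- features[[i]]
    col <- f$root_pos + offset
    if (f$kind == "deletion") {
      cols <- col:(col + f$len - 1L)
      if (any(mat[f$carriers, cols, drop = FALSE] == "-"))
        stop("config conflict: planted events overlap")
      mat[f$carriers, cols] <- "-"
      coords[[i]] <- c(col, col + f$len - 1L)
    } else {
      ins <- matrix("-", nrow = nrow(mat), ncol = f$len,
                    dimnames = list(rownames(mat), NULL))
      for (sp in f$carriers)
        ins[sp, ] <- sample(c("A", "C", "G", "T"), f$len, replace = TRUE)
      left <- if (col > 1L) mat[, seq_len(col - 1L), drop = FALSE] else NULL
      right <- if (col <= ncol(mat)) mat[, col:ncol(mat), drop = FALSE]
               else NULL
      mat <- cbind(left, ins, right)
      coords[[i]] <- c(col, col + f$len - 1L)
      offset <- offset + f$len
    }
  }
  list(mat = mat, coords = coords)
}

# indel features realizing a template at root-coordinate pos
template_features <- function(tpl, pos, carriers) {
  c5 <- if (tpl$kind_5p == "deletion") tpl$len_5p else 0L
  list(
    list(root_pos = pos, kind = tpl$kind_5p, len = tpl$len_5p,
         carriers = carriers),
    list(root_pos = pos + c5 + tpl$spacer_nt, kind = tpl$kind_3p,
         len = tpl$len_3p, carriers = carriers))
}

ALLOWED_TEMPLATES <- list(
  c("deletion", 2L, "deletion", 1L), c("deletion", 1L, "deletion", 2L),
  c("insertion", 1L, "insertion", 2L), c("insertion", 2L, "insertion", 1L),
  c("deletion", 1L, "insertion", 1L), c("insertion", 1L, "deletion", 1L),
  c("deletion", 2L, "insertion", 2L), c("insertion", 2L, "deletion", 2L))

sample_template <- function(spacer_range = c(5L, 40L)) {
  t <- ALLOWED_TEMPLATES[[sample(length(ALLOWED_TEMPLATES), 1L)]]
  pcfm_template(t[1L], as.integer(t[2L]), t[3L], as.integer(t[4L]),
                sample(spacer_range[1L]:spacer_range[2L], 1L))
}

#' Simulation configuration
#'
#' Defines the conditions under which synthetic ortholog alignments are
#' generated: the tree (given, or a random coalescent-shaped tree with
#' `n_leaves`), the number of genes and their length, the substitution
#' rate, and a per-gene scenario assignment. Scenarios: `"none"` (no
#' indels), `"pcfm"` (a filter-conforming same-edge compensatory pair,
#' template drawn from the allowed short-indel set), and the negative
#' controls `"single_indel"` (one uncompensated frameshifting indel),
#' `"triple_indel"` (three 1-nt deletions on one edge), `"cross_edge"`
#' (compensating indels on two nested edges) and `"long_pair"`
#' (a 4+2-nt deletion pair, compensatory but over the length filter).
#'
#' @param tree optional rooted [ape::phylo]; otherwise sampled.
#' @param n_leaves leaves of the sampled tree (ignored when `tree` given).
#' @param n_genes number of genes.
#' @param gene_length_codons gene length in codons (scalar, or vector
#'   recycled over genes).
#' @param subst_rate substitutions per site per unit branch length.
#' @param scenarios character vector recycled over genes.
#' @param pseudogenize optional data.frame with columns `gene`, `species`,
#'   `defect` (`no_start`, `no_stop`, `internal_stop`, `len_mod3`).
#' @param seed integer seed; the whole simulation is deterministic under
#'   it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(tree = NULL, n_leaves = 8L, n_genes = 10L,
                       gene_length_codons = 200L, subst_rate = 0.05,
                       scenarios = "pcfm", pseudogenize = NULL, seed = 1L) {
  ok <- c("none", "pcfm", "single_indel", "triple_indel", "cross_edge",
          "long_pair")
  if (!all(scenarios %in% ok))
    stop("unknown scenario(s): ", paste(setdiff(scenarios, ok), collapse = ", "))
  structure(list(tree = tree, n_leaves = n_leaves, n_genes = n_genes,
                 gene_length_codons = gene_length_codons,
                 subst_rate = subst_rate, scenarios = scenarios,
                 pseudogenize = pseudogenize, seed = seed),
            class = "sim_config")
}

#' Simulate gapped ortholog alignments with a known indel history
#'
#' Roots a random stop-free CDS per gene, evolves it down the tree with
#' the substitution process, plants the scenario's indels (gap columns are
#' introduced globally, so the emitted alignment is the true alignment),
#' applies pseudogenization defects last, and returns the truth table in
#' emitted-alignment coordinates. Positions of planted pairs are resampled
#' until every carrier row passes [quality_check()], so filter-conforming
#' pairs are recoverable by construction.
#'
#' @param config a [sim_config()].
#' @return list with `alignments` (named list of [gene_alignment()]),
#'   `tree`, and `truth` (data.frame; `is_conforming` marks pairs the
#'   detection pipeline is expected to report).
#' @export
simulate_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rcoal(config$n_leaves,
                       tip.label = sprintf("sp%02d", seq_len(config$n_leaves)))
    tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  }
  tree <- validate_tree(tree)
  scen <- rep_len(config$scenarios, config$n_genes)
  lens <- rep_len(config$gene_length_codons, config$n_genes)
  alignments <- list()
  truth <- list()
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("gene%03d", g)
    res <- simulate_one_gene(gid, tree, lens[g], config$subst_rate, scen[g])
    aln <- res$aln
    if (!is.null(config$pseudogenize)) {
      pg <- config$pseudogenize
      pg <- pg[pg$gene == g | pg$gene == gid, , drop = FALSE]
      for (i in seq_len(nrow(pg)))
        aln <- apply_defect(aln, pg$species[i], pg$defect[i])
      if (nrow(pg) > 0L)
        res$truth <- rbind_fill(res$truth, data.frame(
          gene_id = gid, scenario = "pseudogene", is_conforming = FALSE,
          carriers = paste(pg$species, collapse = ","),
          stringsAsFactors = FALSE))
    }
    alignments[[gid]] <- aln
    truth[[g]] <- res$truth
  }
  list(alignments = alignments, tree = tree,
       truth = do.call(rbind_fill, truth))
}

rbind_fill <- function(...) {
  dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0L, list(...))
  if (length(dfs) == 0L) return(NULL)
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[, cols, drop = FALSE]
  })
  do.call(rbind, dfs)
}

simulate_one_gene <- function(gid, tree, n_codons, subst_rate, scenario,
                              max_tries = 50L) {
  L <- 3L * n_codons
  for (try in seq_len(max_tries)) {
    root_seq <- random_cds(n_codons)
    leaves <- evolve_leaves(tree, root_seq, subst_rate)
    mat <- do.call(rbind, strsplit(unlist(leaves), "", fixed = TRUE))
    rownames(mat) <- names(leaves)
    if (scenario == "none")
      return(list(aln = gene_alignment(apply(mat, 1L, paste, collapse = ""),
                                       gid),
                  truth = NULL))
    node <- sample(eligible_edge_nodes(tree), 1L)
    carr <- tips_below(tree, node)
    plan <- switch(
      scenario,
      pcfm = {
        tpl <- sample_template()
        pos <- sample_position(L, template_consumed(tpl))
        list(features = template_features(tpl, pos, carr), tpl = tpl,
             conforming = TRUE, need_quality = TRUE)
      },
      single_indel = {
        len <- sample(1:2, 1L)
        pos <- sample_position(L, len)
        list(features = list(list(root_pos = pos,
                                  kind = sample(c("deletion", "insertion"), 1L),
                                  len = len, carriers = carr)),
             conforming = FALSE, need_quality = FALSE)
      },
      triple_indel = {
        pos <- sample_position(L, 60L)
        list(features = lapply(c(0L, 25L, 50L), function(o)
          list(root_pos = pos + o, kind = "deletion", len = 1L,
               carriers = carr)),
          conforming = FALSE, need_quality = FALSE)
      },
      cross_edge = {
        anc <- ancestor_node(tree, node)
        if (is.na(anc)) return(simulate_one_gene(gid, tree, n_codons,
                                                 subst_rate, scenario,
                                                 max_tries - 1L))
        wide <- tips_below(tree, anc)
        pos <- sample_position(L, 30L)
        list(features = list(
          list(root_pos = pos, kind = "deletion", len = 1L, carriers = wide),
          list(root_pos = pos + 20L, kind = "deletion", len = 2L,
               carriers = carr)),
          conforming = FALSE, need_quality = FALSE)
      },
      long_pair = {
        pos <- sample_position(L, 30L)
        list(features = list(
          list(root_pos = pos, kind = "deletion", len = 4L, carriers = carr),
          list(root_pos = pos + 24L, kind = "deletion", len = 2L,
               carriers = carr)),
          conforming = FALSE, need_quality = FALSE)
      })
    planted <- plant_features(mat, plan$features)
    rows <- apply(planted$mat, 1L, paste, collapse = "")
    if (plan$need_quality &&
        !all(vapply(carr, function(sp) quality_check(rows[[sp]])$passes,
                    logical(1L))))
      next  # shifted frame produced a stop in a carrier; resample
    aln <- gene_alignment(rows, gid)
    f <- plan$features
    cd <- planted$coords
    tr <- data.frame(
      gene_id = gid, scenario = scenario, is_conforming = plan$conforming,
      kind_5p = f[[1L]]$kind, len_5p = f[[1L]]$len,
      col_start_5p = cd[[1L]][1L], col_end_5p = cd[[1L]][2L],
      kind_3p = if (length(f) >= 2L) f[[length(f)]]$kind else NA_character_,
      len_3p = if (length(f) >= 2L) f[[length(f)]]$len else NA_integer_,
      col_start_3p = if (length(f) >= 2L) cd[[length(f)]][1L] else NA_integer_,
      col_end_3p = if (length(f) >= 2L) cd[[length(f)]][2L] else NA_integer_,
      spacer_nt = if (plan$conforming) plan$tpl$spacer_nt else NA_integer_,
      edge_label = edge_label_for(carr),
      carriers = edge_label_for(carr),
      stringsAsFactors = FALSE)
    return(list(aln = aln, truth = tr))
  }
  stop("could not place scenario '", scenario, "' in gene ", gid,
       " after ", max_tries, " tries")
}

sample_position <- function(L, consumed) {
  lo <- 7L
  hi <- L - 6L - consumed
  if (hi < lo) stop("gene too short for planted feature")
  sample(lo:hi, 1L)
}

ancestor_node <- function(tree, node) {
  e <- tree$edge[tree$edge[, 2L] == node, 1L]
  root <- length(tree$tip.label) + 1L
  if (length(e) == 0L || e == root) return(NA_integer_)
  if (!e %in% eligible_edge_nodes(tree)) return(NA_integer_)
  e
}

apply_defect <- function(aln, species, defect) {
  row <- aln$rows[[species]]
  n <- nchar(row)
  row <- switch(
    defect,
    no_start = { substr(row, 1L, 3L) <- "GTG"; row },
    no_stop = { substr(row, n - 2L, n) <- "AAA"; row },
    internal_stop = {
      mid <- 3L * ((n %/% 2L) %/% 3L) + 1L
      substr(row, mid, mid + 2L) <- "TAA"
      row
    },
    len_mod3 = {
      mid <- n %/% 2L
      substr(row, mid, mid) <- "-"
      row
    },
    stop("unknown defect: ", defect))
  aln$rows[[species]] <- row
  gene_alignment(aln$rows, aln$gene_id)
}

#' Plant a compensatory-pair template into an existing alignment
#'
#' Used to verify detectability when building matched controls: the
#' template is planted on the carrier clade in a stretch of columns that
#' is gap-free in every row, and several positions are tried until the
#' carrier rows still pass [quality_check()].
#'
#' @param aln a [gene_alignment()].
#' @param tree rooted [ape::phylo].
#' @param carrier_species species inheriting the planted pair (must allow
#'   unambiguous placement on `tree`).
#' @param template a [pcfm_template()].
#' @param max_tries positions tried.
#' @return list with the planted `aln` and the truth coordinates
#'   (`col_start_5p`, `col_end_3p`, kinds, `edge_label`), or an error when
#'   no valid placement exists.
#' @export
plant_pcfm_in_alignment <- function(aln, tree, carrier_species, template,
                                    max_tries = 10L) {
  stopifnot(inherits(aln, "gene_alignment"), inherits(template, "pcfm_template"))
  mat <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(mat) <- aln$species_ids
  clean <- colSums(mat == "-") == 0L
  consumed <- template_consumed(template)
  width <- consumed + 2L
  # candidate start columns: gap-free run wide enough, away from the ends
  runs <- which(vapply(seq_len(ncol(mat) - width + 1L), function(j)
    all(clean[j:(j + width - 1L)]), logical(1L)))
  runs <- runs[runs >= 7L & runs + consumed <= ncol(mat) - 6L]
  if (length(runs) == 0L) stop("no gap-free stretch wide enough to plant")
  for (i in seq_len(max_tries)) {
    pos <- if (length(runs) == 1L) runs else sample(runs, 1L)
    planted <- plant_features(mat, template_features(template, pos,
                                                     carrier_species))
    rows <- apply(planted$mat, 1L, paste, collapse = "")
    if (all(vapply(carrier_species, function(sp)
      quality_check(rows[[sp]])$passes, logical(1L)))) {
      return(list(
        aln = gene_alignment(rows, aln$gene_id),
        kind_5p = template$kind_5p, kind_3p = template$kind_3p,
        col_start_5p = planted$coords[[1L]][1L],
        col_end_3p = planted$coords[[2L]][2L],
        edge_label = edge_label_for(carrier_species)))
    }
  }
  stop("planting failed: carriers never passed quality")
}

#' Run the detection pipeline and score it against a truth table
#'
#' @param alignments named list of [gene_alignment()].
#' @param tree rooted [ape::phylo].
#' @param truth truth table from [simulate_genes()].
#' @param mode postfilter mode.
#' @return list with `recall`, `precision`, `detected` (all reported
#'   pairs), `n_true` (conforming planted pairs).
#' @export
evaluate_detection <- function(alignments, tree, truth,
                               mode = "low_confidence") {
  detected <- list()
  for (aln in alignments) {
    ev <- suppressMessages(infer_indels(aln, tree))
    q <- quality_check_alignment(aln)
    pr <- postfilter_pcfms(pair_pcfms(ev, q, aln), mode)
    if (nrow(pr) > 0L) detected[[length(detected) + 1L]] <- pr
  }
  detected <- if (length(detected)) do.call(rbind, detected) else
    pair_pcfms(NULL, NULL, gene_alignment(c(x = "AAA"), "empty"))
  pos <- truth[!is.na(truth$is_conforming) & truth$is_conforming, ,
               drop = FALSE]
  match_key <- function(d) paste(d$gene_id, d$col_start_5p, d$col_end_3p,
                                 d$kind_5p, d$kind_3p, d$edge_label)
  truth_keys <- if (nrow(pos)) match_key(pos) else character(0)
  det_keys <- if (nrow(detected)) match_key(detected) else character(0)
  list(recall = if (length(truth_keys)) mean(truth_keys %in% det_keys) else NA,
       precision = if (length(det_keys)) mean(det_keys %in% truth_keys) else NA,
       detected = detected, n_true = nrow(pos))
}

#' Pool of quality-passing control coding sequences
#'
#' Ungapped random CDS with log-normally distributed lengths (rounded to
#' whole codons) around the preset mean gene length: 1897 nt for the
#' vertebrate preset, 1204 nt for the insect preset. Every sequence starts
#' with ATG, ends with a stop and is internally stop-free, so the whole
#' pool passes [quality_check()] by construction.
#'
#' @param n_genes pool size.
#' @param preset `"vertebrate"` or `"insect"`, or `NULL` with explicit
#'   `mean_length_nt`.
#' @param mean_length_nt mean CDS length in nucleotides.
#' @param sdlog log-scale standard deviation of the length distribution.
#' @param seed integer seed.
#' @return Character vector of CDS.
#' @export
make_control_pool <- function(n_genes, preset = c("vertebrate", "insect"),
                              mean_length_nt = NULL, sdlog = 0.45,
                              seed = 1L) {
  if (is.null(mean_length_nt)) {
    preset <- match.arg(preset)
    mean_length_nt <- if (preset == "vertebrate") 1897 else 1204
  }
  set.seed(seed)
  meanlog <- log(mean_length_nt) - sdlog^2 / 2
  lens <- pmax(60L, as.integer(round(stats::rlnorm(n_genes, meanlog,
                                                   sdlog) / 3) * 3L))
  vapply(lens, function(L) random_cds(L %/% 3L), character(1L))
}
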
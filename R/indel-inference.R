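#' Maximal gap blocks of an alignment
#'
#' A gap block is a maximal run of consecutive alignment columns sharing an
#' identical, nonempty set of gap-carrying species. Columns gapped in every
#' species carry no phylogenetic information and are skipped with a warning
#' (they also break block adjacency).
#'
#' @param aln a [gene_alignment()].
#' @return data.frame with columns `col_start`, `col_end` (1-based,
#'   inclusive) and `carriers` (comma-joined, sorted species ids); zero rows
#'   if the alignment is gap-free.
#' @export
find_gap_blocks <- function(aln) {
  stopifnot(inherits(aln, "gene_alignment"))
  mat <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(mat) <- aln$species_ids
  gap <- mat == "-"
  all_gap <- colSums(gap) == nrow(gap)
  if (any(all_gap))
    warning(sum(all_gap), " all-gap column(s) dropped")
  key <- apply(gap, 2L, function(g)
    paste(sort(rownames(mat)[g]), collapse = ","))
  key[all_gap] <- NA_character_   # break adjacency, emit no block
  key[key == ""] <- NA_character_
  out <- list()
  run_start <- NA_integer_
  for (j in seq_len(ncol(gap) + 1L)) {
    cur <- if (j <= ncol(gap)) key[j] else NA_character_
    prev <- if (j > 1L) key[j - 1L] else NA_character_
    same <- !is.na(cur) && !is.na(prev) && cur == prev
    if (!same && !is.na(prev))
      out[[length(out) + 1L]] <- data.frame(
        col_start = run_start, col_end = j - 1L, carriers = prev,
        stringsAsFactors = FALSE)
    if (!same && !is.na(cur)) run_start <- j
  }
  if (length(out) == 0L)
    return(data.frame(col_start = integer(), col_end = integer(),
                      carriers = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

carriers_of <- function(block_carriers) strsplit(block_carriers, ",", fixed = TRUE)[[1L]]

# zero-row event table flagged with the reason the block could not be placed
ambiguous_placement <- function(reason) {
  out <- data.frame(
    kind = character(), length_nt = integer(), col_start = integer(),
    col_end = integer(), edge_label = character(),
    n_descendants = integer(), descendants = character(),
    polarity_confident = logical(), stringsAsFactors = FALSE)
  attr(out, "reason") <- reason
  out
}

is_clade <- function(tree, tips) {
  if (length(tips) == 0L) return(FALSE)
  if (length(tips) == 1L) return(tips %in% tree$tip.label)
  if (!all(tips %in% tree$tip.label)) return(FALSE)
  m <- ape::getMRCA(tree, tips)
  below <- ape::extract.clade(tree, m)$tip.label
  setequal(below, tips)
}

edge_label_for <- function(tips) paste(sort(tips), collapse = ",")

#' Parsimony placement of one gap block on the phylogeny
#'
#' Gap presence/absence is treated as a binary character on the tree
#' restricted to `included_species` and the minimum-change (Fitch)
#' reconstruction is sought. A block is placed if and only if a single state
#' change on a single edge explains all carriers and the root state is
#' unambiguous: gap gained below the edge is a deletion (descendants = the
#' carriers); gap ancestral with nucleotides gained below the edge is an
#' insertion (descendants = the non-carriers). For one binary character this
#' reduces to a clade test: the minimal reconstruction has one change iff
#' the carriers or their complement form a clade, and the root is ambiguous
#' iff both do. Multi-change (homoplastic) blocks and root-ambiguous blocks
#' are reported as ambiguous and discarded upstream.
#'
#' @param block one row of [find_gap_blocks()] output (data.frame or list
#'   with `col_start`, `col_end`, `carriers`).
#' @param tree rooted [ape::phylo].
#' @param included_species species to analyse; carriers and non-carriers
#'   must both be nonempty within this set.
#' @return A one-row data.frame describing the event (columns `kind`,
#'   `length_nt`, `col_start`, `col_end`, `edge_label`, `n_descendants`,
#'   `descendants`, `polarity_confident`); when ambiguous, a zero-row
#'   data.frame with attribute `reason` (`"homoplastic"` or
#'   `"root_ambiguous"`).
#' @export
place_event <- function(block, tree, included_species = tree$tip.label) {
  carr <- intersect(carriers_of(block$carriers), included_species)
  nonc <- setdiff(included_species, carr)
  if (length(carr) == 0L || length(nonc) == 0L)
    stop("uninformative block: carriers empty or equal to all included species")
  if (!all(included_species %in% tree$tip.label))
    stop("included species missing from tree: ",
         paste(setdiff(included_species, tree$tip.label), collapse = ", "))
  sub <- if (length(included_species) < length(tree$tip.label))
    ape::keep.tip(tree, included_species) else tree
  carr_clade <- is_clade(sub, carr)
  nonc_clade <- is_clade(sub, nonc)
  if (carr_clade && nonc_clade) return(ambiguous_placement("root_ambiguous"))
  if (!carr_clade && !nonc_clade) return(ambiguous_placement("homoplastic"))
  desc <- if (carr_clade) carr else nonc
  kind <- if (carr_clade) "deletion" else "insertion"
  data.frame(
    kind = kind,
    length_nt = block$col_end - block$col_start + 1L,
    col_start = block$col_start,
    col_end = block$col_end,
    edge_label = edge_label_for(desc),
    n_descendants = length(desc),
    descendants = edge_label_for(desc),
    polarity_confident = TRUE,
    stringsAsFactors = FALSE)
}

#' Reconstruct indel events from a gapped alignment on a phylogeny
#'
#' Runs [find_gap_blocks()] and [place_event()] per block; ambiguous blocks
#' are dropped with a message. Quality filtering is deliberately applied
#' after this reconstruction (at the pairing stage), so that lower-quality
#' rows still inform the phylogenetic placement of shared gaps.
#'
#' @param aln a [gene_alignment()].
#' @param tree rooted [ape::phylo] whose leaves cover the alignment species.
#' @param included_species species to analyse (default: all alignment rows);
#'   at least 4 required.
#' @return data.frame of events sorted by `col_start`, with a `gene_id`
#'   column prepended to the [place_event()] columns; zero rows when the
#'   alignment is gap-free.
#' @export
infer_indels <- function(aln, tree, included_species = aln$species_ids) {
  stopifnot(inherits(aln, "gene_alignment"))
  if (length(included_species) < 4L)
    stop("too few species: ", length(included_species), " < 4")
  blocks <- find_gap_blocks(aln)
  empty <- data.frame(
    gene_id = character(), kind = character(), length_nt = integer(),
    col_start = integer(), col_end = integer(), edge_label = character(),
    n_descendants = integer(), descendants = character(),
    polarity_confident = logical(), stringsAsFactors = FALSE)
  if (nrow(blocks) == 0L) return(empty)
  events <- list()
  n_ambiguous <- 0L
  for (i in seq_len(nrow(blocks))) {
    carr <- intersect(carriers_of(blocks$carriers[i]), included_species)
    if (length(carr) == 0L || length(carr) == length(included_species))
      next  # uninformative within the included set
    ev <- place_event(blocks[i, ], tree, included_species)
    if (nrow(ev) == 0L) n_ambiguous <- n_ambiguous + 1L
    else events[[length(events) + 1L]] <- ev
  }
  if (n_ambiguous > 0L)
    message(n_ambiguous, " ambiguous gap block(s) dropped in gene ",
            aln$gene_id)
  if (length(events) == 0L) return(empty)
  out <- do.call(rbind, events)
  out <- cbind(gene_id = aln$gene_id, out, stringsAsFactors = FALSE)
  out[order(out$col_start), , drop = FALSE]
}

#' Write an indel event table as TSV
#'
#' Columns: gene_id, kind, length_nt, col_start_1based, col_end_1based,
#' edge_label, n_descendants, descendants.
#'
#' @param events output of [infer_indels()].
#' @param path output path.
#' @export
write_indel_table <- function(events, path) {
  out <- data.frame(
    gene_id = events$gene_id, kind = events$kind,
    length_nt = events$length_nt,
    col_start_1based = events$col_start, col_end_1based = events$col_end,
    edge_label = events$edge_label, n_descendants = events$n_descendants,
    descendants = events$descendants, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
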
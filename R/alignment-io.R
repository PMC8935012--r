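#' Gapped coding-sequence alignment for one gene
#'
#' Constructs a `gene_alignment`: a multiple nucleotide alignment of
#' orthologous CDS across species, with `-` as the gap character. All rows
#' must have identical length and may contain only `A`, `C`, `G`, `T`, `N`
#' and `-` (lowercase input is uppercased).
#'
#' @param rows named character vector of gapped sequences; names are species
#'   identifiers and must be unique.
#' @param gene_id single string identifying the gene.
#' @return An object of class `gene_alignment` with elements `gene_id`,
#'   `species_ids`, `rows` (named character vector) and `n_columns`.
#' @export
gene_alignment <- function(rows, gene_id = "gene") {
  if (length(rows) == 0L) stop("empty alignment: no sequences")
  if (is.null(names(rows)) || anyNA(names(rows)) || any(names(rows) == ""))
    stop("all rows must be named by species id")
  if (anyDuplicated(names(rows)))
    stop("duplicate species ids: ",
         paste(unique(names(rows)[duplicated(names(rows))]), collapse = ", "))
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("malformed alignment: row lengths differ (",
         names(rows)[which(widths != widths[1L])[1L]], " has ",
         widths[widths != widths[1L]][1L], " columns, expected ", widths[1L], ")")
  if (widths[1L] < 1L) stop("malformed alignment: zero-length rows")
  bad <- regexpr("[^ACGTN-]", rows)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("illegal character in record '", names(rows)[i],
         "' at position ", bad[i])
  }
  structure(
    list(gene_id = gene_id, species_ids = names(rows), rows = rows,
         n_columns = unname(widths[1L])),
    class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("gene_alignment '", x$gene_id, "': ", length(x$rows), " species x ",
      x$n_columns, " columns\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file into a gene_alignment
#'
#' @param path path to an aligned FASTA file (gap character `-`).
#' @param gene_id gene identifier; defaults to the file name without extension.
#' @return A [gene_alignment()] with record order preserved.
#' @export
read_alignment <- function(path, gene_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty input: no FASTA records in ", path)
  rows <- as.character(ss)
  # keep only the first whitespace-delimited token of each FASTA header
  names(rows) <- sub("\\s.*$", "", names(rows))
  if (is.null(gene_id)) gene_id <- sub("\\.[^.]*$", "", basename(path))
  gene_alignment(rows, gene_id = gene_id)
}

#' Write a gene_alignment to FASTA
#'
#' @param aln a [gene_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "gene_alignment"))
  ss <- Biostrings::BStringSet(aln$rows)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Missing branch lengths are set to 0 with a warning; duplicate leaf labels
#' are an error. The tree is used both for parsimony placement of indel
#' events and for gene-age calculations, with branch lengths in expected
#' substitutions per site.
#'
#' @param path path to a Newick file containing one tree.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (is.null(tr)) stop("could not parse a Newick tree from ", path)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning(sum(is.na(tr$edge.length)), " missing branch length(s) set to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  tr
}

# stop codons of the standard genetic code (both clades analysed use it)
STOP_CODONS <- c("TAA", "TAG", "TGA")

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Sequence-quality criteria for one coding sequence
#'
#' A gene copy is considered likely functional when its ungapped sequence
#' (i) starts with ATG, (ii) ends with a stop codon, (iii) has length
#' divisible by 3, and (iv) contains no internal in-frame stop codon.
#' Rows failing any criterion are excluded from pairing (pseudogenized or
#' misassembled copies).
#'
#' @param nt ungapped nucleotide string (gaps, if present, are removed).
#' @param species_id optional species label carried through to the report.
#' @return A one-row data.frame with columns `species_id`, `has_start`,
#'   `has_terminal_stop`, `length_mod3_ok`, `internal_stop_free`,
#'   `n_frame_disrupting_indels` (filled by the detection stage; 0 here)
#'   and `passes`.
#' @export
quality_check <- function(nt, species_id = NA_character_) {
  nt <- toupper(ungap(nt))
  if (nchar(nt) == 0L) stop("empty sequence")
  n <- nchar(nt)
  has_start <- substr(nt, 1L, 3L) == "ATG"
  has_terminal_stop <- n >= 3L && substr(nt, n - 2L, n) %in% STOP_CODONS
  length_mod3_ok <- n %% 3L == 0L
  k <- n %/% 3L
  internal_stop_free <- TRUE
  if (k > 1L) {
    starts <- seq(1L, by = 3L, length.out = k - 1L)
    codons <- substring(nt, starts, starts + 2L)
    internal_stop_free <- !any(codons %in% STOP_CODONS)
  }
  data.frame(
    species_id = species_id,
    has_start = has_start,
    has_terminal_stop = has_terminal_stop,
    length_mod3_ok = length_mod3_ok,
    internal_stop_free = internal_stop_free,
    n_frame_disrupting_indels = 0L,
    passes = has_start && has_terminal_stop && length_mod3_ok &&
      internal_stop_free,
    stringsAsFactors = FALSE)
}

#' Quality reports for every row of an alignment
#'
#' @param aln a [gene_alignment()].
#' @return data.frame with one [quality_check()] row per species.
#' @export
quality_check_alignment <- function(aln) {
  stopifnot(inherits(aln, "gene_alignment"))
  do.call(rbind, lapply(aln$species_ids, function(sp)
    quality_check(aln$rows[[sp]], species_id = sp)))
}

#' Translate a nucleotide string in a given reading frame
#'
#' Standard genetic code. Stop codons are rendered as `*` and retained in
#' place (no truncation), so peptides from frame-shifted regions keep their
#' positional alignment with the unshifted translation. Codons containing
#' `N` (or any non-ACGT character) translate to `X`. A trailing partial
#' codon is dropped.
#'
#' @param nt ungapped nucleotide string.
#' @param frame_offset 0, 1 or 2 nucleotides skipped before the first codon.
#' @return Amino-acid string over the 20 standard residues plus `*` and `X`.
#' @export
translate_nt <- function(nt, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  nt <- toupper(nt)
  if (grepl("-", nt, fixed = TRUE)) stop("translate_nt expects ungapped input")
  nt <- substr(nt, frame_offset + 1L, nchar(nt))
  k <- nchar(nt) %/% 3L
  if (k == 0L) return("")
  starts <- seq(1L, by = 3L, length.out = k)
  codons <- substring(nt, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- code[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
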
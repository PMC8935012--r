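#' Pair frame-disrupting indels into candidate compensatory pairs
#'
#' Restricted to species passing all four quality criteria, a species'
#' frame-disrupting events (length not divisible by 3) are examined: a
#' species with exactly two such events contributes a candidate pair, which
#' is kept iff the signed net length change (insertions positive, deletions
#' negative) is divisible by 3, i.e. the second indel restores the reading
#' frame. Species with more than two frame-disrupting events are excluded
#' (their reconstruction is considered untrustworthy); species with one or
#' zero contribute nothing. Identical pairs supported by several species
#' are emitted once with the union carrier set.
#'
#' @param events event table from [infer_indels()] for one gene.
#' @param quality data.frame from [quality_check_alignment()].
#' @param aln the [gene_alignment()] the events came from (used to count
#'   spacer nucleotides on a carrier row and, as a secondary column, on a
#'   non-carrier row).
#' @return data.frame of candidate pairs, possibly empty, with columns
#'   `gene_id`, `kind_5p`, `len_5p`, `col_start_5p`, `col_end_5p`,
#'   `kind_3p`, `len_3p`, `col_start_3p`, `col_end_3p`, `spacer_nt`
#'   (derived-sequence nucleotides strictly between the indels, primary),
#'   `spacer_nt_anc` (ancestral-coordinate count), `combined_offset`,
#'   `same_edge`, `edge_label`, `n_carriers`, `carriers`.
#' @export
pair_pcfms <- function(events, quality, aln) {
  stopifnot(inherits(aln, "gene_alignment"))
  empty <- data.frame(
    gene_id = character(), kind_5p = character(), len_5p = integer(),
    col_start_5p = integer(), col_end_5p = integer(), kind_3p = character(),
    len_3p = integer(), col_start_3p = integer(), col_end_3p = integer(),
    spacer_nt = integer(), spacer_nt_anc = integer(),
    combined_offset = integer(), same_edge = logical(),
    edge_label = character(), n_carriers = integer(), carriers = character(),
    stringsAsFactors = FALSE)
  if (is.null(events) || nrow(events) == 0L) return(empty)
  passing <- quality$species_id[quality$passes]
  if (length(passing) == 0L) return(empty)
  fd <- events[events$length_nt %% 3L != 0L, , drop = FALSE]
  if (nrow(fd) == 0L) return(empty)
  desc_sets <- strsplit(fd$descendants, ",", fixed = TRUE)
  found <- list()
  for (sp in passing) {
    idx <- which(vapply(desc_sets, function(d) sp %in% d, logical(1L)))
    if (length(idx) != 2L) next
    idx <- idx[order(fd$col_start[idx])]
    e5 <- fd[idx[1L], ]; e3 <- fd[idx[2L], ]
    off <- sum(ifelse(c(e5$kind, e3$kind) == "insertion", 1L, -1L) *
                 c(e5$length_nt, e3$length_nt))
    if (off %% 3L != 0L) next
    key <- paste(e5$col_start, e5$col_end, e3$col_start, e3$col_end, sep = ":")
    if (is.null(found[[key]])) {
      found[[key]] <- list(e5 = e5, e3 = e3, off = off, carriers = sp)
    } else {
      found[[key]]$carriers <- c(found[[key]]$carriers, sp)
    }
  }
  if (length(found) == 0L) return(empty)
  rows <- lapply(found, function(f) {
    carr <- sort(unique(f$carriers))
    data.frame(
      gene_id = aln$gene_id,
      kind_5p = f$e5$kind, len_5p = f$e5$length_nt,
      col_start_5p = f$e5$col_start, col_end_5p = f$e5$col_end,
      kind_3p = f$e3$kind, len_3p = f$e3$length_nt,
      col_start_3p = f$e3$col_start, col_end_3p = f$e3$col_end,
      spacer_nt = count_spacer(aln, f$e5$col_end, f$e3$col_start, carr[1L]),
      spacer_nt_anc = count_spacer_anc(aln, f$e5$col_end, f$e3$col_start, carr),
      combined_offset = f$off,
      same_edge = f$e5$edge_label == f$e3$edge_label,
      edge_label = if (f$e5$edge_label == f$e3$edge_label) f$e5$edge_label
                   else paste(f$e5$edge_label, f$e3$edge_label, sep = " | "),
      n_carriers = length(carr),
      carriers = paste(carr, collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$col_start_5p), , drop = FALSE]
}

# non-gap nucleotides strictly between the two indels on a carrier row
count_spacer <- function(aln, col_end_5p, col_start_3p, carrier) {
  if (col_start_3p - col_end_5p <= 1L) return(0L)
  seg <- substr(aln$rows[[carrier]], col_end_5p + 1L, col_start_3p - 1L)
  nchar(ungap(seg))
}

# same count on a non-carrier (ancestral-like) row
count_spacer_anc <- function(aln, col_end_5p, col_start_3p, carriers) {
  ref <- setdiff(aln$species_ids, carriers)[1L]
  if (is.na(ref)) return(NA_integer_)
  if (col_start_3p - col_end_5p <= 1L) return(0L)
  seg <- substr(aln$rows[[ref]], col_end_5p + 1L, col_start_3p - 1L)
  nchar(ungap(seg))
}

#' Length and confidence filters for candidate compensatory pairs
#'
#' The low-confidence filter keeps pairs of short indels: each indel of
#' length 1 or 2, combined length at most 4, one of the allowed type
#' combinations (lengths 1+2 of the same kind; 1+1 of opposite kinds; 2+2
#' of opposite kinds), and both indels placed on the same tree edge. The
#' high-confidence filter additionally requires the pair to be inherited by
#' at least two species.
#'
#' @param pairs output of [pair_pcfms()].
#' @param mode `"low_confidence"` or `"high_confidence"`.
#' @return The filtered subset of `pairs`.
#' @export
postfilter_pcfms <- function(pairs, mode = c("low_confidence", "high_confidence")) {
  mode <- match.arg(mode)
  if (nrow(pairs) == 0L) return(pairs)
  lens_ok <- pairs$len_5p <= 2L & pairs$len_3p <= 2L &
    (pairs$len_5p + pairs$len_3p) <= 4L
  same_kind <- pairs$kind_5p == pairs$kind_3p
  combo_ok <- (same_kind & pairs$len_5p + pairs$len_3p == 3L) |
    (!same_kind & pairs$len_5p == pairs$len_3p)
  keep <- lens_ok & combo_ok & pairs$same_edge
  if (mode == "high_confidence") keep <- keep & pairs$n_carriers >= 2L
  pairs[keep, , drop = FALSE]
}

#' Relative position of a compensatory pair along the CDS
#'
#' `P = p1 / (L - (p2 - p1))` where `p1` is the ungapped ancestral-frame
#' position of the 5' indel's 5' edge (0 when the pair starts at the very
#' first nucleotide), `p2` the position of the 3' indel's 3' edge, and `L`
#' the CDS length; `P = 0` when the 5' indel sits at the 5'-most end of the
#' CDS and `P = 1` when the 3' indel reaches the 3'-most end.
#'
#' @param p1,p2 nucleotide offsets, `0 <= p1 <= p2 <= L`.
#' @param L CDS length in nucleotides.
#' @return `P` in `[0, 1]`.
#' @export
relative_position <- function(p1, p2, L) {
  stopifnot(p1 >= 0, p2 >= p1, L >= p2)
  denom <- L - (p2 - p1)
  if (denom == 0) stop("degenerate span: pair covers the entire CDS")
  min(max(p1 / denom, 0), 1)
}

#' Ancestral-coordinate endpoints of a compensatory pair
#'
#' Measures `p1`, `p2` and `L` on the ungapped coordinate system of a
#' reference row that does not carry the pair (the ancestral, non-shifted
#' coordinates, comparable to genomic CDS coordinates of polymorphism
#' indels), then computes [relative_position()].
#'
#' @param pair one row of [pair_pcfms()] output.
#' @param aln the [gene_alignment()].
#' @param reference_species row to measure on; default: first species not in
#'   the carrier set.
#' @return list with `p1`, `p2`, `L`, `P`.
#' @export
pcfm_positions <- function(pair, aln, reference_species = NULL) {
  carr <- strsplit(pair$carriers, ",", fixed = TRUE)[[1L]]
  if (is.null(reference_species))
    reference_species <- setdiff(aln$species_ids, carr)[1L]
  if (is.na(reference_species) || !reference_species %in% aln$species_ids)
    stop("no non-carrier reference row available")
  row <- aln$rows[[reference_species]]
  nongap_before <- function(col) {
    if (col == 0L) return(0L)
    nchar(ungap(substr(row, 1L, col)))
  }
  p1 <- nongap_before(pair$col_start_5p - 1L)
  p2 <- nongap_before(pair$col_end_3p)
  L <- nchar(ungap(row))
  list(p1 = p1, p2 = p2, L = L, P = relative_position(p1, p2, L))
}

#' Compare a set of relative positions with uniformity and a reference set
#'
#' Computes (i) the one-sample Kolmogorov-Smirnov test against Uniform(0,1),
#' (ii) the two-sample KS test against `reference` when given, and (iii)
#' binned density curves with 95% bootstrap confidence intervals.
#'
#' @param observed numeric vector of relative positions in `[0, 1]`.
#' @param reference optional comparison vector (e.g. relative positions of
#'   uncompensated polymorphism indels).
#' @param n_boot number of bootstrap resamples for the density CIs.
#' @param seed integer seed for the bootstrap.
#' @param n_bins number of equal-width density bins on `[0, 1]`.
#' @return list of class `pcfm_position_test` with elements `ks_uniform`,
#'   `ks_reference` (or `NULL`), and `density` (data.frame with bin mids,
#'   density, and bootstrap CI bounds).
#' @export
compare_position_distributions <- function(observed, reference = NULL,
                                           n_boot = 1000L, seed = 1L,
                                           n_bins = 20L) {
  if (length(observed) == 0L) stop("observed is empty")
  if (n_boot < 1L) stop("n_boot must be >= 1")
  ks_u <- suppressWarnings(stats::ks.test(observed, "punif"))
  ks_r <- NULL
  if (!is.null(reference)) {
    if (length(reference) == 0L) stop("reference is empty")
    ks_r <- suppressWarnings(stats::ks.test(observed, reference))
  }
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  dens <- function(x) {
    h <- graphics::hist(pmin(pmax(x, 0), 1), breaks = breaks, plot = FALSE)
    h$density
  }
  obs_d <- dens(observed)
  set.seed(seed)
  boot <- replicate(n_boot,
                    dens(sample(observed, replace = TRUE)))
  ci <- apply(boot, 1L, stats::quantile, probs = c(0.025, 0.975))
  structure(list(
    ks_uniform = ks_u,
    ks_reference = ks_r,
    density = data.frame(
      mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
      density = obs_d, lower = ci[1L, ], upper = ci[2L, ])),
    class = "pcfm_position_test")
}

#' @export
print.pcfm_position_test <- function(x, ...) {
  cat("One-sample KS vs Uniform(0,1): D =",
      format(unname(x$ks_uniform$statistic), digits = 4),
      ", p =", format(x$ks_uniform$p.value, digits = 4), "\n")
  if (!is.null(x$ks_reference))
    cat("Two-sample KS vs reference:    D =",
        format(unname(x$ks_reference$statistic), digits = 4),
        ", p =", format(x$ks_reference$p.value, digits = 4), "\n")
  invisible(x)
}

#' Write a pCFM table as TSV
#'
#' @param pairs [pair_pcfms()] output, optionally augmented with positions.
#' @param aln the corresponding [gene_alignment()] (for `p1`/`p2`/`P`).
#' @param path output path.
#' @export
write_pcfm_table <- function(pairs, aln, path) {
  if (nrow(pairs) > 0L) {
    pos <- lapply(seq_len(nrow(pairs)), function(i)
      tryCatch(pcfm_positions(pairs[i, ], aln),
               error = function(e) list(p1 = NA, p2 = NA, L = NA, P = NA)))
    pairs$p1_1based <- vapply(pos, function(p) p$p1 + 1L, numeric(1L))
    pairs$p2_1based <- vapply(pos, function(p) as.numeric(p$p2), numeric(1L))
    pairs$P <- vapply(pos, function(p) as.numeric(p$P), numeric(1L))
  }
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
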
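# Independent oracles and small fixture builders used across the suite.

# Exhaustive minimum-change placement oracle for a binary gap character:
# enumerates every assignment of states to internal nodes and returns the
# event only when a unique minimal reconstruction with exactly one changed
# edge exists. Independent of the package's clade-based implementation.
oracle_place <- function(tree, carriers) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  internal <- ntip + seq_len(nnode)
  leaf_states <- as.integer(tree$tip.label %in% carriers)
  best <- Inf
  best_assignments <- list()
  for (mask in 0:(2^nnode - 1L)) {
    states <- integer(ntip + nnode)
    states[seq_len(ntip)] <- leaf_states
    states[internal] <- bitwAnd(bitwShiftR(mask, 0:(nnode - 1L)), 1L)
    changes <- sum(states[tree$edge[, 1L]] != states[tree$edge[, 2L]])
    if (changes < best) {
      best <- changes
      best_assignments <- list(states)
    } else if (changes == best) {
      best_assignments[[length(best_assignments) + 1L]] <- states
    }
  }
  if (best != 1L || length(best_assignments) != 1L) return(NULL)
  st <- best_assignments[[1L]]
  k <- which(st[tree$edge[, 1L]] != st[tree$edge[, 2L]])
  child <- tree$edge[k, 2L]
  desc <- if (child <= ntip) tree$tip.label[child]
          else ape::extract.clade(tree, child)$tip.label
  list(kind = if (st[child] == 1L) "deletion" else "insertion",
       descendants = sort(desc))
}

# quartet tree used throughout: ((a,b),(c,d)) with unit branch lengths
quartet_tree <- function()
  ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")

# alignment with one gap block for the given carriers
block_alignment <- function(carriers, tips = c("a", "b", "c", "d"),
                            flank = "ATGAAA", gap_len = 2L,
                            tail = "CCCTAA") {
  base <- paste0(flank, strrep("G", gap_len), tail)
  rows <- setNames(rep(base, length(tips)), tips)
  for (sp in carriers)
    substr(rows[[sp]], nchar(flank) + 1L, nchar(flank) + gap_len) <-
      strrep("-", gap_len)
  gene_alignment(rows, "toy")
}

write_temp_fasta <- function(rows) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(rows), function(n)
    c(paste0(">", n), rows[[n]]))), path)
  path
}
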
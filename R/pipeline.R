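# Orchestration: chain the stages on one input set with a single seed
# fanned out to per-stage child seeds, writing TSV/JSON artifacts and a
# run manifest so any stage can be rerun from the manifest alone.

STAGE_SEED_OFFSETS <- c(simulate = 101L, detect = 211L, position = 307L,
                        conserve = 401L, effects = 503L, popgen = 601L)

stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + STAGE_SEED_OFFSETS[[stage]]) %% 2147483647L
}

#' Run the analysis pipeline
#'
#' Subcommands: `simulate` (synthetic alignments + truth), `detect`
#' (indel inference, pairing, filters), `position` (relative positions and
#' distribution tests), `effects` (per-pair null distributions and
#' percentile p-values), `popgen` (expected-frequency model), or `all`
#' (simulate then every downstream stage). Outputs are TSV/JSON files in
#' `config$out_dir` plus a `manifest.json` echoing the configuration,
#' seed, package version and input checksums.
#'
#' @param subcommand one of `"simulate"`, `"detect"`, `"position"`,
#'   `"effects"`, `"popgen"`, `"all"`.
#' @param config list: `out_dir` (required); for `detect`/`position`/
#'   `effects` either `alignment_dir` + `tree_file` on disk or
#'   `alignments` + `tree` in memory; `mode`
#'   (`"low_confidence"`/`"high_confidence"`), `n_null_draws` (default
#'   10000), `n_boot` (default 1000), `clade` (popgen preset), `seed`,
#'   and any [sim_config()] fields under `sim`.
#' @return Invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "detect",
                                        "position", "effects", "popgen"),
                         config = list()) {
  subcommand <- match.arg(subcommand)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$mode)) config$mode <- "low_confidence"
  if (is.null(config$n_null_draws)) config$n_null_draws <- 10000L
  if (is.null(config$n_boot)) config$n_boot <- 1000L
  results <- list()
  stages <- if (subcommand == "all")
    c("simulate", "detect", "position", "effects", "popgen") else subcommand
  state <- load_inputs(config)
  for (st in stages) {
    results[[st]] <- switch(
      st,
      simulate = {
        sc <- do.call(sim_config, c(config$sim,
                                    list(seed = stage_seed(config$seed,
                                                           "simulate"))))
        sim <- simulate_genes(sc)
        dir.create(file.path(config$out_dir, "alignments"),
                   showWarnings = FALSE)
        for (gid in names(sim$alignments))
          write_alignment(sim$alignments[[gid]],
                          file.path(config$out_dir, "alignments",
                                    paste0(gid, ".fasta")))
        ape::write.tree(sim$tree, file.path(config$out_dir, "tree.nwk"))
        utils::write.table(sim$truth, file.path(config$out_dir, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        state$alignments <- sim$alignments
        state$tree <- sim$tree
        sim
      },
      detect = {
        stopifnot(!is.null(state$alignments), !is.null(state$tree))
        all_events <- list(); all_pairs <- list()
        for (aln in state$alignments) {
          ev <- suppressMessages(infer_indels(aln, state$tree))
          q <- quality_check_alignment(aln)
          pr <- postfilter_pcfms(pair_pcfms(ev, q, aln), config$mode)
          if (nrow(ev)) all_events[[aln$gene_id]] <- ev
          if (nrow(pr)) all_pairs[[aln$gene_id]] <- pr
        }
        events <- if (length(all_events)) do.call(rbind, all_events) else NULL
        pairs <- if (length(all_pairs)) do.call(rbind, all_pairs) else
          postfilter_pcfms(pair_pcfms(NULL, NULL, state$alignments[[1L]]),
                           config$mode)
        if (!is.null(events))
          write_indel_table(events, file.path(config$out_dir, "indels.tsv"))
        utils::write.table(pairs, file.path(config$out_dir, "pcfms.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        state$pairs <- pairs
        list(events = events, pairs = pairs)
      },
      position = {
        pairs <- state$pairs
        if (is.null(pairs) || nrow(pairs) == 0L) {
          message("no pairs: position stage skipped")
          NULL
        } else {
          P <- vapply(seq_len(nrow(pairs)), function(i)
            pcfm_positions(pairs[i, ],
                           state$alignments[[pairs$gene_id[i]]])$P,
            numeric(1L))
          ref <- if (!is.null(config$reference_positions_file))
            utils::read.delim(config$reference_positions_file)[[1L]] else NULL
          tst <- compare_position_distributions(
            P, ref, n_boot = config$n_boot,
            seed = stage_seed(config$seed, "position"))
          utils::write.table(
            data.frame(gene_id = pairs$gene_id, P = P),
            file.path(config$out_dir, "positions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
          tst
        }
      },
      effects = {
        pairs <- state$pairs
        if (is.null(pairs) || nrow(pairs) == 0L) {
          message("no pairs: effects stage skipped")
          NULL
        } else {
          pool <- if (!is.null(config$control_pool)) config$control_pool
          else make_control_pool(
            200L, mean_length_nt = 1500,
            seed = stage_seed(config$seed, "effects"))
          rows <- lapply(seq_len(nrow(pairs)), function(i) {
            pair <- pairs[i, ]
            aln <- state$alignments[[pair$gene_id]]
            q <- tryCatch(ancestral_states(aln, state$tree, pair),
                          error = function(e) NULL)
            if (is.null(q)) return(NULL)
            obs <- miyata_mean(q$A, q$E)
            nl <- build_null(pool, template_from_pair(pair), "miyata",
                             n_draws = config$n_null_draws,
                             seed = stage_seed(config$seed, "effects") + i,
                             observed = obs)
            data.frame(gene_id = pair$gene_id, observed_miyata = obs,
                       null_mean = mean(nl$draws),
                       percentile_p = nl$percentile_p,
                       stringsAsFactors = FALSE)
          })
          rows <- Filter(Negate(is.null), rows)
          out <- if (length(rows)) do.call(rbind, rows) else NULL
          if (!is.null(out))
            utils::write.table(out, file.path(config$out_dir, "effects.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
          out
        }
      },
      popgen = {
        params <- popgen_params(clade = if (is.null(config$clade))
          "vertebrate" else config$clade)
        res <- expected_pcfm(params)
        s1 <- simultaneous_scenario(params)
        out <- list(
          m1_by_type = as.list(res$m1_by_type),
          m2_by_type = as.list(res$m2_by_type),
          P_gene = res$P_gene, P_gene_rounded = res$P_gene_rounded,
          expected_count = res$expected_count_rounded,
          ci_halfwidth = res$ci_halfwidth_rounded,
          simultaneous_P_gene = s1$P_gene,
          simultaneous_P_gene_unrounded = s1$P_gene_unrounded)
        jsonlite::write_json(out, file.path(config$out_dir, "popgen.json"),
                             auto_unbox = TRUE, digits = NA)
        res
      })
  }
  write_manifest(config, subcommand)
  invisible(results)
}

load_inputs <- function(config) {
  state <- list(alignments = config[["alignments"]], tree = config[["tree"]],
                pairs = config[["pairs"]])
  if (is.null(state$alignments) && !is.null(config$alignment_dir)) {
    files <- list.files(config$alignment_dir, pattern = "\\.(fa|fasta)$",
                        full.names = TRUE)
    if (length(files) == 0L)
      stop("no FASTA files in ", config$alignment_dir)
    state$alignments <- lapply(files, read_alignment)
    names(state$alignments) <- vapply(state$alignments, `[[`, character(1L),
                                      "gene_id")
  }
  if (is.null(state$tree) && !is.null(config$tree_file))
    state$tree <- read_tree(config$tree_file)
  state
}

write_manifest <- function(config, subcommand) {
  inputs <- c(config$tree_file, config$reference_positions_file)
  manifest <- list(
    subcommand = subcommand,
    seed = config$seed,
    mode = config$mode,
    n_null_draws = config$n_null_draws,
    n_boot = config$n_boot,
    package_version = as.character(utils::packageVersion("pcfm")),
    input_checksums = if (length(inputs))
      as.list(tools::md5sum(inputs[file.exists(inputs)])) else list(),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}
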
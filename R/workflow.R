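# End-to-end purge workflow: the programmatic core behind the command-line
# interface.

#' Run the haplotig purge workflow
#'
#' Reads an assembly, its all-by-all contig alignments and per-contig BUSCO
#' results, then either applies a single purge at fixed thresholds
#' (hill climbing off: the "default" mode) or optimises the thresholds by
#' randomised hill climbing and exports the best unique candidates. All
#' outputs land in `out_dir`: per-candidate FASTA and purge reports, a
#' ranking table, assembly statistics before/after, the optimisation trace
#' (when hill climbing ran) and a JSON run summary capturing every
#' effective parameter.
#'
#' @param assembly Path to the contig FASTA.
#' @param alignments Path to a PSL/PAF file (optionally gzipped).
#' @param busco Path to either a directory of per-contig BUSCO runs or a
#'   merged per-contig table (see [load_busco_dir()], [load_busco_table()]).
#' @param universe_size Total BUSCO genes in the lineage set.
#' @param out_dir Output directory.
#' @param hillclimb Run threshold optimisation (`TRUE`) or a single purge
#'   at `thresholds` (`FALSE`).
#' @param thresholds A [purge_thresholds()] object used when
#'   `hillclimb = FALSE` (default 0.70/0.70/0.70).
#' @param config A [hillclimb_config()] used when `hillclimb = TRUE`.
#' @param alignment_format `"auto"`, `"psl"` or `"paf"`.
#' @param max_query_length Purge-eligibility cap on query contig length in
#'   bases (see [filter_eligible()]).
#' @return Invisibly, a list with the `store` of exported candidates, the
#'   `trace` (or `NULL`), and the summary list written to
#'   `run_summary.json`.
#' @export
run_haplopurge <- function(assembly, alignments, busco, universe_size,
                           out_dir, hillclimb = FALSE,
                           thresholds = purge_thresholds(),
                           config = hillclimb_config(),
                           alignment_format = "auto",
                           max_query_length = 1e7) {
  contigs <- read_contigs(assembly)
  raw <- parse_alignments(alignments, alignment_format)
  table <- filter_eligible(compute_metrics(raw), max_query_length)
  catalog <- if (dir.exists(busco)) {
    load_busco_dir(busco, universe_size)
  } else {
    load_busco_table(busco, universe_size)
  }
  all_contigs <- names(contigs)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trace <- NULL
  if (hillclimb) {
    res <- hill_climb(table, catalog, all_contigs, config)
    store <- res$store
    trace <- res$trace
    write_trace(trace, file.path(out_dir, "trace.tsv"))
  } else {
    cand <- score_candidate(
      candidate_assembly(table, thresholds, all_contigs),
      catalog, config$weights
    )
    store <- store_push(candidate_store(1L), cand)
  }

  export_candidates(store, contigs, out_dir)

  best <- store_best(store)
  stats <- rbind(
    cbind(assembly = "unreduced", assembly_stats(contigs)),
    cbind(assembly = "best_candidate",
          assembly_stats(contigs[best$retained]))
  )
  write_assembly_stats(stats, file.path(out_dir, "assembly_stats.tsv"))

  summary <- list(
    inputs = list(assembly = assembly, alignments = alignments,
                  busco = busco, universe_size = universe_size),
    parameters = list(
      hillclimb = hillclimb,
      max_query_length = max_query_length,
      thresholds = if (!hillclimb) {
        thresholds[c("id", "q", "qr")]
      },
      hillclimb_config = if (hillclimb) {
        list(iterations = config$iterations,
             step_increment = config$step_increment,
             plateau_limit = config$plateau_limit,
             best_x = config$best_x,
             weights = as.list(unclass(config$weights)),
             seed = config$seed)
      }
    ),
    results = list(
      n_contigs = length(all_contigs),
      n_alignment_rows = nrow(table),
      best_cost = best$cost,
      best_counts = as.list(unclass(best$counts)),
      n_retained = length(best$retained),
      n_purged = length(best$purged),
      best_thresholds = best$thresholds[c("id", "q", "qr")]
    )
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(store = store, trace = trace, summary = summary))
}
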
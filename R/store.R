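# Bounded unique-candidate store: the best-x assemblies, deduplicated by
# retained contig set.

#' Create a bounded unique-candidate store
#'
#' Retains at most `capacity` candidate assemblies, ordered by cost
#' ascending and deduplicated by retained contig set. Set-equality is only
#' ever tested between candidates whose retained sets have the same size
#' (sets of different sizes cannot be equal), and the worst retained cost is
#' available without scanning, so most pushes into a full store are rejected
#' by a single comparison.
#'
#' @param capacity Maximum number of unique candidates kept (`x`).
#' @return An empty `candidate_store`.
#' @export
candidate_store <- function(capacity) {
  stopifnot(length(capacity) == 1, capacity >= 1)
  structure(list(capacity = as.integer(capacity),
                 entries = list(),
                 costs = numeric(0),
                 sizes = integer(0)),
            class = "candidate_store")
}

# Deterministic ordering: cost ascending, then retained-set size
# descending, then lexicographic on the sorted retained set.
store_order <- function(costs, sizes, keys) {
  order(costs, -sizes, keys, method = "radix")
}

store_key <- function(candidate) {
  paste(sort(candidate$retained), collapse = "\r")
}

#' Push a scored candidate into the store
#'
#' A candidate worse than the current worst entry of a full store is
#' rejected outright. Otherwise it is compared against stored candidates
#' with the same retained-set size: if an identical retained set exists,
#' the lower-cost copy is kept; a new set is inserted, evicting the worst
#' entry when capacity is exceeded.
#'
#' @param store A [candidate_store()].
#' @param candidate A scored `candidate_assembly` (cost set).
#' @return The updated store.
#' @export
store_push <- function(store, candidate) {
  if (is.null(candidate$cost)) {
    stop("candidate must be scored before pushing", call. = FALSE)
  }
  full <- length(store$entries) >= store$capacity
  if (full && candidate$cost > store_worst(store)) {
    return(store)
  }
  size <- length(candidate$retained)
  key <- store_key(candidate)
  same_size <- which(store$sizes == size)
  dup <- same_size[vapply(store$entries[same_size],
                          function(e) attr(e, "store_key") == key,
                          logical(1))]
  if (length(dup)) {
    if (candidate$cost < store$costs[dup]) {
      attr(candidate, "store_key") <- key
      store$entries[[dup]] <- candidate
      store$costs[dup] <- candidate$cost
    }
  } else {
    attr(candidate, "store_key") <- key
    store$entries <- c(store$entries, list(candidate))
    store$costs <- c(store$costs, candidate$cost)
    store$sizes <- c(store$sizes, size)
  }
  keys <- vapply(store$entries, attr, character(1), "store_key")
  ord <- store_order(store$costs, store$sizes, keys)
  if (length(ord) > store$capacity) {
    ord <- ord[seq_len(store$capacity)]
  }
  store$entries <- store$entries[ord]
  store$costs <- store$costs[ord]
  store$sizes <- store$sizes[ord]
  store
}

#' Worst (highest) cost currently retained
#'
#' @param store A `candidate_store`.
#' @return The cost of the last entry; `Inf` for an empty store, so that
#'   any candidate qualifies.
#' @export
store_worst <- function(store) {
  n <- length(store$costs)
  if (n == 0L) Inf else store$costs[n]
}

#' Best candidate in the store
#'
#' @param store A `candidate_store`.
#' @return The lowest-cost `candidate_assembly`, or `NULL` if empty.
#' @export
store_best <- function(store) {
  if (length(store$entries) == 0L) NULL else store$entries[[1L]]
}

#' All stored candidates, best first
#'
#' @param store A `candidate_store`.
#' @return A list of `candidate_assembly` objects ordered by cost.
#' @export
store_candidates <- function(store) {
  store$entries
}

#' Merge candidate stores from independent runs
#'
#' Replaces multi-core execution: several independently seeded runs over
#' the same inputs are merged by pooling their candidates, deduplicating by
#' retained contig set (keeping the lower cost) and truncating to the
#' `best_x` lowest-cost unique sets.
#'
#' @param stores A list of `candidate_store` objects built over the same
#'   contig universe.
#' @param best_x Capacity of the merged store.
#' @return A `candidate_store`.
#' @export
merge_runs <- function(stores, best_x) {
  universes <- unique(vapply(stores, function(s) {
    paste(sort(unique(unlist(lapply(s$entries, function(e) {
      c(e$retained, e$purged)
    })))), collapse = "\r")
  }, character(1)))
  universes <- universes[nzchar(universes)]
  if (length(universes) > 1L) {
    stop("stores were built over different contig universes", call. = FALSE)
  }
  out <- candidate_store(best_x)
  for (s in stores) {
    for (e in s$entries) {
      out <- store_push(out, e)
    }
  }
  out
}

#' @export
print.candidate_store <- function(x, ...) {
  cat("Candidate store:", length(x$entries), "of up to", x$capacity,
      "unique assemblies\n")
  if (length(x$entries)) {
    cat(sprintf("  best cost %.4g (%d contigs), worst retained %.4g\n",
                x$costs[1], x$sizes[1], store_worst(x)))
  }
  invisible(x)
}

#' Export stored candidates to disk
#'
#' Writes, for each stored candidate in cost order, a FASTA of the retained
#' contigs (`candidate_<rank>.fasta`), a purge report
#' (`candidate_<rank>.purge.tsv`) and one combined ranking table
#' (`candidates.tsv`).
#'
#' @param store A `candidate_store`.
#' @param contigs A `DNAStringSet` of the full assembly.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the ranking data frame.
#' @export
export_candidates <- function(store, contigs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- store_candidates(store)
  rows <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    write_contigs(contigs, e$retained,
                  file.path(out_dir, sprintf("candidate_%02d.fasta", i)))
    write_purge_report(e, file.path(out_dir,
                                    sprintf("candidate_%02d.purge.tsv", i)))
    data.frame(rank = i, cost = e$cost,
               n_retained = length(e$retained),
               n_purged = length(e$purged),
               M = e$counts[["M"]], D = e$counts[["D"]],
               F = e$counts[["F"]], S = e$counts[["S"]],
               id_t = e$thresholds$id, q_t = e$thresholds$q,
               qr_t = e$thresholds$qr)
  })
  ranking <- do.call(rbind, rows)
  if (!is.null(ranking)) {
    utils::write.table(ranking, file.path(out_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(ranking)
}
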
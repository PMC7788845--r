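# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive results with naive loops rather
# than calling the package's own fast paths.

# Naive purge: test every (contig, row) pair with explicit loops.
naive_purge <- function(table, id_t, q_t, qr_t, all_contigs) {
  qr_prime_t <- exp(-log2(qr_t))
  lo <- min(qr_t, qr_prime_t)
  hi <- max(qr_t, qr_prime_t)
  purged <- character(0)
  for (ctg in all_contigs) {
    for (i in seq_len(nrow(table))) {
      if (table$query_name[i] == ctg &&
          table$ID[i] >= id_t && table$Q[i] >= q_t &&
          table$QR[i] >= lo && table$QR[i] <= hi) {
        purged <- c(purged, ctg)
        break
      }
    }
  }
  list(purged = sort(purged),
       retained = sort(setdiff(all_contigs, purged)))
}

# Naive BUSCO classification: loop over every gene seen in the catalog.
naive_counts <- function(catalog, retained) {
  genes <- unique(unlist(lapply(catalog$records, function(r) {
    c(r$complete_ids, r$fragmented_ids)
  })))
  s <- d <- f <- 0L
  for (g in genes) {
    n_complete <- 0L
    n_fragmented <- 0L
    for (ctg in retained) {
      r <- catalog$records[[ctg]]
      if (is.null(r)) next
      if (g %in% r$complete_ids) n_complete <- n_complete + 1L
      if (g %in% r$fragmented_ids) n_fragmented <- n_fragmented + 1L
    }
    if (n_complete == 1L) s <- s + 1L
    else if (n_complete >= 2L) d <- d + 1L
    else if (n_fragmented >= 1L) f <- f + 1L
  }
  c(M = catalog$universe_size - s - d - f, D = d, F = f, S = s)
}

# Brute-force best-x unique store: dedup by retained set keeping the
# minimum cost, order by (cost, size descending, sorted-set key), keep x.
naive_best_x <- function(candidates, x) {
  keys <- vapply(candidates, function(c) {
    paste(sort(c$retained), collapse = "\r")
  }, character(1))
  best <- list()
  for (i in seq_along(candidates)) {
    k <- keys[i]
    if (is.null(best[[k]]) || candidates[[i]]$cost < best[[k]]$cost) {
      best[[k]] <- candidates[[i]]
    }
  }
  costs <- vapply(best, `[[`, numeric(1), "cost")
  sizes <- vapply(best, function(c) length(c$retained), integer(1))
  ord <- order(costs, -sizes, names(best), method = "radix")
  unname(best[ord][seq_len(min(x, length(best)))])
}

# A bare alignment table from metric values (bypasses coordinates), for
# purge-rule tests that control ID/Q/QR directly.
metrics_table <- function(query, target, ID, Q, QR) {
  df <- data.frame(query_name = query, target_name = target,
                   ID = ID, Q = Q, R = Q / QR, QR = QR,
                   QR_prime = exp(-log2(QR)),
                   stringsAsFactors = FALSE)
  structure(df, class = c("alignment_table", "data.frame"))
}

# Random purge instance: coordinates-first so the real metric path runs.
random_instance <- function(n_contigs, n_rows) {
  contigs <- sprintf("c%02d", seq_len(n_contigs))
  lens <- sample(200:2000, n_contigs, replace = TRUE)
  qi <- sample(n_contigs, n_rows, replace = TRUE)
  ti <- vapply(qi, function(i) sample(setdiff(seq_len(n_contigs), i), 1L),
               integer(1))
  qspan <- pmax(1L, round(stats::runif(n_rows, 0.05, 1) * lens[qi]))
  qstart <- vapply(seq_len(n_rows), function(i) {
    sample.int(lens[qi[i]] - qspan[i] + 1L, 1L) - 1L
  }, integer(1))
  tspan <- pmin(lens[ti], pmax(1L, round(stats::runif(n_rows, 0.05, 1) *
                                           lens[ti])))
  tstart <- vapply(seq_len(n_rows), function(i) {
    sample.int(lens[ti[i]] - tspan[i] + 1L, 1L) - 1L
  }, integer(1))
  block <- qspan
  matches <- pmax(0L, round(stats::runif(n_rows, 0.2, 1) * block))
  raw <- raw_alignments(
    query_name = contigs[qi], query_length = lens[qi],
    query_start = qstart, query_end = qstart + qspan,
    target_name = contigs[ti], target_length = lens[ti],
    target_start = tstart, target_end = tstart + tspan,
    matches = matches, mismatches = block - matches
  )
  list(table = suppressWarnings(compute_metrics(raw)), contigs = contigs)
}

# Random BUSCO catalog over a small gene universe.
random_catalog <- function(n_contigs = 5, n_genes = 12) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  contigs <- sprintf("c%02d", seq_len(n_contigs))
  records <- lapply(contigs, function(ctg) {
    comp <- genes[stats::runif(n_genes) < 0.3]
    frag <- setdiff(genes[stats::runif(n_genes) < 0.15], comp)
    contig_busco(ctg, comp, frag)
  })
  busco_catalog(records, n_genes)
}

# A scored candidate with arbitrary retained set and cost, for store tests.
fake_candidate <- function(retained, cost, universe = letters[1:8]) {
  structure(list(retained = retained,
                 purged = setdiff(universe, retained),
                 counts = structure(c(M = 0L, D = 0L, F = 0L, S = 1L),
                                    class = "busco_counts"),
                 cost = cost, thresholds = purge_thresholds()),
            class = "candidate_assembly")
}

# One hand-checkable PSL data row (21 columns).
psl_row <- function(matches = 950, mismatches = 50, rep_matches = 0,
                    qname = "ctgB", qsize = 1000, qstart = 0, qend = 1000,
                    tname = "ctgA", tsize = 1200, tstart = 0, tend = 1000) {
  paste(matches, mismatches, rep_matches, 0, 0, 0, 0, 0, "+",
        qname, qsize, qstart, qend, tname, tsize, tstart, tend,
        1, paste0(qend - qstart, ","), paste0(qstart, ","),
        paste0(tstart, ","), sep = "\t")
}

psl_header <- function() {
  c("psLayout version 3", "",
    paste("match\tmis-\trep.\tN's\tQ gap\tQ gap\tT gap\tT gap\tstrand\tQ",
          "\tQ\tQ\tQ\tT\tT\tT\tT\tblock\tblockSizes\tqStarts\ttStarts"),
    paste("\tmatch\tmatch\t\tcount\tbases\tcount\tbases\t\tname",
          "\tsize\tstart\tend\tname\tsize\tstart\tend\tcount"),
    strrep("-", 80))
}
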
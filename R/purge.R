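# Applying one threshold triple: purge, score, cost.

#' Purge thresholds
#'
#' A point (ID_T, Q_T, QR_T) in the threshold search space. The derived
#' QR'_T = exp(-log2(QR_T)) is computed on construction; together QR_T and
#' QR'_T bound the symmetric QR acceptance window (see [qr_window()]).
#'
#' @param id ID threshold, in (0, 1].
#' @param q Q threshold, in (0, 1].
#' @param qr QR threshold, positive.
#' @return A `purge_thresholds` list with fields `id`, `q`, `qr`,
#'   `qr_prime`.
#' @export
purge_thresholds <- function(id = 0.7, q = 0.7, qr = 0.7) {
  stopifnot(length(id) == 1, length(q) == 1, length(qr) == 1)
  if (!is.finite(qr) || qr <= 0) {
    stop("QR threshold must be positive", call. = FALSE)
  }
  if (id <= 0 || id > 1 || q <= 0 || q > 1) {
    stop("ID and Q thresholds must lie in (0, 1]", call. = FALSE)
  }
  structure(list(id = id, q = q, qr = qr, qr_prime = exp(-log2(qr))),
            class = "purge_thresholds")
}

#' QR acceptance window
#'
#' The purge condition on QR is symmetric: a row passes when its QR falls
#' inside `[min(QR_T, QR'_T), max(QR_T, QR'_T)]`, inclusive at both ends.
#'
#' @param thresholds A [purge_thresholds()] object.
#' @return Numeric `c(lo, hi)`.
#' @export
#' @examples
#' qr_window(purge_thresholds(qr = 0.70))  # ~ [0.70, 1.673]
qr_window <- function(thresholds) {
  c(min(thresholds$qr, thresholds$qr_prime),
    max(thresholds$qr, thresholds$qr_prime))
}

#' Apply thresholds to an alignment table
#'
#' A query contig is purged when at least one of its alignment rows
#' satisfies all three conditions: `ID >= ID_T`, `Q >= Q_T`, and QR inside
#' the symmetric window of [qr_window()]. Purging is single-pass: a purged
#' contig still serves as the reference of other rows, and no re-purging
#' iteration is performed.
#'
#' @param table An `alignment_table`, normally already restricted by
#'   [filter_eligible()].
#' @param thresholds A [purge_thresholds()] object.
#' @param all_contigs Character vector of every contig in the assembly
#'   (purge candidates and references alike).
#' @return A `candidate_assembly` with `retained`, `purged` and
#'   `thresholds` set; BUSCO counts and cost are filled in by
#'   [score_candidate()].
#' @export
candidate_assembly <- function(table, thresholds, all_contigs) {
  all_contigs <- as.character(all_contigs)
  used <- unique(c(table$query_name, table$target_name))
  missing <- setdiff(used, all_contigs)
  if (length(missing)) {
    stop("alignment table names contig(s) absent from all_contigs: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  win <- qr_window(thresholds)
  pass <- table$ID >= thresholds$id & table$Q >= thresholds$q &
    table$QR >= win[1] & table$QR <= win[2]
  purged <- unique(table$query_name[pass])
  structure(list(retained = setdiff(all_contigs, purged),
                 purged = purged,
                 counts = NULL, cost = NULL,
                 thresholds = thresholds),
            class = "candidate_assembly")
}

#' Assembly weight vector for the BUSCO cost
#'
#' Defaults follow the convention of weighting Missing, Duplicated and
#' Single-copy genes at 1 and ignoring Fragmented genes.
#'
#' @param m,d,f,s Weights in \[0, 1\] for Missing, Duplicated, Fragmented
#'   and Single-copy counts; `s` must be positive (it is the denominator
#'   scale).
#' @return A `busco_weights` named numeric vector.
#' @export
busco_weights <- function(m = 1, d = 1, f = 0, s = 1) {
  w <- c(m = m, d = d, f = f, s = s)
  if (any(w < 0 | w > 1)) {
    stop("weights must lie in [0, 1]", call. = FALSE)
  }
  if (s <= 0) {
    stop("the single-copy weight must be positive", call. = FALSE)
  }
  structure(w, class = "busco_weights")
}

#' BUSCO cost of a candidate assembly
#'
#' `Cost = (m*M + d*D + f*F) / (s*S)`. A candidate with no single-copy
#' genes is assigned infinite cost rather than an error, so the optimizer
#' can traverse degenerate regions of the threshold space.
#'
#' @param counts A `busco_counts` vector from [aggregate_counts()].
#' @param weights A [busco_weights()] vector.
#' @return A non-negative number, `Inf` when `S = 0`.
#' @export
#' @examples
#' busco_cost(c(M = 10, D = 5, F = 3, S = 100), busco_weights())
busco_cost <- function(counts, weights = busco_weights()) {
  if (weights[["s"]] <= 0) {
    stop("the single-copy weight must be positive", call. = FALSE)
  }
  if (counts[["S"]] == 0) {
    return(Inf)
  }
  (weights[["m"]] * counts[["M"]] + weights[["d"]] * counts[["D"]] +
     weights[["f"]] * counts[["F"]]) / (weights[["s"]] * counts[["S"]])
}

#' Score a candidate assembly
#'
#' Fills in the BUSCO counts of the retained contig set and the resulting
#' cost.
#'
#' @param candidate A `candidate_assembly` from [candidate_assembly()].
#' @param catalog A `busco_catalog`.
#' @param weights A [busco_weights()] vector.
#' @return The completed `candidate_assembly`.
#' @export
score_candidate <- function(candidate, catalog, weights = busco_weights()) {
  candidate$counts <- aggregate_counts(catalog, candidate$retained)
  candidate$cost <- busco_cost(candidate$counts, weights)
  candidate
}

#' Write a purge report
#'
#' Two-column TSV labelling every contig `primary` (retained) or
#' `secondary` (purged).
#'
#' @param candidate A `candidate_assembly`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_purge_report <- function(candidate, path) {
  contigs <- c(candidate$retained, candidate$purged)
  status <- rep(c("primary", "secondary"),
                c(length(candidate$retained), length(candidate$purged)))
  ord <- order(contigs)
  writeLines(c("contig\tstatus",
               paste(contigs[ord], status[ord], sep = "\t")), path)
  invisible(path)
}

#' @export
print.candidate_assembly <- function(x, ...) {
  cat("Candidate primary assembly\n")
  cat("  retained:", length(x$retained), "contig(s); purged:",
      length(x$purged), "\n")
  if (!is.null(x$thresholds)) {
    cat(sprintf("  thresholds: ID >= %.4f, Q >= %.4f, QR in [%.4f, %.4f]\n",
                x$thresholds$id, x$thresholds$q,
                qr_window(x$thresholds)[1], qr_window(x$thresholds)[2]))
  }
  if (!is.null(x$counts)) {
    cat(sprintf("  BUSCO: M=%d D=%d F=%d S=%d; cost = %.4g\n",
                as.integer(x$counts[["M"]]), as.integer(x$counts[["D"]]),
                as.integer(x$counts[["F"]]), as.integer(x$counts[["S"]]),
                x$cost))
  }
  invisible(x)
}
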
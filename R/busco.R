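# Per-contig BUSCO tables and candidate-assembly completeness counts.

#' Per-contig BUSCO record
#'
#' @param contig Contig name.
#' @param complete_ids Character vector of BUSCO gene ids reported Complete
#'   (or Duplicated) on this contig.
#' @param fragmented_ids Character vector of BUSCO gene ids reported
#'   Fragmented on this contig. Ids also present in `complete_ids` are
#'   dropped: complete evidence on a contig dominates.
#' @return A `contig_busco` list with fields `contig`, `complete_ids`,
#'   `fragmented_ids`.
#' @export
contig_busco <- function(contig, complete_ids = character(),
                         fragmented_ids = character()) {
  complete_ids <- unique(as.character(complete_ids))
  fragmented_ids <- setdiff(unique(as.character(fragmented_ids)),
                            complete_ids)
  structure(list(contig = as.character(contig),
                 complete_ids = complete_ids,
                 fragmented_ids = fragmented_ids),
            class = "contig_busco")
}

#' Parse one BUSCO v3 full_table file
#'
#' Reads the tab-separated `full_table_*.tsv` that BUSCO v3 writes per run,
#' here one run per contig. Genes with status `Complete` or `Duplicated` are
#' recorded as complete on the contig (duplication within a single contig is
#' still a complete gene there); `Fragmented` genes are recorded as
#' fragmented unless the same gene is also complete on the contig;
#' `Missing` genes are ignored.
#'
#' @param path Path to the full_table TSV (`#` comment lines allowed).
#' @param contig Contig name; default derives it from the file's directory
#'   (stripping a `run_` prefix) or, failing that, the file name.
#' @return A [contig_busco()] record.
#' @export
parse_busco_full_table <- function(path, contig = NULL) {
  if (is.null(contig)) {
    dir_name <- basename(dirname(path))
    contig <- if (grepl("^run_", dir_name)) {
      sub("^run_", "", dir_name)
    } else {
      sub("^full_table_?", "",
          tools::file_path_sans_ext(basename(path)))
    }
  }
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  complete <- character()
  fragmented <- character()
  if (any(keep)) {
    lineno <- which(keep)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    ids <- vapply(fields, `[`, character(1), 1L)
    status <- vapply(fields, `[`, character(1), 2L)
    ok <- status %in% c("Complete", "Duplicated", "Fragmented", "Missing")
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop("unknown BUSCO status '", status[i], "' at line ", lineno[i],
           " of ", path, call. = FALSE)
    }
    complete <- ids[status %in% c("Complete", "Duplicated")]
    fragmented <- ids[status == "Fragmented"]
  }
  contig_busco(contig, complete, fragmented)
}

#' Build a BUSCO catalog
#'
#' @param records A list of [contig_busco()] records.
#' @param universe_size Total number of BUSCO genes in the lineage set. This
#'   must be supplied by the user: genes missing from every contig leave no
#'   trace in the per-contig tables.
#' @return A `busco_catalog` with fields `records` (named by contig) and
#'   `universe_size`.
#' @export
busco_catalog <- function(records, universe_size) {
  stopifnot(length(universe_size) == 1, universe_size >= 0)
  names(records) <- vapply(records, `[[`, character(1), "contig")
  seen <- unique(unlist(lapply(records, function(r) {
    c(r$complete_ids, r$fragmented_ids)
  })))
  if (length(seen) > universe_size) {
    stop("universe_size (", universe_size, ") is smaller than the ",
         length(seen), " distinct BUSCO genes observed", call. = FALSE)
  }
  structure(list(records = records, universe_size = as.integer(universe_size)),
            class = "busco_catalog")
}

#' Load per-contig BUSCO results from a directory tree
#'
#' Searches `dir` recursively for files matching `full_table*` (the BUSCO v3
#' per-run output); each file contributes one contig, identified from its
#' `run_<contig>` directory or its file name.
#'
#' @param dir Directory containing one BUSCO run per contig.
#' @inheritParams busco_catalog
#' @return A `busco_catalog`.
#' @export
load_busco_dir <- function(dir, universe_size) {
  paths <- list.files(dir, pattern = "^full_table.*\\.(tsv|txt)$",
                      recursive = TRUE, full.names = TRUE)
  busco_catalog(lapply(sort(paths), parse_busco_full_table), universe_size)
}

#' Load a merged per-contig BUSCO table
#'
#' Reads a single TSV with columns `busco_id`, `status`, `contig`
#' (header optional, `#` comments allowed) — the concatenated form of the
#' per-contig full tables.
#'
#' @param path Path to the merged TSV.
#' @inheritParams busco_catalog
#' @return A `busco_catalog`.
#' @export
load_busco_table <- function(path, universe_size) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lines <- lines[keep]
  if (length(lines) && grepl("^busco_id\t", lines[1])) {
    lines <- lines[-1]
  }
  records <- list()
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 3L)) {
      stop("merged BUSCO table needs 3 columns: busco_id, status, contig",
           call. = FALSE)
    }
    ids <- vapply(fields, `[`, character(1), 1L)
    status <- vapply(fields, `[`, character(1), 2L)
    ctg <- vapply(fields, `[`, character(1), 3L)
    ok <- status %in% c("Complete", "Duplicated", "Fragmented", "Missing")
    if (!all(ok)) {
      stop("unknown BUSCO status '", status[which(!ok)[1]], "' in ", path,
           call. = FALSE)
    }
    records <- lapply(split(seq_along(ids), ctg), function(i) {
      contig_busco(ctg[i[1]],
                   ids[i][status[i] %in% c("Complete", "Duplicated")],
                   ids[i][status[i] == "Fragmented"])
    })
  }
  busco_catalog(unname(records), universe_size)
}

#' Write a catalog as a merged BUSCO TSV
#'
#' @param catalog A `busco_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_busco_table <- function(catalog, path) {
  rows <- unlist(lapply(catalog$records, function(r) {
    c(if (length(r$complete_ids))
        paste(r$complete_ids, "Complete", r$contig, sep = "\t"),
      if (length(r$fragmented_ids))
        paste(r$fragmented_ids, "Fragmented", r$contig, sep = "\t"))
  }), use.names = FALSE)
  writeLines(c("busco_id\tstatus\tcontig", rows), path)
  invisible(path)
}

#' Aggregate BUSCO counts over a retained contig set
#'
#' Classifies every gene of the lineage set against the retained contigs:
#' a gene complete on exactly one retained contig is Single-copy (S), on two
#' or more Duplicated (D); a gene never complete but fragmented on at least
#' one retained contig is Fragmented (F); the remainder of the universe is
#' Missing (M). Complete evidence dominates fragmented evidence across
#' contigs.
#'
#' @param catalog A `busco_catalog`.
#' @param retained Character vector of retained contig names (names absent
#'   from the catalog contribute empty sets).
#' @return A `busco_counts` named integer vector with elements
#'   `M`, `D`, `F`, `S`; these always sum to `universe_size`.
#' @export
#' @examples
#' cat <- busco_catalog(list(
#'   contig_busco("A", c("g1", "g2")),
#'   contig_busco("B", "g2", "g3")
#' ), universe_size = 5)
#' aggregate_counts(cat, c("A", "B"))
aggregate_counts <- function(catalog, retained) {
  recs <- catalog$records[intersect(retained, names(catalog$records))]
  comp <- unlist(lapply(recs, `[[`, "complete_ids"), use.names = FALSE)
  frag <- unlist(lapply(recs, `[[`, "fragmented_ids"), use.names = FALSE)
  cc <- table(comp)
  s <- sum(cc == 1L)
  d <- sum(cc >= 2L)
  f <- length(setdiff(unique(frag), names(cc)))
  m <- catalog$universe_size - s - d - f
  structure(c(M = m, D = d, F = f, S = s), class = "busco_counts")
}

# Dense gene-by-contig incidence used by the optimizer's inner loop; one
# row per gene observed anywhere, columns ordered as `contigs`.
busco_incidence <- function(catalog, contigs) {
  genes <- sort(unique(unlist(lapply(catalog$records, function(r) {
    c(r$complete_ids, r$fragmented_ids)
  }), use.names = FALSE)))
  cmat <- matrix(0, nrow = length(genes), ncol = length(contigs),
                 dimnames = list(genes, contigs))
  fmat <- cmat
  for (r in catalog$records) {
    j <- match(r$contig, contigs)
    if (is.na(j)) next
    cmat[match(r$complete_ids, genes), j] <- 1
    fmat[match(r$fragmented_ids, genes), j] <- 1
  }
  list(complete = cmat, fragmented = fmat,
       universe_size = catalog$universe_size)
}

# Fast path equivalent of aggregate_counts(); `ret` is a 0/1 numeric vector
# over the incidence's contig columns.
counts_from_incidence <- function(inc, ret) {
  cc <- drop(inc$complete %*% ret)
  ff <- drop(inc$fragmented %*% ret)
  s <- sum(cc == 1)
  d <- sum(cc >= 2)
  f <- sum(cc == 0 & ff >= 1)
  c(M = inc$universe_size - s - d - f, D = d, F = f, S = s)
}
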
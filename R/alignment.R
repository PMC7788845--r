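# Pairwise contig alignment input (PSL/PAF) and per-alignment metrics.

RAW_ALIGNMENT_COLS <- c(
  "query_name", "query_length", "query_start", "query_end",
  "target_name", "target_length", "target_start", "target_end",
  "matches", "mismatches", "rep_matches", "block_length"
)

#' Construct a raw-alignment table
#'
#' Builds the canonical raw-alignment data frame used by [compute_metrics()].
#' Coordinates are 0-based, half-open for both the query and the target span
#' (the native convention of both PSL and PAF).
#'
#' @param query_name,target_name Character vectors of contig names.
#' @param query_length,target_length Contig lengths in bases.
#' @param query_start,query_end,target_start,target_end Aligned span
#'   coordinates (0-based, half-open).
#' @param matches Matching bases in the alignment.
#' @param mismatches Mismatching bases.
#' @param rep_matches Matches in repeat-masked sequence (PSL only; 0 for PAF).
#' @param block_length Total alignment block length in bases.
#'
#' @return A `data.frame` with one row per alignment, class
#'   `"raw_alignments"`.
#' @export
raw_alignments <- function(query_name, query_length, query_start, query_end,
                           target_name, target_length, target_start,
                           target_end, matches, mismatches,
                           rep_matches = 0L, block_length = NULL) {
  if (is.null(block_length)) {
    block_length <- matches + mismatches + rep_matches
  }
  df <- data.frame(
    query_name = as.character(query_name),
    query_length = as.numeric(query_length),
    query_start = as.numeric(query_start),
    query_end = as.numeric(query_end),
    target_name = as.character(target_name),
    target_length = as.numeric(target_length),
    target_start = as.numeric(target_start),
    target_end = as.numeric(target_end),
    matches = as.numeric(matches),
    mismatches = as.numeric(mismatches),
    rep_matches = rep(as.numeric(rep_matches), length.out = length(matches)),
    block_length = as.numeric(block_length),
    stringsAsFactors = FALSE
  )
  validate_raw_alignments(df)
  class(df) <- c("raw_alignments", "data.frame")
  df
}

validate_raw_alignments <- function(df, lines = NULL) {
  where <- function(i) {
    if (is.null(lines)) paste0("row ", i) else paste0("line ", lines[i])
  }
  bad <- which(df$query_start < 0 | df$target_start < 0)
  if (length(bad)) {
    stop("negative alignment coordinate at ", where(bad[1]), call. = FALSE)
  }
  bad <- which(!(df$query_start < df$query_end &
                   df$query_end <= df$query_length))
  if (length(bad)) {
    stop("invalid query span at ", where(bad[1]),
         " (need 0 <= start < end <= length)", call. = FALSE)
  }
  bad <- which(!(df$target_start < df$target_end &
                   df$target_end <= df$target_length))
  if (length(bad)) {
    stop("invalid target span at ", where(bad[1]),
         " (need 0 <= start < end <= length)", call. = FALSE)
  }
  invisible(df)
}

open_maybe_gz <- function(path, gzipped = NULL) {
  if (is.null(gzipped)) {
    gzipped <- grepl("\\.gz$", path, ignore.case = TRUE)
  }
  # gzfile() also reads plain text transparently, but keep the intent explicit
  if (gzipped) gzfile(path, "rt") else file(path, "rt")
}

#' Parse a BLAT PSL alignment file
#'
#' Reads 21-column PSL output (plain or gzip-compressed). The optional
#' 5-line `psLayout` header is detected and skipped. Coordinates are kept
#' verbatim (PSL is already 0-based, half-open). The alignment block length
#' is reconstituted as `matches + mismatches + rep_matches`.
#'
#' @param path Path to the PSL file.
#' @param gzipped Force gzip decompression; default `NULL` auto-detects from
#'   a `.gz` suffix.
#'
#' @return A `raw_alignments` data frame (possibly 0 rows).
#' @export
#' @seealso [parse_paf()], [compute_metrics()]
parse_psl <- function(path, gzipped = NULL) {
  con <- open_maybe_gz(path, gzipped)
  on.exit(close(con))
  lines <- readLines(con)
  first_data <- 1L
  if (length(lines) && startsWith(lines[1], "psLayout")) {
    first_data <- 6L  # version line, blank, two header rows, dash rule
  }
  keep <- seq_along(lines) >= first_data & nzchar(trimws(lines))
  if (!any(keep)) {
    return(empty_raw_alignments())
  }
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 21L)) {
    i <- which(nf != 21L)[1]
    stop("PSL line ", lineno[i], ": expected 21 columns, found ", nf[i],
         call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 21L, byrow = TRUE)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop("PSL line ", lineno[i], ": non-numeric ", what, " field",
           call. = FALSE)
    }
    v
  }
  df <- data.frame(
    query_name = m[, 10], query_length = num(11, "qSize"),
    query_start = num(12, "qStart"), query_end = num(13, "qEnd"),
    target_name = m[, 14], target_length = num(15, "tSize"),
    target_start = num(16, "tStart"), target_end = num(17, "tEnd"),
    matches = num(1, "matches"), mismatches = num(2, "misMatches"),
    rep_matches = num(3, "repMatches"),
    stringsAsFactors = FALSE
  )
  df$block_length <- df$matches + df$mismatches + df$rep_matches
  validate_raw_alignments(df, lines = lineno)
  class(df) <- c("raw_alignments", "data.frame")
  df
}

#' Parse a minimap2 PAF alignment file
#'
#' Reads the 12 mandatory PAF columns (plain or gzip-compressed); trailing
#' SAM-style tags are ignored. Residue matches come from column 10 and the
#' alignment block length from column 11; with no separate mismatch count in
#' PAF, mismatches are taken as `block_length - matches`, which folds indel
#' and substitution error together.
#'
#' @inheritParams parse_psl
#' @return A `raw_alignments` data frame (possibly 0 rows).
#' @export
parse_paf <- function(path, gzipped = NULL) {
  con <- open_maybe_gz(path, gzipped)
  on.exit(close(con))
  lines <- readLines(con)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    return(empty_raw_alignments())
  }
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    i <- which(nf < 12L)[1]
    stop("PAF line ", lineno[i], ": expected at least 12 columns, found ",
         nf[i], call. = FALSE)
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12L)))
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop("PAF line ", lineno[i], ": non-integer ", what, " field",
           call. = FALSE)
    }
    v
  }
  df <- data.frame(
    query_name = m[, 1], query_length = num(2, "query length"),
    query_start = num(3, "query start"), query_end = num(4, "query end"),
    target_name = m[, 6], target_length = num(7, "target length"),
    target_start = num(8, "target start"), target_end = num(9, "target end"),
    matches = num(10, "residue matches"),
    stringsAsFactors = FALSE
  )
  df$block_length <- num(11, "block length")
  df$mismatches <- df$block_length - df$matches
  df$rep_matches <- 0
  df <- df[, RAW_ALIGNMENT_COLS]
  validate_raw_alignments(df, lines = lineno)
  class(df) <- c("raw_alignments", "data.frame")
  df
}

#' Parse an alignment file, auto-detecting PSL vs PAF
#'
#' @param path Path to a `.psl`, `.paf`, `.psl.gz` or `.paf.gz` file.
#' @param format `"auto"` (by file extension), `"psl"` or `"paf"`.
#' @inheritParams parse_psl
#' @return A `raw_alignments` data frame.
#' @export
parse_alignments <- function(path, format = c("auto", "psl", "paf"),
                             gzipped = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", basename(path), ignore.case = TRUE)
    ext <- tolower(tools::file_ext(base))
    format <- switch(ext, psl = "psl", paf = "paf",
                     stop("cannot infer alignment format from '", path,
                          "'; pass format = \"psl\" or \"paf\"",
                          call. = FALSE))
  }
  switch(format, psl = parse_psl(path, gzipped), paf = parse_paf(path, gzipped))
}

empty_raw_alignments <- function() {
  df <- as.data.frame(
    setNames(rep(list(character(0)), length(RAW_ALIGNMENT_COLS)),
             RAW_ALIGNMENT_COLS),
    stringsAsFactors = FALSE
  )
  for (col in setdiff(RAW_ALIGNMENT_COLS, c("query_name", "target_name"))) {
    df[[col]] <- numeric(0)
  }
  class(df) <- c("raw_alignments", "data.frame")
  df
}

#' Compute per-alignment purge metrics
#'
#' Derives, for every aligned contig pair, the four metrics that drive
#' haplotig purging:
#' \describe{
#'   \item{ID}{nucleotide identity,
#'     `matches / (matches + mismatches + rep_matches)`;}
#'   \item{Q}{the aligned fraction of the query contig;}
#'   \item{R}{the aligned fraction of the reference (target) contig;}
#'   \item{QR}{the ratio `Q / R`, sensitive to clipped alignments and
#'     structural differences between the two contigs;}
#'   \item{QR_prime}{the symmetric transform `exp(-log2(QR))`, so that QR
#'     and 1/QR map to reciprocal values and QR = 1 maps to 1.}
#' }
#' Self-alignments (query == target) are dropped, as are degenerate records
#' with an empty reference span or a zero metric denominator (with a
#' warning).
#'
#' @param raw A `raw_alignments` data frame from [parse_psl()],
#'   [parse_paf()] or [raw_alignments()].
#'
#' @return An `alignment_table`: a data frame with the raw columns plus
#'   `ID`, `Q`, `R`, `QR`, `QR_prime`, and a `contig_lengths` attribute
#'   (named vector over every contig seen).
#' @export
#' @examples
#' raw <- raw_alignments("ctgB", 1000, 0, 1000, "ctgA", 1200, 0, 1000,
#'                       matches = 950, mismatches = 50)
#' tab <- compute_metrics(raw)
#' tab[, c("ID", "Q", "R", "QR")]
compute_metrics <- function(raw) {
  df <- as.data.frame(raw, stringsAsFactors = FALSE)
  lens <- contig_lengths_from_raw(df)
  self <- df$query_name == df$target_name
  if (any(self)) df <- df[!self, , drop = FALSE]
  denom <- df$matches + df$mismatches + df$rep_matches
  r_span <- df$target_end - df$target_start
  bad <- denom <= 0 | r_span <= 0
  if (any(bad)) {
    warning(sum(bad), " degenerate alignment record(s) dropped",
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  df$ID <- df$matches / (df$matches + df$mismatches + df$rep_matches)
  df$Q <- (df$query_end - df$query_start) / df$query_length
  df$R <- (df$target_end - df$target_start) / df$target_length
  df$QR <- df$Q / df$R
  df$QR_prime <- exp(-log2(df$QR))
  rownames(df) <- NULL
  structure(df, contig_lengths = lens,
            class = c("alignment_table", "data.frame"))
}

contig_lengths_from_raw <- function(df) {
  nm <- c(df$query_name, df$target_name)
  ln <- c(df$query_length, df$target_length)
  keep <- !duplicated(nm)
  setNames(ln[keep], nm[keep])
}

#' Restrict an alignment table to purge-eligible rows
#'
#' Long contigs are unlikely to be alternative haplotigs, so rows whose
#' query exceeds `max_query_length` (default 10 Mb) are removed. With
#' `require_query_not_longer` (the default) a query must not be longer than
#' its reference; for equal-length pairs only the row whose query name sorts
#' lexicographically later is kept, so exactly one member of a reciprocal
#' pair stays purge-eligible.
#'
#' @param table An `alignment_table` from [compute_metrics()].
#' @param max_query_length Maximum query contig length in bases.
#' @param require_query_not_longer Drop rows where the query is longer than
#'   the target (ties broken by name as described).
#'
#' @return The filtered `alignment_table` (attributes preserved).
#' @export
filter_eligible <- function(table, max_query_length = 1e7,
                            require_query_not_longer = TRUE) {
  keep <- table$query_length <= max_query_length
  if (require_query_not_longer) {
    keep <- keep & (table$query_length < table$target_length |
                      (table$query_length == table$target_length &
                         table$query_name > table$target_name))
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, contig_lengths = attr(table, "contig_lengths"),
            class = class(table))
}

#' Write an alignment metrics table as TSV
#'
#' @param table An `alignment_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(table, path) {
  cols <- c("query_name", "target_name", "ID", "Q", "R", "QR", "QR_prime")
  utils::write.table(as.data.frame(table)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise raw alignments as a valid PSL file
#'
#' Writes a headerless 21-column PSL representation of `raw`; columns not
#' represented in the raw table (inserts, block structure) are emitted as a
#' single gapless block on the + strand. Round-trips through [parse_psl()].
#'
#' @param raw A `raw_alignments` data frame.
#' @param path Output path (a `.gz` suffix triggers gzip compression).
#' @return `path`, invisibly.
#' @export
write_psl <- function(raw, path) {
  df <- as.data.frame(raw, stringsAsFactors = FALSE)
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- paste(
    fmt(df$matches), fmt(df$mismatches), fmt(df$rep_matches), 0L,
    0L, 0L, 0L, 0L, "+",
    df$query_name, fmt(df$query_length), fmt(df$query_start),
    fmt(df$query_end),
    df$target_name, fmt(df$target_length), fmt(df$target_start),
    fmt(df$target_end),
    1L, paste0(fmt(df$query_end - df$query_start), ","),
    paste0(fmt(df$query_start), ","), paste0(fmt(df$target_start), ","),
    sep = "\t"
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
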
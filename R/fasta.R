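# Contig FASTA handling and assembly summary statistics.

#' Read a contig FASTA
#'
#' Contig identity is the header token before the first whitespace;
#' sequences are upper-cased on read. Duplicate names are an error; empty
#' sequences draw a warning.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig.
#' @export
read_contigs <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  names(set) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(set))) {
    dup <- names(set)[duplicated(names(set))][1]
    stop("duplicate contig name in ", path, ": ", dup, call. = FALSE)
  }
  if (any(Biostrings::width(set) == 0)) {
    warning("empty sequence(s) in ", path, call. = FALSE)
  }
  Biostrings::DNAStringSet(toupper(as.character(set)))
}

#' Write contigs to FASTA
#'
#' @param contigs A `DNAStringSet` (or named character vector of
#'   sequences).
#' @param names Which contigs to write, in this order; default all.
#' @param path Output path. Sequence lines are wrapped at 80 columns.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, names = NULL, path) {
  if (is.character(contigs)) {
    contigs <- Biostrings::DNAStringSet(contigs)
  }
  if (is.null(names)) {
    names <- base::names(contigs)
  }
  missing <- setdiff(names, base::names(contigs))
  if (length(missing)) {
    stop("contig(s) not in set: ", paste(utils::head(missing, 3),
                                         collapse = ", "), call. = FALSE)
  }
  Biostrings::writeXStringSet(contigs[names], path, width = 80L)
  invisible(path)
}

#' Order contig names by decreasing length
#'
#' Ties are broken lexicographically by name, so the ordering is total and
#' reproducible.
#'
#' @param contigs A `DNAStringSet`, or a named numeric vector of lengths.
#' @return Character vector of contig names, longest first.
#' @export
size_sort <- function(contigs) {
  lens <- contig_length_vector(contigs)
  names(lens)[order(-lens, names(lens), method = "radix")]
}

contig_length_vector <- function(contigs) {
  if (is.numeric(contigs)) {
    contigs
  } else {
    stats::setNames(Biostrings::width(contigs), names(contigs))
  }
}

#' Split an assembly into one FASTA per contig
#'
#' File names are the contig names with characters outside
#' `[A-Za-z0-9._-]` replaced by `_`; a collision after sanitising is an
#' error.
#'
#' @param contigs A `DNAStringSet`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
split_contigs <- function(contigs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (length(contigs) == 0L) {
    return(invisible(character(0)))
  }
  safe <- gsub("[^A-Za-z0-9._-]", "_", names(contigs))
  if (anyDuplicated(safe)) {
    stop("contig names collide after sanitising: ",
         safe[duplicated(safe)][1], call. = FALSE)
  }
  paths <- file.path(out_dir, paste0(safe, ".fasta"))
  for (i in seq_along(contigs)) {
    Biostrings::writeXStringSet(contigs[i], paths[i], width = 80L)
  }
  invisible(paths)
}

#' Assembly summary statistics
#'
#' N50 is the length of the contig at which the cumulative sum of
#' descending-sorted lengths first reaches at least half the total assembly
#' length; L50 is that contig's 1-based rank.
#'
#' @param lengths A numeric vector of contig lengths (all positive), or a
#'   `DNAStringSet`.
#' @return A one-row data frame with `n_contigs`, `total_length`,
#'   `largest`, `N50`, `L50`.
#' @export
#' @examples
#' assembly_stats(c(10, 5, 3, 2))  # N50 = 10, L50 = 1
assembly_stats <- function(lengths) {
  lengths <- unname(contig_length_vector(lengths))
  if (length(lengths) == 0L) {
    stop("cannot compute assembly statistics of an empty contig set",
         call. = FALSE)
  }
  if (any(lengths <= 0)) {
    stop("contig lengths must be positive", call. = FALSE)
  }
  sorted <- sort(lengths, decreasing = TRUE)
  csum <- cumsum(sorted)
  l50 <- which(csum >= csum[length(csum)] / 2)[1]
  data.frame(n_contigs = length(lengths),
             total_length = sum(lengths),
             largest = sorted[1],
             N50 = sorted[l50],
             L50 = l50)
}

#' Write assembly statistics as TSV
#'
#' @param stats A data frame from [assembly_stats()] (rows may be labelled
#'   via an `assembly` column added by the caller).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
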
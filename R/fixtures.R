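# Synthetic diploid-like assemblies with planted alternative haplotigs,
# matching alignment tables and BUSCO catalogs, and ground-truth labels.
# Everything downstream of the aligner and of BUSCO is emulated exactly:
# substitution-only divergence keeps alignment identity analytically exact,
# so no external aligner is needed to produce a consistent test world.

#' Specification of a synthetic fixture assembly
#'
#' @param n_primary Number of primary contigs.
#' @param primary_length_range Length range (bases) primaries are drawn
#'   from, uniformly.
#' @param n_haplotigs Number of planted secondary haplotigs; sources are
#'   assigned round-robin over the primaries.
#' @param divergence Per-base substitution rate applied to each haplotig
#'   copy, in \[0, 0.5); alignment identity is exactly
#'   `1 - divergence` up to rounding of the substitution count.
#' @param haplotig_span Fraction of the source contig copied into each
#'   haplotig, in (0, 1].
#' @param n_busco_genes Size of the emulated BUSCO lineage set (the
#'   universe); must be at least `n_primary * busco_per_contig`.
#' @param busco_per_contig Complete BUSCO genes planted on each primary.
#' @param decoys Add low-identity decoy alignments between unrelated
#'   primaries, exercising the negative purge path.
#' @param decoy_id,decoy_q Identity and aligned-query fraction of decoy
#'   rows; defaults sit far below any plausible purge threshold.
#' @param seed Integer seed; fixture generation is fully deterministic
#'   given the spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_primary = 8, primary_length_range = c(2000, 5000),
                         n_haplotigs = 4, divergence = 0.02,
                         haplotig_span = 0.8, n_busco_genes = 60,
                         busco_per_contig = 5, decoys = TRUE,
                         decoy_id = 0.30, decoy_q = 0.20, seed = 42L) {
  stopifnot(n_primary >= 1, n_haplotigs >= 0,
            divergence >= 0, divergence < 0.5,
            haplotig_span > 0, haplotig_span <= 1,
            busco_per_contig >= 1)
  if (n_busco_genes < n_primary * busco_per_contig) {
    stop("n_busco_genes must cover the ", n_primary * busco_per_contig,
         " genes planted on primaries", call. = FALSE)
  }
  structure(list(n_primary = as.integer(n_primary),
                 primary_length_range = primary_length_range,
                 n_haplotigs = as.integer(n_haplotigs),
                 divergence = divergence,
                 haplotig_span = haplotig_span,
                 n_busco_genes = as.integer(n_busco_genes),
                 busco_per_contig = as.integer(busco_per_contig),
                 decoys = isTRUE(decoys),
                 decoy_id = decoy_id, decoy_q = decoy_q,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic assembly with planted haplotigs
#'
#' Primary contigs are independent random nucleotide strings; each
#' haplotig copies a contiguous span of its source primary and applies
#' substitutions at the spec's divergence rate (`round(divergence *
#' span_length)` positions, each mutated to a different base). Contig
#' names are a random permutation of `ctg01..ctgNN`, so names carry no
#' information about which contigs are secondary — that lives only in the
#' returned truth labels.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `contigs` (a `DNAStringSet`), and `truth`: a list
#'   with `secondary_names`, `source_of` (named character), and `details`
#'   (a data frame with per-haplotig `span_start`, `span_length`, `n_subs`;
#'   coordinates 0-based).
#' @export
make_fixture <- function(spec) {
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed))
  set.seed(spec$seed)

  bases <- c("A", "C", "G", "T")
  n_total <- spec$n_primary + spec$n_haplotigs
  name_pool <- sprintf("ctg%02d", seq_len(n_total))
  assigned <- sample(name_pool)
  primary_names <- assigned[seq_len(spec$n_primary)]
  haplotig_names <- assigned[spec$n_primary + seq_len(spec$n_haplotigs)]

  lens <- sample(spec$primary_length_range[1]:spec$primary_length_range[2],
                 spec$n_primary, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(bases, L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- primary_names

  details <- NULL
  if (spec$n_haplotigs > 0) {
    src_idx <- rep_len(seq_len(spec$n_primary), spec$n_haplotigs)
    rows <- lapply(seq_len(spec$n_haplotigs), function(i) {
      src <- primary_names[src_idx[i]]
      src_len <- lens[src_idx[i]]
      span_len <- max(1L, round(spec$haplotig_span * src_len))
      span_start <- sample.int(src_len - span_len + 1L, 1L) - 1L
      copy <- substring(seqs[[src]], span_start + 1L, span_start + span_len)
      n_subs <- round(spec$divergence * span_len)
      if (n_subs > 0) {
        pos <- sample.int(span_len, n_subs)
        chars <- strsplit(copy, "", fixed = TRUE)[[1]]
        chars[pos] <- vapply(chars[pos], function(b) {
          sample(setdiff(bases, b), 1L)
        }, character(1))
        copy <- paste(chars, collapse = "")
      }
      seqs[[haplotig_names[i]]] <<- copy
      data.frame(haplotig = haplotig_names[i], source = src,
                 span_start = span_start, span_length = span_len,
                 n_subs = n_subs, stringsAsFactors = FALSE)
    })
    details <- do.call(rbind, rows)
  }

  contigs <- Biostrings::DNAStringSet(seqs)
  truth <- list(
    secondary_names = haplotig_names,
    primary_names = primary_names,
    source_of = if (is.null(details)) {
      stats::setNames(character(0), character(0))
    } else {
      stats::setNames(details$source, details$haplotig)
    },
    details = details
  )
  list(contigs = contigs, truth = truth)
}

#' Alignment table for a synthetic fixture
#'
#' Emits one alignment row per planted haplotig against its source, with
#' the whole haplotig aligned (`Q = 1`), the copied span as the reference
#' span, and match/mismatch counts fixed exactly by the planted
#' substitutions — so `ID = 1 - n_subs / span_length` with no aligner
#' involved. When the spec asks for decoys, one low-identity partial
#' alignment is added between each consecutive pair of primaries.
#'
#' @param fixture The list returned by [make_fixture()].
#' @param spec The [fixture_spec()] used to build it.
#' @param psl_path Optional path; when given, the raw rows are also
#'   serialised as a valid PSL file via [write_psl()].
#' @return An `alignment_table` (possibly 0 rows).
#' @export
make_alignment_table <- function(fixture, spec, psl_path = NULL) {
  lens <- stats::setNames(Biostrings::width(fixture$contigs),
                          names(fixture$contigs))
  det <- fixture$truth$details
  rows <- list()
  if (!is.null(det) && nrow(det)) {
    rows[[1]] <- data.frame(
      query_name = det$haplotig,
      query_length = as.numeric(det$span_length),
      query_start = 0, query_end = as.numeric(det$span_length),
      target_name = det$source,
      target_length = as.numeric(lens[det$source]),
      target_start = as.numeric(det$span_start),
      target_end = as.numeric(det$span_start + det$span_length),
      matches = as.numeric(det$span_length - det$n_subs),
      mismatches = as.numeric(det$n_subs),
      rep_matches = 0,
      block_length = as.numeric(det$span_length),
      stringsAsFactors = FALSE
    )
  }
  prim <- fixture$truth$primary_names
  if (spec$decoys && length(prim) >= 2) {
    q <- prim[-length(prim)]
    t <- prim[-1]
    aln <- pmax(1, round(spec$decoy_q * lens[q]))
    matches <- round(spec$decoy_id * aln)
    rows[[length(rows) + 1]] <- data.frame(
      query_name = q, query_length = as.numeric(lens[q]),
      query_start = 0, query_end = as.numeric(aln),
      target_name = t, target_length = as.numeric(lens[t]),
      target_start = 0, target_end = as.numeric(pmin(aln, lens[t])),
      matches = as.numeric(matches),
      mismatches = as.numeric(aln - matches),
      rep_matches = 0, block_length = as.numeric(aln),
      stringsAsFactors = FALSE
    )
  }
  raw <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    as.data.frame(empty_raw_alignments())
  }
  raw <- raw[, RAW_ALIGNMENT_COLS]
  class(raw) <- c("raw_alignments", "data.frame")
  if (!is.null(psl_path)) {
    write_psl(raw, psl_path)
  }
  compute_metrics(raw)
}

#' BUSCO catalog for a synthetic fixture
#'
#' Plants `busco_per_contig` distinct complete genes on each primary
#' contig, at evenly spaced intervals along it (each gene occupies the
#' middle half of its window). Each haplotig inherits, as complete, every
#' source gene whose interval overlaps the copied span — these are the
#' planted duplicated BUSCOs that purging should eliminate. The universe
#' size is the spec's `n_busco_genes`; genes beyond those planted are
#' missing from every contig.
#'
#' @inheritParams make_alignment_table
#' @return A `busco_catalog` covering every fixture contig.
#' @export
make_busco_catalog <- function(fixture, spec) {
  lens <- stats::setNames(Biostrings::width(fixture$contigs),
                          names(fixture$contigs))
  prim <- fixture$truth$primary_names
  k <- spec$busco_per_contig
  gene_ids <- sprintf("busco_g%04d", seq_len(spec$n_busco_genes))
  gene_of <- list()  # per primary: data.frame(id, start, end)
  for (i in seq_along(prim)) {
    L <- lens[[prim[i]]]
    w <- L / k
    j <- seq_len(k)
    gene_of[[prim[i]]] <- data.frame(
      id = gene_ids[(i - 1) * k + j],
      start = (j - 1) * w + 0.25 * w,
      end = (j - 1) * w + 0.75 * w,
      stringsAsFactors = FALSE
    )
  }
  records <- lapply(prim, function(p) contig_busco(p, gene_of[[p]]$id))
  det <- fixture$truth$details
  if (!is.null(det) && nrow(det)) {
    hap_records <- lapply(seq_len(nrow(det)), function(i) {
      g <- gene_of[[det$source[i]]]
      span_lo <- det$span_start[i]
      span_hi <- det$span_start[i] + det$span_length[i]
      inherited <- g$id[g$start < span_hi & g$end > span_lo]
      contig_busco(det$haplotig[i], inherited)
    })
    records <- c(records, hap_records)
  }
  busco_catalog(records, spec$n_busco_genes)
}

#' Write a complete fixture to a directory
#'
#' Emits `assembly.fasta`, `alignments.psl`, `busco_table.tsv` (merged
#' per-contig table) and `truth.tsv` (contig, role, source, span columns).
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the fixture list from [make_fixture()] with the
#'   catalog and alignment table attached.
#' @export
write_fixture_dir <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fixture <- make_fixture(spec)
  table <- make_alignment_table(fixture, spec,
                                psl_path = file.path(out_dir,
                                                     "alignments.psl"))
  catalog <- make_busco_catalog(fixture, spec)
  write_contigs(fixture$contigs, path = file.path(out_dir, "assembly.fasta"))
  write_busco_table(catalog, file.path(out_dir, "busco_table.tsv"))

  nm <- names(fixture$contigs)
  role <- ifelse(nm %in% fixture$truth$secondary_names,
                 "secondary", "primary")
  src <- fixture$truth$source_of[nm]
  truth_df <- data.frame(contig = nm, role = role,
                         source = ifelse(is.na(src), ".", src),
                         stringsAsFactors = FALSE)
  utils::write.table(truth_df, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fixture, list(table = table, catalog = catalog)))
}
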
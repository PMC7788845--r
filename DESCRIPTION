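Package: haplopurge
Title: Haplotig Purging for Diploid Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and removes secondary (alternative) haplotigs from
    diploid contig assemblies. Pairwise contig alignments (BLAT PSL or
    minimap2 PAF, optionally gzip-compressed) are summarised per aligned
    pair by identity, aligned query fraction and the query/reference
    aligned-fraction ratio; contigs whose alignments exceed user or
    optimised thresholds are purged. Candidate primary assemblies are
    scored by a weighted cost over missing, duplicated, fragmented and
    single-copy BUSCO genes, and thresholds are optimised by randomised
    hill climbing with plateau and boundary restarts, retaining the best
    unique candidates in a bounded priority queue. Includes FASTA
    utilities, assembly summary statistics (N50/L50), and a synthetic
    fixture generator with planted haplotigs and ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
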
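test_that("full_table parsing maps statuses to per-contig sets", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# BUSCO version is: 3.0.2",
               "g1\tComplete\tctgA\t1\t500\t100\t400",
               "g2\tFragmented\tctgA\t600\t700\t50\t90",
               "g3\tMissing"), path)
  rec <- parse_busco_full_table(path, contig = "ctgA")
  expect_equal(rec$contig, "ctgA")
  expect_equal(rec$complete_ids, "g1")
  expect_equal(rec$fragmented_ids, "g2")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tDuplicated\tctgA\t1\t500",
               "g1\tDuplicated\tctgA\t600\t900"), dup)
  rec <- parse_busco_full_table(dup, contig = "ctgA")
  expect_equal(rec$complete_ids, "g1")
  expect_equal(rec$fragmented_ids, character(0))

  comments <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# only", "# comments"), comments)
  rec <- parse_busco_full_table(comments, contig = "x")
  expect_equal(rec$complete_ids, character(0))
  expect_equal(rec$fragmented_ids, character(0))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("g1\tBroken", bad)
  expect_error(parse_busco_full_table(bad, "x"), "line 1")
})

test_that("a gene both complete and fragmented on one contig counts complete", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tComplete\tctgA\t1\t500",
               "g1\tFragmented\tctgA\t900\t950"), path)
  rec <- parse_busco_full_table(path, "ctgA")
  expect_equal(rec$complete_ids, "g1")
  expect_equal(rec$fragmented_ids, character(0))
})

test_that("directory loading recovers contig identity from run_ dirs", {
  root <- withr::local_tempdir()
  for (ctg in c("ctgA", "ctgB")) {
    d <- file.path(root, paste0("run_", ctg))
    dir.create(d)
    writeLines(sprintf("g_%s\tComplete\t%s\t1\t10", ctg, ctg),
               file.path(d, "full_table.tsv"))
  }
  cat <- load_busco_dir(root, universe_size = 5)
  expect_setequal(names(cat$records), c("ctgA", "ctgB"))
  expect_equal(cat$records[["ctgB"]]$complete_ids, "g_ctgB")
  expect_equal(cat$universe_size, 5L)

  empty <- withr::local_tempdir()
  expect_length(load_busco_dir(empty, 5)$records, 0L)
})

test_that("universe smaller than the observed union is rejected", {
  recs <- list(contig_busco("A", c("g1", "g2")), contig_busco("B", "g3"))
  expect_error(busco_catalog(recs, 2), "universe_size")
  expect_silent(busco_catalog(recs, 3))
})

test_that("merged table round-trips through write/load", {
  cat <- busco_catalog(list(
    contig_busco("A", c("g1", "g2"), "g4"),
    contig_busco("B", "g2", "g3")
  ), universe_size = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_busco_table(cat, path)
  back <- load_busco_table(path, 6)
  expect_setequal(names(back$records), c("A", "B"))
  expect_setequal(back$records[["A"]]$complete_ids, c("g1", "g2"))
  expect_equal(back$records[["A"]]$fragmented_ids, "g4")
  expect_equal(back$records[["B"]]$fragmented_ids, "g3")
})

test_that("aggregate_counts matches hand enumeration", {
  cat <- busco_catalog(list(
    contig_busco("A", c("g1", "g2")),
    contig_busco("B", "g2", "g3")
  ), universe_size = 5)
  # over {A,B}: g1 single, g2 duplicated, g3 fragmented, 2 missing
  expect_equal(unclass(aggregate_counts(cat, c("A", "B"))),
               c(M = 2L, D = 1L, F = 1L, S = 1L))
  expect_equal(unclass(aggregate_counts(cat, "A")),
               c(M = 3L, D = 0L, F = 0L, S = 2L))
  expect_equal(unclass(aggregate_counts(cat, character(0))),
               c(M = 5L, D = 0L, F = 0L, S = 0L))
  # names absent from the catalog contribute empty sets
  expect_equal(unclass(aggregate_counts(cat, c("A", "nope"))),
               c(M = 3L, D = 0L, F = 0L, S = 2L))
})

test_that("complete evidence dominates fragmented evidence across contigs", {
  cat <- busco_catalog(list(
    contig_busco("A", "g1"),
    contig_busco("B", character(0), "g1")
  ), universe_size = 1)
  counts <- aggregate_counts(cat, c("A", "B"))
  expect_equal(counts[["S"]], 1L)
  expect_equal(counts[["F"]], 0L)
})

test_that("count conservation and monotonicity hold on random catalogs", {
  set.seed(2024)
  for (rep in 1:60) {
    cat <- random_catalog(sample(2:6, 1), sample(6:15, 1))
    contigs <- names(cat$records)
    retained <- sample(contigs, sample(0:length(contigs), 1))
    counts <- aggregate_counts(cat, retained)
    expect_equal(sum(counts), cat$universe_size)
    expect_equal(unclass(counts), naive_counts(cat, retained))
    extra <- setdiff(contigs, retained)
    if (length(extra)) {
      grown <- aggregate_counts(cat, c(retained, sample(extra, 1)))
      expect_lte(grown[["M"]], counts[["M"]])
      expect_gte(grown[["D"]] + grown[["S"]],
                 counts[["D"]] + counts[["S"]])
    }
  }
})
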
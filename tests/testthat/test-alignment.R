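test_that("PSL parsing handles headers, gzip and hand-built rows", {
  plain <- withr::local_tempfile(fileext = ".psl")
  writeLines(psl_row(), plain)
  got <- parse_psl(plain)
  expect_equal(nrow(got), 1L)
  expect_equal(got$matches, 950)
  expect_equal(got$mismatches, 50)
  expect_equal(got$query_name, "ctgB")
  expect_equal(got$query_length, 1000)
  expect_equal(got$target_length, 1200)
  expect_equal(got$block_length, 1000)

  headed <- withr::local_tempfile(fileext = ".psl")
  writeLines(c(psl_header(), psl_row()), headed)
  expect_equal(as.data.frame(parse_psl(headed)), as.data.frame(got))

  empty <- withr::local_tempfile(fileext = ".psl")
  writeLines(psl_header(), empty)
  expect_equal(nrow(parse_psl(empty)), 0L)

  gz <- withr::local_tempfile(fileext = ".psl.gz")
  con <- gzfile(gz, "wt")
  writeLines(psl_row(), con)
  close(con)
  expect_equal(as.data.frame(parse_psl(gz)), as.data.frame(got))
  expect_equal(as.data.frame(parse_psl(gz, gzipped = TRUE)),
               as.data.frame(got))
})

test_that("PSL parse errors name the offending line", {
  bad <- withr::local_tempfile(fileext = ".psl")
  writeLines(c(psl_row(), "1\t2\t3"), bad)
  expect_error(parse_psl(bad), "line 2.*21 columns")

  neg <- withr::local_tempfile(fileext = ".psl")
  writeLines(psl_row(qstart = -5), neg)
  expect_error(parse_psl(neg), "line 1")
})

test_that("PAF parsing reads 12 columns, ignores tags, derives mismatches", {
  paf <- withr::local_tempfile(fileext = ".paf")
  writeLines(paste("ctgB", 1000, 0, 1000, "+", "ctgA", 1200, 0, 1000,
                   950, 1000, 60, sep = "\t"), paf)
  got <- parse_paf(paf)
  expect_equal(got$query_length, 1000)
  expect_equal(got$matches, 950)
  expect_equal(got$block_length, 1000)
  expect_equal(got$mismatches, 50)  # block - matches
  expect_equal(got$rep_matches, 0)
  expect_equal(got$target_length, 1200)

  tagged <- withr::local_tempfile(fileext = ".paf")
  writeLines(paste("ctgB", 1000, 0, 1000, "+", "ctgA", 1200, 0, 1000,
                   950, 1000, 60, "tp:A:P", "cg:Z:1000M", sep = "\t"),
             tagged)
  expect_equal(as.data.frame(parse_paf(tagged)), as.data.frame(got))

  empty <- withr::local_tempfile(fileext = ".paf")
  file.create(empty)
  expect_equal(nrow(parse_paf(empty)), 0L)

  short <- withr::local_tempfile(fileext = ".paf")
  writeLines("a\tb\tc", short)
  expect_error(parse_paf(short), "line 1.*12 columns")

  noint <- withr::local_tempfile(fileext = ".paf")
  writeLines(paste("ctgB", "xx", 0, 1000, "+", "ctgA", 1200, 0, 1000,
                   950, 1000, 60, sep = "\t"), noint)
  expect_error(parse_paf(noint), "non-integer")
})

test_that("format auto-detection dispatches on extension", {
  psl <- withr::local_tempfile(fileext = ".psl")
  writeLines(psl_row(), psl)
  expect_equal(parse_alignments(psl)$matches, 950)
  expect_error(parse_alignments("whatever.txt"), "cannot infer")
})

test_that("compute_metrics reproduces the metric definitions exactly", {
  raw <- raw_alignments("ctgB", 1000, 0, 1000, "ctgA", 1200, 0, 1000,
                        matches = 950, mismatches = 50)
  tab <- compute_metrics(raw)
  expect_equal(tab$ID, 0.95)
  expect_equal(tab$Q, 1.0)
  expect_equal(tab$R, 1000 / 1200)
  expect_equal(tab$QR, 1.2)
  expect_equal(tab$QR_prime, exp(-log2(1.2)))
  expect_named(attr(tab, "contig_lengths"))
  expect_equal(attr(tab, "contig_lengths")[["ctgA"]], 1200)
})

test_that("QR_prime transform fixed points and symmetry", {
  expect_equal(exp(-log2(1)), 1)
  tab <- metrics_table(c("a", "b"), c("b", "a"), ID = c(0.9, 0.9),
                       Q = c(0.5, 0.5), QR = c(2, 0.5))
  expect_equal(tab$QR_prime[1], exp(-1), tolerance = 1e-12)
  expect_equal(tab$QR_prime[1] * tab$QR_prime[2], 1, tolerance = 1e-12)
})

test_that("metric invariants hold on random alignment tables", {
  set.seed(101)
  for (rep in 1:20) {
    inst <- random_instance(sample(3:8, 1), sample(5:30, 1))
    tab <- inst$table
    expect_true(all(abs(tab$QR * tab$R / tab$Q - 1) < 1e-12))
    expect_true(all(tab$QR_prime[order(tab$QR)] ==
                      sort(tab$QR_prime, decreasing = TRUE)))
    expect_false(any(tab$query_name == tab$target_name))
  }
})

test_that("self-alignments and degenerate rows are dropped", {
  raw <- raw_alignments(c("a", "a"), c(100, 100), c(0, 0), c(100, 50),
                        c("a", "b"), c(100, 200), c(0, 0), c(100, 40),
                        matches = c(100, 50), mismatches = c(0, 0))
  tab <- compute_metrics(raw)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$query_name, "a")
  expect_equal(tab$target_name, "b")
})

test_that("PSL serialisation round-trips through the parser", {
  set.seed(77)
  inst <- random_instance(5, 12)
  path <- withr::local_tempfile(fileext = ".psl")
  write_psl(inst$table, path)
  reparsed <- compute_metrics(parse_psl(path))
  cols <- c("query_name", "target_name", "ID", "Q", "R", "QR")
  expect_equal(as.data.frame(reparsed)[cols], as.data.frame(inst$table)[cols])
})

test_that("filter_eligible drops long queries and orients reciprocal pairs", {
  tab <- compute_metrics(raw_alignments(
    query_name = c("big", "A", "B", "X", "Y"),
    query_length = c(12e6, 2000, 1000, 500, 500),
    query_start = 0, query_end = c(12e6, 900, 900, 400, 400),
    target_name = c("other", "B", "A", "Y", "X"),
    target_length = c(15e6, 1000, 2000, 500, 500),
    target_start = 0, target_end = c(12e6, 900, 900, 400, 400),
    matches = c(12e6, 900, 900, 400, 400), mismatches = 0
  ))
  out <- filter_eligible(tab)
  # >10 Mb query dropped; of the A/B reciprocal pair only query B (shorter)
  # survives; of the equal-length X/Y pair only the later-sorting query Y
  expect_setequal(out$query_name, c("B", "Y"))
  expect_equal(nrow(filter_eligible(tab[0, , drop = FALSE])), 0L)
  kept_all <- filter_eligible(tab, max_query_length = Inf,
                              require_query_not_longer = FALSE)
  expect_equal(nrow(kept_all), nrow(tab))
})

test_that("metrics table writer emits the inspection columns", {
  raw <- raw_alignments("q", 100, 0, 80, "t", 200, 0, 100,
                        matches = 70, mismatches = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_table(compute_metrics(raw), path)
  got <- read.delim(path)
  expect_equal(names(got),
               c("query_name", "target_name", "ID", "Q", "R", "QR",
                 "QR_prime"))
  expect_equal(got$ID, 0.875)
})
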
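test_that("QR window is symmetric and inclusive bounds are as defined", {
  expect_equal(qr_window(purge_thresholds(qr = 0.70)),
               c(0.70, exp(-log2(0.70))))
  expect_equal(qr_window(purge_thresholds(qr = 1.0)), c(1, 1))
  expect_equal(qr_window(purge_thresholds(qr = 2.0)), c(exp(-1), 2.0))
  expect_error(purge_thresholds(qr = 0), "positive")
  expect_error(purge_thresholds(qr = -1), "positive")
  expect_error(purge_thresholds(id = 0), "\\(0, 1\\]")
})

test_that("threshold triple purges per the three-condition rule", {
  tab <- metrics_table(query = c("B", "C"), target = c("A", "A"),
                       ID = c(0.95, 0.95), Q = c(1.0, 0.5),
                       QR = c(1.2, 1.0))
  cand <- candidate_assembly(tab, purge_thresholds(0.70, 0.70, 0.70),
                             c("A", "B", "C"))
  expect_equal(cand$purged, "B")          # all three conditions pass
  expect_setequal(cand$retained, c("A", "C"))  # C fails Q >= 0.70

  none <- candidate_assembly(tab, purge_thresholds(1, 1, 1e6),
                             c("A", "B", "C"))
  expect_length(none$purged, 0L)
  expect_setequal(none$retained, c("A", "B", "C"))

  empty <- candidate_assembly(tab[0, , drop = FALSE], purge_thresholds(),
                              c("A", "B", "C"))
  expect_setequal(empty$retained, c("A", "B", "C"))

  expect_error(candidate_assembly(tab, purge_thresholds(), c("A", "B")),
               "absent from all_contigs")
})

test_that("window boundaries are inclusive", {
  thr <- purge_thresholds(0.5, 0.5, 0.8)
  win <- qr_window(thr)
  tab <- metrics_table(c("lo", "hi"), c("t", "t"), ID = c(1, 1),
                       Q = c(1, 1), QR = win)
  cand <- candidate_assembly(tab, thr, c("lo", "hi", "t"))
  expect_setequal(cand$purged, c("lo", "hi"))
})

test_that("cost formula, zero cases and the S = 0 sentinel", {
  expect_equal(busco_cost(c(M = 10, D = 5, F = 3, S = 100),
                          busco_weights(1, 1, 0, 1)), 0.15)
  expect_equal(busco_cost(c(M = 0, D = 0, F = 0, S = 50)), 0)
  expect_equal(busco_cost(c(M = 1, D = 1, F = 1, S = 0)), Inf)
  # fragmented genes enter only through their weight
  expect_equal(busco_cost(c(M = 0, D = 0, F = 7, S = 10),
                          busco_weights(1, 1, 1, 1)), 0.7)
  expect_equal(busco_cost(c(M = 2, D = 5, F = 0, S = 10),
                          busco_weights(1, 0, 0, 1)), 0.2)
  expect_error(busco_weights(s = 0), "positive")
  expect_error(busco_weights(m = 2), "\\[0, 1\\]")
})

test_that("score_candidate composes purge and BUSCO aggregation", {
  cat <- busco_catalog(list(
    contig_busco("A", c("g1", "g2")),
    contig_busco("B", "g2", "g3")
  ), universe_size = 5)
  cand <- candidate_assembly(metrics_table(character(0), character(0),
                                           numeric(0), numeric(0),
                                           numeric(0)),
                             purge_thresholds(), c("A", "B"))
  scored <- score_candidate(cand, cat)
  expect_equal(unclass(scored$counts), c(M = 2L, D = 1L, F = 1L, S = 1L))
  expect_equal(scored$cost, 3)  # (2 + 1) / 1 with default weights

  nothing <- score_candidate(
    structure(list(retained = character(0), purged = c("A", "B"),
                   thresholds = purge_thresholds()),
              class = "candidate_assembly"), cat)
  expect_equal(nothing$cost, Inf)
})

test_that("raising ID or Q thresholds never enlarges the purged set", {
  set.seed(303)
  for (rep in 1:25) {
    inst <- random_instance(sample(3:8, 1), sample(5:25, 1))
    qr_t <- runif(1, 0.3, 2)
    id1 <- runif(1, 0.1, 0.9); id2 <- id1 + runif(1, 0, 1 - id1)
    q1 <- runif(1, 0.1, 0.9); q2 <- q1 + runif(1, 0, 1 - q1)
    p_loose <- candidate_assembly(inst$table,
                                  purge_thresholds(id1, q1, qr_t),
                                  inst$contigs)$purged
    p_tight <- candidate_assembly(inst$table,
                                  purge_thresholds(id2, q2, qr_t),
                                  inst$contigs)$purged
    expect_true(all(p_tight %in% p_loose))
  }
})

test_that("purge decisions match the naive brute-force oracle", {
  set.seed(404)
  for (rep in 1:40) {
    inst <- random_instance(sample(2:8, 1), sample(1:30, 1))
    thr <- purge_thresholds(runif(1, 0.05, 1), runif(1, 0.05, 1),
                            runif(1, 0.1, 2))
    got <- candidate_assembly(inst$table, thr, inst$contigs)
    oracle <- naive_purge(inst$table, thr$id, thr$q, thr$qr, inst$contigs)
    expect_equal(sort(got$purged), oracle$purged)
    expect_equal(sort(got$retained), oracle$retained)
  }
})

test_that("purge report labels every contig exactly once", {
  tab <- metrics_table("B", "A", 0.99, 1, 1)
  cand <- candidate_assembly(tab, purge_thresholds(), c("A", "B", "C"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_purge_report(cand, path)
  rep <- read.delim(path)
  expect_equal(rep$contig, c("A", "B", "C"))
  expect_equal(rep$status, c("primary", "secondary", "primary"))
})
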
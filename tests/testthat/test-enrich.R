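test_that("hypergeometric upper tail matches closed forms and the pmf oracle", {
  expect_equal(hypergeom_upper_tail(0, 5, 5, 10), 1)
  expect_equal(hypergeom_upper_tail(0, 0, 0, 7), 1)
  # single maximal draw: all 5 annotated genes in a 5-gene draw from 10
  expect_equal(hypergeom_upper_tail(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(hypergeom_upper_tail(4, 6, 8, 20),
               oracle_hyper_upper(4, 6, 8, 20))
  # non-increasing in k
  tail_k <- vapply(0:6, hypergeom_upper_tail, numeric(1), K = 6, n = 8,
                   N = 20)
  expect_true(all(diff(tail_k) <= 0))
  expect_error(hypergeom_upper_tail(5, 3, 4, 10), "min")
  expect_error(hypergeom_upper_tail(1, 11, 4, 10), "N")
})

test_that("upper tail stays accurate in log space for large universes", {
  expect_gt(hypergeom_upper_tail(50, 200, 300, 20000), 0)
  expect_lt(hypergeom_upper_tail(50, 200, 300, 20000), 1e-40)
})

test_that("enrichment ratio is observed over expected overlap", {
  expect_equal(enrichment_ratio(4, 6, 8, 20), (4 / 8) / (6 / 20))
  expect_equal(enrichment_ratio(6, 10, 12, 20), 1)  # k = n*K/N exactly
  expect_equal(enrichment_ratio(0, 6, 8, 20), 0)
  expect_true(is.na(enrichment_ratio(0, 0, 8, 20)))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(21)
  p <- runif(50)
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_true(all(bh_adjust(p) >= p))
  # the set passing q <= alpha equals the classical step-up rejection set
  alpha <- 0.1
  m <- length(p)
  ord <- order(p)
  passes <- which(p[ord] <= alpha * seq_len(m) / m)
  rejected <- if (length(passes) == 0) integer() else ord[seq_len(max(passes))]
  expect_setequal(which(bh_adjust(p) <= alpha), rejected)
})

test_that("GMT files round-trip and malformed collections are rejected", {
  dir <- withr::local_tempdir()
  coll <- tibble::tibble(
    term_id = c("T1", "T2"), name = c("alpha", "beta"),
    members = list(c("A", "B", "C"), c("B", "D"))
  )
  path <- file.path(dir, "sets.gmt")
  write_gmt(coll, path)
  back <- read_gmt(path, "BP")
  expect_equal(back$term_id, coll$term_id)
  expect_equal(back$members, coll$members)
  expect_equal(unique(back$namespace), "BP")

  writeLines(c("T1\tonly-two-fields"), path)
  expect_error(read_gmt(path), "fewer than 3")
  writeLines(c("T1\td\tA", "T1\td\tB"), path)
  expect_error(read_gmt(path), "Duplicate")
})

test_that("a term exactly matching the query ranks first", {
  collection <- tibble::tibble(
    term_id = c("T1", "T2"), name = c("target", "filler"), namespace = "BP",
    members = list(c("A", "B", "C", "D"), sprintf("X%02d", 1:20))
  )
  res <- suppressMessages(enrich(c("A", "B", "C", "D"), collection))
  expect_equal(res$term_id[1], "T1")
  expect_equal(res$k[1], 4)
  expect_true(res$significant[1])
  expect_true(all(res$q >= res$p))
})

test_that("a query disjoint from all terms produces p = 1 everywhere", {
  collection <- tibble::tibble(
    term_id = c("T1", "T2"), name = c("a", "b"), namespace = "BP",
    members = list(c("A", "B"), c("C", "D"))
  )
  res <- suppressMessages(
    enrich(c("Z1", "Z2"), collection,
           universe = c("A", "B", "C", "D", "Z1", "Z2"), min_overlap = 0)
  )
  expect_true(all(res$k == 0))
  expect_true(all(res$p == 1))
  # with the default minimum overlap those terms are simply not tested
  res2 <- suppressMessages(
    enrich(c("Z1", "Z2"), collection,
           universe = c("A", "B", "C", "D", "Z1", "Z2"))
  )
  expect_equal(nrow(res2), 0)
})

test_that("enrichment results are invariant to term order", {
  set.seed(31)
  collection <- tibble::tibble(
    term_id = paste0("T", 1:8), name = paste0("term", 1:8), namespace = "BP",
    members = lapply(1:8, function(i) sample(sprintf("G%02d", 1:40), 10))
  )
  query <- sprintf("G%02d", 1:12)
  r1 <- suppressMessages(enrich(query, collection))
  r2 <- suppressMessages(enrich(query, collection[sample(8), ]))
  expect_equal(tibble::as_tibble(r1), tibble::as_tibble(r2),
               ignore_attr = TRUE)
})

test_that("term-gene extraction unions members of significant named terms", {
  collection <- tibble::tibble(
    term_id = c("T1", "T2"), name = c("coagulation", "other process"),
    namespace = "BP",
    members = list(c("A", "B", "C"), c("C", "D", "E"))
  )
  query <- c("A", "B", "C", "D")
  res <- suppressMessages(enrich(query, collection,
                                 universe = c(collection$members[[1]],
                                              collection$members[[2]],
                                              sprintf("X%02d", 1:30)),
                                 min_overlap = 2))
  # no significant terms -> empty set
  expect_length(genes_in_terms(res, collection, query, "nonexistent"), 0)
  # a significant term fully containing a query subset returns it
  sig_names <- res$name[res$q <= 0.05]
  if ("coagulation" %in% sig_names) {
    expect_setequal(genes_in_terms(res, collection, query, "coagulation"),
                    c("A", "B", "C"))
  }
})
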
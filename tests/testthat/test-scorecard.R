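make_profiles <- function(n, seed = 13) {
  set.seed(seed)
  flags <- matrix(sample(c(TRUE, FALSE), n * 7, replace = TRUE), ncol = 7,
                  dimnames = list(NULL, criterion_flags()))
  out <- tibble::as_tibble(flags)
  out <- tibble::add_column(out, gene = sprintf("G%03d", seq_len(n)),
                            .before = 1)
  out$score <- profile_score(out)
  out
}

test_that("profiles saturate with full evidence and zero without", {
  genes <- c("FULL", "NONE")
  ld <- tibble::tibble(rsid = "rs1", gene = "FULL", consequence = "missense")
  eqtl <- tibble::tibble(rsid = "rs2", gene = "FULL", significant = TRUE)
  go <- tibble::tibble(gene = genes, go_bp = c(TRUE, FALSE),
                       go_cc = c(TRUE, FALSE), go_mf = c(TRUE, FALSE),
                       go_evidence = list(list(go_bp = "T1", go_cc = "T2",
                                               go_mf = "T3"), NULL))
  prof <- build_profiles(genes, top_genes = "FULL", ld_variants = ld,
                         eqtl = eqtl, go_flags = go, pid_genes = "FULL")
  expect_equal(prof$score[prof$gene == "FULL"], 7L)
  expect_equal(prof$score[prof$gene == "NONE"], 0L)
  # every set flag carries provenance
  ev <- prof$evidence[prof$gene == "FULL"][[1]]
  expect_setequal(names(ev), criterion_flags())
  expect_equal(ev$has_missense_in_ld, "rs1")
  expect_length(prof$evidence[prof$gene == "NONE"][[1]], 0)
})

test_that("a missense consequence is required for criterion 2", {
  ld <- tibble::tibble(rsid = c("rs1", "rs2"), gene = c("A", "B"),
                       consequence = c("other", "missense"))
  eqtl <- tibble::tibble(rsid = character(), gene = character(),
                         significant = logical())
  go <- tibble::tibble(gene = character(), go_bp = logical(),
                       go_cc = logical(), go_mf = logical(),
                       go_evidence = list())
  prof <- build_profiles(c("A", "B"), character(), ld, eqtl, go, character())
  expect_false(prof$has_missense_in_ld[prof$gene == "A"])
  expect_true(prof$has_missense_in_ld[prof$gene == "B"])
})

test_that("scores are bounded and risk calling equals a brute-force filter", {
  prof <- make_profiles(60)
  expect_true(all(prof$score >= 0 & prof$score <= 7))
  for (ms in 0:7) {
    oracle <- prof$gene[rowSums(prof[, criterion_flags()]) >= ms]
    expect_setequal(risk_genes(prof, ms), oracle)
  }
  expect_setequal(risk_genes(prof, 0), prof$gene)
})

test_that("risk gene sets are nested as the minimum score rises", {
  prof <- make_profiles(80, seed = 29)
  sets <- lapply(0:7, function(ms) risk_genes(prof, ms))
  for (i in 2:8) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
  # ordering: score descending, then symbol ascending
  rg <- risk_genes(prof, 3)
  sc <- prof$score[match(rg, prof$gene)]
  expect_true(all(diff(sc) <= 0))
  for (s in unique(sc)) {
    expect_false(is.unsorted(rg[sc == s]))
  }
})

test_that("the transcribed scorecard reproduces the published scores", {
  sc <- read_scorecard(extdata("scorecard_table2_synthetic.tsv"))
  expect_equal(sc$score[sc$gene == "IL6R"], 6L)
  expect_equal(sc$score[sc$gene == "F5"], 5L)
  expect_equal(sc$score[sc$gene == "ABO"], 5L)
  expect_equal(sc$score[sc$gene == "THBD"], 4L)
  expect_setequal(
    sc$gene[sc$score == 4],
    c("F2", "F9", "F11", "IL1RN", "KLKB1", "SH2B3", "FGB", "VWF", "FGA",
      "ADAMTS13", "THBD")
  )
  expect_equal(length(risk_genes(sc, 3)), 28)
})

test_that("scorecards round-trip through write and read", {
  dir <- withr::local_tempdir()
  prof <- make_profiles(10)
  class(prof) <- c("dvt_scorecard", class(prof))
  path <- file.path(dir, "sc.tsv")
  write_scorecard(prof, path)
  back <- read_scorecard(path)
  expect_equal(back$gene, prof$gene)
  expect_equal(back$score, prof$score)
})

test_that("GO criterion flags follow enrichment of the mapped set", {
  # one clearly enriched term containing the flagged genes, fillers without
  collection <- tibble::tibble(
    term_id = c("BP:1", paste0("BP:F", 1:6)),
    name = c("coagulation", paste("filler", 1:6)),
    namespace = "BP",
    members = c(list(c("A", "B", "C")),
                lapply(1:6, function(i) sprintf("X%02d", (6 * i):(6 * i + 9))))
  )
  flags <- suppressMessages(
    go_criterion_flags(c("A", "B", "Z"), list(BP = collection),
                       mapped_genes = c("A", "B", "C", "Z"))
  )
  expect_true(all(flags$go_bp[flags$gene %in% c("A", "B")]))
  expect_false(flags$go_bp[flags$gene == "Z"])
  expect_equal(flags$go_evidence[flags$gene == "A"][[1]]$go_bp, "BP:1")
})
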
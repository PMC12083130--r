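write_expr <- function(dir = withr::local_tempdir(.local_envir =
                                                    parent.frame())) {
  expr_path <- file.path(dir, "expr.tsv")
  map_path <- file.path(dir, "map.tsv")
  writeLines(c(
    "gene\tS1\tS2\tS3\tS4\tS5\tS6",
    "A\t1\t3\t5\t10\t10\t10",
    "B\t2\t2\t2\t0.1\t0.2\t0.3"
  ), expr_path)
  writeLines(c("sample_id\ttissue",
               "S1\tWhole Blood", "S2\tWhole Blood", "S3\tWhole Blood",
               "S4\tLiver", "S5\tLiver", "S6\tLiver"), map_path)
  list(expr = expr_path, map = map_path)
}

test_that("expression loading validates the tissue map", {
  f <- write_expr()
  expr <- read_expression(f$expr, f$map)
  expect_equal(nrow(expr), 12)
  expect_setequal(unique(expr$tissue), c("Whole Blood", "Liver"))

  # a sample missing from the map is a configuration error naming it
  bad_map <- file.path(dirname(f$map), "bad_map.tsv")
  writeLines(c("sample_id\ttissue", "S1\tWhole Blood"), bad_map)
  expect_error(read_expression(f$expr, bad_map), "S2")
})

test_that("all-missing genes are dropped with a warning", {
  dir <- withr::local_tempdir()
  expr_path <- file.path(dir, "e.tsv")
  map_path <- file.path(dir, "m.tsv")
  writeLines(c("gene\tS1\tS2", "A\t1\t2", "B\tNA\tNA"), expr_path)
  writeLines(c("sample_id\ttissue", "S1\tLiver", "S2\tLiver"), map_path)
  expect_warning(expr <- read_expression(expr_path, map_path), "B")
  expect_equal(unique(expr$gene), "A")
})

test_that("tissue summaries are hand-checkable medians and IQRs", {
  f <- write_expr()
  expr <- read_expression(f$expr, f$map)
  ts <- tissue_summary(expr, c("A", "B"))
  a_blood <- ts[ts$gene == "A" & ts$tissue == "Whole Blood", ]
  expect_equal(a_blood$median_tpm, 3)
  expect_equal(a_blood$iqr_tpm, 2)
  a_liver <- ts[ts$gene == "A" & ts$tissue == "Liver", ]
  expect_equal(a_liver$median_tpm, 10)
  expect_equal(a_liver$iqr_tpm, 0)
  expect_error(tissue_summary(expr, "NOPE"), "NOPE")
})

test_that("generated expression medians recover the planted profiles", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 23, n_snps = 40, n_significant = 20,
                           n_genes = 15, n_samples_per_tissue = 40)
  gt <- generate_bundle(cfg, dir)
  expr <- read_expression(gt$files[["expression"]],
                          gt$files[["tissue_map"]])
  ts <- tissue_summary(expr, gt$selected_biomarkers)
  blood <- ts[ts$tissue == "Whole Blood", ]
  # planted blood-biomarker class: log-normal around 20 TPM
  expect_true(all(blood$median_tpm > 10 & blood$median_tpm < 40))
  net_only <- setdiff(gt$network_genes, gt$selected_biomarkers)
  ts2 <- tissue_summary(expr, net_only)
  expect_true(all(ts2$median_tpm[ts2$tissue == "Liver"] >
                    ts2$median_tpm[ts2$tissue == "Whole Blood"]))
})

test_that("biomarker selection is the eQTL-and-detectability conjunction", {
  summaries <- tibble::tibble(
    gene = rep(c("A", "B", "C"), each = 2),
    tissue = rep(c("Whole Blood", "Liver"), 3),
    n_samples = 10,
    median_tpm = c(5, 1, 8, 50, 0, 30),
    iqr_tpm = 1
  )
  flags <- tibble::tibble(gene = c("A", "B", "C"),
                          has_blood_eqtl = c(TRUE, FALSE, TRUE))
  calls <- call_biomarkers(summaries, flags)
  # eQTL flag 0 -> never selected regardless of expression
  expect_false(calls$selected[calls$gene == "B"])
  # blood median 0 -> not selected
  expect_false(calls$selected[calls$gene == "C"])
  expect_true(calls$selected[calls$gene == "A"])
  # selected-first ordering, then blood median descending
  expect_equal(calls$gene, c("A", "B", "C"))
})

test_that("selection shrinks as the detectability threshold rises", {
  summaries <- tibble::tibble(
    gene = rep(sprintf("G%d", 1:5), each = 2),
    tissue = rep(c("Whole Blood", "Liver"), 5),
    n_samples = 10,
    median_tpm = c(0.5, 1, 2, 1, 5, 1, 10, 1, 20, 1),
    iqr_tpm = 1
  )
  flags <- tibble::tibble(gene = sprintf("G%d", 1:5), has_blood_eqtl = TRUE)
  sel <- lapply(c(0.1, 1, 4, 15, 100), function(t) {
    calls <- call_biomarkers(summaries, flags, tpm_min = t)
    sort(calls$gene[calls$selected])
  })
  for (i in 2:5) expect_true(all(sel[[i]] %in% sel[[i - 1]]))
  # permutation invariance in gene order
  c1 <- call_biomarkers(summaries, flags, genes = sprintf("G%d", 1:5))
  c2 <- call_biomarkers(summaries, flags, genes = sprintf("G%d", 5:1))
  expect_equal(tibble::as_tibble(c1), tibble::as_tibble(c2))
})

test_that("missing summaries yield per-gene errors, not failures", {
  summaries <- tibble::tibble(
    gene = c("A", "A", "B"),
    tissue = c("Whole Blood", "Liver", "Liver"),
    n_samples = 5, median_tpm = c(3, 1, 2), iqr_tpm = 1
  )
  flags <- tibble::tibble(gene = c("A", "B"), has_blood_eqtl = TRUE)
  calls <- call_biomarkers(summaries, flags, genes = c("A", "B"))
  expect_true(calls$selected[calls$gene == "A"])
  expect_match(calls$error[calls$gene == "B"], "whole-blood")
  expect_false(calls$selected[calls$gene == "B"])
})
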
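make_panel <- function(seed, proxy, r2, pop = "ASN") {
  tibble::tibble(seed_rsid = seed, proxy_rsid = proxy, r2 = r2,
                 population = pop)
}

test_that("panel reading enforces the r2 invariant row-wise", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "panel.tsv")
  readr::write_tsv(make_panel(c("rsA", "rsA", "rsB"),
                              c("rsP1", "rsP2", "rsP3"),
                              c(0.9, 1.2, 0.85)), path)
  expect_warning(panel <- read_ld_panel(path), "line\\(s\\): 2")
  expect_equal(nrow(panel), 2)
  expect_setequal(panel$proxy_rsid, c("rsP1", "rsP3"))

  # round-trip identity on a generated panel
  gt <- generate_bundle(simulation_config(seed = 5, n_snps = 40,
                                          n_significant = 20, n_genes = 15),
                        file.path(dir, "b"))
  panel1 <- read_ld_panel(gt$files[["ld_panel"]])
  path2 <- file.path(dir, "panel2.tsv")
  readr::write_tsv(panel1, path2)
  expect_equal(read_ld_panel(path2), panel1, ignore_attr = TRUE)
})

test_that("expansion honors the strict r2 boundary and population match", {
  panel <- make_panel(c("rsA", "rsA", "rsA"), c("rsB", "rsC", "rsD"),
                      c(0.85, 0.8, 0.95), pop = c("ASN", "ASN", "EUR"))
  out <- expand_snps(panel, "rsA", r2_min = 0.8, population = "ASN")
  expect_setequal(as.character(out), c("rsA", "rsB"))
  # degenerate threshold keeps only the seeds
  expect_setequal(as.character(expand_snps(panel, "rsA", r2_min = 1)), "rsA")
  # empty panel warns and passes seeds through
  empty <- make_panel(character(), character(), double())
  expect_warning(out2 <- expand_snps(empty, c("rsX", "rsY")), "empty")
  expect_setequal(as.character(out2), c("rsX", "rsY"))
})

test_that("expansion equals an exhaustive panel scan and is monotone", {
  set.seed(9)
  panel <- make_panel(
    sample(paste0("rs", 1:12), 60, replace = TRUE),
    paste0("px", 1:60),
    runif(60),
    sample(c("ASN", "EUR"), 60, replace = TRUE)
  )
  seeds <- paste0("rs", c(1, 3, 5, 7, 9, 11))
  for (r2m in c(0, 0.5, 0.8, 0.99)) {
    expect_equal(as.character(expand_snps(panel, seeds, r2m, "ASN")),
                 oracle_expand(panel, seeds, r2m, "ASN"))
  }
  # output contains the seeds and shrinks as r2_min grows
  sizes <- vapply(c(0, 0.3, 0.6, 0.9), function(r2m) {
    out <- expand_snps(panel, seeds, r2m, "ASN")
    expect_true(all(seeds %in% out))
    length(out)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("gene mapping inverts links and reports unmapped SNPs", {
  links <- tibble::tibble(
    rsid = c("rs1", "rs2", "rs3", "rs3"),
    gene = c("F5", "F5", "ABO", "FGB"),
    consequence = "other"
  )
  gm <- map_to_genes(links, c("rs1", "rs2", "rs3", "rs9"))
  expect_equal(gm$gene, c("ABO", "F5", "FGB"))
  expect_equal(gm$rsids[gm$gene == "F5"][[1]], c("rs1", "rs2"))
  expect_equal(attr(gm, "unmapped"), "rs9")

  empty <- map_to_genes(links[0, ], c("rs1", "rs2"))
  expect_equal(nrow(empty), 0)
  expect_setequal(attr(empty, "unmapped"), c("rs1", "rs2"))
})

test_that("distinct mapped genes equal a group-by count oracle", {
  set.seed(13)
  links <- tibble::tibble(
    rsid = sample(paste0("rs", 1:40), 100, replace = TRUE),
    gene = sample(paste0("G", 1:15), 100, replace = TRUE),
    consequence = "other"
  )
  snps <- paste0("rs", sample(1:40, 25))
  gm <- map_to_genes(links, snps)
  oracle <- length(unique(links$gene[links$rsid %in% snps]))
  expect_equal(nrow(gm), oracle)
})
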
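# Builds the synthetic reconstructions of the published enrichment and
# expression inputs shipped under inst/extdata/. The scorecard, network and
# eQTL fixtures are hand-transcribed; the two built here need either bulk
# term membership (GMT) or random draws (TPM values), so they are generated
# deterministically from fixed seeds. Run from the package root:
#   Rscript data-raw/fixtures.R

set.seed(20241024)

risk28 <- c(
  "IL6R", "F5", "ABO", "F2", "F9", "F11", "IL1RN", "KLKB1", "SH2B3", "FGB",
  "VWF", "FGA", "ADAMTS13", "THBD", "PLCG2", "ST3GAL4", "PROC", "PLEK",
  "ATP1B1", "NME7", "FGG", "PROCR", "SLC44A2", "TSPAN15", "F8", "SERPINC1",
  "PROS1", "GP6"
)

# External (non-risk) genes padding the annotated universe.
ext <- sprintf("EXTG%03d", 1:270)

terms <- list(
  list("GO:0050817", "coagulation",
       c("F2", "F5", "F9", "F11", "FGA", "FGB", "VWF", "KLKB1", "THBD",
         "PROC", "ADAMTS13", "ST3GAL4", ext[1:8])),
  list("GO:0042060", "wound healing",
       c("PLEK", "PLCG2", "THBD", "F5", "F2", "VWF", "FGA", "FGB",
         ext[9:14])),
  list("GO:1903034", "regulation of response to wounding",
       c("SH2B3", "KLKB1", "F9", "F11", "PROC", "F5", "F2", ext[15:18])),
  list("GO:0006954", "inflammatory response",
       c("IL6R", "IL1RN", ext[19:26])),
  list("GO:0006811", "monoatomic ion transport",
       c("ATP1B1", "SLC44A2", ext[27:36])),
  list("GO:0007596", "platelet activation",
       c("GP6", "F8", ext[37:44])),
  list("GO:0030168", "protein processing",
       c("PROCR", "FGG", ext[45:52])),
  list("GO:0016337", "cell-cell adhesion",
       c("TSPAN15", "NME7", ext[53:60])),
  list("GO:0008015", "blood circulation",
       c("SERPINC1", "PROS1", "ABO", ext[61:68]))
)
# Filler terms: partition the remaining external pool so the universe size
# is deterministic.
rest <- ext[69:270]
chunks <- split(rest, ceiling(seq_along(rest) / 9))
for (i in seq_along(chunks)) {
  terms[[length(terms) + 1]] <- list(
    sprintf("GO:9%06d", i), sprintf("background process %d", i), chunks[[i]]
  )
}
lines <- vapply(terms, function(t) paste(c(t[[1]], t[[2]], t[[3]]),
                                         collapse = "\t"), character(1))
writeLines(lines, "inst/extdata/go_bp_fig3_synthetic.gmt")

# Expression: five genes, 20 liver + 20 whole-blood samples, log-normal TPM.
genes <- c("F2", "F5", "F9", "PROC", "THBD")
profiles <- list(
  F2 = c(liver = log(250), blood = log(0.3)),
  F5 = c(liver = log(25), blood = log(4)),
  F9 = c(liver = log(60), blood = log(0.15)),
  PROC = c(liver = log(120), blood = log(0.4)),
  THBD = c(liver = log(12), blood = log(8))
)
n <- 20
samples <- c(sprintf("LIV%03d", 1:n), sprintf("BLD%03d", 1:n))
tissues <- c(rep("Liver", n), rep("Whole Blood", n))
mat <- t(vapply(genes, function(g) {
  mu <- ifelse(tissues == "Liver", profiles[[g]][["liver"]],
               profiles[[g]][["blood"]])
  round(rlnorm(length(samples), meanlog = mu, sdlog = 0.45), 3)
}, numeric(length(samples))))
df <- data.frame(gene = genes, mat, check.names = FALSE)
colnames(df) <- c("gene", samples)
write.table(df, "inst/extdata/expression_fig5_synthetic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = samples, tissue = tissues),
            "inst/extdata/tissue_map_fig5_synthetic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("fixtures written")
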
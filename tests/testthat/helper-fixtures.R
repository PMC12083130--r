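# Shared fixtures and independent oracles for the test suite.

extdata <- function(f) {
  system.file("extdata", f, package = "dvtmark", mustWork = TRUE)
}

fig3_term_filter <- c("coagulation", "regulation of response to wounding",
                      "wound healing")

# The 15 coagulation/wound genes printed in the study.
fig3_genes <- sort(c("F5", "F11", "THBD", "SH2B3", "F9", "KLKB1", "PLCG2",
                     "FGB", "VWF", "FGA", "ADAMTS13", "F2", "ST3GAL4",
                     "PROC", "PLEK"))

# Minimal in-code association table builder.
make_assoc <- function(rsid, chrom, pos, pvalue, genes = NULL,
                       trait = "Deep vein thrombosis", study = "GCST000001") {
  tibble::tibble(
    rsid = rsid, chrom = as.character(chrom), pos = as.integer(pos),
    pvalue = pvalue, trait = trait,
    mapped_genes = genes %||% replicate(length(rsid), character(),
                                        simplify = FALSE),
    study_id = study
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle: hypergeometric upper tail by brute-force summation of
# the probability mass function with choose().
oracle_hyper_upper <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Independent oracle: Benjamini-Hochberg step-up from its textbook
# definition (sort, scale by m/rank, enforce monotonicity from the largest
# rank down, cap at 1, restore input order).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Independent oracle: LD expansion by exhaustive row scan of the panel.
oracle_expand <- function(panel, seeds, r2_min, population) {
  out <- as.character(seeds)
  for (i in seq_len(nrow(panel))) {
    if (panel$seed_rsid[i] %in% seeds &&
        panel$population[i] == population &&
        panel$r2[i] > r2_min) {
      out <- c(out, panel$proxy_rsid[i])
    }
  }
  sort(unique(out))
}

run_quiet <- function(config) suppressMessages(run_pipeline(config))

mini_bundle <- function(seed = 42, dir = withr::local_tempdir(.local_envir =
                                                                parent.frame()),
                        ...) {
  gt <- generate_bundle(sim_preset("mini", seed = seed), dir)
  list(dir = dir, gt = gt)
}
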
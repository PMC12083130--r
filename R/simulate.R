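#' Configure a synthetic fixture bundle
#'
#' Describes one coherent synthetic study: a catalog-style association
#' table, an LD proxy panel, variant-gene consequence links, a whole-blood
#' eQTL table, GO gene-set collections, a PID list, a gene-disease edge
#' list and a two-tissue expression matrix — with a planted set of blood
#' biomarker genes designed to survive every pipeline stage, and decoy gene
#' classes that carry strict subsets of the evidence:
#'
#' * `biomarker` — full evidence (top SNP, missense proxy, blood eQTL,
#'   enriched GO terms, optional PID, direct disease edge, blood-shifted
#'   expression); these and only these should be selected.
#' * `network` decoys — reach the network stage but, like the liver-specific
#'   coagulation factors, lack a blood eQTL and blood expression.
#' * `coag` decoys — members of the coagulation/wound terms but without a
#'   direct disease edge.
#' * `risk` decoys — score >= 3 through enriched GO terms that do not match
#'   the coagulation term filter.
#' * remaining mapped genes — at most two criteria, below any risk score.
#'
#' @param seed Master RNG seed; per-file sub-seeds are derived from it so a
#'   bundle is one reproducible object.
#' @param n_snps Total association rows.
#' @param n_significant Rows with p below `alpha` (p-values are drawn
#'   log-uniform within the significant and non-significant bands; the
#'   pipeline consumes only ranks and thresholds, so band membership is the
#'   only distributional property that matters).
#' @param n_genes Size of the mapped gene pool (all classes included).
#' @param planted_biomarkers Symbols of the planted blood biomarker genes.
#' @param n_network_decoys,n_coag_decoys,n_risk_decoys Decoy class sizes.
#' @param proxies_per_seed Mean LD fan-out (Poisson) when `n_expanded` is
#'   not fixed.
#' @param n_expanded If non-NULL, the exact total expanded SNP count
#'   (seeds + passing proxies), allocated deterministically across seeds.
#' @param n_external_genes Non-mapped gene pool used to pad gene-set terms
#'   and populate filler terms.
#' @param n_filler_terms Filler terms per GO namespace (a partition of the
#'   external pool, so the enrichment universe is deterministic).
#' @param term_padding External genes appended to each planted term.
#' @param plant_pid Whether planted biomarkers join the PID list.
#' @param n_samples_per_tissue Expression samples per tissue.
#' @param alpha Genome-wide significance threshold used for the p-value
#'   bands.
#' @param population LD panel population label.
#' @return A `dvt_sim_config` list.
#' @export
simulation_config <- function(seed = 1,
                              n_snps = 60,
                              n_significant = 30,
                              n_genes = 30,
                              planted_biomarkers = c("BMK1", "BMK2"),
                              n_network_decoys = 2,
                              n_coag_decoys = 3,
                              n_risk_decoys = 3,
                              proxies_per_seed = 2,
                              n_expanded = NULL,
                              n_external_genes = 60,
                              n_filler_terms = 10,
                              term_padding = 3,
                              plant_pid = TRUE,
                              n_samples_per_tissue = 8,
                              alpha = 5e-8,
                              population = "ASN") {
  planted_biomarkers <- unique(normalize_symbols(planted_biomarkers))
  n_bmk <- length(planted_biomarkers)
  n_risk_class <- n_bmk + n_network_decoys + n_coag_decoys + n_risk_decoys
  stopifnot(
    n_significant <= n_snps,
    n_risk_class <= n_genes,
    n_significant >= n_genes,
    is.null(n_expanded) || n_expanded >= n_significant + n_bmk
  )
  structure(
    list(
      seed = seed, n_snps = n_snps, n_significant = n_significant,
      n_genes = n_genes, planted_biomarkers = planted_biomarkers,
      n_network_decoys = n_network_decoys, n_coag_decoys = n_coag_decoys,
      n_risk_decoys = n_risk_decoys, proxies_per_seed = proxies_per_seed,
      n_expanded = n_expanded, n_external_genes = n_external_genes,
      n_filler_terms = n_filler_terms, term_padding = term_padding,
      plant_pid = plant_pid, n_samples_per_tissue = n_samples_per_tissue,
      alpha = alpha, population = population
    ),
    class = "dvt_sim_config"
  )
}

#' Preset simulation configurations
#'
#' `"mini"` is a small bundle that generates and runs in well under a
#' second; `"study-scale"` mirrors the magnitudes of the study stages
#' exactly by construction: 689 association rows of which 458 are
#' genome-wide significant, an expanded set of 4430 SNPs mapping to 334
#' genes, 28 risk-class genes, 15 coagulation-term genes, 5 network genes
#' and 2 planted biomarkers.
#'
#' @param preset `"mini"` or `"study-scale"`.
#' @param seed Master RNG seed.
#' @return A `dvt_sim_config` list.
#' @export
sim_preset <- function(preset = c("mini", "study-scale"), seed = 1) {
  preset <- match.arg(preset)
  if (preset == "mini") {
    simulation_config(seed = seed)
  } else {
    simulation_config(
      seed = seed, n_snps = 689, n_significant = 458, n_genes = 334,
      planted_biomarkers = c("BMK1", "BMK2"),
      n_network_decoys = 3, n_coag_decoys = 10, n_risk_decoys = 13,
      n_expanded = 4430, n_external_genes = 300, n_filler_terms = 30,
      term_padding = 5, n_samples_per_tissue = 30
    )
  }
}

# Gene pool and class assignment for a config; deterministic, no RNG.
sim_gene_classes <- function(config) {
  bmk <- config$planted_biomarkers
  net <- sprintf("NETD%02d", seq_len(config$n_network_decoys))
  coag <- sprintf("COAG%02d", seq_len(config$n_coag_decoys))
  risk <- sprintf("RISK%02d", seq_len(config$n_risk_decoys))
  n_fill <- config$n_genes - length(bmk) - length(net) - length(coag) -
    length(risk)
  fill <- sprintf("GENE%04d", seq_len(n_fill))
  tibble::tibble(
    gene = c(bmk, net, coag, risk, fill),
    class = c(rep("biomarker", length(bmk)), rep("network", length(net)),
              rep("coag", length(coag)), rep("risk", length(risk)),
              rep("mapped", n_fill))
  )
}

#' File names of a synthetic bundle
#' @return Named character vector of the bundle's relative file names.
#' @export
bundle_files <- function() {
  c(
    associations = "associations.tsv",
    ld_panel = "ld_panel.tsv",
    variant_links = "variant_links.tsv",
    eqtl = "eqtl_blood.tsv",
    go_bp = "go_bp.gmt",
    go_cc = "go_cc.gmt",
    go_mf = "go_mf.gmt",
    pid = "pid_genes.txt",
    edges = "disease_edges.tsv",
    expression = "expression_tpm.tsv",
    tissue_map = "tissue_map.tsv"
  )
}

#' Generate a synthetic fixture bundle
#'
#' Writes all input files consumed by [run_pipeline()] into `out_dir` and
#' returns the per-stage ground truth. Identical configuration (including
#' seed) yields byte-identical files.
#'
#' @param config A `dvt_sim_config` from [simulation_config()] or
#'   [sim_preset()].
#' @param out_dir Output directory (created if needed).
#' @return A `dvt_ground_truth` list with the expected significant SNP set,
#'   expanded SNP set, mapped/risk/term/network gene sets, selected
#'   biomarkers, the gene class table and the written file paths.
#' @export
generate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "dvt_sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    abort(paste0("Output directory is not writable: ", out_dir))
  }
  files <- file.path(out_dir, bundle_files())
  names(files) <- names(bundle_files())
  classes <- sim_gene_classes(config)
  bmk <- classes$gene[classes$class == "biomarker"]
  net <- classes$gene[classes$class == "network"]
  coag <- classes$gene[classes$class == "coag"]
  risk <- classes$gene[classes$class == "risk"]
  fill <- classes$gene[classes$class == "mapped"]
  risk_class <- c(bmk, net, coag, risk)
  term_genes <- c(bmk, net, coag)
  network_genes <- c(bmk, net)
  ext <- sprintf("EXT%04d", seq_len(config$n_external_genes))

  ## --- associations -------------------------------------------------------
  set.seed(derive_seed(config$seed, "associations"))
  n_sig <- config$n_significant
  n_non <- config$n_snps - n_sig
  sig_ids <- sprintf("rs1%06d", seq_len(n_sig))
  non_ids <- sprintf("rs2%06d", seq_len(n_non))
  # log-uniform bands; significant p strictly below alpha
  p_sig <- sort(10^runif(n_sig, -30, log10(config$alpha) - 1e-9))
  p_non <- 10^runif(n_non, log10(config$alpha), -1e-12)
  # seed -> gene: smallest p-values to planted biomarkers, then round-robin
  # across the remaining pool so every gene is covered
  other_genes <- setdiff(classes$gene, bmk)
  seed_genes <- c(bmk, rep(other_genes, length.out = n_sig - length(bmk)))
  assoc <- tibble::tibble(
    rsid = c(sig_ids, non_ids),
    chrom = sample(chromosome_levels(), config$n_snps, replace = TRUE),
    pos = sample.int(240000000L, config$n_snps, replace = TRUE),
    pvalue = c(p_sig, p_non),
    trait = sample(c("Deep vein thrombosis", "Venous thromboembolism"),
                   config$n_snps, replace = TRUE),
    mapped_genes = as.list(c(seed_genes,
                             sample(classes$gene, n_non, replace = TRUE))),
    study_id = sprintf("GCST%06d", sample.int(999999L, config$n_snps,
                                              replace = TRUE))
  )
  write_associations(assoc, files[["associations"]])

  ## --- LD panel and variant links ----------------------------------------
  set.seed(derive_seed(config$seed, "ld"))
  n_bmk <- length(bmk)
  if (!is.null(config$n_expanded)) {
    n_pass <- config$n_expanded - n_sig
    counts <- rep(n_pass %/% n_sig, n_sig)
    extra <- n_pass %% n_sig
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1
    # biomarker seeds (ranks 1..n_bmk) must carry the missense proxy
    counts[seq_len(n_bmk)] <- pmax(counts[seq_len(n_bmk)], 1)
    deficit <- sum(counts) - n_pass
    if (deficit > 0) {
      donors <- which(counts > 1)
      donors <- donors[donors > n_bmk]
      counts[donors[seq_len(deficit)]] <- counts[donors[seq_len(deficit)]] - 1
    }
  } else {
    counts <- rpois(n_sig, config$proxies_per_seed)
    counts[seq_len(n_bmk)] <- pmax(counts[seq_len(n_bmk)], 1)
  }
  panel <- purrr::map_dfr(seq_len(n_sig), function(i) {
    if (counts[i] == 0) return(NULL)
    tibble::tibble(
      seed_rsid = sig_ids[i],
      proxy_rsid = sprintf("%sp%02d", sig_ids[i], seq_len(counts[i])),
      r2 = runif(counts[i], 0.805, 0.995),
      population = config$population
    )
  })
  # sub-threshold and off-population negatives: never expanded
  neg_idx <- which(runif(n_sig) < 0.4)
  negatives <- tibble::tibble(
    seed_rsid = sig_ids[neg_idx],
    proxy_rsid = sprintf("%sn01", sig_ids[neg_idx]),
    r2 = runif(length(neg_idx), 0.3, 0.795),
    population = config$population
  )
  offpop_idx <- which(runif(n_sig) < 0.1)
  offpop <- tibble::tibble(
    seed_rsid = sig_ids[offpop_idx],
    proxy_rsid = sprintf("%se01", sig_ids[offpop_idx]),
    r2 = runif(length(offpop_idx), 0.85, 0.99),
    population = "EUR"
  )
  readr::write_tsv(dplyr::bind_rows(panel, negatives, offpop),
                   files[["ld_panel"]], progress = FALSE)
  expanded <- sort(unique(c(sig_ids, panel$proxy_rsid)))

  missense_proxies <- setNames(
    sprintf("%sp01", sig_ids[seq_len(n_bmk)]), bmk
  )
  seed_links <- tibble::tibble(rsid = sig_ids, gene = seed_genes,
                               consequence = "other")
  proxy_gene <- setNames(seed_genes, sig_ids)[panel$seed_rsid]
  proxy_links <- tibble::tibble(
    rsid = panel$proxy_rsid, gene = unname(proxy_gene),
    consequence = ifelse(panel$proxy_rsid %in% missense_proxies,
                         "missense", "other")
  )
  # a sliver of proxies stays unannotated so unmapped SNPs are exercised
  drop_link <- runif(nrow(proxy_links)) < 0.05 &
    !(proxy_links$rsid %in% missense_proxies)
  readr::write_tsv(dplyr::bind_rows(seed_links, proxy_links[!drop_link, ]),
                   files[["variant_links"]], progress = FALSE)

  ## --- whole-blood eQTLs --------------------------------------------------
  set.seed(derive_seed(config$seed, "eqtl"))
  eqtl_rows <- tibble::tibble(
    rsid = sig_ids[seq_len(n_bmk)], gene = bmk, significant = 1L
  )
  decoy_fill <- fill[runif(length(fill)) < 0.2]
  decoy_rows <- tibble::tibble(
    rsid = setNames(sig_ids, seed_genes)[decoy_fill],
    gene = decoy_fill, significant = 1L
  )
  negative_rows <- tibble::tibble(
    rsid = setNames(sig_ids, seed_genes)[net],
    gene = net, significant = 0L
  )
  readr::write_tsv(dplyr::bind_rows(eqtl_rows, decoy_rows, negative_rows),
                   files[["eqtl"]], progress = FALSE)

  ## --- GO collections and PID list ---------------------------------------
  set.seed(derive_seed(config$seed, "genesets"))
  pad <- function() sample(ext, config$term_padding)
  half <- function(x, first) {
    if (length(x) == 0) return(character())
    idx <- seq_len(ceiling(length(x) / 2))
    if (first) x[idx] else x[setdiff(seq_along(x), idx)]
  }
  filler_terms <- function(ns) {
    groups <- split(ext, ceiling(seq_along(ext) / max(1, ceiling(
      length(ext) / config$n_filler_terms
    ))))
    tibble::tibble(
      term_id = sprintf("%s:F%03d", ns, seq_along(groups)),
      name = sprintf("%s filler process %d", tolower(ns), seq_along(groups)),
      members = unname(groups)
    )
  }
  bp <- dplyr::bind_rows(
    tibble::tibble(term_id = "BP:0001", name = "coagulation",
                   members = list(c(term_genes, pad()))),
    tibble::tibble(term_id = "BP:0002",
                   name = "regulation of response to wounding",
                   members = list(c(network_genes, half(coag, TRUE), pad()))),
    tibble::tibble(term_id = "BP:0003", name = "wound healing",
                   members = list(c(network_genes, half(coag, FALSE), pad()))),
    tibble::tibble(term_id = "BP:0004", name = "acute inflammatory response",
                   members = list(c(risk, network_genes, pad()))),
    filler_terms("BP")
  )
  cc <- dplyr::bind_rows(
    tibble::tibble(term_id = "CC:0001", name = "platelet alpha granule",
                   members = list(c(risk_class, pad()))),
    filler_terms("CC")
  )
  mf <- dplyr::bind_rows(
    tibble::tibble(term_id = "MF:0001",
                   name = "serine-type endopeptidase activity",
                   members = list(c(risk_class, pad()))),
    filler_terms("MF")
  )
  write_gmt(bp, files[["go_bp"]])
  write_gmt(cc, files[["go_cc"]])
  write_gmt(mf, files[["go_mf"]])
  pid <- sort(c(if (config$plant_pid) bmk else character(),
                sample(ext, min(5, length(ext)))))
  readr::write_lines(pid, files[["pid"]])

  ## --- disease network ----------------------------------------------------
  set.seed(derive_seed(config$seed, "network"))
  dvt_edges <- tibble::tibble(
    gene = network_genes, concept_id = "DOID:0001",
    concept_label = "deep vein thrombosis", source = "disease"
  )
  thromb_edges <- tibble::tibble(
    gene = network_genes[seq_len(ceiling(length(network_genes) / 2))],
    concept_id = "DOID:0002", concept_label = "thrombophilia",
    source = "disease"
  )
  decoy_edges <- tibble::tibble(
    gene = c(coag, risk),
    concept_id = "HP:0001", concept_label = "abnormal bleeding",
    source = "phenotype"
  )
  ext_edges <- tibble::tibble(
    gene = sample(ext, min(10, length(ext))),
    concept_id = "DOID:0003", concept_label = "varicose veins",
    source = "disease"
  )
  readr::write_tsv(
    dplyr::bind_rows(dvt_edges, thromb_edges, decoy_edges, ext_edges),
    files[["edges"]], progress = FALSE
  )

  ## --- expression ---------------------------------------------------------
  set.seed(derive_seed(config$seed, "expression"))
  n_s <- config$n_samples_per_tissue
  samples <- c(sprintf("LIV%03d", seq_len(n_s)), sprintf("BLD%03d", seq_len(n_s)))
  tissues <- c(rep("Liver", n_s), rep("Whole Blood", n_s))
  profile <- function(class, tissue) {
    switch(paste(class, tissue),
      "biomarker Liver" = c(log(5), 0.35),
      "biomarker Whole Blood" = c(log(20), 0.35),
      "network Liver" = c(log(80), 0.35),
      "network Whole Blood" = c(log(0.2), 0.35),
      c(log(2), 0.35)
    )
  }
  expr_rows <- purrr::map(risk_class, function(g) {
    cls <- classes$class[classes$gene == g]
    vals <- purrr::map_dbl(tissues, function(tis) {
      pr <- profile(cls, tis)
      rlnorm(1, meanlog = pr[1], sdlog = pr[2])
    })
    setNames(c(list(g), as.list(round(vals, 4))), c("gene", samples))
  })
  readr::write_tsv(dplyr::bind_rows(expr_rows), files[["expression"]],
                   progress = FALSE)
  readr::write_tsv(tibble::tibble(sample_id = samples, tissue = tissues),
                   files[["tissue_map"]], progress = FALSE)

  structure(
    list(
      config = config,
      files = files,
      classes = classes,
      n_snps = config$n_snps,
      significant_snps = sort(sig_ids),
      expanded_snps = expanded,
      mapped_genes = sort(unique(seed_genes)),
      risk_genes = sort(risk_class),
      term_genes = sort(term_genes),
      network_genes = sort(network_genes),
      selected_biomarkers = sort(bmk)
    ),
    class = "dvt_ground_truth"
  )
}

#' Ablate one evidence type for one gene in a written bundle
#'
#' Edits the bundle files in place to remove a single evidence record,
#' supporting ablation-sensitivity checks: removing evidence on the
#' selection-critical path must remove the gene from the final selection,
#' while boundary ablations flip individual criterion flags.
#'
#' @param dir Bundle directory written by [generate_bundle()].
#' @param gene Gene symbol to ablate.
#' @param type One of `"eqtl"` (drop significant blood eQTL records),
#'   `"network"` (drop all disease/phenotype edges), `"go"` (remove the gene
#'   from every gene-set term), `"variant_link"` (drop all variant-gene
#'   links), `"missense"` (demote missense consequences to `other`),
#'   `"missense_r2_boundary"` (set the r-squared of the gene's missense
#'   proxies to exactly 0.80, the excluded boundary), or `"expression"`
#'   (flatten whole-blood expression to a trace level).
#' @return `dir`, invisibly.
#' @export
ablate_evidence <- function(dir, gene,
                            type = c("eqtl", "network", "go", "variant_link",
                                     "missense", "missense_r2_boundary",
                                     "expression")) {
  type <- match.arg(type)
  gene <- normalize_symbols(gene)
  f <- setNames(file.path(dir, bundle_files()), names(bundle_files()))
  rewrite <- function(path, fn) {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    readr::write_tsv(fn(df), path, progress = FALSE)
  }
  if (type == "eqtl") {
    rewrite(f[["eqtl"]], function(df) {
      df[!(df$gene == gene & df$significant == "1"), ]
    })
  } else if (type == "network") {
    rewrite(f[["edges"]], function(df) df[df$gene != gene, ])
  } else if (type == "go") {
    for (key in c("go_bp", "go_cc", "go_mf")) {
      coll <- read_gmt(f[[key]])
      coll$members <- purrr::map(coll$members, setdiff, gene)
      coll <- coll[purrr::map_int(coll$members, length) > 0, ]
      write_gmt(coll, f[[key]])
    }
  } else if (type == "variant_link") {
    rewrite(f[["variant_links"]], function(df) df[df$gene != gene, ])
  } else if (type == "missense") {
    rewrite(f[["variant_links"]], function(df) {
      hit <- df$gene == gene & df$consequence == "missense"
      df$consequence[hit] <- "other"
      df
    })
  } else if (type == "missense_r2_boundary") {
    links <- read_variant_links(f[["variant_links"]])
    rsids <- links$rsid[links$gene == gene & links$consequence == "missense"]
    rewrite(f[["ld_panel"]], function(df) {
      df$r2[df$proxy_rsid %in% rsids] <- "0.80"
      df
    })
  } else if (type == "expression") {
    tmap <- readr::read_tsv(f[["tissue_map"]],
                            col_types = readr::cols(.default = "c"),
                            progress = FALSE)
    blood <- tmap$sample_id[tmap$tissue == "Whole Blood"]
    rewrite(f[["expression"]], function(df) {
      df[df$gene == gene, blood] <- "0.01"
      df
    })
  }
  invisible(dir)
}

#' Compare pipeline output against planted ground truth
#'
#' Per-stage set-equality report between a bundle's ground truth and the
#' stage sets recorded in a pipeline report run on that bundle.
#'
#' @param ground_truth `dvt_ground_truth` from [generate_bundle()].
#' @param report `dvt_report` from [run_pipeline()] on the same bundle.
#' @return Tibble with columns `stage`, `expected_n`, `observed_n`, `match`;
#'   all-`TRUE` `match` means full recovery.
#' @export
verify_recovery <- function(ground_truth, report) {
  stages <- c("significant_snps", "expanded_snps", "mapped_genes",
              "risk_genes", "term_genes", "network_genes",
              "selected_biomarkers")
  purrr::map_dfr(stages, function(st) {
    exp_set <- ground_truth[[st]]
    obs_set <- report$sets[[st]]
    tibble::tibble(
      stage = st,
      expected_n = length(exp_set),
      observed_n = length(obs_set),
      match = setequal(exp_set, obs_set)
    )
  })
}
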
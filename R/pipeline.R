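#' Configure a pipeline run
#'
#' Collects every threshold of the workflow and the input file paths. All
#' thresholds are read from this object by [run_pipeline()], never
#' hard-coded: the genome-wide significance level, the top-SNP cut, the LD
#' threshold and population, the minimum annotation score, the FDR level
#' and minimum overlap for enrichment, the coagulation term filter, the
#' disease labels, and the blood detectability threshold.
#'
#' @param input_dir Directory holding the input files under the
#'   [bundle_files()] names; individual paths can be overridden via `files`.
#' @param out_dir If non-NULL, every intermediate is materialized there as
#'   TSV (plus `report.json`), so each set reduction of the workflow is
#'   auditable.
#' @param alpha Genome-wide significance threshold (strict "<").
#' @param top_n Top-SNP cut for the first annotation criterion.
#' @param r2_min LD proxy threshold (strict ">").
#' @param population LD panel population label.
#' @param min_score Minimum annotation score (non-strict ">=").
#' @param fdr FDR threshold for enrichment and GO criteria.
#' @param min_overlap Minimum term overlap tested.
#' @param term_filter Names of the enriched terms whose member genes are
#'   carried into the network stage.
#' @param disease_labels Disease concept labels defining a direct link.
#' @param tpm_min Blood detectability threshold in TPM (non-strict ">=").
#' @param universe Optional enrichment background; default all collection
#'   genes.
#' @param files Optional named character vector overriding entries of
#'   [bundle_files()] (absolute paths).
#' @return A `dvt_pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir = NULL,
                            alpha = 5e-8, top_n = 40, r2_min = 0.8,
                            population = "ASN", min_score = 3, fdr = 0.05,
                            min_overlap = 2,
                            term_filter = c("coagulation",
                                            "regulation of response to wounding",
                                            "wound healing"),
                            disease_labels = c("deep vein thrombosis",
                                               "thrombophilia"),
                            tpm_min = 1.0, universe = NULL, files = NULL) {
  stopifnot(alpha > 0, alpha < 1, top_n >= 1, r2_min >= 0, r2_min <= 1,
            min_score >= 0, min_score <= 7, fdr > 0, fdr <= 1,
            min_overlap >= 0, tpm_min >= 0)
  paths <- setNames(file.path(input_dir, bundle_files()),
                    names(bundle_files()))
  if (!is.null(files)) {
    bad <- setdiff(names(files), names(paths))
    if (length(bad) > 0) {
      abort(paste0("Unknown file key(s): ", paste(bad, collapse = ", ")))
    }
    paths[names(files)] <- files
  }
  structure(
    list(
      files = paths, out_dir = out_dir, alpha = alpha, top_n = top_n,
      r2_min = r2_min, population = population, min_score = min_score,
      fdr = fdr, min_overlap = min_overlap, term_filter = term_filter,
      disease_labels = disease_labels, tpm_min = tpm_min,
      universe = universe
    ),
    class = "dvt_pipeline_config"
  )
}

#' Run the biomarker prioritization pipeline end-to-end
#'
#' Executes the full chain of set reductions: catalog ingestion, genome-wide
#' significance filtering, top-SNP selection, LD proxy expansion, gene
#' mapping, the seven-criterion scorecard, GO over-representation, extraction
#' of the coagulation/wound-term genes, disease-network filtering, and the
#' blood expression + eQTL biomarker call. Any stage failure aborts with the
#' stage name; intermediates written so far are retained.
#'
#' @param config A `dvt_pipeline_config` from [pipeline_config()].
#' @return A `dvt_report` list: `stages` (per-stage counts and artifact
#'   paths), `sets` (the per-stage SNP/gene sets), `profiles` (the
#'   scorecard), `enrichment`, `calls`, `selected_biomarkers` and
#'   `metadata`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "dvt_pipeline_config"))
  missing <- config$files[!file.exists(config$files)]
  if (length(missing) > 0) {
    abort(paste0("Missing input file(s): ",
                 paste(missing, collapse = ", ")))
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  emit <- function(df, name) {
    if (is.null(out_dir)) return(NA_character_)
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path, progress = FALSE)
    path
  }
  stages <- list()
  log_stage <- function(stage, n_in, n_out, artifact = NA_character_) {
    inform(sprintf("[%s] %d -> %d", stage, n_in, n_out))
    stages[[length(stages) + 1]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_out = n_out, artifact = artifact
    )
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", stage, "' failed: ",
                   conditionMessage(e)), class = "dvt_stage_error")
    })
  }

  ## ingest + filter + top-N
  assoc <- run_stage("ingest", read_associations(config$files[["associations"]]))
  sig <- run_stage("filter", filter_genomewide(assoc, config$alpha))
  log_stage("filter_genomewide", nrow(assoc), nrow(sig),
            emit(dplyr::mutate(sig, mapped_genes = purrr::map_chr(
              .data$mapped_genes, paste, collapse = ", ")),
              "associations_significant.tsv"))
  top <- run_stage("top_snps", select_top_snps(assoc, config$top_n))
  top_genes <- top_mapped_genes(top)
  log_stage("select_top_snps", nrow(assoc), nrow(top))

  ## LD expansion + gene mapping
  panel <- run_stage("ld_panel", read_ld_panel(config$files[["ld_panel"]]))
  seeds <- unique(sig$rsid)
  expanded <- run_stage("expand", expand_snps(panel, seeds,
                                              r2_min = config$r2_min,
                                              population = config$population))
  log_stage("expand_snps", length(seeds), length(expanded),
            emit(tibble::tibble(rsid = expanded), "expanded_snps.tsv"))
  links <- run_stage("links", read_variant_links(config$files[["variant_links"]]))
  gene_map <- run_stage("map_genes", map_to_genes(links, expanded))
  mapped_genes <- gene_map$gene
  log_stage("map_to_genes", length(expanded), length(mapped_genes),
            emit(dplyr::mutate(gene_map, rsids = purrr::map_chr(
              .data$rsids, paste, collapse = ";")), "gene_map.tsv"))

  ## scorecard
  collections <- run_stage("gmt", list(
    BP = read_gmt(config$files[["go_bp"]], "BP"),
    CC = read_gmt(config$files[["go_cc"]], "CC"),
    MF = read_gmt(config$files[["go_mf"]], "MF")
  ))
  go_flags <- run_stage("go_flags", go_criterion_flags(
    mapped_genes, collections, mapped_genes,
    fdr = config$fdr, min_overlap = config$min_overlap
  ))
  eqtl <- run_stage("eqtl", read_eqtl(config$files[["eqtl"]]))
  pid <- run_stage("pid", read_gene_list(config$files[["pid"]]))
  ld_variants <- links[links$rsid %in% expanded, , drop = FALSE]
  profiles <- run_stage("scorecard", build_profiles(
    mapped_genes, top_genes, ld_variants, eqtl, go_flags, pid
  ))
  risk <- risk_genes(profiles, config$min_score)
  log_stage("risk_genes", length(mapped_genes), length(risk),
            emit(profiles[, c("gene", criterion_flags(), "score")] |>
                   dplyr::mutate(dplyr::across(dplyr::all_of(criterion_flags()),
                                               as.integer)),
                 "scorecard.tsv"))

  ## enrichment of the risk set + term-gene extraction
  enr <- run_stage("enrich", enrich(risk, collections$BP,
                                    universe = config$universe,
                                    fdr = config$fdr,
                                    min_overlap = config$min_overlap))
  term_genes <- run_stage("term_genes", genes_in_terms(
    enr, collections$BP, risk, config$term_filter, fdr = config$fdr
  ))
  log_stage("genes_in_terms", length(risk), length(term_genes),
            emit(tibble::as_tibble(enr[, setdiff(names(enr), "namespace")]),
                 "enrichment_bp.tsv"))

  ## network filtering
  edges <- run_stage("edges", read_disease_edges(config$files[["edges"]]))
  net_genes <- run_stage("network", direct_disease_genes(
    edges, term_genes, disease_labels = config$disease_labels
  ))
  log_stage("direct_disease_genes", length(term_genes), length(net_genes),
            emit(tibble::tibble(gene = net_genes), "network_genes.tsv"))

  ## expression + biomarker call
  expr <- run_stage("expression", read_expression(
    config$files[["expression"]], config$files[["tissue_map"]]
  ))
  summaries <- run_stage("tissue_summary", tissue_summary(expr, net_genes))
  eqtl_flags <- tibble::tibble(
    gene = unique(c(net_genes, eqtl$gene)),
    has_blood_eqtl = unique(c(net_genes, eqtl$gene)) %in%
      eqtl$gene[eqtl$significant]
  )
  calls <- run_stage("biomarkers", call_biomarkers(
    summaries, eqtl_flags, genes = net_genes, tpm_min = config$tpm_min
  ))
  selected <- calls$gene[calls$selected]
  log_stage("call_biomarkers", length(net_genes), length(selected),
            emit(tibble::as_tibble(calls), "biomarker_calls.tsv"))

  report <- structure(
    list(
      config = config,
      stages = dplyr::bind_rows(stages),
      sets = list(
        significant_snps = sort(unique(sig$rsid)),
        expanded_snps = sort(as.character(expanded)),
        mapped_genes = sort(mapped_genes),
        top_genes = sort(top_genes),
        risk_genes = sort(risk),
        term_genes = sort(term_genes),
        network_genes = sort(net_genes),
        selected_biomarkers = sort(selected)
      ),
      profiles = profiles,
      enrichment = enr,
      summaries = summaries,
      calls = calls,
      selected_biomarkers = sort(selected),
      metadata = list(
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        package_version = as.character(utils::packageVersion("dvtmark"))
      )
    ),
    class = "dvt_report"
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(
        stages = report$stages,
        counts = glance(report),
        sets = report$sets,
        metadata = report$metadata
      ),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  report
}

#' @export
print.dvt_report <- function(x, ...) {
  cat("DVT biomarker pipeline report\n")
  print(x$stages, n = Inf)
  cat("Selected biomarkers:",
      if (length(x$selected_biomarkers) == 0) "(none)" else
        paste(x$selected_biomarkers, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the per-stage counts of a pipeline report
#' @param x A `dvt_report`.
#' @param ... Unused.
#' @return Tibble with columns `stage`, `n_in`, `n_out`, `artifact`.
#' @method tidy dvt_report
#' @export
tidy.dvt_report <- function(x, ...) {
  x$stages
}

#' One-row summary of a pipeline report
#' @param x A `dvt_report`.
#' @param ... Unused.
#' @return One-row tibble with the count at each stage of the reduction
#'   chain and the selected biomarkers collapsed into one string.
#' @method glance dvt_report
#' @export
glance.dvt_report <- function(x, ...) {
  s <- x$sets
  tibble::tibble(
    n_snps = x$stages$n_in[x$stages$stage == "filter_genomewide"],
    n_significant = length(s$significant_snps),
    n_expanded = length(s$expanded_snps),
    n_mapped_genes = length(s$mapped_genes),
    n_risk_genes = length(s$risk_genes),
    n_term_genes = length(s$term_genes),
    n_network_genes = length(s$network_genes),
    n_selected = length(s$selected_biomarkers),
    selected = paste(s$selected_biomarkers, collapse = ",")
  )
}
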
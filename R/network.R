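#' Read a gene-concept bipartite edge list
#'
#' Edges link genes to disease or phenotype concepts (the offline analogue
#' of a gene-disease knowledge graph). Malformed rows (any empty required
#' field) are rejected with their line numbers; duplicate edges are
#' collapsed.
#'
#' @param path TSV with columns `gene`, `concept_id`, `concept_label`,
#'   `source` (`disease` or `phenotype`).
#' @return A tibble of class `dvt_bipartite` with one row per distinct edge;
#'   attribute `"rejected_lines"` lists rejected data-row numbers.
#' @export
read_disease_edges <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, comment = "#")
  need <- c("gene", "concept_id", "concept_label", "source")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Edge list is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  ok <- rep(TRUE, nrow(raw))
  for (col in need) {
    ok <- ok & !is.na(raw[[col]]) & nzchar(stringr::str_trim(raw[[col]]))
  }
  if (any(!ok)) {
    warn(paste0("Rejected ", sum(!ok), " malformed edge row(s) at line(s): ",
                paste(which(!ok), collapse = ", ")))
  }
  out <- tibble::tibble(
    gene = toupper(stringr::str_trim(raw$gene[ok])),
    concept_id = raw$concept_id[ok],
    concept_label = raw$concept_label[ok],
    source = raw$source[ok]
  ) |>
    dplyr::distinct(.data$gene, .data$concept_id, .keep_all = TRUE)
  attr(out, "rejected_lines") <- which(!ok)
  class(out) <- c("dvt_bipartite", class(out))
  out
}

#' Genes with a direct edge to target disease concepts
#'
#' Selects the query genes incident to at least one concept whose label is
#' in `disease_labels` (matched case-insensitively). "Direct link" means
#' edge incidence; the graph carries no edge-weight statistic, so no scoring
#' beyond adjacency is applied.
#'
#' @param edges Bipartite edge tibble from [read_disease_edges()].
#' @param query_genes Character vector of candidate gene symbols.
#' @param disease_labels Target concept labels (default the deep-vein
#'   thrombosis and thrombophilia concepts).
#' @param sources Concept sources to consider; default both `disease` and
#'   `phenotype` ("either" semantics), restrict to one to require a specific
#'   ontology.
#' @return Sorted character vector, a subset of `query_genes`.
#' @export
direct_disease_genes <- function(edges, query_genes,
                                 disease_labels = c("deep vein thrombosis",
                                                    "thrombophilia"),
                                 sources = c("disease", "phenotype")) {
  query_genes <- unique(normalize_symbols(query_genes))
  hit_concepts <- tolower(edges$concept_label) %in% tolower(disease_labels) &
    edges$source %in% sources
  if (!any(hit_concepts)) {
    warn("No concept in the graph matches any requested disease label.")
    return(character())
  }
  sort(intersect(query_genes, edges$gene[hit_concepts]))
}
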
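#' Read a tissue expression matrix
#'
#' Loads a GCT-like TPM matrix (first column gene symbol, one column per
#' sample) together with a companion sample-to-tissue map, and returns the
#' values in long form. Genes with all-missing rows are dropped with a
#' warning; a sample present in the matrix but absent from the tissue map is
#' a configuration error naming the sample.
#'
#' @param path Expression TSV: column `gene`, then one numeric column per
#'   sample.
#' @param tissue_map_path TSV with columns `sample_id`, `tissue`.
#' @return Long tibble with columns `gene`, `sample_id`, `tissue`, `tpm`.
#' @export
read_expression <- function(path, tissue_map_path) {
  mat <- readr::read_tsv(path, col_types = readr::cols(
    gene = "c", .default = "d"
  ), progress = FALSE)
  if (!"gene" %in% names(mat)) {
    abort("Expression matrix must have a 'gene' first column.")
  }
  tmap <- readr::read_tsv(tissue_map_path,
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  missing_cols <- setdiff(c("sample_id", "tissue"), names(tmap))
  if (length(missing_cols) > 0) {
    abort(paste0("Tissue map is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  samples <- setdiff(names(mat), "gene")
  unmapped <- setdiff(samples, tmap$sample_id)
  if (length(unmapped) > 0) {
    abort(paste0("Sample(s) in the expression matrix missing from the ",
                 "tissue map: ", paste(unmapped, collapse = ", ")))
  }
  all_na <- apply(is.na(mat[, samples, drop = FALSE]), 1, all)
  if (any(all_na)) {
    warn(paste0("Dropping ", sum(all_na), " gene(s) with all-missing ",
                "expression: ",
                paste(mat$gene[all_na], collapse = ", ")))
    mat <- mat[!all_na, ]
  }
  mat |>
    dplyr::mutate(gene = toupper(stringr::str_trim(.data$gene))) |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "tpm") |>
    dplyr::left_join(tmap, by = "sample_id") |>
    dplyr::select("gene", "sample_id", "tissue", "tpm")
}

#' Per-tissue expression summaries
#'
#' Median and interquartile range of TPM per gene and tissue (the median,
#' not the mean, is the central tendency used throughout: it matches the
#' violin-plot reading and is robust to the heavy upper tails typical of
#' blood expression).
#'
#' @param expr Long expression tibble from [read_expression()].
#' @param genes Genes to summarize; all must be present in the matrix.
#' @param tissues Tissues to summarize (default Liver and Whole Blood); each
#'   must have at least one sample.
#' @return Tibble with columns `gene`, `tissue`, `n_samples`, `median_tpm`,
#'   `iqr_tpm`.
#' @export
tissue_summary <- function(expr, genes,
                           tissues = c("Liver", "Whole Blood")) {
  genes <- unique(normalize_symbols(genes))
  unknown <- setdiff(genes, unique(expr$gene))
  if (length(unknown) > 0) {
    abort(paste0("Gene(s) absent from the expression matrix: ",
                 paste(unknown, collapse = ", ")))
  }
  empty <- setdiff(tissues, unique(expr$tissue))
  if (length(empty) > 0) {
    abort(paste0("Tissue(s) with no samples: ", paste(empty, collapse = ", ")))
  }
  expr |>
    dplyr::filter(.data$gene %in% genes, .data$tissue %in% tissues,
                  !is.na(.data$tpm)) |>
    dplyr::group_by(.data$gene, .data$tissue) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      median_tpm = median(.data$tpm),
      iqr_tpm = IQR(.data$tpm),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene, .data$tissue)
}

#' Call blood-based biomarkers
#'
#' A gene is selected as a practical blood biomarker when it is detectable
#' in whole blood (blood median TPM at or above `tpm_min`) AND carries a
#' significant whole-blood eQTL — i.e. it is both measurable in an easily
#' collected sample and its genetic variation demonstrably acts on
#' expression there. Genes with a missing blood or liver summary or eQTL
#' flag yield a per-gene error entry (`error` column) while the rest are
#' still called.
#'
#' @param summaries Tissue summaries from [tissue_summary()] covering
#'   `"Whole Blood"` and `"Liver"`.
#' @param eqtl_flags Tibble with columns `gene`, `has_blood_eqtl` (logical).
#' @param genes Genes to call; defaults to all genes in `summaries`.
#' @param tpm_min Blood detectability threshold in TPM (non-strict ">=").
#' @return Tibble of class `dvt_biomarker_calls` with columns `gene`,
#'   `has_blood_eqtl`, `blood_median_tpm`, `liver_median_tpm`,
#'   `blood_detectable`, `selected`, `error`; sorted selected-first, then by
#'   blood median descending.
#' @export
call_biomarkers <- function(summaries, eqtl_flags, genes = NULL,
                            tpm_min = 1.0) {
  genes <- sort(unique(normalize_symbols(genes %||% summaries$gene)))
  wide <- summaries |>
    dplyr::filter(.data$tissue %in% c("Whole Blood", "Liver")) |>
    dplyr::select("gene", "tissue", "median_tpm") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "median_tpm")
  for (col in c("Whole Blood", "Liver")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  if (!"gene" %in% names(wide)) wide$gene <- character()
  out <- tibble::tibble(gene = genes) |>
    dplyr::left_join(wide, by = "gene") |>
    dplyr::left_join(eqtl_flags[, c("gene", "has_blood_eqtl")], by = "gene") |>
    dplyr::rename(blood_median_tpm = "Whole Blood",
                  liver_median_tpm = "Liver")
  out$error <- dplyr::case_when(
    is.na(out$blood_median_tpm) ~ "missing whole-blood summary",
    is.na(out$liver_median_tpm) ~ "missing liver summary",
    is.na(out$has_blood_eqtl) ~ "missing eQTL flag",
    TRUE ~ NA_character_
  )
  out$blood_detectable <- !is.na(out$blood_median_tpm) &
    out$blood_median_tpm >= tpm_min
  out$selected <- is.na(out$error) & out$blood_detectable &
    out$has_blood_eqtl
  out |>
    dplyr::arrange(dplyr::desc(.data$selected),
                   dplyr::desc(.data$blood_median_tpm)) |>
    structure(class = c("dvt_biomarker_calls", class(out)))
}

#' Plot per-tissue expression of candidate genes
#'
#' Strip + box summary of TPM per gene and tissue, the simple replacement
#' for per-gene violin plots.
#'
#' @param object Long expression tibble from [read_expression()].
#' @param genes Genes to display.
#' @param tissues Tissues to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_tissue_expression <- function(object, genes,
                                   tissues = c("Liver", "Whole Blood"), ...) {
  df <- dplyr::filter(object, .data$gene %in% normalize_symbols(genes),
                      .data$tissue %in% tissues)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$tpm,
                                   fill = .data$tissue)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 0.6, alpha = 0.5) +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "TPM") +
    ggplot2::theme(legend.position = "none")
  }
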
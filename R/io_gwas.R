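#' Default GWAS-Catalog association column names
#'
#' Header names of the tab-separated association dialect read by
#' [read_associations()]. Override individual entries through `column_map`.
#'
#' @return Named character vector mapping internal field names to file headers.
#' @export
gwas_catalog_columns <- function() {
  c(
    rsid = "SNPS",
    chrom = "CHR_ID",
    pos = "CHR_POS",
    pvalue = "P-VALUE",
    mapped_genes = "MAPPED_GENE",
    trait = "DISEASE/TRAIT",
    study_id = "STUDY ACCESSION"
  )
}

#' Read a GWAS-Catalog-style association table
#'
#' Parses a tab-separated association table into one record per row. Multi-gene
#' "mapped gene" cells are split on commas, semicolons, intergenic `"A - B"`
#' dashes (both flanking genes kept) and `" x "` interaction markers into an
#' ordered list of symbols. Chromosome labels are normalized by stripping a
#' `chr` prefix and upper-casing X/Y. Rows whose p-value cannot be parsed (or
#' is outside `(0, 1]`) are dropped; the number dropped is attached as the
#' `"n_dropped"` attribute and reported.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Optional named character vector overriding entries of
#'   [gwas_catalog_columns()] (names are internal field names, values the
#'   file's header names).
#' @return A tibble with columns `rsid`, `chrom`, `pos`, `pvalue`, `trait`,
#'   `mapped_genes` (list column of character vectors), `study_id`.
#' @export
read_associations <- function(path, column_map = NULL) {
  cols <- gwas_catalog_columns()
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(cols))
    if (length(bad) > 0) {
      abort(paste0("Unknown column_map field(s): ", paste(bad, collapse = ", ")))
    }
    cols[names(column_map)] <- column_map
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = c("", "NA"))
  missing <- setdiff(unname(cols), names(raw))
  if (length(missing) > 0) {
    abort(paste0("Association table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    warn("Association table has a header but no rows; returning empty table.")
    return(empty_associations())
  }
  out <- tibble::tibble(
    rsid = stringr::str_trim(raw[[cols[["rsid"]]]]),
    chrom = normalize_chrom(raw[[cols[["chrom"]]]]),
    pos = suppressWarnings(as.integer(raw[[cols[["pos"]]]])),
    pvalue = suppressWarnings(as.numeric(raw[[cols[["pvalue"]]]])),
    trait = raw[[cols[["trait"]]]],
    mapped_genes = purrr::map(raw[[cols[["mapped_genes"]]]], split_gene_cell),
    study_id = raw[[cols[["study_id"]]]]
  )
  ok <- !is.na(out$pvalue) & out$pvalue > 0 & out$pvalue <= 1
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(paste0("Dropped ", n_dropped, " row(s) with unparseable or ",
                  "out-of-range p-values."))
  }
  out <- out[ok, ]
  attr(out, "n_dropped") <- n_dropped
  out
}

empty_associations <- function() {
  tibble::tibble(
    rsid = character(), chrom = character(), pos = integer(),
    pvalue = double(), trait = character(),
    mapped_genes = list(), study_id = character()
  )
}

#' Write associations in the GWAS-Catalog dialect
#'
#' Inverse of [read_associations()]; mapped-gene lists are joined with ", ".
#'
#' @param assoc Association tibble as returned by [read_associations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  cols <- gwas_catalog_columns()
  out <- tibble::tibble(
    !!cols[["rsid"]] := assoc$rsid,
    !!cols[["chrom"]] := assoc$chrom,
    !!cols[["pos"]] := assoc$pos,
    !!cols[["pvalue"]] := format(assoc$pvalue, scientific = TRUE, digits = 15),
    !!cols[["mapped_genes"]] := purrr::map_chr(
      assoc$mapped_genes, ~ paste(.x, collapse = ", ")
    ),
    !!cols[["trait"]] := assoc$trait,
    !!cols[["study_id"]] := assoc$study_id
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Filter associations at genome-wide significance
#'
#' Keeps exactly the rows with `pvalue` strictly below `alpha` (the
#' conventional genome-wide threshold 5e-8 by default). A record at the
#' boundary is excluded. Input order is preserved and duplicate rsIDs from
#' different studies are retained: SNP counting follows catalog rows, and
#' deduplication happens only when gene sets are formed downstream.
#'
#' @param assoc Association tibble.
#' @param alpha Significance threshold in (0, 1).
#' @return The filtered tibble.
#' @export
filter_genomewide <- function(assoc, alpha = 5e-8) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  dplyr::filter(assoc, .data$pvalue < alpha)
}

#' Select the top-N most significant SNPs
#'
#' Returns the `n` records with the smallest p-values. Ties at the boundary
#' are broken deterministically by (chromosome order, position, rsID); if
#' fewer than `n` records exist, all are returned.
#'
#' @param assoc Association tibble.
#' @param n Number of SNPs to keep (>= 1).
#' @return A tibble of at most `n` rows, ordered by ascending p-value.
#' @export
select_top_snps <- function(assoc, n = 40) {
  stopifnot(n >= 1)
  chrom_rank <- match(assoc$chrom, chromosome_levels())
  ord <- order(assoc$pvalue, chrom_rank, assoc$pos, assoc$rsid)
  assoc[head(ord, n), ]
}

#' Genes mapped by a set of SNP records
#'
#' Union of the mapped-gene lists across records, deduplicated and
#' upper-cased.
#'
#' @param assoc Association tibble (typically the top-N selection).
#' @return Sorted character vector of gene symbols.
#' @export
top_mapped_genes <- function(assoc) {
  sort(unique(normalize_symbols(unlist(assoc$mapped_genes))))
}

#' Manhattan-plot coordinates
#'
#' Lays SNPs on a genome-wide linear axis: chromosomes are ordered 1-22, X, Y;
#' within the axis each SNP sits at its base-pair position plus the summed
#' spans of all preceding observed chromosomes (a chromosome's span is the
#' maximum position observed on it). The y-axis value is -log10(p).
#' Records on unrecognized chromosome labels are skipped with a warning.
#'
#' @param assoc Association tibble.
#' @param alpha Genome-wide significance threshold; drawn as a reference line
#'   by [autoplot.dvt_manhattan()].
#' @param top_n If non-NULL, the p-value of the `top_n`-th ranked SNP defines
#'   a second reference line (the top-SNP cut); exposed as the computed
#'   attribute `"top_line"`, never a constant.
#' @return A tibble of class `dvt_manhattan` with columns `rsid`, `chrom`,
#'   `pos`, `cumulative_x`, `neglog10p`, ordered by genome position, plus
#'   attributes `genomewide_line` and (optionally) `top_line` on the
#'   -log10 scale.
#' @export
manhattan_coordinates <- function(assoc, alpha = 5e-8, top_n = NULL) {
  known <- assoc$chrom %in% chromosome_levels()
  if (any(!known)) {
    warn(paste0("Skipping ", sum(!known), " record(s) on unknown chromosome ",
                "label(s): ",
                paste(unique(assoc$chrom[!known]), collapse = ", ")))
  }
  df <- assoc[known, c("rsid", "chrom", "pos", "pvalue")]
  df$chrom <- factor(df$chrom, levels = chromosome_levels())
  spans <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(span = max(.data$pos), .groups = "drop") |>
    dplyr::arrange(.data$chrom) |>
    dplyr::mutate(offset = dplyr::lag(cumsum(as.numeric(.data$span)),
                                      default = 0))
  out <- df |>
    dplyr::left_join(spans[, c("chrom", "offset")], by = "chrom") |>
    dplyr::mutate(
      cumulative_x = .data$offset + .data$pos,
      neglog10p = -log10(.data$pvalue)
    ) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::select("rsid", "chrom", "pos", "cumulative_x", "neglog10p")
  attr(out, "genomewide_line") <- -log10(alpha)
  if (!is.null(top_n) && nrow(df) > 0) {
    p_sorted <- sort(df$pvalue)
    attr(out, "top_line") <- -log10(p_sorted[min(top_n, length(p_sorted))])
  }
  class(out) <- c("dvt_manhattan", class(out))
  out
}

#' Plot Manhattan coordinates
#'
#' Standard Manhattan plot: alternating chromosome shading, a dashed line at
#' the genome-wide threshold and, when computed, a second dashed line at the
#' top-SNP cut.
#'
#' @param object A `dvt_manhattan` tibble from [manhattan_coordinates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dvt_manhattan
#' @export
autoplot.dvt_manhattan <- function(object, ...) {
  chrom_parity <- (match(object$chrom, chromosome_levels()) %% 2) == 0
  p <- ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$cumulative_x, y = .data$neglog10p)
  ) +
    ggplot2::geom_point(ggplot2::aes(colour = chrom_parity),
                        show.legend = FALSE, size = 0.8) +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::geom_hline(yintercept = attr(object, "genomewide_line"),
                        linetype = "dashed", colour = "black") +
    ggplot2::labs(x = "Genome position", y = expression(-log[10](p)))
  if (!is.null(attr(object, "top_line"))) {
    p <- p + ggplot2::geom_hline(yintercept = attr(object, "top_line"),
                                 linetype = "dashed", colour = "red")
  }
  p
}
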
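#' Read a linkage-disequilibrium proxy panel
#'
#' Parses a tab-separated panel of seed-to-proxy LD links. Rows with an
#' r-squared value outside `[0, 1]` (or unparseable) are rejected row-wise
#' with their line numbers reported; valid rows are kept.
#'
#' @param path TSV with columns `seed_rsid`, `proxy_rsid`, `r2`, `population`.
#' @return A tibble with those four columns; rejected line numbers (1-based,
#'   counting data rows) in attribute `"rejected_lines"`.
#' @export
read_ld_panel <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, comment = "#")
  need <- c("seed_rsid", "proxy_rsid", "r2", "population")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("LD panel is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  r2 <- suppressWarnings(as.numeric(raw$r2))
  ok <- !is.na(r2) & r2 >= 0 & r2 <= 1
  if (any(!ok)) {
    warn(paste0("Rejected ", sum(!ok), " LD panel row(s) with malformed r2 ",
                "at line(s): ", paste(which(!ok), collapse = ", ")))
  }
  out <- tibble::tibble(
    seed_rsid = raw$seed_rsid[ok],
    proxy_rsid = raw$proxy_rsid[ok],
    r2 = r2[ok],
    population = raw$population[ok]
  )
  attr(out, "rejected_lines") <- which(!ok)
  out
}

#' Expand seed SNPs to their LD proxies
#'
#' Returns the seeds together with every panel proxy linked to a seed at
#' r-squared strictly greater than `r2_min` in the matching population
#' (mirroring the r2 > 0.8 proxy-expansion convention; a proxy at exactly
#' `r2_min` is excluded). Seeds absent from the panel pass through
#' unexpanded; they are counted in the `"n_unexpanded_seeds"` attribute,
#' never dropped.
#'
#' @param panel LD panel tibble from [read_ld_panel()].
#' @param seeds Character vector of seed rsIDs.
#' @param r2_min LD threshold in `[0, 1]`; strict ">" comparison.
#' @param population Exact panel label to match (default `"ASN"`).
#' @return Sorted character vector of distinct rsIDs (superset of `seeds`).
#' @export
expand_snps <- function(panel, seeds, r2_min = 0.8, population = "ASN") {
  stopifnot(is.numeric(r2_min), r2_min >= 0, r2_min <= 1)
  seeds <- unique(as.character(seeds))
  if (nrow(panel) == 0) {
    warn("LD panel is empty; returning seeds unexpanded.")
    return(sort(seeds))
  }
  hits <- panel[panel$population == population &
                  panel$seed_rsid %in% seeds &
                  panel$r2 > r2_min, , drop = FALSE]
  out <- sort(unique(c(seeds, hits$proxy_rsid)))
  n_unexpanded <- sum(!(seeds %in% panel$seed_rsid[panel$population == population]))
  attr(out, "n_unexpanded_seeds") <- n_unexpanded
  out
}

#' Read variant-to-gene consequence links
#'
#' @param path TSV with columns `rsid`, `gene`, `consequence`
#'   (`missense` or `other`).
#' @return A tibble with those columns; rows with an empty gene symbol are
#'   rejected with line numbers reported.
#' @export
read_variant_links <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, comment = "#")
  need <- c("rsid", "gene", "consequence")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Variant link table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  ok <- !is.na(raw$gene) & nzchar(stringr::str_trim(raw$gene))
  if (any(!ok)) {
    warn(paste0("Rejected ", sum(!ok), " variant link row(s) with empty gene ",
                "symbol at line(s): ", paste(which(!ok), collapse = ", ")))
  }
  tibble::tibble(
    rsid = raw$rsid[ok],
    gene = toupper(stringr::str_trim(raw$gene[ok])),
    consequence = raw$consequence[ok]
  )
}

#' Map an expanded SNP set to genes
#'
#' Inverts the variant-gene links restricted to `snps` into a gene-to-SNPs
#' index. SNPs with no link are reported separately in the `"unmapped"`
#' attribute.
#'
#' @param links Variant-gene link tibble from [read_variant_links()].
#' @param snps Character vector of rsIDs.
#' @return A tibble with columns `gene`, `rsids` (list column) and `n_snps`,
#'   one row per distinct gene, sorted by symbol.
#' @export
map_to_genes <- function(links, snps) {
  snps <- unique(as.character(snps))
  hit <- links[links$rsid %in% snps, , drop = FALSE]
  out <- hit |>
    dplyr::distinct(.data$gene, .data$rsid) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(rsids = list(sort(.data$rsid)),
                     n_snps = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$gene)
  attr(out, "unmapped") <- sort(setdiff(snps, hit$rsid))
  out
}
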
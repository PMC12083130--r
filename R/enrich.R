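#' Read gene sets in GMT format
#'
#' One term per line: `term_id TAB description TAB member TAB member ...`.
#' Lines starting with `#` are ignored.
#'
#' @param path GMT file path.
#' @param namespace Annotation namespace label to attach to every term
#'   (`"BP"`, `"CC"`, `"MF"`, `"disease"`, `"phenotype"` ...).
#' @return A tibble with columns `term_id`, `name`, `namespace` and `members`
#'   (list column of normalized symbols).
#' @export
read_gmt <- function(path, namespace = NA_character_) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- stringr::str_split(lines, "\t")
  bad <- which(purrr::map_int(fields, length) < 3)
  if (length(bad) > 0) {
    abort(paste0("GMT line(s) with fewer than 3 fields: ",
                 paste(bad, collapse = ", ")))
  }
  out <- tibble::tibble(
    term_id = purrr::map_chr(fields, 1),
    name = purrr::map_chr(fields, 2),
    namespace = namespace,
    members = purrr::map(fields, ~ unique(normalize_symbols(.x[-(1:2)])))
  )
  if (anyDuplicated(out$term_id)) {
    abort("Duplicate term_id values in GMT collection.")
  }
  if (any(purrr::map_int(out$members, length) == 0)) {
    abort("GMT term with no members.")
  }
  out
}

#' Write gene sets in GMT format
#' @param collection Tibble from [read_gmt()] (namespace column ignored).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(
    list(collection$term_id, collection$name, collection$members),
    function(id, nm, mem) paste(c(id, nm, mem), collapse = "\t")
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` annotated genes when `n` genes are drawn without replacement
#' from a universe of `N` genes of which `K` carry the annotation. The tail
#' includes `k` itself and is evaluated in log space for numerical stability
#' at large `N`.
#'
#' @param k Observed overlap count.
#' @param K Annotated genes in the universe.
#' @param n Query size in the universe.
#' @param N Universe size.
#' @return Probability in `(0, 1]`; vectorized over its arguments.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  args <- vctrs_recycle(k, K, n, N)
  k <- args[[1]]; K <- args[[2]]; n <- args[[3]]; N <- args[[4]]
  if (any(K < 0 | K > N | n < 0 | n > N | k < 0 | k > pmin(K, n))) {
    abort("hypergeom_upper_tail: need 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(K, n).")
  }
  ifelse(k == 0, 1,
         exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)))
}

# Minimal common-length recycling for scalar-or-vector numeric arguments.
vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, rep_len, length.out = n)
}

#' Enrichment ratio
#'
#' Observed over expected overlap, `(k/n) / (K/N)`. Undefined when the
#' expected overlap is zero, in which case `NA` is returned.
#'
#' @inheritParams hypergeom_upper_tail
#' @return Non-negative ratio (or `NA` when `K`, `n` or `N` is zero).
#' @export
enrichment_ratio <- function(k, K, n, N) {
  args <- vctrs_recycle(k, K, n, N)
  k <- args[[1]]; K <- args[[2]]; n <- args[[3]]; N <- args[[4]]
  ifelse(K > 0 & n > 0 & N > 0, (k / n) / (K / N), NA_real_)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: monotone, capped at 1, original
#' order preserved.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis of a gene set
#'
#' Tests each term of a GMT collection for over-representation of the query
#' genes with the hypergeometric upper tail, adjusting across all tested
#' terms by Benjamini-Hochberg. The universe defaults to all genes appearing
#' in the collection ("annotated genome" reference); query genes outside the
#' universe are reported and dropped from the test. Terms overlapping the
#' query by fewer than `min_overlap` genes are not tested and do not count
#' toward the number of hypotheses.
#'
#' @param query Character vector of gene symbols.
#' @param collection Gene-set tibble from [read_gmt()].
#' @param universe Optional character vector of background symbols; default
#'   is the union of all term members.
#' @param fdr Significance threshold on the adjusted p-value (annotation
#'   only; all tested terms are returned).
#' @param min_overlap Minimum query overlap for a term to be tested.
#' @return A tibble of class `dvt_enrichment` with columns `term_id`, `name`,
#'   `namespace`, `k`, `K`, `n`, `N`, `ratio`, `p`, `q`, `significant`,
#'   sorted by `q` then `p`.
#' @export
enrich <- function(query, collection, universe = NULL, fdr = 0.05,
                   min_overlap = 2) {
  if (is.null(universe)) {
    universe <- unique(unlist(collection$members))
  } else {
    universe <- unique(normalize_symbols(universe))
  }
  if (length(universe) == 0) {
    abort("Enrichment universe is empty.")
  }
  query <- unique(normalize_symbols(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    inform(paste0("Dropping ", length(outside), " query gene(s) absent from ",
                  "the universe: ", paste(sort(outside), collapse = ", ")))
  }
  query <- intersect(query, universe)
  N <- length(universe)
  n <- length(query)
  res <- collection |>
    dplyr::mutate(
      members_u = purrr::map(.data$members, intersect, universe),
      K = purrr::map_int(.data$members_u, length),
      k = purrr::map_int(.data$members_u, ~ length(intersect(.x, query)))
    ) |>
    dplyr::filter(.data$k >= min_overlap)
  out <- tibble::tibble(
    term_id = res$term_id,
    name = res$name,
    namespace = res$namespace,
    k = res$k, K = res$K, n = n, N = N,
    ratio = enrichment_ratio(res$k, res$K, n, N),
    p = if (nrow(res) == 0) double() else
      hypergeom_upper_tail(res$k, res$K, n, N)
  )
  out$q <- if (nrow(out) == 0) double() else bh_adjust(out$p)
  out$significant <- out$q <= fdr
  out <- dplyr::arrange(out, .data$q, .data$p, .data$term_id)
  attr(out, "query") <- sort(query)
  attr(out, "dropped_query") <- sort(outside)
  class(out) <- c("dvt_enrichment", class(out))
  out
}

#' Query genes driving significant terms
#'
#' Union, over the significant terms whose names pass `term_filter`, of the
#' intersection between term members and the query. This is the step that
#' extracts, e.g., the genes behind significantly enriched coagulation and
#' wound-healing terms.
#'
#' @param results `dvt_enrichment` tibble from [enrich()].
#' @param collection The collection the results were computed from.
#' @param query The same query gene set.
#' @param term_filter Character vector of term names to keep (matched
#'   case-insensitively), or a predicate function on term names.
#' @param fdr Adjusted-p threshold defining significance.
#' @return Sorted character vector of gene symbols.
#' @export
genes_in_terms <- function(results, collection, query, term_filter,
                           fdr = 0.05) {
  query <- unique(normalize_symbols(query))
  keep_name <- if (is.function(term_filter)) {
    term_filter(results$name)
  } else {
    tolower(results$name) %in% tolower(term_filter)
  }
  sig_ids <- results$term_id[results$q <= fdr & keep_name]
  mem <- collection$members[collection$term_id %in% sig_ids]
  sort(intersect(unique(unlist(mem)), query))
}

#' Bar plot of enrichment results
#'
#' Enrichment ratio per significant term, shaded by FDR, mirroring the usual
#' over-representation bar chart.
#'
#' @param object `dvt_enrichment` tibble.
#' @param top Number of top terms (by `q`) to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dvt_enrichment
#' @export
autoplot.dvt_enrichment <- function(object, top = 20, ...) {
  df <- head(tibble::as_tibble(object), top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$ratio,
    y = stats::reorder(.data$name, .data$ratio),
    fill = -log10(.data$q)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Enrichment ratio", y = NULL,
                  fill = expression(-log[10](FDR)))
}
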
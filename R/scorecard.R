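#' Names of the seven annotation criteria
#'
#' Flag columns of a gene annotation profile, in scorecard order:
#' membership among the top GWAS genes, a missense variant in strong LD,
#' a whole-blood eQTL, enriched Gene Ontology biological process, cellular
#' component and molecular function, and primary-immunodeficiency (PID)
#' list membership.
#'
#' @return Character vector of the seven flag column names.
#' @export
criterion_flags <- function() {
  c("is_top_gwas_gene", "has_missense_in_ld", "has_blood_eqtl",
    "go_bp", "go_cc", "go_mf", "is_pid_gene")
}

#' Read a whole-blood eQTL table
#'
#' @param path TSV with columns `rsid`, `gene`, `significant` (0/1 or
#'   TRUE/FALSE).
#' @return A tibble with `rsid`, `gene`, `significant` (logical).
#' @export
read_eqtl <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, comment = "#")
  need <- c("rsid", "gene", "significant")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("eQTL table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tibble::tibble(
    rsid = raw$rsid,
    gene = toupper(stringr::str_trim(raw$gene)),
    significant = stringr::str_trim(raw$significant) %in%
      c("1", "TRUE", "true", "T")
  )
}

#' Read a one-symbol-per-line gene list
#'
#' Used for the packaged PID (primary immunodeficiency) list and for plain
#' gene-set inputs. Lines starting with `#` are ignored.
#'
#' @param path Text file, one gene symbol per line.
#' @return Sorted character vector of normalized symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sort(unique(normalize_symbols(lines)))
}

#' Gene Ontology criterion flags from enrichment
#'
#' Flags a gene for a namespace (BP/CC/MF) when it belongs to at least one
#' term of that namespace significantly enriched (adjusted p <= `fdr`) in
#' the mapped-gene set. Raw term membership alone would flag nearly every
#' gene; tying the flag to enrichment keeps the criterion informative.
#'
#' @param genes Character vector of genes to flag.
#' @param collections Named list of GMT tibbles, names among `BP`, `CC`, `MF`.
#' @param mapped_genes The gene set whose enrichment defines significance
#'   (typically all genes mapped from the LD-expanded SNPs).
#' @param fdr Adjusted-p threshold.
#' @param min_overlap Minimum overlap for a term to be tested.
#' @return Tibble with columns `gene`, one logical column per namespace
#'   (lower-cased, e.g. `go_bp`), and `go_evidence` (list column naming the
#'   significant terms containing the gene, per namespace).
#' @export
go_criterion_flags <- function(genes, collections, mapped_genes, fdr = 0.05,
                               min_overlap = 2) {
  genes <- unique(normalize_symbols(genes))
  out <- tibble::tibble(gene = genes)
  evidence <- setNames(vector("list", length(genes)), genes)
  for (ns in names(collections)) {
    col_name <- paste0("go_", tolower(ns))
    res <- enrich(mapped_genes, collections[[ns]], fdr = fdr,
                  min_overlap = min_overlap)
    sig <- res[res$q <= fdr, , drop = FALSE]
    sig_members <- collections[[ns]][collections[[ns]]$term_id %in% sig$term_id, ]
    flagged <- unique(unlist(sig_members$members))
    out[[col_name]] <- out$gene %in% flagged
    for (g in genes) {
      terms_g <- sig_members$term_id[purrr::map_lgl(sig_members$members,
                                                    ~ g %in% .x)]
      if (length(terms_g) > 0) {
        evidence[[g]][[col_name]] <- evidence_note(terms_g)
      }
    }
  }
  out$go_evidence <- unname(evidence[out$gene])
  out
}

#' Build seven-criterion annotation profiles
#'
#' One profile per input gene; each flag is set iff at least one supporting
#' evidence record exists, with provenance (source record identifiers)
#' recorded for every set flag. A gene absent from all sources yields an
#' all-zero profile, not an error. Flags are binary regardless of evidence
#' multiplicity; multiplicity survives only in the provenance notes.
#'
#' @param genes Character vector of gene symbols to profile.
#' @param top_genes Genes mapped by the top GWAS SNPs (criterion 1), e.g.
#'   from [top_mapped_genes()].
#' @param ld_variants Variant-gene link tibble restricted to the seed SNPs
#'   and their strong-LD proxies (criterion 2 requires a `missense`
#'   consequence there).
#' @param eqtl Whole-blood eQTL tibble from [read_eqtl()] (criterion 3 uses
#'   rows with `significant`).
#' @param go_flags Tibble from [go_criterion_flags()] (criteria 4-6).
#' @param pid_genes Character vector, the PID list (criterion 7).
#' @return Tibble of class `dvt_scorecard`: `gene`, the seven logical flag
#'   columns of [criterion_flags()], `score` (0-7) and `evidence` (list
#'   column of per-flag provenance notes).
#' @export
build_profiles <- function(genes, top_genes, ld_variants, eqtl, go_flags,
                           pid_genes) {
  genes <- sort(unique(normalize_symbols(genes)))
  top_genes <- unique(normalize_symbols(top_genes))
  pid_genes <- unique(normalize_symbols(pid_genes))
  missense <- ld_variants[ld_variants$consequence == "missense", , drop = FALSE]
  eqtl_sig <- eqtl[eqtl$significant, , drop = FALSE]

  out <- tibble::tibble(gene = genes) |>
    dplyr::mutate(
      is_top_gwas_gene = .data$gene %in% top_genes,
      has_missense_in_ld = .data$gene %in% missense$gene,
      has_blood_eqtl = .data$gene %in% eqtl_sig$gene
    ) |>
    dplyr::left_join(go_flags, by = "gene")
  for (ns in c("go_bp", "go_cc", "go_mf")) {
    if (!ns %in% names(out)) out[[ns]] <- FALSE
    out[[ns]] <- !is.na(out[[ns]]) & out[[ns]]
  }
  out$is_pid_gene <- out$gene %in% pid_genes

  out$evidence <- purrr::map(seq_len(nrow(out)), function(i) {
    g <- out$gene[i]
    ev <- list()
    if (out$is_top_gwas_gene[i]) ev$is_top_gwas_gene <- "top_mapped_genes"
    if (out$has_missense_in_ld[i]) {
      ev$has_missense_in_ld <- evidence_note(missense$rsid[missense$gene == g])
    }
    if (out$has_blood_eqtl[i]) {
      ev$has_blood_eqtl <- evidence_note(eqtl_sig$rsid[eqtl_sig$gene == g])
    }
    if ("go_evidence" %in% names(out) && !is.null(out$go_evidence[[i]])) {
      ev <- c(ev, out$go_evidence[[i]])
    }
    if (out$is_pid_gene[i]) ev$is_pid_gene <- "pid_list"
    ev
  })
  out$go_evidence <- NULL
  out$score <- profile_score(out)
  out <- dplyr::select(out, "gene", dplyr::all_of(criterion_flags()),
                       "score", "evidence")
  class(out) <- c("dvt_scorecard", class(out))
  out
}

#' Total annotation score
#'
#' Arithmetic sum of the seven binary criterion flags, one value per profile
#' row; always in 0-7.
#'
#' @param profiles Tibble carrying the [criterion_flags()] columns.
#' @return Integer vector of scores.
#' @export
profile_score <- function(profiles) {
  flags <- as.matrix(profiles[, criterion_flags()])
  storage.mode(flags) <- "integer"
  if (any(is.na(flags)) || any(flags < 0 | flags > 1)) {
    abort("Criterion flags must all be 0/1.")
  }
  as.integer(rowSums(flags))
}

#' Call risk genes at a minimum score
#'
#' Genes whose total annotation score is at least `min_score` (default 3,
#' the minimum-score criterion), ordered by descending score and then by
#' symbol.
#'
#' @param profiles Scorecard tibble from [build_profiles()] or
#'   [read_scorecard()].
#' @param min_score Integer in 0-7; non-strict ">=" comparison.
#' @return Character vector of gene symbols in (score desc, symbol asc) order.
#' @export
risk_genes <- function(profiles, min_score = 3) {
  stopifnot(min_score >= 0, min_score <= 7)
  score <- if ("score" %in% names(profiles)) profiles$score else
    profile_score(profiles)
  keep <- score >= min_score
  ord <- order(-score[keep], profiles$gene[keep])
  profiles$gene[keep][ord]
}

#' Read a transcribed scorecard table
#'
#' A TSV with a `gene` column and the seven 0/1 flag columns of
#' [criterion_flags()]; the total score is recomputed, never trusted from
#' the file.
#'
#' @param path Scorecard TSV path.
#' @return A `dvt_scorecard` tibble (`gene`, flags, `score`).
#' @export
read_scorecard <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, comment = "#")
  need <- c("gene", criterion_flags())
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Scorecard is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(gene = toupper(stringr::str_trim(raw$gene)))
  for (fl in criterion_flags()) {
    v <- as.integer(raw[[fl]])
    if (any(is.na(v) | !v %in% 0:1)) {
      abort(paste0("Scorecard column ", fl, " must be 0/1."))
    }
    out[[fl]] <- as.logical(v)
  }
  out$score <- profile_score(out)
  class(out) <- c("dvt_scorecard", class(out))
  out
}

#' Write a scorecard table
#' @param profiles `dvt_scorecard` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scorecard <- function(profiles, path) {
  out <- profiles[, c("gene", criterion_flags(), "score")]
  out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(criterion_flags()),
                                          as.integer))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
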
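#' Normalize gene symbols
#'
#' Upper-cases symbols and strips surrounding whitespace. Alias resolution is
#' deliberately out of scope: all bundled and simulated resources use
#' consistent symbols.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of normalized symbols; empty strings dropped.
#' @export
normalize_symbols <- function(x) {
  x <- toupper(stringr::str_trim(as.character(x)))
  x[!is.na(x) & nzchar(x)]
}

#' Chromosome labels in canonical genome order
#' @return Character vector `c("1", ..., "22", "X", "Y")`.
#' @export
chromosome_levels <- function() c(as.character(1:22), "X", "Y")

# Strip a leading "chr" prefix and upper-case X/Y; unknown labels pass
# through unchanged so callers can decide to skip them.
normalize_chrom <- function(x) {
  x <- stringr::str_trim(as.character(x))
  x <- stringr::str_remove(x, stringr::regex("^chr", ignore_case = TRUE))
  toupper(x)
}

# Split a GWAS-Catalog "mapped gene" cell into an ordered vector of symbols.
# Catalog dialects vary: comma or semicolon lists, "A - B" for intergenic
# hits (both flanking genes kept), and " x " for interaction terms.
split_gene_cell <- function(cell) {
  if (is.na(cell) || !nzchar(stringr::str_trim(cell))) return(character())
  parts <- stringr::str_split_1(
    cell, "\\s*[,;]\\s*|\\s+-\\s+|\\s+x\\s+"
  )
  parts <- stringr::str_trim(parts)
  parts[nzchar(parts)]
}

# Deterministic 32-bit sub-seed derived from a master seed and a stream tag,
# kept in [0, 2^31) so it is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}

# Collapse a character vector into a single provenance note.
evidence_note <- function(ids) {
  if (length(ids) == 0) NA_character_ else paste(sort(unique(ids)), collapse = ";")
}
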
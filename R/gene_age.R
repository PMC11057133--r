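#' Classify a phylostratum as unicellular or multicellular origin
#'
#' Genes are dated on a 16-level phylogenetic scale (phylostrata), from genes
#' shared with all organisms (stratum 1) to human-specific genes (stratum 16).
#' Genes whose most distant orthologs lie in bacteria or single-celled
#' eukaryotes (strata 1-3) are of unicellular origin ("UC"); genes with
#' orthologs only in other metazoans are of multicellular origin ("MC").
#'
#' @param stratum Integer vector of phylostrata, each in 1..16.
#' @return Character vector, `"UC"` or `"MC"`.
#' @examples
#' age_class(c(1, 3, 4, 16))
#' @export
age_class <- function(stratum) {
  stratum <- as.integer(stratum)
  if (any(is.na(stratum)) || any(stratum < 1L) || any(stratum > 16L)) {
    bad <- which(is.na(stratum) | stratum < 1L | stratum > 16L)
    stop("phylostratum out of range 1..16 at position(s): ",
         paste(bad, collapse = ", "))
  }
  ifelse(stratum <= 3L, "UC", "MC")
}

#' Build a gene age table from gene/phylostratum pairs
#'
#' @param gene Character vector of gene identifiers (opaque strings; no
#'   symbol/ID mapping is attempted).
#' @param phylostratum Integer vector in 1..16, same length as `gene`.
#' @return A tibble with columns `gene`, `phylostratum`, `age_class`, of class
#'   `gene_age_tbl`.
#' @export
gene_age_table <- function(gene, phylostratum) {
  gene <- as.character(gene)
  if (length(gene) != length(phylostratum)) {
    stop("`gene` and `phylostratum` must have the same length")
  }
  if (anyDuplicated(gene)) {
    stop("duplicate gene id(s): ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  ps <- suppressWarnings(as.integer(phylostratum))
  if (any(is.na(ps))) {
    stop("non-integer phylostratum at row(s): ",
         paste(which(is.na(ps)), collapse = ", "))
  }
  bad <- which(ps < 1L | ps > 16L)
  if (length(bad)) {
    stop("phylostratum outside 1..16 at row(s): ",
         paste(bad, collapse = ", "), " (gene ",
         paste(gene[bad], collapse = ", "), ")")
  }
  out <- tibble::tibble(gene = gene, phylostratum = ps,
                        age_class = age_class(ps))
  class(out) <- c("gene_age_tbl", class(out))
  out
}

#' Read phylostratum assignments from a two-column TSV
#'
#' The file must have a header with columns `gene` and `phylostratum`
#' (extra columns are ignored).
#'
#' @param path Path to a tab-separated file.
#' @return A `gene_age_tbl` tibble (see [gene_age_table()]).
#' @export
read_phylostrata <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene", "phylostratum") %in% names(df))) {
    stop("expected columns `gene` and `phylostratum` in ", path)
  }
  gene_age_table(df$gene, df$phylostratum)
}

#' Write a gene age table to TSV (gene, phylostratum, age_class)
#'
#' @param ages A `gene_age_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylostrata <- function(ages, path) {
  readr::write_tsv(ages[, c("gene", "phylostratum", "age_class")], path)
  invisible(path)
}

#' Look up age classes for a set of genes
#'
#' Genes absent from the age table are labeled `"unknown"`; downstream
#' enrichment counts exclude them (both in modules and in the background).
#'
#' @param genes Character vector of gene ids.
#' @param ages A `gene_age_tbl`.
#' @return Character vector of `"UC"`, `"MC"`, or `"unknown"`.
#' @export
lookup_age <- function(genes, ages) {
  cls <- ages$age_class[match(genes, ages$gene)]
  cls[is.na(cls)] <- "unknown"
  cls
}
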
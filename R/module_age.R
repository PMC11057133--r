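#' Fisher's exact test on a 2x2 table with cross-product odds ratio
#'
#' The p-value is the exact (hypergeometric) probability from
#' [stats::fisher.test()]; the reported odds ratio is the unconditional
#' cross-product estimate `(a*d)/(b*c)`, not the conditional MLE, because the
#' cross-product is the quantity obtained by direct arithmetic on published
#' module-count tables. A Haldane-Anscombe 0.5 correction is applied to the
#' odds ratio only when some cell is zero, and flagged.
#'
#' @param table 2x2 numeric matrix of non-negative integer counts.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @param conditional_or Report the conditional-MLE odds ratio instead.
#' @return Tibble with columns `odds_ratio`, `p`, `corrected` (logical: 0.5
#'   added to cells for the OR), `degenerate` (a zero row/column total).
#' @examples
#' fisher_2x2(matrix(c(774, 137, 392, 200), 2))
#' @export
fisher_2x2 <- function(table, alternative = "two.sided",
                       conditional_or = FALSE) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(table < 0) || sum(table) <= 0) stop("invalid 2x2 table")
  degenerate <- any(rowSums(table) == 0) || any(colSums(table) == 0)
  ft <- stats::fisher.test(table, alternative = alternative)
  corrected <- FALSE
  if (conditional_or) {
    or <- unname(ft$estimate)
  } else {
    tt <- table
    if (any(tt == 0)) {
      tt <- tt + 0.5
      corrected <- TRUE
    }
    or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
    if (degenerate) or <- NA_real_
  }
  tibble::tibble(odds_ratio = or, p = ft$p.value,
                 corrected = corrected, degenerate = degenerate)
}

#' Age-enrichment test for one module (pre-adjustment)
#'
#' One-sided (greater) Fisher tests for over-representation of UC genes and,
#' separately, of MC genes in the module relative to the cohort background.
#' Genes of unknown age are excluded from both module and background counts.
#' The final category is assigned only after cohort-wide BH adjustment by
#' [adjust_and_categorize()].
#'
#' @param module Character vector of gene ids (subset of `background`).
#' @param ages A `gene_age_tbl`.
#' @param background Character vector: all genes surviving expression
#'   filtering in the cohort.
#' @param label Module label carried into the result.
#' @return One-row tibble with counts, `p_uc`, `p_mc`, and an
#'   `unclassifiable` flag (no age-classified genes in the module).
#' @export
classify_module_age <- function(module, ages, background,
                                label = "module") {
  if (!all(module %in% background)) stop("module must be a subset of background")
  m_cls <- lookup_age(module, ages)
  b_cls <- lookup_age(background, ages)
  m_uc <- sum(m_cls == "UC"); m_mc <- sum(m_cls == "MC")
  b_uc <- sum(b_cls == "UC"); b_mc <- sum(b_cls == "MC")
  if (m_uc + m_mc == 0) {
    return(tibble::tibble(module = label, n_uc = 0L, n_mc = 0L,
                          bg_uc = b_uc, bg_mc = b_mc,
                          p_uc = NA_real_, p_mc = NA_real_,
                          unclassifiable = TRUE))
  }
  # rows: in module / out of module; cols: this age / other age
  t_uc <- matrix(c(m_uc, b_uc - m_uc, m_mc, b_mc - m_mc), 2)
  t_mc <- matrix(c(m_mc, b_mc - m_mc, m_uc, b_uc - m_uc), 2)
  tibble::tibble(
    module = label, n_uc = m_uc, n_mc = m_mc, bg_uc = b_uc, bg_mc = b_mc,
    p_uc = stats::fisher.test(t_uc, alternative = "greater")$p.value,
    p_mc = stats::fisher.test(t_mc, alternative = "greater")$p.value,
    unclassifiable = FALSE
  )
}

#' BH-adjust age-enrichment p-values and assign categories
#'
#' Benjamini-Hochberg adjustment is applied across the modules of one cohort;
#' by default the UC-direction and MC-direction tests form separate families
#' (`family = "per_direction"`); `family = "pooled"` adjusts both directions
#' together. A module is `UC-enriched` if its adjusted UC p-value is below
#' `alpha`, `MC-enriched` for the MC direction, otherwise `mixed`. The two
#' one-sided tests on a two-class labeling can never both be significant.
#'
#' @param results Row-bound output of [classify_module_age()] for one cohort.
#' @param alpha Significance level (default 0.05).
#' @param family `"per_direction"` or `"pooled"` BH family.
#' @return `results` with `adj_p_uc`, `adj_p_mc`, `category` columns added.
#' @export
adjust_and_categorize <- function(results, alpha = 0.05,
                                  family = c("per_direction", "pooled")) {
  family <- match.arg(family)
  if (nrow(results) == 0) {
    return(dplyr::mutate(results, adj_p_uc = numeric(0), adj_p_mc = numeric(0),
                         category = character(0)))
  }
  if (family == "per_direction") {
    adj_uc <- stats::p.adjust(results$p_uc, method = "BH")
    adj_mc <- stats::p.adjust(results$p_mc, method = "BH")
  } else {
    pooled <- stats::p.adjust(c(results$p_uc, results$p_mc), method = "BH")
    adj_uc <- pooled[seq_len(nrow(results))]
    adj_mc <- pooled[nrow(results) + seq_len(nrow(results))]
  }
  category <- dplyr::case_when(
    results$unclassifiable ~ NA_character_,
    !is.na(adj_uc) & adj_uc < alpha ~ "UC-enriched",
    !is.na(adj_mc) & adj_mc < alpha ~ "MC-enriched",
    TRUE ~ "mixed"
  )
  dplyr::mutate(results, adj_p_uc = adj_uc, adj_p_mc = adj_mc,
                category = category)
}

#' Age-classify every module of a module set
#'
#' Convenience wrapper: runs [classify_module_age()] per module and
#' [adjust_and_categorize()] across the cohort.
#'
#' @inheritParams adjust_and_categorize
#' @param modset A `module_set`.
#' @param ages A `gene_age_tbl`.
#' @param background Cohort background gene set (default: all assigned genes
#'   plus grey).
#' @return Tibble, one row per module, with `mc_fraction` (MC share among
#'   age-classified module genes) added.
#' @export
module_age_classification <- function(modset, ages, background = NULL,
                                      alpha = 0.05,
                                      family = "per_direction") {
  if (is.null(background)) {
    background <- c(unlist(modset$modules, use.names = FALSE), modset$grey)
  }
  if (length(modset$modules) == 0) {
    return(tibble::tibble(module = character(), n_uc = integer(),
                          n_mc = integer(), bg_uc = integer(),
                          bg_mc = integer(), p_uc = numeric(),
                          p_mc = numeric(), unclassifiable = logical(),
                          adj_p_uc = numeric(), adj_p_mc = numeric(),
                          category = character(), mc_fraction = numeric()))
  }
  res <- purrr::imap(modset$modules,
                     ~classify_module_age(.x, ages, background, label = .y))
  res <- dplyr::bind_rows(res)
  res <- adjust_and_categorize(res, alpha = alpha, family = family)
  dplyr::mutate(res,
                mc_fraction = ifelse(n_uc + n_mc > 0, n_mc / (n_uc + n_mc),
                                     NA_real_))
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name <tab> description <tab> gene1 <tab> ...`.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}

#' Over-representation analysis against a gene-set collection
#'
#' One-sided hypergeometric test per gene set (module genes vs background),
#' BH-adjusted across sets, sorted by adjusted p. Sets with no background
#' overlap are skipped with a warning. An optional exclusion list (set names,
#' case-insensitive) is applied as a post-filter.
#'
#' @param module Character vector of gene ids.
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param background Character vector of background genes (non-empty).
#' @param exclude Optional character vector of set names to drop from output.
#' @return Tibble with columns `set`, `set_size`, `overlap`, `p`, `adj_p`.
#' @export
ora <- function(module, gene_sets, background, exclude = NULL) {
  if (length(background) == 0) stop("background must be non-empty")
  module <- intersect(module, background)
  rows <- purrr::imap(gene_sets, function(s, nm) {
    s <- intersect(s, background)
    if (length(s) == 0) {
      warning("gene set `", nm, "` has no background overlap; skipped")
      return(NULL)
    }
    ov <- length(intersect(module, s))
    p <- stats::phyper(ov - 1, length(s), length(background) - length(s),
                       length(module), lower.tail = FALSE)
    tibble::tibble(set = nm, set_size = length(s), overlap = ov, p = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$adj_p, out$p, out$set), ]
  if (!is.null(exclude)) {
    out <- out[!(tolower(out$set) %in% tolower(exclude)), ]
  }
  tibble::as_tibble(out)
}

#' Read a term exclusion list (one term per line, `#` comments allowed)
#'
#' @param path Text file path.
#' @return Character vector of terms.
#' @export
read_exclusion_terms <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
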
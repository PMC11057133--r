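#' Single-sample gene-set enrichment score for one sample
#'
#' Genes are ordered by decreasing expression (ties broken by stable gene-id
#' order). Walking down that ranking, the score is the sum over positions of
#' the difference between the weighted running fraction of in-set genes
#' (weights `rank^alpha`, with ranks taken from the ascending order so the
#' most expressed genes weigh most) and the uniform running fraction of
#' out-of-set genes. Consistently top-ranked set genes give large positive
#' scores. The score depends on expression only through ranks, so it is
#' invariant to any strictly increasing per-sample transform.
#'
#' @param expr_col Named numeric vector: expression of each gene in one
#'   sample.
#' @param gene_set Character vector of gene ids; must cover at least one but
#'   not all of the expressed genes.
#' @param alpha Rank-weight exponent (default 0.25).
#' @return Numeric enrichment score.
#' @export
ssgsea_sample <- function(expr_col, gene_set, alpha = 0.25) {
  genes <- names(expr_col)
  if (is.null(genes)) stop("expr_col must be named by gene")
  n <- length(expr_col)
  in_set <- genes %in% gene_set
  n_in <- sum(in_set)
  if (n_in == 0 || n_in == n) {
    stop("gene set must cover at least one but not all genes")
  }
  ord <- order(-expr_col, genes)          # decreasing expression, stable ties
  in_ord <- in_set[ord]
  w <- (n - seq_len(n) + 1)^alpha         # ascending rank of gene at position i
  w_in <- w * in_ord
  p_in <- cumsum(w_in) / sum(w_in)
  p_out <- cumsum(!in_ord) / (n - n_in)
  sum(p_in - p_out)
}

#' Per-sample activity scores for every module
#'
#' Applies [ssgsea_sample()] to each module and sample. Modules with no
#' expressed genes are dropped with a warning. With `normalize = TRUE`, all
#' scores are divided by the global `max - min` across the matrix, so the
#' matrix spans a unit range.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param modset A `module_set` (grey is not scored).
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize Divide by the global score range (default `TRUE`).
#' @return A `module_score_matrix`: numeric matrix modules x samples with
#'   attributes `alpha` and `normalized`.
#' @export
ssgsea_matrix <- function(expr, modset, alpha = 0.25, normalize = TRUE) {
  stopifnot(is.matrix(expr))
  genes <- rownames(expr)
  mods <- modset$modules
  expressed <- vapply(mods, function(m) length(intersect(m, genes)) > 0,
                      TRUE)
  if (any(!expressed)) {
    warning("module(s) with no expressed genes dropped: ",
            paste(names(mods)[!expressed], collapse = ", "))
    mods <- mods[expressed]
  }
  if (length(mods) == 0) stop("no module overlaps the expression genes")
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    col <- stats::setNames(expr[, j], genes)
    vapply(mods, function(m) ssgsea_sample(col, m, alpha = alpha), 1.0)
  }, numeric(length(mods)))
  scores <- matrix(scores, nrow = length(mods),
                   dimnames = list(names(mods), colnames(expr)))
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  structure(scores, alpha = alpha, normalized = normalize,
            class = c("module_score_matrix", class(scores)))
}

#' Share of each novelty tertile among top-quartile modules
#'
#' Each module is summarized across samples (mean by default); the cohort's
#' top score quartile is the set of modules at or above the 0.75 quantile of
#' the summaries. Returns, for each novelty tertile, the fraction of its
#' modules falling in that top quartile.
#'
#' @param scores A `module_score_matrix` (or plain modules x samples matrix).
#' @param classes Tibble with columns `module`, `tertile`, covering the
#'   scored modules.
#' @param summary `"mean"` (default) or `"median"` per-module summary.
#' @return Tibble with columns `tertile`, `n_modules`, `n_top_quartile`,
#'   `share` (in \[0, 1\]).
#' @export
upper_quartile_share <- function(scores, classes, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  fun <- if (summary == "mean") mean else stats::median
  summ <- apply(unclass(scores), 1, fun)
  if (!all(rownames(scores) %in% classes$module)) {
    stop("`classes` must cover all scored modules")
  }
  cutoff <- stats::quantile(summ, 0.75, type = 7, names = FALSE)
  top <- summ >= cutoff
  tb <- tibble::tibble(module = rownames(scores), top = top)
  tb <- dplyr::left_join(tb, classes[, c("module", "tertile")], by = "module")
  dplyr::summarise(dplyr::group_by(tb, tertile),
                   n_modules = dplyr::n(),
                   n_top_quartile = sum(top),
                   share = mean(top), .groups = "drop")
}
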
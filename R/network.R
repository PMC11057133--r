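#' Filter genes by counts-per-million across sample groups
#'
#' Keeps a gene when its CPM exceeds `threshold` in every tumor sample or in
#' every normal sample, so that genes reliably expressed in either condition
#' survive while noise-level genes are dropped.
#'
#' @param counts Numeric matrix, genes x samples, raw counts with dimnames.
#' @param tumor_ids,normal_ids Character vectors of sample (column) ids.
#' @param threshold CPM threshold (default 1, strict `>`).
#' @return Character vector of retained gene ids.
#' @export
cpm_filter <- function(counts, tumor_ids, normal_ids, threshold = 1) {
  stopifnot(is.matrix(counts))
  if (length(tumor_ids) == 0 || length(normal_ids) == 0) {
    stop("both sample groups must be non-empty")
  }
  miss <- setdiff(c(tumor_ids, normal_ids), colnames(counts))
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  libs <- colSums(counts)
  if (any(libs <= 0)) stop("library size must be > 0 for all samples")
  cpm <- sweep(counts, 2, libs, "/") * 1e6
  keep_t <- rowSums(cpm[, tumor_ids, drop = FALSE] > threshold) == length(tumor_ids)
  keep_n <- rowSums(cpm[, normal_ids, drop = FALSE] > threshold) == length(normal_ids)
  rownames(counts)[keep_t | keep_n]
}

#' Drop outlier samples by hierarchical clustering
#'
#' Samples are clustered by average linkage on Euclidean distance between
#' expression profiles; the tree is cut at `mean + k * sd` of the merge
#' heights and only the largest resulting cluster is retained. When a pairing
#' is supplied, a sample is also dropped whenever its partner is dropped.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param pair_id Optional character vector (one per sample, aligned with
#'   columns) linking paired samples; `NA` marks unpaired samples.
#' @param k Multiplier on the merge-height standard deviation (default 2.5).
#' @return The matrix restricted to retained samples, with attribute
#'   `"dropped"` listing removed sample ids.
#' @export
remove_outlier_samples <- function(expr, pair_id = NULL, k = 2.5) {
  stopifnot(is.matrix(expr))
  n <- ncol(expr)
  if (n < 4) stop("need at least 4 samples for outlier screening")
  hc <- stats::hclust(stats::dist(t(expr)), method = "average")
  cut_h <- mean(hc$height) + k * stats::sd(hc$height)
  keep <- rep(TRUE, n)
  if (is.finite(cut_h) && cut_h < max(hc$height)) {
    cl <- stats::cutree(hc, h = cut_h)
    main <- as.integer(names(which.max(table(cl))))
    keep <- cl == main
  }
  if (!is.null(pair_id)) {
    stopifnot(length(pair_id) == n)
    dropped_pairs <- unique(pair_id[!keep])
    dropped_pairs <- dropped_pairs[!is.na(dropped_pairs)]
    keep <- keep & !(pair_id %in% dropped_pairs)
  }
  if (!any(keep)) stop("all samples flagged as outliers")
  out <- expr[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(expr)[!keep]
  out
}

#' Drop genes unusable for correlation networks
#'
#' Removes genes with zero variance (constant across samples) or with more
#' than `max_missing` fraction of missing values.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param max_missing Maximum tolerated fraction of `NA`s per gene.
#' @return The filtered matrix.
#' @export
drop_bad_genes <- function(expr, max_missing = 0.5) {
  stopifnot(is.matrix(expr))
  frac_na <- rowMeans(is.na(expr))
  v <- apply(expr, 1, stats::var, na.rm = TRUE)
  keep <- frac_na <= max_missing & !is.na(v) & v > 0
  expr[keep, , drop = FALSE]
}

#' Unsigned weighted adjacency from expression
#'
#' `a_ij = |pearson(x_i, x_j)|^beta` for `i != j`, diagonal 1. The network is
#' unsigned: perfectly anti-correlated genes are maximally adjacent.
#'
#' @param expr Numeric matrix, genes x samples (>= 3 samples).
#' @param beta Soft-thresholding power (default 6, the conventional unsigned
#'   default; no scale-free-fit selection is performed).
#' @return A `coex_net` object (list with `weights`, `kind`, `beta`, `genes`).
#' @export
adjacency <- function(expr, beta = 6) {
  stopifnot(is.matrix(expr), beta > 0)
  if (ncol(expr) < 3) stop("need at least 3 samples")
  v <- apply(expr, 1, stats::var, na.rm = TRUE)
  if (any(is.na(v) | v == 0)) {
    stop("zero-variance gene(s): ",
         paste(rownames(expr)[is.na(v) | v == 0], collapse = ", "))
  }
  r <- stats::cor(t(expr), use = "pairwise.complete.obs")
  a <- abs(r)^beta
  diag(a) <- 1
  a <- (a + t(a)) / 2  # guard against asymmetric rounding
  new_coex_net(a, kind = "adjacency", beta = beta)
}

new_coex_net <- function(weights, kind, beta = NA_real_) {
  structure(list(weights = weights, kind = kind, beta = beta,
                 genes = rownames(weights)),
            class = "coex_net")
}

#' @export
print.coex_net <- function(x, ...) {
  cat(sprintf("<coex_net: %d genes, kind = %s, beta = %s>\n",
              length(x$genes), x$kind,
              ifelse(is.na(x$beta), "NA", format(x$beta))))
  invisible(x)
}

net_weights <- function(net) {
  if (inherits(net, "coex_net")) net$weights else net
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i` the connectivity
#' (row sum excluding the diagonal). High topological overlap means two genes
#' share neighbors in addition to being directly adjacent.
#'
#' @param adj A `coex_net` of kind `"adjacency"` (or a plain symmetric
#'   matrix in \[0, 1\] with unit diagonal).
#' @return A `coex_net` of kind `"tom"`.
#' @export
tom <- function(adj) {
  a <- net_weights(adj)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(a < 0) || any(a > 1)) stop("adjacency values must lie in [0, 1]")
  a0 <- a
  diag(a0) <- 0
  l <- a0 %*% a0
  k <- rowSums(a0)
  denom <- outer(k, k, pmin) + 1 - a0
  t_mat <- (l + a0) / denom
  diag(t_mat) <- 1
  t_mat <- (t_mat + t(t_mat)) / 2
  dimnames(t_mat) <- dimnames(a)
  beta <- if (inherits(adj, "coex_net")) adj$beta else NA_real_
  new_coex_net(t_mat, kind = "tom", beta = beta)
}

#' Partition a co-expression network into modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed height; branches smaller than `min_size` are pooled into the
#' grey (unassigned) set. Module labels are `"M1"`, `"M2"`, ... in decreasing
#' size order, with ties broken by the alphabetically first member gene, so
#' the result is deterministic for a fixed input.
#'
#' @param net A `coex_net` of kind `"tom"` (adjacency also accepted).
#' @param min_size Minimum module size (default 30).
#' @param cut_height Dendrogram cut height on the dissimilarity scale
#'   (default 0.99).
#' @return A `module_set`: list with `modules` (named list of gene-id
#'   vectors), `grey` (character vector), and `provenance`.
#' @export
detect_modules <- function(net, min_size = 30, cut_height = 0.99) {
  w <- net_weights(net)
  diss <- 1 - w
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  genes <- rownames(w)
  sets <- split(genes, cl)
  keep <- vapply(sets, length, 1L) >= min_size
  grey <- sort(unlist(sets[!keep], use.names = FALSE))
  mods <- unname(sets[keep])
  if (length(mods)) {
    mods <- lapply(mods, sort)
    ord <- order(-vapply(mods, length, 1L),
                 vapply(mods, `[`, "", 1L))
    mods <- mods[ord]
    names(mods) <- paste0("M", seq_along(mods))
  } else {
    mods <- stats::setNames(list(), character())
  }
  new_module_set(mods, grey)
}

new_module_set <- function(modules, grey = character(), provenance = NULL) {
  structure(list(modules = modules, grey = grey, provenance = provenance),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set: %d modules (%d genes assigned), %d grey>\n",
              length(x$modules), sum(lengths(x$modules)), length(x$grey)))
  invisible(x)
}

#' Module membership as a tibble
#'
#' @param modset A `module_set`.
#' @param include_grey Include grey genes (module label `"grey"`)?
#' @return Tibble with columns `gene`, `module`.
#' @export
module_table <- function(modset, include_grey = TRUE) {
  tb <- tibble::tibble(
    gene = unlist(modset$modules, use.names = FALSE),
    module = rep(names(modset$modules), lengths(modset$modules))
  )
  if (include_grey && length(modset$grey)) {
    tb <- dplyr::bind_rows(tb, tibble::tibble(gene = modset$grey,
                                              module = "grey"))
  }
  tb
}

#' Rebuild a module_set from a gene/module table
#'
#' @param tb Tibble or data frame with columns `gene`, `module`; the label
#'   `"grey"` is reserved for unassigned genes.
#' @return A `module_set`.
#' @export
module_set_from_table <- function(tb) {
  tb <- tibble::as_tibble(tb)
  grey <- sort(unname(tb$gene[tb$module == "grey"]))
  rest <- tb[tb$module != "grey", ]
  mods <- split(unname(rest$gene), rest$module)
  mods <- lapply(mods, function(x) sort(unname(x)))
  mods <- mods[order(-lengths(mods), names(mods))]
  new_module_set(mods, grey)
}

#' Extract the intra-module network
#'
#' Subsets the full co-expression network to a module's genes, giving the
#' weighted all-against-all network within the module.
#'
#' @param net A `coex_net` (or matrix).
#' @param module Character vector of gene ids.
#' @return Symmetric numeric matrix over the module's genes.
#' @export
extract_module_network <- function(net, module) {
  w <- net_weights(net)
  miss <- setdiff(module, rownames(w))
  if (length(miss)) stop("gene(s) not in network: ", paste(miss, collapse = ", "))
  w[module, module, drop = FALSE]
}
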
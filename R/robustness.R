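#' Restrict a module to its strongest connections
#'
#' Drops intra-module edges whose weight lies strictly below the median of
#' the module's off-diagonal weights (so the top half of connections, with
#' median ties, survives), then keeps only genes still connected to at least
#' half of the original module (retained-edge count >= ceiling(S/2), S the
#' original module size). A single pass; the filter is not iterated.
#'
#' @param module_net Symmetric numeric matrix (intra-module network,
#'   size >= 2).
#' @param label Module label carried into the result.
#' @return A `filtered_module`: list with `label`, `size` (original S),
#'   `median_weight`, `retained_degree` (per retained gene, its count of
#'   above-median edges before gene removal), `edges` (tibble gene_a,
#'   gene_b, weight, restricted to retained genes), `genes` (retained),
#'   `dropped`, and `empty` flag.
#' @export
filter_strong_edges <- function(module_net, label = "module") {
  stopifnot(is.matrix(module_net), nrow(module_net) >= 2)
  s <- nrow(module_net)
  genes <- rownames(module_net)
  ut <- upper.tri(module_net)
  w <- module_net[ut]
  med <- stats::median(w)
  idx <- which(ut & module_net >= med, arr.ind = TRUE)
  edges <- tibble::tibble(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                          weight = module_net[idx])
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = genes))
  floor_deg <- ceiling(s / 2)
  keep <- names(deg)[deg >= floor_deg]
  edges <- edges[edges$gene_a %in% keep & edges$gene_b %in% keep, ]
  structure(list(label = label, size = s, median_weight = med,
                 retained_degree = c(deg)[sort(keep)],
                 edges = edges, genes = sort(keep),
                 dropped = sort(setdiff(genes, keep)),
                 empty = length(keep) == 0),
            class = "filtered_module")
}

#' @export
print.filtered_module <- function(x, ...) {
  cat(sprintf("<filtered_module %s: %d/%d genes retained, %d edges>\n",
              x$label, length(x$genes), x$size, nrow(x$edges)))
  invisible(x)
}

#' Apply the strong-edge filter to every module of a set
#'
#' Re-derives module composition after the filter so the standard age and
#' novelty operations can be rerun on the filtered modules through the same
#' code path as the main pipeline.
#'
#' @param modset A `module_set`.
#' @param net The full `coex_net` the modules came from.
#' @return List with `filtered` (list of `filtered_module`) and `modset`
#'   (a `module_set` of the retained gene sets; emptied modules are dropped
#'   and their genes pooled into grey).
#' @export
filter_strong_edges_set <- function(modset, net) {
  filtered <- purrr::imap(modset$modules, function(g, lab) {
    filter_strong_edges(extract_module_network(net, g), label = lab)
  })
  kept <- purrr::keep(filtered, ~!.x$empty)
  mods <- purrr::map(kept, "genes")
  dropped <- unlist(purrr::map(filtered, "dropped"), use.names = FALSE)
  list(filtered = filtered,
       modset = new_module_set(mods, grey = sort(c(modset$grey, dropped))))
}
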
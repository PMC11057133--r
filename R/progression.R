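#' Stage-stratified module chains
#'
#' Builds co-expression modules independently for each ordered stage (e.g.
#' normal, low grade, high grade, or normal, benign, malignant) and scores
#' each stage's modules for novelty against the previous stage's modules, so
#' progressive rewiring shows up as rising novelty along the chain.
#'
#' @param expr Genes x samples numeric matrix (already normalized, e.g.
#'   log2 CPM).
#' @param manifest Tibble with columns `sample` and `stage`.
#' @param stages Character vector giving the stage order; defaults to the
#'   order of first appearance in the manifest.
#' @param min_samples Minimum samples per stage (default 6).
#' @param beta,min_size,cut_height Network parameters (see [adjacency()] and
#'   [detect_modules()]).
#' @return A `stage_chain`: list with `stages` (names), `module_sets` (one
#'   `module_set` per stage), and `links` (tibble of per-link novelty results
#'   with columns `link`, `target_stage`, `reference_stage`, plus the
#'   [module_novelty()] columns; tertiles are computed within each link).
#' @export
build_stage_chain <- function(expr, manifest, stages = NULL,
                              min_samples = 6, beta = 6, min_size = 30,
                              cut_height = 0.99) {
  stopifnot(is.matrix(expr))
  if (!all(c("sample", "stage") %in% names(manifest))) {
    stop("manifest must have columns `sample` and `stage`")
  }
  if (is.null(stages)) stages <- unique(manifest$stage)
  if (length(stages) < 2) stop("need at least 2 stages")
  modsets <- lapply(stages, function(st) {
    ids <- manifest$sample[manifest$stage == st]
    ids <- intersect(ids, colnames(expr))
    if (length(ids) < min_samples) {
      stop("stage `", st, "` has fewer than ", min_samples, " samples")
    }
    sub <- drop_bad_genes(expr[, ids, drop = FALSE])
    detect_modules(tom(adjacency(sub, beta = beta)),
                   min_size = min_size, cut_height = cut_height)
  })
  names(modsets) <- stages
  links <- lapply(seq_len(length(stages) - 1), function(k) {
    nov <- module_novelty(modsets[[k + 1]], modsets[[k]])
    dplyr::mutate(nov, link = k, target_stage = stages[k + 1],
                  reference_stage = stages[k], .before = 1)
  })
  structure(list(stages = stages, module_sets = modsets,
                 links = dplyr::bind_rows(links)),
            class = "stage_chain")
}

#' @export
print.stage_chain <- function(x, ...) {
  cat(sprintf("<stage_chain: %s; %d link(s)>\n",
              paste(x$stages, collapse = " -> "),
              length(x$stages) - 1))
  invisible(x)
}

#' Random-forest tumor grade classifier on module activity scores
#'
#' Repeatedly splits samples into stratified train/test sets, fits a random
#' forest on the per-sample module scores, and records the test-set ROC AUC
#' and the per-module mean decrease in Gini impurity. Stratified splits keep
#' both classes present in every test set. The whole procedure is a
#' deterministic function of (scores, labels, seed).
#'
#' @param scores Modules x samples numeric matrix (e.g. from
#'   [ssgsea_matrix()]).
#' @param labels Binary class labels, one per sample (factor, character, or
#'   logical); both classes must be present.
#' @param n_iter Number of random splits (default 100).
#' @param train_frac Training fraction (default 0.7).
#' @param seed Master seed; per-iteration seeds are drawn from it.
#' @param ntree Trees per forest (default 500).
#' @param importance_threshold Mean-decrease-in-Gini cutoff for flagging a
#'   module as important (default 5).
#' @return A `grade_rf`: list with `auc` (length `n_iter`), `importance`
#'   (tibble: module, mean_decrease_gini, important), and the settings.
#' @export
rf_grade_classifier <- function(scores, labels, n_iter = 100,
                                train_frac = 0.7, seed = 1, ntree = 500,
                                importance_threshold = 5) {
  x <- t(unclass(scores))
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must contain exactly two classes")
  if (nrow(x) < 10) stop("need at least 10 samples")
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max, n_iter)
  gini <- matrix(0, nrow = ncol(x), ncol = n_iter,
                 dimnames = list(colnames(x), NULL))
  auc <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    set.seed(iter_seeds[i])
    train <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      sample(idx, max(1, round(train_frac * length(idx))))
    }))
    test <- setdiff(seq_len(nrow(x)), train)
    fit <- randomForest::randomForest(x[train, , drop = FALSE], y[train],
                                      ntree = ntree)
    prob <- stats::predict(fit, x[test, , drop = FALSE], type = "prob")[, 2]
    roc <- pROC::roc(response = y[test], predictor = prob,
                     levels = levels(y), direction = "<", quiet = TRUE)
    auc[i] <- as.numeric(pROC::auc(roc))
    gini[, i] <- fit$importance[, "MeanDecreaseGini"]
  }
  imp <- tibble::tibble(module = colnames(x),
                        mean_decrease_gini = rowMeans(gini))
  imp$important <- imp$mean_decrease_gini > importance_threshold
  structure(list(auc = auc, importance = imp, n_iter = n_iter,
                 train_frac = train_frac, seed = seed, ntree = ntree,
                 importance_threshold = importance_threshold,
                 classes = levels(y)),
            class = "grade_rf")
}

#' @export
print.grade_rf <- function(x, ...) {
  cat(sprintf("<grade_rf: %d iterations, median AUC %.3f (%s vs %s)>\n",
              x$n_iter, stats::median(x$auc), x$classes[1], x$classes[2]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-module importance table of a grade classifier
#'
#' @param x A `grade_rf`.
#' @param ... Unused.
#' @return Tibble with `module`, `mean_decrease_gini`, `important`, sorted by
#'   decreasing importance.
#' @export
tidy.grade_rf <- function(x, ...) {
  dplyr::arrange(x$importance, dplyr::desc(mean_decrease_gini))
}

#' One-row performance summary of a grade classifier
#'
#' @param x A `grade_rf`.
#' @param ... Unused.
#' @return Tibble with median AUC, IQR bounds, iteration count, and the
#'   number of important modules.
#' @export
glance.grade_rf <- function(x, ...) {
  q <- stats::quantile(x$auc, c(0.25, 0.75), names = FALSE)
  tibble::tibble(median_auc = stats::median(x$auc),
                 auc_q25 = q[1], auc_q75 = q[2],
                 n_iter = x$n_iter,
                 n_important = sum(x$importance$important))
}

#' Summarize important modules by gene-age category
#'
#' Tabulates modules whose mean decrease in Gini exceeds the threshold by
#' their age-enrichment category, and additionally reports how many of the
#' important modules are "mixed" in the balanced 40-60% MC-fraction sense.
#'
#' @param report A `grade_rf`.
#' @param age_results Output of [module_age_classification()] covering the
#'   scored modules (columns `module`, `category`, `mc_fraction`).
#' @param threshold Importance cutoff (default 5).
#' @return List with `by_category` (tibble category, n) and `mixed_band`
#'   (tibble n_important, n_mixed_band).
#' @export
importance_age_summary <- function(report, age_results, threshold = 5) {
  imp <- report$importance
  imp <- imp[imp$mean_decrease_gini > threshold, ]
  joined <- dplyr::left_join(imp, age_results, by = "module")
  if (any(is.na(joined$category))) {
    stop("age category unknown for module(s): ",
         paste(joined$module[is.na(joined$category)], collapse = ", "))
  }
  by_cat <- dplyr::count(joined, category, name = "n")
  mixed_band <- tibble::tibble(
    n_important = nrow(joined),
    n_mixed_band = sum(joined$mc_fraction >= 0.4 & joined$mc_fraction <= 0.6,
                       na.rm = TRUE)
  )
  list(by_category = by_cat, mixed_band = mixed_band)
}
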
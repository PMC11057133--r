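#' Novelty score distributions by module age category
#'
#' @param novelty Novelty tibble (from [module_novelty()]).
#' @param age_results Age classification tibble (from
#'   [module_age_classification()]).
#' @return A ggplot: boxplots of novelty score per age category.
#' @export
plot_novelty_by_age <- function(novelty, age_results) {
  df <- dplyr::left_join(novelty, age_results[, c("module", "category")],
                         by = "module")
  ggplot2::ggplot(df, ggplot2::aes(x = category, y = score,
                                   fill = category)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "novelty score (N / S)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of module activity scores
#'
#' @param object A `module_score_matrix`.
#' @param ... Unused.
#' @return A ggplot tile heatmap, modules x samples.
#' @export
autoplot.module_score_matrix <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object), rownames = "module")
  df <- tidyr::pivot_longer(df, -module, names_to = "sample",
                            values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(x = sample, y = module, fill = score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "ssGSEA") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Module importance profile of a grade classifier
#'
#' @param object A `grade_rf`.
#' @param ... Unused.
#' @return A ggplot bar chart of mean decrease in Gini per module, with the
#'   importance threshold marked.
#' @export
autoplot.grade_rf <- function(object, ...) {
  df <- tidy(object)
  df$module <- factor(df$module, levels = rev(df$module))
  ggplot2::ggplot(df, ggplot2::aes(x = mean_decrease_gini, y = module,
                                   fill = important)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$importance_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "mean decrease in Gini", y = NULL) +
    ggplot2::theme_minimal()
}
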
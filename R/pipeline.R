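#' End-to-end cohort analysis
#'
#' Runs the full pipeline on a paired tumor/normal cohort: CPM filtering,
#' outlier-sample removal, gene quality filtering, log2-CPM transform,
#' unsigned adjacency and topological overlap, module detection per
#' condition, module age classification, tumor-module novelty against the
#' normal modules, per-sample ssGSEA module activity, and (when mutation
#' inputs are present) the somatic mutation overlay. Accepts either a
#' `synthetic_cohort` or a list of file paths (`expression`, `manifest`,
#' `ages`, and optionally `mutations`, `segments`, `gene_coords`,
#' `drivers`).
#'
#' @param cohort A `synthetic_cohort`, or a named list of input file paths.
#' @param out_dir Optional output directory; when given, all stage outputs
#'   and a JSON summary are written there.
#' @param beta Soft power (default 6).
#' @param min_size Minimum module size (default 30).
#' @param cut_height Dendrogram cut height (default 0.99).
#' @param alpha Significance level for age enrichment (default 0.05).
#' @param ssgsea_alpha Rank-weight exponent (default 0.25).
#' @param cna_min_fraction Module CNA flag threshold (default 0.10).
#' @param tumor_type Driver tumor type to match (default `"SYNTH"`).
#' @param outlier_k Outlier cut multiplier (default 2.5).
#' @return A `cohort_result` list: `tumor_modules`, `normal_modules`
#'   (`module_set`s), `tumor_net`, `normal_net` (`coex_net`s, TOM),
#'   `age_tumor`, `age_normal`, `novelty`, `scores`, `mutation_overlay`
#'   (or `NULL`), `summary` (counts per category/tertile), and `settings`.
#' @export
run_cohort <- function(cohort, out_dir = NULL, beta = 6, min_size = 30,
                       cut_height = 0.99, alpha = 0.05, ssgsea_alpha = 0.25,
                       cna_min_fraction = 0.10, tumor_type = "SYNTH",
                       outlier_k = 2.5) {
  inp <- load_cohort_inputs(cohort)
  manifest <- inp$manifest
  tumor_ids <- manifest$sample[manifest$condition == "tumor"]
  normal_ids <- manifest$sample[manifest$condition == "normal"]
  if (!length(tumor_ids) || !length(normal_ids)) {
    stop("manifest must contain both tumor and normal samples")
  }

  keep <- cpm_filter(inp$counts, tumor_ids, normal_ids)
  expr <- logcpm(inp$counts[keep, , drop = FALSE])
  ## outlier screening runs within each condition (the conditions differ
  ## biologically, so a joint screen would read that separation as
  ## outlierness); a dropped sample then takes its pair partner with it
  screen <- function(ids) {
    sub <- expr[, ids, drop = FALSE]
    attr(remove_outlier_samples(sub, k = outlier_k), "dropped")
  }
  dropped <- c(screen(tumor_ids), screen(normal_ids))
  dropped_pairs <- manifest$pair_id[match(dropped, manifest$sample)]
  dropped_pairs <- dropped_pairs[!is.na(dropped_pairs)]
  dropped <- union(dropped,
                   manifest$sample[manifest$pair_id %in% dropped_pairs])
  expr <- expr[, setdiff(colnames(expr), dropped), drop = FALSE]
  manifest <- manifest[manifest$sample %in% colnames(expr), ]
  tumor_ids <- intersect(tumor_ids, colnames(expr))
  normal_ids <- intersect(normal_ids, colnames(expr))

  build <- function(ids) {
    sub <- drop_bad_genes(expr[, ids, drop = FALSE])
    net <- tom(adjacency(sub, beta = beta))
    mods <- detect_modules(net, min_size = min_size, cut_height = cut_height)
    list(net = net, mods = mods)
  }
  tum <- build(tumor_ids)
  nor <- build(normal_ids)
  if (length(tum$mods$modules) == 0) {
    warning("no tumor module reached min_size; all genes grey")
  }

  age_tumor <- module_age_classification(tum$mods, inp$ages, alpha = alpha)
  age_normal <- module_age_classification(nor$mods, inp$ages, alpha = alpha)
  novelty <- module_novelty(tum$mods, nor$mods)
  scores <- if (length(tum$mods$modules)) {
    ssgsea_matrix(expr[, tumor_ids, drop = FALSE], tum$mods,
                  alpha = ssgsea_alpha)
  } else NULL

  overlay <- NULL
  if (!is.null(inp$mutations) && !is.null(inp$segments) &&
      !is.null(inp$gene_coords)) {
    rec_point <- recurrent_point_mutated(inp$mutations)
    focal <- focal_gene_calls(inp$segments, inp$gene_coords)
    rec <- recurrent_cna(focal, n_patients = length(tumor_ids))
    flags <- purrr::imap(tum$mods$modules, function(g, lab) {
      tibble::tibble(
        module = lab,
        amp_fraction = module_cna_flag(g, rec$amp, cna_min_fraction)$fraction,
        amp_flagged = module_cna_flag(g, rec$amp, cna_min_fraction)$flagged,
        del_fraction = module_cna_flag(g, rec$del, cna_min_fraction)$fraction,
        del_flagged = module_cna_flag(g, rec$del, cna_min_fraction)$flagged,
        driver_percent = if (!is.null(inp$drivers)) {
          driver_fraction(g, inp$drivers, tumor_type)$percent
        } else NA_real_
      )
    }) |> dplyr::bind_rows()
    enrich <- if (length(tum$mods$modules) && length(nor$mods$modules)) {
      cna_module_enrichment(tum$mods, nor$mods, rec,
                            min_fraction = cna_min_fraction)
    } else NULL
    overlay <- list(recurrent_point = rec_point, recurrent_cna = rec,
                    module_flags = flags, enrichment = enrich)
  }

  summary <- list(
    n_tumor_modules = length(tum$mods$modules),
    n_normal_modules = length(nor$mods$modules),
    n_grey_tumor = length(tum$mods$grey),
    tumor_age_categories = as.list(table(age_tumor$category)),
    normal_age_categories = as.list(table(age_normal$category)),
    novelty_tertiles = as.list(table(novelty$tertile))
  )
  res <- structure(list(tumor_modules = tum$mods, normal_modules = nor$mods,
                        tumor_net = tum$net, normal_net = nor$net,
                        age_tumor = age_tumor, age_normal = age_normal,
                        novelty = novelty, scores = scores,
                        mutation_overlay = overlay, summary = summary,
                        manifest = manifest, expr = expr,
                        settings = list(beta = beta, min_size = min_size,
                                        cut_height = cut_height,
                                        alpha = alpha,
                                        ssgsea_alpha = ssgsea_alpha,
                                        cna_min_fraction = cna_min_fraction)),
                   class = "cohort_result")
  if (!is.null(out_dir)) write_cohort_result(res, out_dir)
  res
}

load_cohort_inputs <- function(cohort) {
  if (inherits(cohort, "synthetic_cohort")) {
    return(list(counts = cohort$counts, manifest = cohort$manifest,
                ages = cohort$ages, mutations = cohort$mutations,
                segments = cohort$segments, gene_coords = cohort$gene_coords,
                drivers = cohort$drivers))
  }
  if (!is.list(cohort) || !all(c("expression", "manifest", "ages") %in%
                                 names(cohort))) {
    stop("cohort must be a synthetic_cohort or a list of file paths with ",
         "at least expression, manifest, ages")
  }
  opt <- function(key, reader) {
    if (!is.null(cohort[[key]])) reader(cohort[[key]]) else NULL
  }
  list(counts = read_expression(cohort$expression),
       manifest = read_manifest(cohort$manifest),
       ages = read_phylostrata(cohort$ages),
       mutations = opt("mutations", read_mutations),
       segments = opt("segments", read_segments),
       gene_coords = opt("gene_coords", read_gene_coords),
       drivers = opt("drivers", read_drivers))
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf(paste0("<cohort_result: %d tumor / %d normal modules; ",
                     "tumor categories: %s>\n"),
              x$summary$n_tumor_modules, x$summary$n_normal_modules,
              paste(names(x$summary$tumor_age_categories),
                    unlist(x$summary$tumor_age_categories),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

write_cohort_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(module_table(res$tumor_modules),
                   file.path(out_dir, "tumor_modules.tsv"))
  readr::write_tsv(module_table(res$normal_modules),
                   file.path(out_dir, "normal_modules.tsv"))
  readr::write_tsv(res$age_tumor, file.path(out_dir, "age_tumor.tsv"))
  readr::write_tsv(res$age_normal, file.path(out_dir, "age_normal.tsv"))
  readr::write_tsv(res$novelty, file.path(out_dir, "novelty.tsv"))
  if (!is.null(res$scores)) {
    readr::write_tsv(tibble::as_tibble(unclass(res$scores),
                                       rownames = "module"),
                     file.path(out_dir, "scores.tsv"))
  }
  if (!is.null(res$mutation_overlay)) {
    readr::write_tsv(res$mutation_overlay$module_flags,
                     file.path(out_dir, "module_cna_flags.tsv"))
    readr::write_tsv(res$mutation_overlay$enrichment,
                     file.path(out_dir, "cna_enrichment.tsv"))
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' End-to-end staged progression analysis
#'
#' Builds the stage chain (per-stage modules plus per-link novelty) and,
#' when a binary grading of the samples is possible (exactly two of the
#' stages or a supplied `label_stages` split), trains the random-forest
#' grade classifier on ssGSEA scores of the final stage's modules.
#'
#' @param cohort A `synthetic_cohort` or file-path list (see [run_cohort()]).
#' @param stages Stage order (default: order of appearance).
#' @param label_stages Character vector of two stage names used as classifier
#'   classes (default: the last two stages).
#' @param out_dir Optional output directory.
#' @param seed Seed for the classifier (default 1).
#' @param n_iter Classifier iterations (default 100).
#' @inheritParams run_cohort
#' @return List with `chain` (a `stage_chain`), `classifier` (a `grade_rf`
#'   or `NULL`), and `scores`.
#' @export
run_progression <- function(cohort, stages = NULL, label_stages = NULL,
                            out_dir = NULL, seed = 1, n_iter = 100,
                            beta = 6, min_size = 30, cut_height = 0.99) {
  inp <- load_cohort_inputs(cohort)
  manifest <- inp$manifest
  if (!"stage" %in% names(manifest)) {
    stop("manifest must contain a `stage` column")
  }
  tumor_ids <- manifest$sample[manifest$condition == "tumor"]
  normal_ids <- manifest$sample[manifest$condition == "normal"]
  keep <- cpm_filter(inp$counts, tumor_ids, normal_ids)
  expr <- logcpm(inp$counts[keep, , drop = FALSE])
  chain <- build_stage_chain(expr, manifest, stages = stages,
                             beta = beta, min_size = min_size,
                             cut_height = cut_height)
  classifier <- NULL
  scores <- NULL
  stages_used <- chain$stages
  if (is.null(label_stages)) {
    label_stages <- utils::tail(stages_used, 2)
  }
  final_mods <- chain$module_sets[[utils::tail(stages_used, 1)]]
  ids <- manifest$sample[manifest$stage %in% label_stages]
  ids <- intersect(ids, colnames(expr))
  if (length(final_mods$modules) > 0 && length(ids) >= 10) {
    scores <- ssgsea_matrix(expr[, ids, drop = FALSE], final_mods)
    labels <- manifest$stage[match(ids, manifest$sample)]
    classifier <- rf_grade_classifier(scores, labels, n_iter = n_iter,
                                      seed = seed)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(chain$links, file.path(out_dir, "stage_novelty.tsv"))
    if (!is.null(classifier)) {
      readr::write_tsv(tidy(classifier),
                       file.path(out_dir, "importance.tsv"))
      jsonlite::write_json(as.list(glance(classifier)),
                           file.path(out_dir, "classifier.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
  }
  list(chain = chain, classifier = classifier, scores = scores)
}
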
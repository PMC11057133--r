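#' Raw novelty of a target module against a reference module set
#'
#' The raw novelty `N` of a (tumor) module is the minimum number of reference
#' (normal) modules needed to cover at least half of its genes. Reference
#' modules are sorted by decreasing overlap with the target (ties broken by
#' larger reference module, then label) and accumulated until coverage
#' reaches `coverage * |target|`; coverage is counted over distinct target
#' genes. Because reference modules are disjoint this greedy rule is exactly
#' optimal. When the threshold is unreachable (target genes absent from every
#' reference module), `N` is the number of overlapping modules plus one and
#' `reached` is `FALSE`, preserving the "more modules needed = more novel"
#' ordering.
#'
#' @param target Non-empty character vector of gene ids.
#' @param reference A `module_set` (grey is excluded from the reference).
#' @param coverage Coverage threshold as a fraction of the target size
#'   (default 0.5, non-strict).
#' @return List with integer `N` and logical `reached`.
#' @export
raw_novelty <- function(target, reference, coverage = 0.5) {
  if (length(target) == 0) stop("target module is empty")
  target <- unique(target)
  mods <- reference$modules
  ov <- vapply(mods, function(m) length(intersect(target, m)), 1L)
  sizes <- lengths(mods)
  ord <- order(-ov, -sizes, names(mods))
  need <- coverage * length(target)
  covered <- character(0)
  n_pos <- sum(ov > 0)
  for (i in seq_along(ord)) {
    m <- mods[[ord[i]]]
    if (length(intersect(target, m)) == 0) break
    covered <- union(covered, intersect(target, m))
    if (length(covered) >= need) {
      return(list(N = i, reached = TRUE))
    }
  }
  list(N = n_pos + 1L, reached = FALSE)
}

#' Novelty score: raw novelty normalized by module size
#'
#' @param N Raw novelty (>= 1).
#' @param S Module size in genes (>= 1).
#' @return `N / S`.
#' @export
novelty_score <- function(N, S) {
  stopifnot(all(N >= 1), all(S >= 1))
  N / S
}

#' Classify novelty scores into tertiles
#'
#' Cutoffs are the 1/3 and 2/3 quantiles of the scores (linear-interpolation
#' quantile, the common statistical default); a score at or below the first
#' cutoff is `low`, at or below the second `medium`, else `high`.
#'
#' @param scores Named numeric vector (names = module labels) or tibble with
#'   columns `module`, `score`.
#' @return Tibble with columns `module`, `score`, `tertile`.
#' @export
classify_tertiles <- function(scores) {
  if (is.data.frame(scores)) {
    lab <- scores$module
    sc <- scores$score
  } else {
    lab <- names(scores)
    sc <- unname(scores)
  }
  stopifnot(length(sc) >= 1)
  q <- stats::quantile(sc, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  tert <- ifelse(sc <= q[1], "low", ifelse(sc <= q[2], "medium", "high"))
  tibble::tibble(module = lab, score = sc,
                 tertile = factor(tert, levels = c("low", "medium", "high")))
}

#' Novelty of every module in a set against a reference set
#'
#' Runs [raw_novelty()] per module, computes the size-normalized score, and
#' classifies tertiles within this comparison.
#'
#' @param modset Target `module_set` (e.g. tumor modules).
#' @param reference Reference `module_set` (e.g. matched normal modules).
#' @param coverage Coverage threshold (see [raw_novelty()]).
#' @return Tibble with columns `module`, `S`, `N`, `reached`, `score`,
#'   `tertile`.
#' @export
module_novelty <- function(modset, reference, coverage = 0.5) {
  rows <- purrr::imap(modset$modules, function(g, lab) {
    rn <- raw_novelty(g, reference, coverage = coverage)
    tibble::tibble(module = lab, S = length(g), N = rn$N,
                   reached = rn$reached,
                   score = novelty_score(rn$N, length(g)))
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) {
    return(tibble::tibble(module = character(), S = integer(), N = integer(),
                          reached = logical(), score = numeric(),
                          tertile = factor(character(),
                                           levels = c("low", "medium", "high"))))
  }
  tert <- classify_tertiles(res[, c("module", "score")])
  dplyr::left_join(res, tert[, c("module", "tertile")], by = "module")
}

#' Maximum pairwise module overlap against other cohorts
#'
#' Overlap of module A with module B is `100 * |A inter B| / |A|`. For each
#' module the maximum over the modules of each other cohort is recorded, and
#' summarized as the per-cohort mean.
#'
#' @param modset A `module_set`.
#' @param others Named list of `module_set`s (the other cohorts).
#' @return List with `per_module` (tibble: module, cohort, max_overlap) and
#'   `per_cohort` (tibble: cohort, mean_max_overlap).
#' @export
max_overlap_profile <- function(modset, others) {
  per_module <- purrr::imap(others, function(other, cname) {
    purrr::imap(modset$modules, function(g, lab) {
      ovs <- vapply(other$modules,
                    function(m) 100 * length(intersect(g, m)) / length(g),
                    1.0)
      tibble::tibble(module = lab, cohort = cname,
                     max_overlap = if (length(ovs)) max(ovs) else 0)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  per_cohort <- dplyr::summarise(dplyr::group_by(per_module, cohort),
                                 mean_max_overlap = mean(max_overlap),
                                 .groups = "drop")
  list(per_module = per_module, per_cohort = per_cohort)
}

#' Random re-partitions of a module set with preserved sizes
#'
#' Genes of the module set's universe (grey excluded) are reassigned uniformly
#' at random to modules of the original sizes; used to build empirical null
#' distributions for module statistics.
#'
#' @param modset A `module_set`.
#' @param n_iter Number of replicates (default 1000).
#' @param seed Integer seed for reproducibility.
#' @return List of `module_set`s of length `n_iter`.
#' @export
randomize_modules <- function(modset, n_iter = 1000, seed = 1) {
  genes <- unlist(modset$modules, use.names = FALSE)
  sizes <- lengths(modset$modules)
  labs <- names(modset$modules)
  set.seed(seed)
  lapply(seq_len(n_iter), function(i) {
    perm <- sample(genes)
    idx <- rep(seq_along(sizes), sizes)
    mods <- split(perm, idx)
    names(mods) <- labs
    new_module_set(lapply(mods, sort), grey = modset$grey)
  })
}
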
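#' Recurrently point-mutated genes
#'
#' A gene is recurrently point mutated when it carries a missense or LoF
#' mutation in at least `min_patients` distinct patients and its
#' non-synonymous to synonymous mutation count ratio is below `max_ns_s`.
#' Non-synonymous counts missense + LoF records; a gene with zero synonymous
#' records has ratio `+Inf` and fails the filter.
#'
#' @param muts Tibble/data frame with columns `gene`, `patient`,
#'   `consequence` (values among `missense`, `LoF`, `synonymous`, `other`).
#' @param min_patients Patient floor (default 3).
#' @param max_ns_s Ratio ceiling (default 1, strict `<`).
#' @return Character vector of gene ids.
#' @export
recurrent_point_mutated <- function(muts, min_patients = 3, max_ns_s = 1) {
  muts <- tibble::as_tibble(muts)
  stopifnot(all(c("gene", "patient", "consequence") %in% names(muts)))
  per_gene <- dplyr::summarise(
    dplyr::group_by(muts, gene),
    n_pat = dplyr::n_distinct(patient[consequence %in% c("missense", "LoF")]),
    n_ns = sum(consequence %in% c("missense", "LoF")),
    n_s = sum(consequence == "synonymous"),
    .groups = "drop"
  )
  ratio <- ifelse(per_gene$n_s == 0, Inf, per_gene$n_ns / per_gene$n_s)
  sort(per_gene$gene[per_gene$n_pat >= min_patients & ratio < max_ns_s])
}

#' Per-gene, per-patient focal copy-number calls
#'
#' A gene's aberration in a patient is taken from the segment overlapping the
#' gene's midpoint; the call is focal when that segment spans at most
#' `focal_fraction` of its chromosome's length (non-strict), separating
#' sub-chromosomal events from arm/whole-chromosome gains and losses.
#' Coordinates are 0-based half-open; chromosome names are normalized by
#' stripping any `chr` prefix.
#'
#' @param segments Tibble with columns `patient`, `chrom`, `start`, `end`,
#'   `state` (`amp`, `del`, or `neutral`).
#' @param gene_coords Tibble with columns `gene`, `chrom`, `start`, `end`.
#' @param chrom_lengths Optional named numeric vector of chromosome lengths;
#'   when missing, the maximum observed end per chromosome is used.
#' @param focal_fraction Focality threshold (default 0.25).
#' @return Tibble with columns `patient`, `gene`, `state`, one row per focal
#'   amp/del call.
#' @export
focal_gene_calls <- function(segments, gene_coords, chrom_lengths = NULL,
                             focal_fraction = 0.25) {
  segments <- tibble::as_tibble(segments)
  gene_coords <- tibble::as_tibble(gene_coords)
  norm_chr <- function(x) sub("^chr", "", as.character(x))
  segments$chrom <- norm_chr(segments$chrom)
  gene_coords$chrom <- norm_chr(gene_coords$chrom)
  if (any(segments$start >= segments$end)) stop("segment start must be < end")
  if (is.null(chrom_lengths)) {
    ends <- c(segments$end, gene_coords$end)
    chroms <- c(segments$chrom, gene_coords$chrom)
    chrom_lengths <- tapply(ends, chroms, max)
  } else {
    names(chrom_lengths) <- norm_chr(names(chrom_lengths))
  }
  gene_coords$mid <- (gene_coords$start + gene_coords$end) / 2
  ab <- segments[segments$state %in% c("amp", "del"), ]
  if (nrow(ab) == 0) {
    return(tibble::tibble(patient = character(), gene = character(),
                          state = character()))
  }
  hits <- dplyr::inner_join(ab, gene_coords, by = "chrom",
                            suffix = c("_seg", "_gene"),
                            relationship = "many-to-many")
  hits <- hits[hits$mid >= hits$start_seg & hits$mid < hits$end_seg, ]
  span <- (hits$end_seg - hits$start_seg) /
    unname(chrom_lengths[hits$chrom])
  hits <- hits[span <= focal_fraction, ]
  out <- tibble::tibble(patient = hits$patient, gene = hits$gene,
                        state = hits$state)
  dplyr::distinct(out)
}

#' Recurrently amplified / deleted genes from focal calls
#'
#' Genes focally amplified (resp. deleted) in at least
#' `min_fraction * n_patients` patients.
#'
#' @param focal_calls Output of [focal_gene_calls()].
#' @param n_patients Cohort size (> 0).
#' @param min_fraction Recurrence threshold (default 0.10, non-strict).
#' @return List with character vectors `amp` and `del`.
#' @export
recurrent_cna <- function(focal_calls, n_patients, min_fraction = 0.10) {
  stopifnot(n_patients > 0)
  floor_n <- min_fraction * n_patients
  count_state <- function(st) {
    calls <- focal_calls[focal_calls$state == st, ]
    if (nrow(calls) == 0) return(character())
    tab <- dplyr::summarise(dplyr::group_by(calls, gene),
                            n = dplyr::n_distinct(patient),
                            .groups = "drop")
    sort(tab$gene[tab$n >= floor_n])
  }
  list(amp = count_state("amp"), del = count_state("del"))
}

#' Flag a module for recurrent CNA content
#'
#' @param module Non-empty character vector of gene ids.
#' @param recurrent Character vector of recurrently altered genes.
#' @param min_fraction Flagging threshold on the module fraction
#'   (default 0.10, non-strict).
#' @return Tibble with `fraction` and logical `flagged`.
#' @export
module_cna_flag <- function(module, recurrent, min_fraction = 0.10) {
  if (length(module) == 0) stop("module is empty")
  frac <- length(intersect(module, recurrent)) / length(module)
  tibble::tibble(fraction = frac, flagged = frac >= min_fraction)
}

#' Percentage of known driver genes in a module
#'
#' Drivers are matched to the tumor type in which they are reported; modules
#' with no driver overlap are flagged for downstream exclusion.
#'
#' @param module Non-empty character vector of gene ids.
#' @param drivers Tibble with columns `gene`, `tumor_type`.
#' @param tumor_type Tumor type to match (must appear in `drivers`).
#' @return Tibble with `percent` and logical `excluded` (no driver overlap).
#' @export
driver_fraction <- function(module, drivers, tumor_type) {
  if (length(module) == 0) stop("module is empty")
  known <- unique(drivers$tumor_type)
  if (!tumor_type %in% known) {
    stop("unknown tumor type `", tumor_type, "`; known types: ",
         paste(sort(known), collapse = ", "))
  }
  dset <- unique(drivers$gene[drivers$tumor_type == tumor_type])
  pct <- 100 * length(intersect(module, dset)) / length(module)
  tibble::tibble(percent = pct, excluded = pct == 0)
}

#' Gene centrality within a module network
#'
#' Degree is the sum of a gene's edge weights to all other module genes;
#' degrees are normalized by the module's median degree, ranked ascending
#' with average ties, divided by the module size, and shifted by -1. The
#' resulting centrality lies in (-1, 0]; values near 0 mark hubs, values near
#' -1 the module periphery.
#'
#' @param module_net Symmetric numeric matrix (intra-module network,
#'   size >= 2).
#' @return Tibble with columns `gene`, `degree`, `norm_degree`, `rel_rank`,
#'   `centrality`.
#' @export
centrality <- function(module_net) {
  stopifnot(is.matrix(module_net), nrow(module_net) >= 2)
  s <- nrow(module_net)
  w <- module_net
  diag(w) <- 0
  deg <- rowSums(w)
  if (all(deg == 0)) warning("all degrees are zero; centralities tie")
  med <- stats::median(deg)
  norm_deg <- if (med > 0) deg / med else deg
  rk <- rank(deg, ties.method = "average")
  rel <- rk / s
  tibble::tibble(gene = rownames(module_net), degree = unname(deg),
                 norm_degree = unname(norm_deg), rel_rank = unname(rel),
                 centrality = unname(rel) - 1)
}

#' Centrality change of a gene between tumor and normal modules
#'
#' @param gene Gene id.
#' @param tumor_tables,normal_tables A centrality tibble (from
#'   [centrality()]) or list of such tibbles, one per module.
#' @return Tibble with `delta` (tumor - normal centrality) and `defined`;
#'   `delta` is `NA` when the gene is missing from either condition.
#' @export
centrality_shift <- function(gene, tumor_tables, normal_tables) {
  as_list <- function(x) if (is.data.frame(x)) list(x) else x
  find <- function(tables) {
    for (tb in as_list(tables)) {
      hit <- tb$centrality[tb$gene == gene]
      if (length(hit)) return(hit[1])
    }
    NA_real_
  }
  ct <- find(tumor_tables)
  cn <- find(normal_tables)
  tibble::tibble(gene = gene, tumor = ct, normal = cn,
                 delta = ct - cn, defined = !is.na(ct) && !is.na(cn))
}

#' Enrichment of CNA-flagged modules in tumors vs normal tissue
#'
#' For each state (`amp`, `del`) builds the 2x2 table of normal vs tumor
#' module collections against flagged (>= `min_fraction` recurrent genes) vs
#' not, and applies a one-sided Fisher test (alternative `less`: flagged
#' modules under-represented among normal modules).
#'
#' @param tumor_modsets,normal_modsets A `module_set` or list of them.
#' @param recurrent List with `amp` and `del` gene vectors
#'   (see [recurrent_cna()]).
#' @param min_fraction Module flagging threshold (default 0.10).
#' @return Tibble, one row per state, with the table cells, `odds_ratio`,
#'   and `p`.
#' @export
cna_module_enrichment <- function(tumor_modsets, normal_modsets, recurrent,
                                  min_fraction = 0.10) {
  all_mods <- function(x) {
    if (inherits(x, "module_set")) x <- list(x)
    unlist(lapply(x, `[[`, "modules"), recursive = FALSE)
  }
  tmods <- all_mods(tumor_modsets)
  nmods <- all_mods(normal_modsets)
  if (!length(tmods) || !length(nmods)) stop("both module collections must be non-empty")
  rows <- lapply(c("amp", "del"), function(st) {
    flag <- function(mods) vapply(mods, function(m) {
      module_cna_flag(m, recurrent[[st]], min_fraction)$flagged
    }, TRUE)
    fn <- flag(nmods); ft <- flag(tmods)
    tab <- matrix(c(sum(fn), sum(ft), sum(!fn), sum(!ft)), 2,
                  dimnames = list(c("normal", "tumor"),
                                  c("flagged", "not_flagged")))
    res <- fisher_2x2(tab, alternative = "less")
    tibble::tibble(state = st,
                   normal_flagged = sum(fn), normal_total = length(fn),
                   tumor_flagged = sum(ft), tumor_total = length(ft),
                   odds_ratio = res$odds_ratio, p = res$p)
  })
  dplyr::bind_rows(rows)
}

#' Read a MAF-like mutation table (gene, patient, consequence TSV)
#' @param path TSV path.
#' @return Tibble.
#' @export
read_mutations <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gene", "patient", "consequence") %in% names(df)))
  if (any(!nzchar(df$gene)) || any(!nzchar(df$patient))) {
    stop("gene and patient ids must be non-empty")
  }
  df
}

#' Read a SEG-like copy-number segment table
#' @param path TSV with columns patient, chrom, start, end, state.
#' @return Tibble.
#' @export
read_segments <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("patient", "chrom", "start", "end", "state") %in% names(df)))
  bad <- setdiff(unique(df$state), c("amp", "del", "neutral"))
  if (length(bad)) stop("unknown CNA state(s): ", paste(bad, collapse = ", "))
  df
}

#' Read a BED-like gene coordinate table
#' @param path TSV with columns gene, chrom, start, end.
#' @return Tibble.
#' @export
read_gene_coords <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(df)))
  df
}

#' Read a driver gene table (gene, tumor_type TSV)
#' @param path TSV path.
#' @return Tibble.
#' @export
read_drivers <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gene", "tumor_type") %in% names(df)))
  df
}
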
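#' Configuration for the paired tumor/normal cohort simulator
#'
#' Defaults describe a desk-scale cohort: 600 genes, 60 tumor/normal sample
#' pairs, and six planted gene blocks of 40-60 genes each. Two blocks are
#' preserved modules active in both conditions (one UC-biased, one
#' MC-biased); three are normal-only "donor" modules of mixed age; the sixth
#' is a mixed-age block active only in high-grade tumors. Two tumor-only
#' modules are built by recombining donor-module genes, emulating the
#' rewiring of co-expression seen in tumors: their genes are co-expressed
#' with new partners in tumors while belonging to distinct donor modules in
#' normal tissue. Counts are negative-binomial around log-normal means driven
#' by per-module latent factors, so the CPM filter and rank-based scoring are
#' exercised on realistic data.
#'
#' @param n_genes Total genes (default 600).
#' @param n_pairs Tumor/normal sample pairs (default 60).
#' @param modules Data frame of planted module specs (columns `name`, `size`,
#'   `uc_fraction`, `activity` in both/normal_only/tumor_only/high_grade_only,
#'   `shift` log2 mean shift when active, `sources` comma-separated donor
#'   names for tumor-only modules).
#' @param loading Latent-factor loading on member genes (default 1.2).
#' @param factor_sd Latent factor standard deviation (default 1).
#' @param noise_sd Per-gene, per-sample log2 noise (default 0.3).
#' @param dispersion Negative-binomial dispersion phi (default 0.2).
#' @param lib_range Library-size factor range (default c(0.7, 1.3)).
#' @param base_range Range of baseline log2 mean expression (default c(3, 9)).
#' @param n_low_genes Background genes with near-silent expression, to give
#'   the CPM filter something to drop (default 20).
#' @param background_uc Genome-wide UC fraction for background genes
#'   (default 0.45).
#' @param high_grade_fraction Fraction of tumor samples labeled high grade
#'   (default 0.5).
#' @param amp_drivers,del_drivers Number of amplification / deletion driver
#'   genes (defaults 3 and 2).
#' @param amp_carrier_fraction,del_carrier_fraction Fractions of tumor
#'   patients carrying the focal events (defaults 0.3 and 0.12).
#' @param amp_log2fc Expression shift in carriers (default 1.5; deletions use
#'   its negative).
#' @param hub_loading,peripheral_loading Loadings of driver genes in their
#'   tumor module (hub) and normal module (periphery) (defaults 1.8, 0.5).
#' @param broad_event_prob Per-tumor-patient probability of a non-focal
#'   whole-chromosome gain (default 0.2).
#' @param seed Master seed (default 1).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 600, n_pairs = 60,
                             modules = default_planted_modules(),
                             loading = 1.2, factor_sd = 1, noise_sd = 0.3,
                             dispersion = 0.2, lib_range = c(0.7, 1.3),
                             base_range = c(3, 9), n_low_genes = 20,
                             background_uc = 0.45,
                             high_grade_fraction = 0.5,
                             amp_drivers = 3, del_drivers = 2,
                             amp_carrier_fraction = 0.3,
                             del_carrier_fraction = 0.12,
                             amp_log2fc = 1.5,
                             hub_loading = 1.8, peripheral_loading = 0.5,
                             broad_event_prob = 0.2,
                             seed = 1) {
  modules <- tibble::as_tibble(modules)
  own <- modules[modules$activity != "tumor_only", ]
  if (sum(own$size) > n_genes) stop("planted module sizes exceed gene count")
  stopifnot(all(modules$uc_fraction >= 0 & modules$uc_fraction <= 1),
            amp_carrier_fraction >= 0, amp_carrier_fraction <= 1,
            del_carrier_fraction >= 0, del_carrier_fraction <= 1)
  reuse <- modules[modules$activity == "tumor_only", ]
  if (nrow(reuse)) {
    donor <- modules$size[modules$activity == "normal_only"]
    if (sum(reuse$size) > sum(donor)) {
      stop("tumor-only module sizes exceed the donor gene pool")
    }
  }
  structure(list(
    n_genes = n_genes, n_pairs = n_pairs, modules = modules,
    loading = loading, factor_sd = factor_sd, noise_sd = noise_sd,
    dispersion = dispersion, lib_range = lib_range, base_range = base_range,
    n_low_genes = n_low_genes, background_uc = background_uc,
    high_grade_fraction = high_grade_fraction,
    amp_drivers = amp_drivers, del_drivers = del_drivers,
    amp_carrier_fraction = amp_carrier_fraction,
    del_carrier_fraction = del_carrier_fraction,
    amp_log2fc = amp_log2fc, hub_loading = hub_loading,
    peripheral_loading = peripheral_loading,
    broad_event_prob = broad_event_prob, seed = seed
  ), class = "synthetic_config")
}

#' Default planted module layout (see [synthetic_config()])
#' @return Tibble of module specs.
#' @export
default_planted_modules <- function() {
  tibble::tibble(
    name = c("P1", "P2", "D1", "D2", "D3", "T1", "T2", "H1"),
    size = c(60L, 50L, 50L, 45L, 45L, 50L, 45L, 40L),
    uc_fraction = c(0.8, 0.2, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    activity = c("both", "both", "normal_only", "normal_only", "normal_only",
                 "tumor_only", "tumor_only", "high_grade_only"),
    shift = c(0, 0, 0, 0, 0, 1, 1, 1),
    sources = c(NA, NA, NA, NA, NA, "D1,D2,D3", "D1,D2,D3", NA)
  )
}

#' Simulate a paired tumor/normal cohort with known ground truth
#'
#' See [synthetic_config()] for the generative model. The same seed always
#' yields the identical cohort.
#'
#' @param config A `synthetic_config`.
#' @return A `synthetic_cohort`: list with `counts` (genes x samples integer
#'   matrix), `manifest` (sample, condition, pair_id, grade, stage), `ages`
#'   (gene age tibble), `truth` (gene, normal_module, tumor_module),
#'   `mutations`, `segments`, `gene_coords`, `drivers`, `amp_drivers`,
#'   `del_drivers`, and the `config`.
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  n_genes <- cfg$n_genes
  genes <- sprintf("G%04d", seq_len(n_genes))

  ## --- membership: owning blocks partition the planted genes -------------
  specs <- cfg$modules
  own_specs <- specs[specs$activity != "tumor_only", ]
  gene_ptr <- 1L
  owner <- stats::setNames(rep(NA_character_, n_genes), genes)
  for (i in seq_len(nrow(own_specs))) {
    idx <- gene_ptr:(gene_ptr + own_specs$size[i] - 1L)
    owner[idx] <- own_specs$name[i]
    gene_ptr <- gene_ptr + own_specs$size[i]
  }

  ## per-condition module membership
  normal_mod <- stats::setNames(
    ifelse(owner %in% specs$name[specs$activity %in%
                                   c("both", "normal_only")],
           owner, NA_character_), genes)
  tumor_mod <- stats::setNames(
    ifelse(owner %in% specs$name[specs$activity %in%
                                   c("both", "high_grade_only")],
           owner, NA_character_), genes)
  ## tumor-only modules recombine donor genes (round-robin across sources)
  t_specs <- specs[specs$activity == "tumor_only", ]
  for (i in seq_len(nrow(t_specs))) {
    srcs <- strsplit(t_specs$sources[i], ",")[[1]]
    pool <- genes[owner %in% srcs & is.na(tumor_mod)]
    ## interleave donors so each tumor-only module mixes all sources
    pool_src <- owner[pool]
    ord <- order(stats::ave(seq_along(pool), pool_src, FUN = seq_along),
                 pool_src)
    take <- pool[ord][seq_len(t_specs$size[i])]
    tumor_mod[take] <- t_specs$name[i]
  }

  ## --- gene ages: exact UC counts per owning block, background at global --
  strata <- stats::setNames(integer(n_genes), genes)
  assign_strata <- function(ids, uc_frac) {
    n_uc <- round(uc_frac * length(ids))
    uc_ids <- sample(ids, n_uc)
    mc_ids <- setdiff(ids, uc_ids)
    strata[uc_ids] <<- sample(1:3, length(uc_ids), replace = TRUE)
    strata[mc_ids] <<- sample(4:16, length(mc_ids), replace = TRUE)
  }
  for (i in seq_len(nrow(own_specs))) {
    assign_strata(genes[!is.na(owner) & owner == own_specs$name[i]],
                  own_specs$uc_fraction[i])
  }
  bg <- genes[is.na(owner)]
  n_uc_bg <- round(cfg$background_uc * length(bg))
  uc_bg <- sample(bg, n_uc_bg)
  strata[uc_bg] <- sample(1:3, length(uc_bg), replace = TRUE)
  strata[setdiff(bg, uc_bg)] <- sample(4:16, length(bg) - n_uc_bg,
                                       replace = TRUE)
  ages <- gene_age_table(genes, unname(strata))

  ## --- samples -----------------------------------------------------------
  np <- cfg$n_pairs
  pair_id <- sprintf("P%03d", seq_len(np))
  normal_samples <- sprintf("N%03d", seq_len(np))
  tumor_samples <- sprintf("T%03d", seq_len(np))
  n_high <- round(cfg$high_grade_fraction * np)
  grade_t <- sample(rep(c("high", "low"), c(n_high, np - n_high)))
  manifest <- tibble::tibble(
    sample = c(normal_samples, tumor_samples),
    condition = rep(c("normal", "tumor"), each = np),
    pair_id = rep(pair_id, 2),
    grade = c(rep(NA_character_, np), grade_t),
    stage = c(rep("normal", np),
              ifelse(grade_t == "high", "high_grade", "low_grade"))
  )

  ## --- baseline means and loadings ---------------------------------------
  b <- stats::runif(n_genes, cfg$base_range[1], cfg$base_range[2])
  names(b) <- genes
  if (cfg$n_low_genes > 0) {
    low <- sample(bg, min(cfg$n_low_genes, length(bg)))
    b[low] <- stats::runif(length(low), -5, -3)
  }

  ## driver genes: hubs of the first tumor-only module / members of the
  ## second, with asymmetric loadings between conditions
  amp_dr <- del_dr <- character(0)
  if (nrow(t_specs) >= 1) {
    amp_dr <- utils::head(genes[!is.na(tumor_mod) &
                                  tumor_mod == t_specs$name[1]],
                          cfg$amp_drivers)
    del_src <- t_specs$name[min(2, nrow(t_specs))]
    del_dr <- utils::head(setdiff(genes[!is.na(tumor_mod) &
                                          tumor_mod == del_src], amp_dr),
                          cfg$del_drivers)
  }
  lam_normal <- stats::setNames(rep(cfg$loading, n_genes), genes)
  lam_tumor <- stats::setNames(rep(cfg$loading, n_genes), genes)
  lam_tumor[amp_dr] <- cfg$hub_loading
  lam_normal[amp_dr] <- cfg$peripheral_loading

  ## --- CNA events --------------------------------------------------------
  n_chr <- 6L
  per_chr <- ceiling(n_genes / n_chr)
  chrom <- as.character(rep(seq_len(n_chr), each = per_chr)[seq_len(n_genes)])
  pos_in_chr <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  gene_coords <- tibble::tibble(
    gene = genes, chrom = chrom,
    start = (pos_in_chr - 1) * 10000, end = (pos_in_chr - 1) * 10000 + 5000
  )
  chr_len <- per_chr * 10000
  amp_carriers <- sort(sample(tumor_samples,
                              round(cfg$amp_carrier_fraction * np)))
  del_carriers <- sort(sample(tumor_samples,
                              round(cfg$del_carrier_fraction * np)))
  seg_rows <- list()
  mk_focal <- function(g, patient, state) {
    gc <- gene_coords[gene_coords$gene == g, ]
    span <- 0.05 * chr_len
    st <- max(0, gc$start - span / 2)
    tibble::tibble(patient = patient, chrom = gc$chrom,
                   start = st, end = min(chr_len, st + span), state = state)
  }
  for (p in amp_carriers) {
    for (g in amp_dr) seg_rows[[length(seg_rows) + 1]] <- mk_focal(g, p, "amp")
  }
  for (p in del_carriers) {
    for (g in del_dr) seg_rows[[length(seg_rows) + 1]] <- mk_focal(g, p, "del")
  }
  broad <- stats::runif(np) < cfg$broad_event_prob
  for (j in which(broad)) {
    seg_rows[[length(seg_rows) + 1]] <- tibble::tibble(
      patient = tumor_samples[j], chrom = as.character(sample.int(n_chr, 1)),
      start = 0, end = chr_len, state = "amp")
  }
  segments <- dplyr::bind_rows(seg_rows)
  if (nrow(segments) == 0) {
    segments <- tibble::tibble(patient = character(), chrom = character(),
                               start = numeric(), end = numeric(),
                               state = character())
  }

  ## --- point mutations ---------------------------------------------------
  mut_rows <- list()
  rec_genes <- if (nrow(t_specs) >= 1) {
    utils::head(setdiff(genes[!is.na(tumor_mod) &
                                tumor_mod == t_specs$name[1]],
                        amp_dr), 3)
  } else character(0)
  for (g in rec_genes) {
    pats <- sample(tumor_samples, 4)
    mut_rows[[length(mut_rows) + 1]] <- tibble::tibble(
      gene = g, patient = pats, consequence = "missense")
    mut_rows[[length(mut_rows) + 1]] <- tibble::tibble(
      gene = g, patient = sample(tumor_samples, 6, replace = TRUE),
      consequence = "synonymous")
  }
  below_floor <- sample(bg, 5)  # mutated in too few patients
  for (g in below_floor) {
    mut_rows[[length(mut_rows) + 1]] <- tibble::tibble(
      gene = g, patient = sample(tumor_samples, 2),
      consequence = "missense")
  }
  high_ratio <- sample(setdiff(bg, below_floor), 3)  # NS/S ratio >= 1
  for (g in high_ratio) {
    mut_rows[[length(mut_rows) + 1]] <- tibble::tibble(
      gene = g, patient = sample(tumor_samples, 6, replace = TRUE),
      consequence = "missense")
    mut_rows[[length(mut_rows) + 1]] <- tibble::tibble(
      gene = g, patient = sample(tumor_samples, 2),
      consequence = "synonymous")
  }
  mutations <- dplyr::bind_rows(mut_rows)
  if (nrow(mutations) == 0) {
    mutations <- tibble::tibble(gene = character(), patient = character(),
                                consequence = character())
  }

  drivers <- tibble::tibble(
    gene = c(amp_dr, del_dr, sample(bg, 4)),
    tumor_type = "SYNTH"
  )

  ## --- expression --------------------------------------------------------
  all_samples <- manifest$sample
  n_s <- nrow(manifest)
  lib <- stats::runif(n_s, cfg$lib_range[1], cfg$lib_range[2])
  log2mu <- matrix(rep(b, n_s), nrow = n_genes,
                   dimnames = list(genes, all_samples))
  active_specs <- function(cond, grd) {
    keep <- specs$activity == "both" |
      (specs$activity == "normal_only" & cond == "normal") |
      (specs$activity == "tumor_only" & cond == "tumor") |
      (specs$activity == "high_grade_only" & cond == "tumor" &
         !is.na(grd) & grd == "high")
    specs$name[keep]
  }
  for (j in seq_len(n_s)) {
    cond <- manifest$condition[j]
    grd <- manifest$grade[j]
    membership <- if (cond == "normal") normal_mod else tumor_mod
    lam <- if (cond == "normal") lam_normal else lam_tumor
    for (m in active_specs(cond, grd)) {
      memb <- genes[!is.na(membership) & membership == m]
      if (length(memb) == 0) next
      f <- stats::rnorm(1, 0, cfg$factor_sd)
      sh <- specs$shift[specs$name == m]
      log2mu[memb, j] <- log2mu[memb, j] + lam[memb] * f + sh
    }
  }
  ## carrier expression shifts from CNAs
  log2mu[amp_dr, amp_carriers] <- log2mu[amp_dr, amp_carriers] + cfg$amp_log2fc
  log2mu[del_dr, del_carriers] <- log2mu[del_dr, del_carriers] - cfg$amp_log2fc
  noise <- matrix(stats::rnorm(n_genes * n_s, 0, cfg$noise_sd),
                  nrow = n_genes)
  mu <- 2^(log2mu + noise) * rep(lib, each = n_genes)
  counts <- matrix(stats::rnbinom(n_genes * n_s, mu = mu,
                                  size = 1 / cfg$dispersion),
                   nrow = n_genes, dimnames = list(genes, all_samples))

  truth <- tibble::tibble(gene = genes,
                          normal_module = unname(normal_mod),
                          tumor_module = unname(tumor_mod))
  structure(list(counts = counts, manifest = manifest, ages = ages,
                 truth = truth, mutations = mutations, segments = segments,
                 gene_coords = gene_coords, drivers = drivers,
                 amp_drivers = amp_dr, del_drivers = del_dr,
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d genes x %d samples (%d pairs), seed %d>\n",
              nrow(x$counts), ncol(x$counts), x$config$n_pairs,
              x$config$seed))
  invisible(x)
}

#' Adjusted Rand index between detected and planted modules
#'
#' Grey/unassigned genes are excluded on the detected side; genes without a
#' planted module are excluded on the truth side. The ARI is computed over
#' the remaining shared genes with [mclust::adjustedRandIndex()].
#'
#' @param detected A `module_set`.
#' @param truth The cohort `truth` tibble (or a named character vector
#'   gene -> module).
#' @param condition Which truth column to use: `"tumor"` or `"normal"`
#'   (ignored for a named vector).
#' @return Numeric ARI.
#' @export
truth_recovery <- function(detected, truth, condition = c("tumor", "normal")) {
  condition <- match.arg(condition)
  if (is.data.frame(truth)) {
    col <- paste0(condition, "_module")
    planted <- stats::setNames(truth[[col]], truth$gene)
  } else {
    planted <- truth
  }
  planted <- planted[!is.na(planted)]
  det_tb <- module_table(detected, include_grey = FALSE)
  shared <- intersect(det_tb$gene, names(planted))
  if (length(shared) == 0) return(0)
  det <- det_tb$module[match(shared, det_tb$gene)]
  mclust::adjustedRandIndex(det, planted[shared])
}

#' Log2 counts-per-million transform
#'
#' @param counts Genes x samples count matrix.
#' @param prior Pseudocount added after CPM scaling (default 1).
#' @return Matrix of `log2(cpm + prior)`.
#' @export
logcpm <- function(counts, prior = 1) {
  libs <- colSums(counts)
  if (any(libs <= 0)) stop("library size must be > 0")
  log2(sweep(counts, 2, libs, "/") * 1e6 + prior)
}

#' Write a synthetic cohort to pipeline-format text files
#'
#' Produces exactly the formats the pipeline readers consume: expression and
#' manifest TSVs, gene ages, MAF-like mutations, SEG-like segments, BED-like
#' gene coordinates, and the driver table.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- tibble::as_tibble(cohort$counts, rownames = "gene")
  readr::write_tsv(expr, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$manifest, file.path(dir, "manifest.tsv"))
  write_phylostrata(cohort$ages, file.path(dir, "ages.tsv"))
  readr::write_tsv(cohort$mutations, file.path(dir, "mutations.tsv"))
  readr::write_tsv(cohort$segments, file.path(dir, "segments.tsv"))
  readr::write_tsv(cohort$gene_coords, file.path(dir, "gene_coords.tsv"))
  readr::write_tsv(cohort$drivers, file.path(dir, "drivers.tsv"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a genes x samples expression TSV (first column `gene`)
#' @param path TSV path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  storage.mode(m) <- "double"
  m
}

#' Read a sample manifest TSV (sample, condition, pair_id, ...)
#' @param path TSV path.
#' @return Tibble.
#' @export
read_manifest <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("sample", "condition") %in% names(df)))
  df
}
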
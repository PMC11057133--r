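mk_muts <- function(...) tibble::tibble(...)

test_that("recurrent point mutation filter applies both rules", {
  muts <- dplyr::bind_rows(
    # 3 patients with missense, 2 NS vs 4 S overall -> ratio 0.5 -> recurrent
    mk_muts(gene = "OK", patient = c("p1", "p2", "p3"),
            consequence = c("missense", "missense", "LoF")),
    mk_muts(gene = "OK", patient = paste0("p", 4:6),
            consequence = "synonymous"),
    mk_muts(gene = "OK", patient = "p7", consequence = "synonymous"),
    # only 2 patients -> below the floor
    mk_muts(gene = "FEW", patient = c("p1", "p2"),
            consequence = "missense"),
    mk_muts(gene = "FEW", patient = paste0("p", 3:8),
            consequence = "synonymous"),
    # 6 NS vs 2 S -> ratio 3 -> fails
    mk_muts(gene = "HOT", patient = paste0("p", 1:6),
            consequence = "missense"),
    mk_muts(gene = "HOT", patient = c("p7", "p8"),
            consequence = "synonymous"),
    # zero synonymous -> ratio +Inf -> fails
    mk_muts(gene = "NOSYN", patient = paste0("p", 1:4),
            consequence = "missense")
  )
  expect_equal(recurrent_point_mutated(muts), "OK")
  # ratio direction is configurable
  expect_true("HOT" %in% recurrent_point_mutated(muts, max_ns_s = Inf))
})

test_that("focality is a bounded fraction of the chromosome", {
  coords <- tibble::tibble(gene = c("EGFRish", "OTHER"),
                           chrom = c("chr7", "7"),
                           start = c(40000, 200000), end = c(45000, 205000))
  segs <- tibble::tibble(
    patient = c("p1", "p1", "p2", "p3"),
    chrom = c("7", "7", "7", "7"),
    start = c(30000, 0, 0, 190000),
    end = c(80000, 1e6, 1e6, 190000 + 0.25 * 1e6),  # exactly at threshold
    state = c("amp", "neutral", "amp", "del")
  )
  lens <- c("7" = 1e6)
  calls <- focal_gene_calls(segs, coords, chrom_lengths = lens)
  # 5% segment containing the gene midpoint -> focal amp
  expect_true(any(calls$patient == "p1" & calls$gene == "EGFRish" &
                    calls$state == "amp"))
  # whole-chromosome gain is not focal
  expect_false(any(calls$patient == "p2"))
  # segment spanning exactly the threshold fraction is focal (non-strict)
  expect_true(any(calls$patient == "p3" & calls$gene == "OTHER" &
                    calls$state == "del"))
})

test_that("CNA recurrence uses an at-least fraction of patients", {
  calls <- tibble::tibble(
    patient = c(paste0("p", 1:5), paste0("q", 1:4)),
    gene = c(rep("AMP10", 5), rep("AMP8", 4)),
    state = "amp"
  )
  rec <- recurrent_cna(calls, n_patients = 50, min_fraction = 0.10)
  expect_equal(rec$amp, "AMP10")     # 5/50 is exactly 10%
  expect_equal(rec$del, character(0))
  # monotone non-increasing in the threshold
  for (f in c(0.02, 0.06, 0.1, 0.2)) {
    hi <- recurrent_cna(calls, 50, f)
    lo <- recurrent_cna(calls, 50, f + 0.02)
    expect_true(all(lo$amp %in% hi$amp))
  }
})

test_that("module CNA flags and driver percentages count boundary cases", {
  mod <- paste0("g", 1:30)
  expect_true(module_cna_flag(mod, paste0("g", 1:3))$flagged)     # 10%
  expect_false(module_cna_flag(mod, paste0("g", 1:2))$flagged)
  expect_equal(module_cna_flag(mod, "none")$fraction, 0)

  drivers <- tibble::tibble(gene = c(paste0("g", 1:5), "x1"),
                            tumor_type = c(rep("BRCA", 5), "LUAD"))
  df <- driver_fraction(paste0("g", 1:50), drivers, "BRCA")
  expect_equal(df$percent, 10)
  expect_false(df$excluded)
  none <- driver_fraction(paste0("h", 1:10), drivers, "BRCA")
  expect_equal(none$percent, 0)
  expect_true(none$excluded)
  full <- driver_fraction(paste0("g", 1:5), drivers, "BRCA")
  expect_equal(full$percent, 100)
  expect_error(driver_fraction(mod, drivers, "NOPE"), "BRCA")
})

test_that("centrality ranks hubs at zero and ties symmetric graphs", {
  # star: one hub connected to all, spokes unconnected among themselves
  s <- 5
  star <- matrix(0, s, s, dimnames = list(paste0("g", 1:s), paste0("g", 1:s)))
  star[1, -1] <- star[-1, 1] <- 1
  diag(star) <- 1
  ct <- centrality(star)
  expect_equal(ct$centrality[ct$gene == "g1"], 0)
  expect_true(all(ct$centrality[-1] < 0))
  expect_equal(length(unique(ct$centrality[-1])), 1)  # spokes tie

  # complete graph with equal weights: everyone ties at (S+1)/(2S) - 1
  comp <- matrix(0.6, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(comp) <- 1
  ctc <- centrality(comp)
  expect_true(all(abs(ctc$centrality - (5 / 8 - 1)) < 1e-12))

  # 4-gene weighted toy against hand-computed values
  w <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  w["a", "b"] <- w["b", "a"] <- 0.9
  w["a", "c"] <- w["c", "a"] <- 0.5
  w["b", "c"] <- w["c", "b"] <- 0.3
  w["c", "d"] <- w["d", "c"] <- 0.1
  diag(w) <- 1
  ct4 <- centrality(w)
  deg <- c(a = 1.4, b = 1.2, c = 0.9, d = 0.1)
  expect_equal(setNames(ct4$degree, ct4$gene), deg)
  expect_equal(setNames(ct4$norm_degree, ct4$gene), deg / median(deg))
  expect_equal(setNames(ct4$centrality, ct4$gene),
               c(a = 4 / 4, b = 3 / 4, c = 2 / 4, d = 1 / 4) - 1)
  # monotone in degree
  expect_equal(order(ct4$degree), order(ct4$centrality))
})

test_that("centrality shifts compare a gene across conditions", {
  tn <- tibble::tibble(gene = c("a", "b"), centrality = c(0, -0.5))
  nn <- tibble::tibble(gene = c("a", "c"), centrality = c(-0.75, 0))
  sh <- centrality_shift("a", tn, nn)
  expect_equal(sh$delta, 0.75)
  expect_true(sh$defined)
  und <- centrality_shift("b", tn, nn)
  expect_false(und$defined)
  # identical topology in both conditions -> zero shift
  same <- centrality_shift("a", tn, tn)
  expect_equal(same$delta, 0)
})

test_that("flagged-module enrichment reproduces the published tables", {
  # Rebuild module collections whose flag counts give the printed tables:
  # normal 2/337 vs tumor 51/1166 amplified; 1/337 vs 39/1166 deleted.
  rec <- list(amp = paste0("A", 1:5), del = paste0("D", 1:5))
  mk_mod <- function(flag_amp, flag_del, i) {
    g <- paste0("bg", i, "_", 1:10)
    if (flag_amp) g[1:2] <- paste0("A", 1:2)
    if (flag_del) g[3:4] <- paste0("D", 1:2)
    g
  }
  mk_set <- function(n_amp, n_del, n_total, tag) {
    mods <- lapply(seq_len(n_total), function(i) {
      mk_mod(i <= n_amp, i > n_amp & i <= n_amp + n_del, paste0(tag, i))
    })
    names(mods) <- paste0(tag, seq_len(n_total))
    do.call(small_module_set, mods)
  }
  normal <- mk_set(2, 1, 337, "n")
  tumor <- mk_set(51, 39, 1166, "t")
  enr <- cna_module_enrichment(tumor, normal, rec)
  expect_equal(enr$normal_flagged, c(2, 1))
  expect_equal(enr$tumor_flagged, c(51, 39))
  expect_equal(enr$odds_ratio[enr$state == "amp"], 0.13,
               tolerance = 0.005 / 0.13)
  expect_equal(enr$odds_ratio[enr$state == "del"], 0.086,
               tolerance = 0.0005 / 0.086)
  # equal flag rates give an odds ratio near 1
  eq <- cna_module_enrichment(mk_set(5, 5, 50, "x"), mk_set(5, 5, 50, "y"),
                              rec)
  expect_equal(eq$odds_ratio, c(1, 1), tolerance = 1e-9)
})
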
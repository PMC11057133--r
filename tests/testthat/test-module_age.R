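test_that("cross-product odds ratios reproduce published module contrasts", {
  # tumor vs normal mixed-module excess
  or1 <- fisher_2x2(matrix(c(774, 137, 392, 200), 2))
  expect_equal(or1$odds_ratio, 2.88, tolerance = 0.005 / 2.88)
  # recurrently amplified / deleted module contrasts (one-sided)
  or2 <- fisher_2x2(matrix(c(2, 51, 335, 1115), 2), alternative = "less")
  expect_equal(or2$odds_ratio, 0.13, tolerance = 0.005 / 0.13)
  or3 <- fisher_2x2(matrix(c(1, 39, 336, 1127), 2), alternative = "less")
  expect_equal(or3$odds_ratio, 0.086, tolerance = 0.0005 / 0.086)
  # balanced proportions
  or4 <- fisher_2x2(matrix(c(10, 20, 10, 20), 2))
  expect_equal(or4$odds_ratio, 1)
  expect_equal(or4$p, 1)
})

test_that("exact p-values agree with direct hypergeometric enumeration", {
  set.seed(21)
  for (rep in 1:30) {
    tab <- matrix(rpois(4, 12), 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    for (alt in c("greater", "less", "two.sided")) {
      expect_equal(fisher_2x2(tab, alternative = alt)$p,
                   brute_fisher_p(tab, alt), tolerance = 1e-10,
                   info = paste(alt, paste(tab, collapse = ",")))
    }
  }
})

test_that("zero cells trigger the flagged continuity correction", {
  res <- fisher_2x2(matrix(c(0, 5, 10, 5), 2))
  expect_true(res$corrected)
  expect_equal(res$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))
  degen <- fisher_2x2(matrix(c(0, 0, 10, 5), 2))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$odds_ratio))
})

test_that("age enrichment flags extreme modules and leaves balanced ones mixed", {
  ages <- gene_age_table(sprintf("G%03d", 1:200),
                         rep(c(1, 8), each = 100))  # 50% UC background
  background <- ages$gene
  uc_mod <- sprintf("G%03d", 1:30)                  # all UC
  res <- classify_module_age(uc_mod, ages, background, label = "ucmod")
  expect_lt(res$p_uc, 1e-6)
  adj <- adjust_and_categorize(res)
  expect_equal(adj$category, "UC-enriched")

  balanced <- sprintf("G%03d", c(1:15, 101:115))    # exactly background ratio
  adj2 <- adjust_and_categorize(
    classify_module_age(balanced, ages, background))
  expect_gte(adj2$adj_p_uc, 0.05)
  expect_gte(adj2$adj_p_mc, 0.05)
  expect_equal(adj2$category, "mixed")

  # MC-only module in an MC-only background: no enrichment is possible
  mc_ages <- gene_age_table(paste0("M", 1:50), rep(10, 50))
  adj3 <- adjust_and_categorize(
    classify_module_age(paste0("M", 1:10), mc_ages, mc_ages$gene))
  expect_equal(adj3$p_mc, 1)
  expect_equal(adj3$category, "mixed")
})

test_that("BH adjustment matches hand-computed values and preserves order", {
  res <- tibble::tibble(module = c("a", "b", "c"),
                        n_uc = 1L, n_mc = 1L, bg_uc = 2L, bg_mc = 2L,
                        p_uc = c(0.01, 0.02, 0.04), p_mc = 1,
                        unclassifiable = FALSE)
  adj <- adjust_and_categorize(res)
  expect_equal(adj$adj_p_uc, c(0.03, 0.03, 0.04))
  # single test: identity
  one <- adjust_and_categorize(res[1, ])
  expect_equal(one$adj_p_uc, 0.01)
  expect_equal(one$category, "UC-enriched")
  # all p = 1 -> all mixed
  allone <- dplyr::mutate(res, p_uc = 1, p_mc = 1)
  expect_true(all(adjust_and_categorize(allone)$category == "mixed"))
  # monotone on random p's
  set.seed(2)
  p <- runif(20)
  res20 <- tibble::tibble(module = paste0("m", 1:20), n_uc = 1L, n_mc = 1L,
                          bg_uc = 2L, bg_mc = 2L, p_uc = p, p_mc = rev(p),
                          unclassifiable = FALSE)
  adj20 <- adjust_and_categorize(res20)
  expect_equal(order(adj20$adj_p_uc[order(p)]), 1:20)
})

test_that("UC and MC over-representation are never both significant", {
  set.seed(31)
  for (rep in 1:30) {
    n_bg <- sample(50:300, 1)
    ages <- gene_age_table(paste0("g", seq_len(n_bg)),
                           sample(1:16, n_bg, TRUE))
    mod <- sample(ages$gene, sample(5:40, 1))
    adj <- adjust_and_categorize(
      classify_module_age(mod, ages, ages$gene), alpha = 0.05)
    expect_false(isTRUE(adj$adj_p_uc < 0.05) && isTRUE(adj$adj_p_mc < 0.05))
  }
})

test_that("over-representation analysis ranks the matching set first", {
  background <- paste0("g", 1:200)
  sets <- list(hit = paste0("g", 1:20),
               other = paste0("g", 101:140))
  res <- ora(paste0("g", 1:20), sets, background)
  expect_equal(res$set[1], "hit")
  expect_lt(res$p[1], 1e-4)
  # disjoint module
  res2 <- ora(paste0("g", 151:160), list(s = paste0("g", 1:10)), background)
  expect_equal(res2$p, 1)
  # module == background: overlap is forced, p = 1 for every set
  res3 <- ora(background, sets, background)
  expect_true(all(res3$p == 1))
  # exclusion post-filter and GMT round trip
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("hit\tdesc\tg1\tg2\tg3", "skipme\tdesc\tg4\tg5"), gmt)
  loaded <- read_gmt(gmt)
  expect_equal(loaded$hit, c("g1", "g2", "g3"))
  res4 <- ora(paste0("g", 1:5), loaded, background, exclude = "skipme")
  expect_false("skipme" %in% res4$set)
})
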
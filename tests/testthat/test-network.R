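test_that("CPM filter keeps genes expressed in all samples of either group", {
  # 4 samples (2 tumor, 2 normal), library sizes engineered via a filler gene
  counts <- rbind(
    gA = c(400, 400, 0, 0),      # high in all tumors, absent in normals
    gB = c(0.5, 0.5, 0.5, 0.5),  # CPM ~0.5 everywhere given the filler
    gC = c(400, 0, 400, 0),      # misses one sample in each group
    filler = c(1e6, 1e6, 1e6, 1e6)
  )
  colnames(counts) <- c("T1", "T2", "N1", "N2")
  cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  expect_true(all(cpm["gA", c("T1", "T2")] > 1))
  expect_true(all(cpm["gB", ] < 1))
  kept <- cpm_filter(counts, c("T1", "T2"), c("N1", "N2"))
  expect_true("gA" %in% kept)
  expect_false("gB" %in% kept)
  expect_false("gC" %in% kept)   # fails the all-samples rule in both groups
  expect_error(cpm_filter(counts, character(0), c("N1", "N2")), "non-empty")
})

test_that("outlier samples and their pair partners are dropped together", {
  set.seed(1)
  expr <- matrix(rnorm(50 * 20, sd = 0.1), 50,
                 dimnames = list(NULL, paste0("s", 1:20)))
  expr[, "s20"] <- expr[, "s20"] + 50        # far from everything
  pair <- rep(paste0("p", 1:10), 2)          # s10 is s20's partner
  out <- remove_outlier_samples(expr, pair_id = pair)
  expect_setequal(attr(out, "dropped"), c("s20", "s10"))

  # identical replicates: nothing dropped
  same <- matrix(rep(rnorm(20), 5), 20)
  colnames(same) <- paste0("r", 1:5)
  expect_equal(ncol(remove_outlier_samples(same)), 5)

  # unpaired design prunes per sample only
  out2 <- remove_outlier_samples(expr)
  expect_equal(attr(out2, "dropped"), "s20")
})

test_that("constant and mostly-missing genes are dropped before networks", {
  expr <- rbind(const = rep(5, 10),
                ok = rnorm(10),
                holey = c(rnorm(4), rep(NA, 6)))
  out <- drop_bad_genes(expr, max_missing = 0.5)
  expect_equal(rownames(out), "ok")
})

test_that("unsigned adjacency equals |pearson|^beta against a hand oracle", {
  set.seed(3)
  expr <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  net <- adjacency(expr, beta = 6)
  for (i in 1:3) for (j in 1:3) {
    expected <- if (i == j) 1 else abs(brute_pearson(expr[i, ], expr[j, ]))^6
    expect_equal(net$weights[i, j], expected, tolerance = 1e-12)
  }
  # identical and sign-flipped profiles are maximally adjacent
  x <- rnorm(6)
  ident <- rbind(g1 = x, g2 = x + 0, g3 = -x)
  net2 <- adjacency(ident, beta = 4)
  expect_equal(unname(net2$weights["g1", "g2"]), 1)
  expect_equal(unname(net2$weights["g1", "g3"]), 1)
  expect_error(adjacency(rbind(a = rep(1, 5), b = rnorm(5))), "zero-variance")
})

test_that("topological overlap matches the triple-loop formula", {
  # complete graph: all off-diagonal TOM = 1
  a <- matrix(1, 3, 3)
  expect_true(all(abs(tom(a)$weights - 1) < 1e-12))
  # no direct edge, no shared neighbor -> 0
  b <- diag(4)
  b[1, 2] <- b[2, 1] <- 0
  b[3, 4] <- b[4, 3] <- 0.5
  expect_equal(tom(b)$weights[1, 2], 0)
  set.seed(11)
  for (rep in 1:5) {
    a <- random_adjacency(sample(4:12, 1))
    expect_equal(tom(a)$weights, brute_tom(a), tolerance = 1e-10)
  }
  expect_error(tom(matrix(c(1, 0.2, 0.4, 1), 2)), "symmetric")
  expect_error(tom(matrix(c(1, 2, 2, 1), 2)), "\\[0, 1\\]")
})

test_that("raising an edge weight never lowers that pair's overlap", {
  set.seed(5)
  for (rep in 1:20) {
    a <- random_adjacency(6)
    i <- 2; j <- 5
    a2 <- a
    bump <- min(1 - a[i, j], runif(1, 0, 0.3))
    a2[i, j] <- a2[j, i] <- a[i, j] + bump
    expect_gte(tom(a2)$weights[i, j], tom(a)$weights[i, j] - 1e-12)
  }
})

test_that("module detection recovers planted blocks and is order-invariant", {
  sim <- make_block_expr(c(12, 10), n_samples = 40, n_noise = 5, seed = 9)
  net <- tom(adjacency(sim$expr, beta = 6))
  mods <- detect_modules(net, min_size = 8)
  expect_length(mods$modules, 2)
  expect_setequal(mods$modules$M1, names(sim$block)[sim$block == "B1"])
  expect_setequal(mods$modules$M2, names(sim$block)[sim$block == "B2"])

  # permuting gene order leaves module contents unchanged
  perm <- sample(nrow(sim$expr))
  mods_p <- detect_modules(tom(adjacency(sim$expr[perm, ], beta = 6)),
                           min_size = 8)
  expect_setequal(mods_p$modules$M1, mods$modules$M1)
  expect_setequal(mods_p$modules$M2, mods$modules$M2)
})

test_that("one shared factor gives one module; pure noise gives all grey", {
  sim <- make_block_expr(25, n_samples = 40, n_noise = 0, seed = 2)
  mods <- detect_modules(tom(adjacency(sim$expr)), min_size = 10)
  expect_length(mods$modules, 1)
  expect_length(mods$modules$M1, 25)

  set.seed(4)
  noise <- matrix(rnorm(40 * 100), 40,
                  dimnames = list(paste0("n", 1:40), NULL))
  mods2 <- detect_modules(tom(adjacency(noise)), min_size = 30)
  expect_length(mods2$modules, 0)
  expect_length(mods2$grey, 40)
})

test_that("intra-module networks are exact sub-matrices of the parent", {
  a <- random_adjacency(5)
  net <- tom(a)
  all_g <- rownames(a)
  expect_equal(extract_module_network(net, all_g), net$weights)
  solo <- extract_module_network(net, all_g[2])
  expect_equal(unname(solo), matrix(1))
  sub <- extract_module_network(net, all_g[c(1, 3, 5)])
  expect_equal(sub, net$weights[c(1, 3, 5), c(1, 3, 5)])
  expect_error(extract_module_network(net, "nope"), "not in network")
})

test_that("module tables round-trip through their TSV representation", {
  ms <- small_module_set(M1 = paste0("a", 1:5), M2 = paste0("b", 1:3))
  tb <- module_table(ms)
  ms2 <- module_set_from_table(tb)
  expect_equal(ms2$modules, ms$modules)
  expect_equal(ms2$grey, ms$grey)
})
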
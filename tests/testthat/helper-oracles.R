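# Independent reference implementations used to freeze expected values.
# These deliberately avoid the package's code paths: plain loops and
# closed-form combinatorics only.

# Pearson correlation from first principles (no stats::cor)
brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Triple-loop topological overlap
brute_tom <- function(a) {
  n <- nrow(a)
  out <- matrix(1, n, n, dimnames = dimnames(a))
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# Exhaustive minimum-subset novelty: smallest number of reference modules
# whose union covers >= coverage * |target| distinct target genes.
brute_min_cover <- function(target, ref_list, coverage = 0.5) {
  need <- coverage * length(unique(target))
  m <- length(ref_list)
  best <- Inf
  for (k in seq_len(m)) {
    combos <- utils::combn(m, k, simplify = FALSE)
    for (cmb in combos) {
      covered <- length(intersect(unique(target),
                                  unique(unlist(ref_list[cmb]))))
      if (covered >= need) {
        best <- min(best, k)
        break
      }
    }
    if (is.finite(best)) break
  }
  best
}

# Hypergeometric tail probabilities by direct enumeration with choose()
brute_fisher_p <- function(tab, alternative) {
  a <- tab[1, 1]
  row1 <- sum(tab[1, ]); col1 <- sum(tab[, 1]); total <- sum(tab)
  k_min <- max(0, row1 + col1 - total)
  k_max <- min(row1, col1)
  pk <- function(k) {
    choose(col1, k) * choose(total - col1, row1 - k) / choose(total, row1)
  }
  ks <- k_min:k_max
  probs <- vapply(ks, pk, 1.0)
  switch(alternative,
         greater = sum(probs[ks >= a]),
         less = sum(probs[ks <= a]),
         two.sided = sum(probs[probs <= pk(a) * (1 + 1e-7)]))
}

# Step-by-step ssGSEA running sum, written against the definition
brute_ssgsea <- function(expr_col, gene_set, alpha = 0.25) {
  n <- length(expr_col)
  ord <- order(-expr_col, names(expr_col))
  genes <- names(expr_col)[ord]
  asc_rank <- n:1                      # position 1 = most expressed
  in_set <- genes %in% gene_set
  total_w <- sum(asc_rank[in_set]^alpha)
  n_out <- sum(!in_set)
  cum_in <- 0; cum_out <- 0; es <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) cum_in <- cum_in + asc_rank[i]^alpha else cum_out <- cum_out + 1
    es <- es + cum_in / total_w - cum_out / n_out
  }
  es
}

# Small block-correlated expression matrix: each block driven by one factor
make_block_expr <- function(block_sizes, n_samples, n_noise = 0,
                            loading = 2, noise_sd = 0.3, seed = 42) {
  set.seed(seed)
  n_genes <- sum(block_sizes) + n_noise
  genes <- sprintf("g%03d", seq_len(n_genes))
  expr <- matrix(rnorm(n_genes * n_samples, sd = noise_sd), n_genes,
                 dimnames = list(genes, paste0("s", seq_len(n_samples))))
  start <- 1
  block <- rep("noise", n_genes)
  for (b in seq_along(block_sizes)) {
    idx <- start:(start + block_sizes[b] - 1)
    f <- rnorm(n_samples)
    expr[idx, ] <- expr[idx, ] + loading * matrix(f, length(idx), n_samples,
                                                  byrow = TRUE)
    block[idx] <- paste0("B", b)
    start <- start + block_sizes[b]
  }
  list(expr = expr, block = setNames(block, genes))
}

small_module_set <- function(...) {
  mods <- list(...)
  coexage::module_set_from_table(
    tibble::tibble(gene = unlist(mods, use.names = FALSE),
                   module = rep(names(mods), lengths(mods)))
  )
}
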
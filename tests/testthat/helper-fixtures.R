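# Shared fixtures and small oracles, built in code at test time.

# small simulator configuration for fast unit tests
small_sim <- function(seed = 1, ...) {
  sim_config(n_genes = 200, n_cell_types = 5, markers_per_type = 10,
             marker_fold_change = 8, n_cells_per_type = 30, grid_side = 10,
             mito_gene_count = 10, seed = seed, ...)
}

# adjusted Rand index (independent of any clustering package)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

# exhaustive-enumeration oracle for the upper-tail hypergeometric:
# draw all C(N, n) subsets of 1..N, count those sharing >= k members with 1..K
hyper_tail_enum <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# brute-force GSEA running sum: explicit step-by-step walk down the list
gsea_es_brute <- function(ranked, metric, gene_set, weight_p = 1) {
  N <- length(ranked)
  hit <- ranked %in% gene_set
  nh <- sum(hit)
  denom_hit <- sum(abs(metric[hit])^weight_p)
  run <- 0
  best_pos <- -Inf
  best_neg <- Inf
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + (if (denom_hit > 0) abs(metric[i])^weight_p / denom_hit
                    else 1 / nh)
    } else {
      run <- run - 1 / (N - nh)
    }
    if (run > best_pos) best_pos <- run
    if (run < best_neg) best_neg <- run
  }
  if (best_pos >= -best_neg - 1e-9) best_pos else best_neg
}

# exact two-sided rank-sum p by enumerating every group assignment
wilcox_exact_enum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# toy QC matrix: spots sitting exactly on, above and below both thresholds
qc_boundary_matrix <- function() {
  n_genes <- 260
  genes <- c("MT-1", sprintf("G%03d", seq_len(n_genes - 1)))
  spots <- c("mito099", "mito100", "mito101", "genes199", "genes200",
             "genes201")
  m <- matrix(0, n_genes, length(spots), dimnames = list(genes, spots))
  # mito spots: total 1000 counts over 250 genes, mito share 99/100/101
  for (i in 1:3) {
    mito_counts <- c(99, 100, 101)[i]
    m["MT-1", i] <- mito_counts
    rest <- 1000 - mito_counts
    idx <- sprintf("G%03d", 1:249)
    base <- rest %/% 249
    m[idx, i] <- base
    extra <- rest - base * 249
    if (extra > 0) m[idx[seq_len(extra)], i] <- base + 1
  }
  # gene-count spots: exactly 199 / 200 / 201 detected genes, no mito
  for (i in 1:3) {
    ng <- c(199, 200, 201)[i]
    m[sprintf("G%03d", 1:ng), 3 + i] <- 1
  }
  count_matrix(m)
}

# planted three-module co-expression design: module m follows a noisy
# indicator of region m, its first gene is a stronger-loading hub, plus
# unstructured background genes
planted_network <- function(seed, n_obs = 120, genes_per = 50, n_noise = 150,
                            hub_loading = 0.97, loading = sqrt(0.8)) {
  set.seed(seed)
  regions <- c("cortex", "medulla", "pelvis")
  reg <- rep(regions, each = n_obs / 3)
  f <- sapply(seq_len(3), function(m) {
    drop(scale(as.numeric(reg == regions[m]) + stats::rnorm(n_obs, 0, 0.5)))
  })
  x <- do.call(rbind, lapply(1:3, function(m) {
    load <- c(hub_loading, rep(loading, genes_per - 1))
    t(sapply(seq_len(genes_per), function(i) {
      load[i] * f[, m] + sqrt(1 - load[i]^2) * stats::rnorm(n_obs)
    }))
  }))
  x <- rbind(x, matrix(stats::rnorm(n_noise * n_obs), n_noise, n_obs))
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%03d", seq_len(n_obs))
  list(x = x, regions = reg,
       truth = rep(c(1, 2, 3, 0), c(genes_per, genes_per, genes_per, n_noise)),
       hubs = sprintf("g%03d", c(1, genes_per + 1, 2 * genes_per + 1)),
       geom = data.frame(spot_id = colnames(x), x = 0, y = 0, region = reg))
}
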
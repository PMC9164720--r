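test_that("QC thresholds are strict: boundary spots are retained", {
  cm <- qc_boundary_matrix()
  res <- qc_filter(cm, max_mito_frac = 0.10, min_genes = 200)
  expect_setequal(res$report$obs_id, c("mito101", "genes199"))
  expect_setequal(colnames(res$filtered$counts),
                  c("mito099", "mito100", "genes200", "genes201"))
  expect_equal(res$report$reason[res$report$obs_id == "mito101"], "mito_frac")
  expect_equal(res$report$reason[res$report$obs_id == "genes199"], "n_genes")
})

test_that("QC without mitochondrial genes applies only the gene-count rule", {
  m <- matrix(1, 250, 2, dimnames = list(sprintf("G%d", 1:250), c("a", "b")))
  m[1:100, 2] <- 0   # b detects only 150 genes
  res <- qc_filter(count_matrix(m), min_genes = 200)
  expect_equal(res$report$obs_id, "b")
  expect_equal(res$report$reason, "n_genes")
  # filtered output is an untouched submatrix
  expect_identical(as.matrix(res$filtered$counts), m[, "a", drop = FALSE])
  expect_error(qc_filter(count_matrix(m), min_genes = 300),
               "no observations survive")
})

test_that("log-CP10K normalization matches its closed form", {
  m <- matrix(c(1, 99, 0, 10, 2, 198, 0, 20), 4, 2,
              dimnames = list(sprintf("G%d", 1:4), c("a", "b")))
  nm <- normalize_cp10k(count_matrix(m))
  expect_equal(nm["G1", "a"], log(1 + 1e4 * 1 / 110))
  expect_equal(nm["G3", "a"], 0)
  # column b doubles column a: identical normalized profiles
  expect_equal(nm[, "a"], nm[, "b"])
  m[, 1] <- 0
  expect_error(normalize_cp10k(count_matrix(m)), "all-zero")
  # the count-1/total-100 closed form
  m2 <- matrix(c(1, 99), 2, 1, dimnames = list(c("G1", "G2"), "a"))
  expect_equal(normalize_cp10k(count_matrix(m2))["G1", "a"], log(101),
               tolerance = 1e-12)
})

test_that("variable-gene selection ranks planted markers on top", {
  cfg <- small_sim(seed = 6)
  ref <- generate_reference(cfg)
  nm <- normalize_cp10k(ref$counts)
  hv <- select_hvgs(nm, n_top = 60)
  planted <- unlist(ref$truth$marker_map)
  expect_gte(mean(planted %in% hv), 0.95)
  expect_setequal(select_hvgs(nm, n_top = nrow(nm)), rownames(nm))
  expect_error(select_hvgs(nm, n_top = nrow(nm) + 1), "exceeds")
  expect_error(select_hvgs(matrix(1, 5, 4,
                                  dimnames = list(letters[1:5], NULL)),
                           n_top = 3),
               "constant")
})

test_that("hypervariable-gene ties break lexicographically", {
  set.seed(1)
  base <- rnorm(20, 5)
  x <- rbind(zB = base, zA = base, other = rnorm(20, 5, 3))
  colnames(x) <- sprintf("s%d", 1:20)
  top <- select_hvgs(x, n_top = 3)
  expect_equal(which(top == "zA") < which(top == "zB"), TRUE)
})

test_that("PCA embedding is ordered, sign-fixed and orthogonal", {
  set.seed(2)
  # rank-1 data: one direction explains everything
  u <- rnorm(30)
  x <- outer(rnorm(10), u)
  dimnames(x) <- list(sprintf("g%d", 1:10), sprintf("s%d", 1:30))
  e <- embed_pca(x + 1e-10 * matrix(rnorm(300), 10), n_components = 2)
  expect_gt(e$variance_explained[1], 0.999)
  # general case: non-increasing variance, exact reconstruction at full rank
  y <- matrix(rnorm(15 * 40), 15, 40,
              dimnames = list(sprintf("g%d", 1:15), sprintf("s%d", 1:40)))
  e2 <- embed_pca(y, n_components = 15)
  expect_true(all(diff(e2$variance_explained) <= 1e-12))
  recon <- e2$coords %*% t(e2$loadings)     # observations x genes
  expect_lt(max(abs(recon - unname(scale(t(y))))), 1e-8)
  # sign convention: the largest-magnitude loading entry is positive
  peak <- apply(e2$loadings, 2, function(l) l[which.max(abs(l))])
  expect_true(all(peak > 0))
  expect_error(embed_pca(y, n_components = 16), "exceeds")
})

test_that("clustering recovers the planted cell-type count on reference data", {
  counts <- vapply(1:3, function(s) {
    cfg <- sim_config(seed = s)
    ref <- generate_reference(cfg)
    nm <- normalize_cp10k(ref$counts)
    cl <- cluster_graph(embed_pca(nm, 30), resolution = 0.9,
                        k_neighbors = 20, seed = 0)
    length(unique(cl$labels))
  }, 0)
  expect_true(all(abs(counts - 15) <= 3))
})

test_that("graph clustering separates well-separated blobs deterministically", {
  aris <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 60
    pts <- rbind(matrix(rnorm(n * 2), n, 2),
                 matrix(rnorm(n * 2, mean = 10), n, 2))
    rownames(pts) <- sprintf("o%03d", seq_len(2 * n))
    cl <- cluster_graph(pts, resolution = 0.9, k_neighbors = 30, seed = 0)
    ari(cl$labels, rep(1:2, each = n))
  }, 0)
  expect_true(all(aris == 1))
  set.seed(9)
  pts <- matrix(rnorm(200), 100, 2, dimnames = list(sprintf("o%d", 1:100)))
  c1 <- cluster_graph(pts, seed = 42)
  c2 <- cluster_graph(pts, seed = 42)
  expect_identical(c1$labels, c2$labels)
  # resolution -> 0 collapses to one community
  c0 <- cluster_graph(pts, resolution = 1e-4, seed = 0)
  expect_equal(length(unique(c0$labels)), 1)
  expect_error(cluster_graph(pts[1:10, ], k_neighbors = 20), "k")
  # labels are contiguous from 1
  expect_setequal(unique(c1$labels), seq_len(max(c1$labels)))
})
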
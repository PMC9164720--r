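test_that("adjacency is |cor|^beta with the expected algebraic behaviour", {
  set.seed(5)
  x <- matrix(rnorm(6 * 50), 6, 50,
              dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:50)))
  x[2, ] <- x[1, ] * 2 + 3                 # perfectly correlated pair
  a1 <- build_adjacency(x, 1)
  expect_equal(a1, abs(cor(t(x))), tolerance = 1e-12, ignore_attr = TRUE)
  a2 <- build_adjacency(x, 2)
  expect_equal(unname(a2[1, 3]), unname(a1[1, 3]^2), tolerance = 1e-12)
  expect_equal(a2[1, 2], 1)
  expect_equal(diag(a2), setNames(rep(1, 6), rownames(x)))
  expect_lt(max(abs(a2 - t(a2))), 1e-12)
  # monotone decreasing in beta off the perfect-correlation diagonal
  a4 <- build_adjacency(x, 4)
  off <- upper.tri(a2) & a1 < 1
  expect_true(all(a4[off] <= a2[off] + 1e-15))
  x[3, ] <- 7
  expect_error(build_adjacency(x, 2), "zero-variance")
  expect_error(build_adjacency(x[-3, ], 0.5), ">= 1")
})

test_that("soft-power selection returns a singleton unconditionally and warns on noise", {
  pn <- planted_network(seed = 21)
  single <- suppressWarnings(pick_soft_power(pn$x, powers = 6))
  expect_equal(single$power, 6)
  # a constant gene is removed with a warning before correlation
  xz <- rbind(pn$x, flat = 1)
  w <- testthat::capture_warnings(pick_soft_power(xz, powers = 6))
  expect_true(any(grepl("constant", w)))
  # structured data reaches the scale-free target at some power
  pk <- suppressWarnings(pick_soft_power(pn$x))
  expect_true(pk$power %in% 1:20)
  expect_equal(nrow(pk$fit_indices), 20)
})

test_that("module detection recovers planted modules and ignores noise genes", {
  for (s in 1:2) {
    pn <- planted_network(seed = s)
    adj <- build_adjacency(pn$x, 6)
    mods <- detect_modules(adj, pn$x, min_size = 20)
    expect_gt(ari(mods$modules, pn$truth), 0.8)
    # noise genes stay unassigned
    noise <- pn$truth == 0
    expect_gt(mean(mods$modules[noise] == 0), 0.9)
  }
  # min_size larger than the gene count leaves everything unassigned
  pn <- planted_network(seed = 3, genes_per = 5, n_noise = 5)
  adj <- build_adjacency(pn$x, 6)
  mods <- detect_modules(adj, pn$x, min_size = 1000)
  expect_true(all(mods$modules == 0))
})

test_that("eigengenes equal the SVD first component and are sign-stable", {
  pn <- planted_network(seed = 6)
  adj <- build_adjacency(pn$x, 6)
  mods <- detect_modules(adj, pn$x, min_size = 20)
  me <- module_eigengenes(pn$x, mods)
  for (m in colnames(me$eigengenes)) {
    id <- as.integer(sub("M", "", m))
    sub <- pn$x[names(mods$modules)[mods$modules == id], , drop = FALSE]
    xs <- t(scale(t(sub)))
    sv <- svd(xs)
    oracle <- sv$v[, 1]
    if (cor(oracle, colMeans(xs)) < 0) oracle <- -oracle
    expect_lt(max(abs(me$eigengenes[, m] - oracle)), 1e-8)
    # unit norm and dominant variance share
    expect_equal(sum(me$eigengenes[, m]^2), 1, tolerance = 1e-12)
    expect_equal(me$variance_explained[[m]], sv$d[1]^2 / sum(sv$d^2),
                 tolerance = 1e-12)
  }
  # flipping the sign of every module gene leaves the eigengene unchanged
  id1 <- names(mods$modules)[mods$modules == 1]
  x2 <- pn$x
  x2[id1, ] <- -x2[id1, ]
  me2 <- module_eigengenes(x2, mods)
  expect_lt(max(abs(abs(me2$eigengenes[, "M1"]) -
                      abs(me$eigengenes[, "M1"]))), 1e-8)
  # a module of identical genes is summarized perfectly
  ident <- matrix(rep(rnorm(30), 4), 4, 30, byrow = TRUE,
                  dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:30)))
  mei <- module_eigengenes(ident, setNames(rep(1L, 4), rownames(ident)))
  expect_equal(unname(mei$variance_explained), 1, tolerance = 1e-12)
})

test_that("module-region correlation flags exactly the planted associations", {
  pn <- planted_network(seed = 7)
  adj <- build_adjacency(pn$x, 6)
  mods <- detect_modules(adj, pn$x, min_size = 20)
  mrc <- module_region_correlation(mods$eigengenes, pn$geom)
  expect_true(all(mrc$r >= -1 & mrc$r <= 1))
  expect_true(all(mrc$p >= 0 & mrc$p <= 1))
  # one strong region per module, and it is the planted one
  strong <- mrc[mrc$strong, ]
  expect_equal(nrow(strong), 3)
  expect_equal(sort(strong$region), c("cortex", "medulla", "pelvis"))
  # an eigengene that IS the indicator correlates perfectly
  ind <- as.numeric(pn$geom$region == "cortex")
  eg <- cbind(Mx = ind)
  rownames(eg) <- pn$geom$spot_id
  mrcx <- module_region_correlation(eg, pn$geom)
  expect_equal(mrcx$r[mrcx$region == "cortex"], 1, tolerance = 1e-12)
  expect_lt(mrcx$p[mrcx$region == "cortex"], 1e-12)
  # the flag needs both r > 0.4 and p below the cutoff
  expect_true(all(!mrcx$strong[mrcx$r <= 0.4]))
})

test_that("hub ranking follows intramodular connectivity", {
  # star module: gene h correlates with everything, satellites barely with
  # each other
  a <- matrix(0.1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  a["a", ] <- a[, "a"] <- 0.9
  diag(a) <- 1
  mods <- setNames(rep(1L, 5), letters[1:5])
  hb <- hub_genes(a, mods, top_n = 5)
  expect_equal(hb$gene[1], "a")
  expect_equal(hb$connectivity[1], 0.9 * 4)
  # two-gene module: equal connectivity, lexicographic order
  a2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("zz", "aa"),
                                                        c("zz", "aa")))
  hb2 <- hub_genes(a2, setNames(c(1L, 1L), c("zz", "aa")))
  expect_equal(hb2$connectivity, c(0.5, 0.5))
  expect_equal(hb2$gene, c("aa", "zz"))
  # planted hubs rank first
  pn <- planted_network(seed = 8)
  adj <- build_adjacency(pn$x, 6)
  mods3 <- detect_modules(adj, pn$x, min_size = 20)
  top <- hub_genes(adj, mods3, top_n = 1)
  expect_true(all(pn$hubs %in% top$gene))
})
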
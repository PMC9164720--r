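test_that("signatures are marker-restricted per-type means", {
  nm <- matrix(c(2, 0, 1,
                 2, 0, 1,
                 0, 3, 1,
                 0, 3, 1), 4, 3, byrow = TRUE,
               dimnames = list(c("gA1", "gA2", "gB1", "gB2"),
                               c("c1", "c2", "c3")))
  labels <- setNames(c("A", "B", "B"), colnames(nm))
  markers <- gene_set_collection(list(A = c("gA1", "gA2"),
                                      B = c("gB1", "gB2")))
  sig <- build_signatures(nm, labels, markers)
  expect_equal(dim(sig), c(4, 2))
  expect_equal(sig["gA1", "A"], 2)
  expect_equal(sig["gB1", "B"], mean(c(3, 1)))
  expect_error(build_signatures(nm, labels,
                                gene_set_collection(list(A = "gNOPE"))),
               "gNOPE")
  # duplicated cell types give collinear columns and a conditioning warning
  labels2 <- setNames(c("A", "A2", "B"), colnames(nm))
  nm2 <- nm; nm2[, 2] <- nm2[, 1]
  expect_warning(build_signatures(nm2, labels2, markers), "ill-conditioned")
})

test_that("NNLS recovers exact mixtures and applies the contribution filter", {
  sig <- diag(c(1, 1, 1))
  dimnames(sig) <- list(c("g1", "g2", "g3"), c("A", "B", "C"))
  spots <- cbind(mix = 0.7 * sig[, "A"] + 0.3 * sig[, "B"],
                 pure = sig[, "C"],
                 minor = 0.88 * sig[, "A"] + 0.07 * sig[, "B"] +
                   0.05 * sig[, "C"])
  pt <- deconvolve_spots(spots, sig, min_contribution = 0.10)
  expect_equal(pt$raw["mix", ], c(A = 0.7, B = 0.3, C = 0), tolerance = 1e-6)
  expect_equal(pt$proportions["pure", ], c(A = 0, B = 0, C = 1),
               tolerance = 1e-6)
  # sub-threshold contributions are zeroed and the rest renormalized
  expect_equal(unname(pt$proportions["minor", ]), c(1, 0, 0),
               tolerance = 1e-6)
  expect_equal(unname(pt$raw["minor", ]), c(0.88, 0.07, 0.05),
               tolerance = 1e-6)
  # without renormalization the surviving entries keep their raw values
  pt2 <- deconvolve_spots(spots, sig, renormalize = FALSE)
  expect_equal(unname(pt2$proportions["minor", ]), c(0.88, 0, 0),
               tolerance = 1e-6)
  # an all-zero profile is flagged, not an error
  spots0 <- cbind(spots, dead = c(0, 0, 0))
  pt3 <- deconvolve_spots(spots0, sig)
  expect_equal(pt3$zero_spots, "dead")
  expect_true(all(pt3$proportions["dead", ] == 0))
})

test_that("NNLS residual never increases as basis types are added", {
  set.seed(4)
  genes <- sprintf("g%02d", 1:30)
  sig <- matrix(abs(rnorm(30 * 4)), 30, 4,
                dimnames = list(genes, LETTERS[1:4]))
  b <- abs(rnorm(30))
  resid <- vapply(1:4, function(k) {
    fit <- pracma::lsqnonneg(sig[, 1:k, drop = FALSE], b)
    sqrt(sum((b - sig[, 1:k, drop = FALSE] %*% fit$x)^2))
  }, 0)
  expect_true(all(diff(resid) <= 1e-10))
})

test_that("noiseless Dirichlet mixtures are recovered within MAE 0.05", {
  cfg <- small_sim(seed = 12)
  ref <- generate_reference(cfg)
  nm <- normalize_cp10k(ref$counts)
  sets <- gene_set_collection(ref$truth$marker_map)
  sig <- build_signatures(nm, ref$truth$cell_labels, sets)
  set.seed(12)
  truth <- t(vapply(1:40, function(i) {
    w <- rgamma(ncol(sig), 0.5); w / sum(w)
  }, numeric(ncol(sig))))
  spots <- sig %*% t(truth)
  colnames(spots) <- sprintf("spot%02d", 1:40)
  rownames(truth) <- colnames(spots)
  pt <- deconvolve_spots(spots, sig, min_contribution = 0.10)
  expect_lt(mean(abs(pt$raw - truth)), 0.05)
})

test_that("region fractions implement the share-of-type formula", {
  p <- matrix(c(1.0, 1.0, 0.5, 0.5, 1.0, 0,
                0,   0,   0,   0,   0,   1), 6, 2,
              dimnames = list(sprintf("s%d", 1:6), c("A", "B")))
  pt <- structure(list(proportions = p), class = "ProportionTable")
  geom <- data.frame(spot_id = sprintf("s%d", 1:6),
                     x = 0, y = 0,
                     region = c("cortex", "cortex", "medulla", "medulla",
                                "pelvis", "pelvis"))
  rf <- region_fractions(pt, geom)
  expect_equal(rf["A", ], c(cortex = 0.5, medulla = 0.25, pelvis = 0.25))
  expect_equal(rf["B", ], c(cortex = 0, medulla = 0, pelvis = 1))
  expect_lt(max(abs(rowSums(rf) - 1)), 1e-9)
  # zero-total cell type yields NA
  p0 <- cbind(p, C = 0)
  pt0 <- structure(list(proportions = p0), class = "ProportionTable")
  expect_true(all(is.na(region_fractions(pt0, geom)["C", ])))
  # unassigned spots are excluded with a warning; unknown regions error
  geom$region[1] <- "unassigned"
  expect_warning(region_fractions(pt, geom), "unassigned")
  geom$region[1] <- "cheese"
  expect_error(region_fractions(pt, geom), "cheese")
  geom$region[1] <- "cortex"
  expect_error(region_fractions(pt, geom[-1, ]), "missing from the geometry")
})

test_that("one-hot spots reproduce the occupancy table exactly", {
  sig <- diag(3)
  dimnames(sig) <- list(c("g1", "g2", "g3"), c("A", "B", "C"))
  reg <- c("cortex", "cortex", "medulla", "pelvis")
  types <- c("A", "B", "A", "C")
  spots <- sig[, types]
  colnames(spots) <- sprintf("s%d", 1:4)
  geom <- data.frame(spot_id = colnames(spots), x = 0, y = 0, region = reg)
  pt <- deconvolve_spots(spots, sig)
  rf <- region_fractions(pt, geom)
  occ <- table(factor(types, colnames(sig)), factor(reg, colnames(rf)))
  expect_equal(unname(as.matrix(rf)), unname(as.matrix(occ / rowSums(occ))))
})
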
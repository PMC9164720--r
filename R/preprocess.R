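#' Quality-control filter for cells or spots
#'
#' Discards observations with more than `max_mito_frac` of their counts on
#' mitochondrial genes, or with fewer than `min_genes` detected genes
#' (count > 0). Both inequalities are strict for discarding, so an
#' observation sitting exactly on a threshold is retained.
#'
#' @param m a `CountMatrix`.
#' @param max_mito_frac maximum tolerated mitochondrial count fraction.
#' @param min_genes minimum number of detected genes.
#' @param mito_pattern regex identifying mitochondrial genes by name.
#' @return A list with `filtered` (the retained submatrix, values untouched)
#'   and `report` (a `data.frame` of discarded ids with `reason`,
#'   `mito_frac` and `n_genes`).
#' @export
qc_filter <- function(m, max_mito_frac = 0.10, min_genes = 200,
                      mito_pattern = "^MT-") {
  stopifnot(inherits(m, "CountMatrix"))
  mf <- mito_fraction(m$counts, mito_pattern)
  ng <- Matrix::colSums(m$counts > 0)
  drop_mito <- mf > max_mito_frac
  drop_genes <- ng < min_genes
  keep <- !(drop_mito | drop_genes)
  if (!any(keep))
    stop("no observations survive QC (max_mito_frac = ", max_mito_frac,
         ", min_genes = ", min_genes, ")")
  reason <- ifelse(drop_mito & drop_genes, "mito_frac;n_genes",
                   ifelse(drop_mito, "mito_frac", "n_genes"))
  report <- data.frame(obs_id = colnames(m$counts)[!keep],
                       reason = reason[!keep],
                       mito_frac = unname(mf[!keep]),
                       n_genes = unname(ng[!keep]),
                       stringsAsFactors = FALSE)
  list(filtered = subset_count_matrix(m, obs = keep), report = report)
}

#' Log-CP10K normalization
#'
#' `value = log(1 + 1e4 * count / total)` per observation (natural log,
#' pseudocount 1), the depth normalization used throughout the pipeline.
#'
#' @param m a `CountMatrix`.
#' @return A dense numeric matrix (genes x observations) with attribute
#'   `normalization = "log-cp10k"`.
#' @export
normalize_cp10k <- function(m) {
  stopifnot(inherits(m, "CountMatrix"))
  tot <- Matrix::colSums(m$counts)
  if (any(tot == 0))
    stop("all-zero observation(s): ",
         paste(colnames(m$counts)[tot == 0], collapse = ", "))
  nm <- log1p(sweep(as.matrix(m$counts), 2, tot, "/") * 1e4)
  attr(nm, "normalization") <- "log-cp10k"
  nm
}

#' Select hypervariable genes by dispersion
#'
#' Genes are ranked by the variance-to-mean ratio of their de-logged
#' normalized values (the overdispersion a Poisson-homogeneous gene would
#' not show). Ties break lexicographically on the gene id. Mean-conditional
#' standardization is deliberately not applied: genes driven by cell-type
#' structure sit at both high mean and high dispersion, and normalizing
#' dispersion within mean bins cancels exactly that signal (see the package
#' vignette).
#'
#' @param nm normalized matrix (genes x observations).
#' @param n_top number of genes to return.
#' @return Character vector of `n_top` gene ids, most variable first.
#' @export
select_hvgs <- function(nm, n_top = 2000) {
  if (n_top > nrow(nm)) stop("n_top exceeds the number of genes")
  e <- expm1(nm)
  mu <- rowMeans(e)
  v <- apply(e, 1, stats::var)
  if (all(v == 0)) stop("constant matrix: no variable genes")
  disp <- ifelse(mu > 0, v / mu, 0)
  ord <- order(-disp, rownames(nm))
  rownames(nm)[ord][seq_len(n_top)]
}

#' PCA embedding of observations
#'
#' Principal components of the gene-standardized matrix (each gene centred
#' and scaled to unit variance; zero-variance genes dropped with a warning).
#' Component signs are fixed so the largest-magnitude loading of each
#' component is positive, making the embedding deterministic.
#'
#' @param nm normalized matrix (genes x observations).
#' @param n_components number of components to keep.
#' @return A list of class `Embedding`: `coords` (observations x components),
#'   `loadings` (genes x components), `variance_explained` (fractions,
#'   non-increasing).
#' @export
embed_pca <- function(nm, n_components = 30) {
  v <- apply(nm, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped before PCA")
    nm <- nm[v > 0, , drop = FALSE]
  }
  if (n_components > min(dim(nm)))
    stop("n_components exceeds the matrix rank bound")
  x <- t(scale(t(nm)))           # genes standardized
  pc <- stats::prcomp(t(x), center = FALSE, scale. = FALSE,
                      rank. = n_components)
  if (n_components > ncol(pc$rotation))
    stop("n_components exceeds the matrix rank")
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  flip[flip == 0] <- 1
  coords <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  ve <- pc$sdev[seq_len(n_components)]^2 / sum(pc$sdev^2)
  structure(list(coords = coords, loadings = loadings,
                 variance_explained = ve, n_components = n_components),
            class = "Embedding")
}

#' Cluster observations on a shared-nearest-neighbour graph
#'
#' Builds a k-nearest-neighbour graph on the embedding (Euclidean), weights
#' edges by the Jaccard overlap of neighbourhoods (self included), prunes
#' weights below `prune`, and runs Louvain modularity optimization at the
#' given resolution. Cluster ids are relabelled 1..K by decreasing size.
#'
#' @param e an `Embedding` (or a plain observations x components matrix).
#' @param resolution Louvain resolution; higher gives more clusters.
#' @param k_neighbors neighbourhood size.
#' @param seed RNG seed making community detection reproducible.
#' @param prune minimum Jaccard weight retained.
#' @return A list of class `ClusterLabeling`: `labels` (named integer vector),
#'   `resolution`, `seed`.
#' @export
cluster_graph <- function(e, resolution = 0.9, k_neighbors = 20, seed = 0L,
                          prune = 1 / 15) {
  coords <- if (inherits(e, "Embedding")) e$coords else as.matrix(e)
  n <- nrow(coords)
  if (n < k_neighbors + 1)
    stop("need at least k_neighbors + 1 = ", k_neighbors + 1,
         " observations; reduce k_neighbors")
  d <- as.matrix(stats::dist(coords))
  nb <- matrix(0L, n, k_neighbors + 1)
  for (i in seq_len(n)) nb[i, ] <- order(d[i, ])[seq_len(k_neighbors + 1)]
  inset <- matrix(FALSE, n, n)
  for (i in seq_len(n)) inset[i, nb[i, ]] <- TRUE
  shared <- tcrossprod(inset * 1)          # |N(i) ∩ N(j)|
  size <- k_neighbors + 1
  jac <- shared / (2 * size - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- as.integer(relab[as.character(memb)])
  names(labels) <- rownames(coords)
  structure(list(labels = labels, resolution = resolution, seed = seed),
            class = "ClusterLabeling")
}
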
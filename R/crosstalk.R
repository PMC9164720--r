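#' Ligand-receptor matching scores between cluster pairs
#'
#' For every ordered cluster pair (a, b) and ligand-receptor pair (L, R),
#' the matching score is the arithmetic mean of L's mean normalized
#' expression in the sender cluster a and R's in the receiver cluster b.
#' The score is set to 0 unless L is detected in at least `min_expr_frac`
#' of a and R in at least `min_expr_frac` of b. Significance comes from a
#' permutation null: cluster labels are shuffled globally (cluster sizes
#' preserved) and the add-one estimator
#' `p = (1 + #permuted >= observed) / (1 + n_perm)` is reported, so p can
#' never be 0 and its floor is `1/(1 + n_perm)`.
#'
#' @param nm normalized matrix (genes x observations).
#' @param labels cluster labels named by observation id (or a
#'   `ClusterLabeling`); clusters with fewer than 3 members are excluded.
#' @param pairs `data.frame` with columns `ligand`, `receptor`; pairs whose
#'   genes are absent from `nm` are skipped with a warning.
#' @param n_perm number of label permutations (a warning below 100).
#' @param min_expr_frac detection-fraction gate.
#' @param seed RNG seed for the permutations.
#' @param score_min,alpha thresholds for the `significant` flag
#'   (`score > score_min` and `p < alpha`).
#' @return A `data.frame` (`LRScoreTable`): `cluster_a`, `cluster_b`,
#'   `ligand`, `receptor`, `score`, `p`, `significant`.
#' @export
lr_scores <- function(nm, labels, pairs, n_perm = 1000, min_expr_frac = 0.10,
                      seed = 0L, score_min = 1, alpha = 0.01) {
  if (inherits(labels, "ClusterLabeling")) labels <- labels$labels
  labels <- labels[colnames(nm)]
  if (anyNA(labels)) stop("every observation needs a cluster label")
  labels <- as.character(labels)
  if (n_perm < 100)
    warning("n_perm < 100 gives coarse p-value resolution")
  sizes <- table(labels)
  small <- names(sizes)[sizes < 3]
  if (length(small) > 0) {
    keep <- !labels %in% small
    nm <- nm[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  clusters <- sort(unique(labels))
  present <- pairs$ligand %in% rownames(nm) & pairs$receptor %in% rownames(nm)
  if (!all(present)) {
    warning(sum(!present), " pair(s) with genes absent from the matrix ",
            "skipped")
    pairs <- pairs[present, , drop = FALSE]
  }
  if (nrow(pairs) == 0) stop("no usable ligand-receptor pairs")
  genes <- unique(c(pairs$ligand, pairs$receptor))
  E <- nm[genes, , drop = FALSE]
  D <- (E > 0) * 1

  score_all <- function(lab) {
    memb <- vapply(clusters, function(cl) (lab == cl) / sum(lab == cl),
                   numeric(length(lab)))
    mu <- E %*% memb                  # gene x cluster mean expression
    det <- D %*% memb                 # gene x cluster detection fraction
    li <- match(pairs$ligand, genes); ri <- match(pairs$receptor, genes)
    # pair x (a, b): gated mean of sender ligand and receiver receptor
    sc <- array(0, c(nrow(pairs), length(clusters), length(clusters)))
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        gate <- det[li, a] >= min_expr_frac & det[ri, b] >= min_expr_frac
        sc[, a, b] <- ifelse(gate, (mu[li, a] + mu[ri, b]) / 2, 0)
      }
    }
    sc
  }

  obs <- score_all(labels)
  set.seed(seed)
  exceed <- array(0L, dim(obs))
  for (p in seq_len(n_perm)) {
    perm <- score_all(sample(labels))
    exceed <- exceed + (perm >= obs)
  }
  pval <- (1 + exceed) / (1 + n_perm)

  grid <- expand.grid(pair = seq_len(nrow(pairs)),
                      a = seq_along(clusters), b = seq_along(clusters))
  res <- data.frame(cluster_a = clusters[grid$a],
                    cluster_b = clusters[grid$b],
                    ligand = pairs$ligand[grid$pair],
                    receptor = pairs$receptor[grid$pair],
                    score = obs[cbind(grid$pair, grid$a, grid$b)],
                    p = pval[cbind(grid$pair, grid$a, grid$b)],
                    stringsAsFactors = FALSE)
  res$significant <- res$score > score_min & res$p < alpha
  res
}
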
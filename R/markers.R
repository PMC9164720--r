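#' Bimodal likelihood-ratio test for single-cell expression
#'
#' Models each group's expression as a two-part mixture: a gene is detected
#' (value > 0) with probability pi, and detected values are Normal(mu,
#' sigma^2) with sigma shared between groups. The null model shares pi and mu
#' across groups. The statistic 2(LL_alt - LL_null) is referred to a
#' chi-square with 2 degrees of freedom (pi and mu differ between groups;
#' sigma is pooled). If either group has no detected values the Gaussian
#' component is dropped and a binomial-only LRT (df = 1) is reported, with
#' `gaussian = FALSE` in the result.
#'
#' @param x_in,x_out numeric vectors of (normalized) expression in the two
#'   groups; both non-empty.
#' @return A list: `statistic`, `p`, `df`, `gaussian`.
#' @export
bimod_lrt <- function(x_in, x_out) {
  if (length(x_in) == 0 || length(x_out) == 0)
    stop("both groups must be non-empty")
  d1 <- x_in[x_in > 0]; d2 <- x_out[x_out > 0]
  n1 <- length(x_in); n2 <- length(x_out)
  binom_ll <- function(k, n) {
    if (k == 0 || k == n) return(0)
    p <- k / n
    k * log(p) + (n - k) * log1p(-p)
  }
  ll_bin_alt <- binom_ll(length(d1), n1) + binom_ll(length(d2), n2)
  ll_bin_null <- binom_ll(length(d1) + length(d2), n1 + n2)
  if (length(d1) == 0 || length(d2) == 0) {
    stat <- 2 * (ll_bin_alt - ll_bin_null)
    return(list(statistic = max(stat, 0),
                p = stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE),
                df = 1L, gaussian = FALSE))
  }
  norm_ll <- function(x, mu, s) sum(stats::dnorm(x, mu, s, log = TRUE))
  d <- c(d1, d2)
  # alternative: group means, pooled MLE sigma
  m1 <- mean(d1); m2 <- mean(d2)
  s_alt <- sqrt((sum((d1 - m1)^2) + sum((d2 - m2)^2)) / length(d))
  # null: common mean and its MLE sigma
  m0 <- mean(d)
  s_null <- sqrt(sum((d - m0)^2) / length(d))
  s_floor <- 1e-8
  s_alt <- max(s_alt, s_floor); s_null <- max(s_null, s_floor)
  ll_alt <- ll_bin_alt + norm_ll(d1, m1, s_alt) + norm_ll(d2, m2, s_alt)
  ll_null <- ll_bin_null + norm_ll(d, m0, s_null)
  stat <- max(2 * (ll_alt - ll_null), 0)
  list(statistic = stat,
       p = stats::pchisq(stat, df = 2, lower.tail = FALSE),
       df = 2L, gaussian = TRUE)
}

# internal: log2 fold change on de-logged means with pseudocount 1
log2_fc <- function(x_in, x_out) {
  log2(mean(expm1(x_in)) + 1) - log2(mean(expm1(x_out)) + 1)
}

# internal: two-sided Wilcoxon rank-sum p-values for many genes at once,
# normal approximation with tie correction and continuity correction --
# identical to stats::wilcox.test(correct = TRUE, exact = FALSE)
wilcox_vec <- function(x, inside) {
  n1 <- sum(inside); n2 <- sum(!inside); N <- n1 + n2
  vapply(seq_len(nrow(x)), function(i) {
    r <- rank(x[i, ])
    w <- sum(r[inside]) - n1 * (n1 + 1) / 2
    ties <- rle(sort(r))$lengths
    z <- w - n1 * n2 / 2
    sigma <- sqrt((n1 * n2 / 12) *
                    ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
    if (sigma == 0) return(1)
    z <- (z - sign(z) * 0.5) / sigma
    2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE), 0.5)
  }, 0)
}

#' One-vs-rest marker detection per cluster
#'
#' For every cluster, compares each gene's expression in the cluster against
#' all other observations. Genes enter testing only if detected in at least
#' `min_pct` of one side and if `|log2 FC| >= logfc_threshold`, where the
#' fold change is computed on de-logged means with a pseudocount of 1.
#' P-values come from the Wilcoxon rank-sum test or the bimodal
#' likelihood-ratio test ([bimod_lrt()]); Benjamini-Hochberg adjustment is
#' applied within each cluster's tested-gene universe.
#'
#' @param nm normalized matrix (genes x observations).
#' @param labels a `ClusterLabeling`, or a vector of cluster/cell-type labels
#'   named by observation id.
#' @param test `"wilcoxon"` or `"bimod"`.
#' @param logfc_threshold minimum absolute log2 fold change to test.
#' @param min_pct minimum detection fraction on at least one side.
#' @return A `data.frame` (`MarkerTable`) with columns `gene`, `cluster`,
#'   `log2_fc`, `p`, `p_adj`, `pct_in`, `pct_out`.
#' @export
rank_markers <- function(nm, labels, test = c("wilcoxon", "bimod"),
                         logfc_threshold = 0.1, min_pct = 0.01) {
  test <- match.arg(test)
  if (inherits(labels, "ClusterLabeling")) labels <- labels$labels
  labels <- labels[colnames(nm)]
  if (anyNA(labels)) stop("every observation needs a cluster label")
  labels <- as.character(labels)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  E <- expm1(nm)
  det <- nm > 0
  tot_e <- rowSums(E)
  tot_d <- rowSums(det)
  out <- list()
  for (cl in clusters) {
    inside <- labels == cl
    n_in <- sum(inside); n_out <- length(labels) - n_in
    if (n_in < 3) {
      warning("cluster ", cl, " has fewer than 3 observations; skipped")
      next
    }
    in_e <- rowSums(E[, inside, drop = FALSE])
    in_d <- rowSums(det[, inside, drop = FALSE])
    pct_in <- in_d / n_in
    pct_out <- (tot_d - in_d) / n_out
    lfc <- log2(in_e / n_in + 1) - log2((tot_e - in_e) / n_out + 1)
    tested <- (pct_in >= min_pct | pct_out >= min_pct) &
      abs(lfc) >= logfc_threshold
    if (!any(tested)) next
    genes <- rownames(nm)[tested]
    if (test == "wilcoxon") {
      if (n_in < 50 && n_out < 50) {
        # stats::wilcox.test picks its exact small-sample method here
        p <- vapply(genes, function(g) {
          suppressWarnings(
            stats::wilcox.test(nm[g, inside], nm[g, !inside])$p.value)
        }, 0)
      } else {
        p <- wilcox_vec(nm[tested, , drop = FALSE], inside)
      }
    } else {
      p <- vapply(genes, function(g) {
        bimod_lrt(nm[g, inside], nm[g, !inside])$p
      }, 0)
    }
    out[[cl]] <- data.frame(gene = genes, cluster = cl,
                            log2_fc = unname(lfc[tested]), p = unname(p),
                            p_adj = stats::p.adjust(unname(p), "BH"),
                            pct_in = unname(pct_in[tested]),
                            pct_out = unname(pct_out[tested]),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract per-cluster marker gene sets from a marker table
#'
#' Keeps up-regulated genes (`log2_fc > 0`) passing both thresholds strictly
#' (`p_adj < p_adj_max` and `log2_fc > log2fc_min`), one set per cluster.
#' Clusters with no passing gene yield an empty set and a warning.
#'
#' @param mt a `MarkerTable` from [rank_markers()].
#' @param p_adj_max adjusted P-value cutoff (exclusive).
#' @param log2fc_min log2 fold-change cutoff (exclusive).
#' @return A `GeneSetCollection`, one set per cluster present in `mt`.
#' @export
extract_gene_sets <- function(mt, p_adj_max = 0.05, log2fc_min = 0.25) {
  keep <- mt$p_adj < p_adj_max & mt$log2_fc > log2fc_min & mt$log2_fc > 0
  clusters <- sort(unique(mt$cluster))
  sets <- lapply(clusters, function(cl) {
    sort(unique(mt$gene[keep & mt$cluster == cl]))
  })
  names(sets) <- clusters
  empty <- lengths(sets) == 0
  if (any(empty))
    warning("empty marker set(s) for cluster(s): ",
            paste(clusters[empty], collapse = ", "))
  structure(sets, class = c("GeneSetCollection", "list"))
}
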
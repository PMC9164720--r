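#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The classic GSEA running sum over a ranked gene list: at each hit the sum
#' advances by `|metric|^weight_p / sum_hits |metric|^weight_p`, at each
#' miss it retreats by `1 / (N - |S|)`; the enrichment score is the signed
#' maximum deviation from zero, so ES is in `[-1, 1]`. When the positive and
#' negative extrema tie exactly, the positive one is reported.
#'
#' @param ranked character vector of gene ids ordered by decreasing metric,
#'   or a `data.frame` with columns `gene` and `metric`.
#' @param metric numeric metric values aligned with `ranked` (ignored when
#'   `ranked` is a data.frame).
#' @param gene_set character vector; must intersect the ranked list.
#' @param weight_p metric weighting exponent (0 = unweighted KS).
#' @return The enrichment score (scalar). The full running sum is attached
#'   as attribute `running`.
#' @export
gsea_es <- function(ranked, metric = NULL, gene_set, weight_p = 1) {
  if (is.data.frame(ranked)) {
    metric <- ranked$metric
    ranked <- ranked$gene
  }
  if (anyDuplicated(ranked)) stop("duplicate genes in the ranked list")
  if (is.null(metric) || length(metric) != length(ranked))
    stop("metric must align with the ranked list")
  if (any(!is.finite(metric))) stop("metric must be finite")
  hit <- ranked %in% gene_set
  if (!any(hit)) stop("gene_set is disjoint from the ranked list")
  N <- length(ranked)
  nh <- sum(hit)
  if (nh == N) stop("gene_set covers the whole ranked list")
  w <- abs(metric)^weight_p
  inc <- numeric(N)
  wh <- sum(w[hit])
  inc[hit] <- if (wh > 0) w[hit] / wh else 1 / nh
  inc[!hit] <- -1 / (N - nh)
  running <- cumsum(inc)
  es_pos <- max(running)
  es_neg <- min(running)
  # positive extremum wins unless the negative one is clearly larger; the
  # tolerance makes the tie-break stable under floating-point accumulation
  es <- if (es_pos >= -es_neg - 1e-9) es_pos else es_neg
  attr(es, "running") <- running
  es
}

#' GSEA between two observation groups
#'
#' Genes are ranked by log2 fold change of group A over group B (de-logged
#' means, pseudocount 1 -- the same metric as [rank_markers()]); each set's
#' enrichment score is tested by gene-set permutation: `n_perm` random sets
#' of the same size are drawn from the ranked list, the P-value is the
#' add-one fraction of same-sign permuted scores at least as extreme, and
#' NES is ES divided by the mean |permuted ES| of the same sign.
#'
#' @param nm normalized matrix (genes x observations).
#' @param group_a,group_b observation ids (each of length >= 3).
#' @param sets a `GeneSetCollection`; sets with fewer than `min_set_size`
#'   genes in the ranked list are skipped with a warning.
#' @param n_perm permutations (0 reports ES only, p = NA).
#' @param weight_p metric weighting exponent.
#' @param min_set_size minimum post-intersection set size.
#' @param seed RNG seed.
#' @return A `data.frame` with columns `set`, `size`, `es`, `nes`, `p`.
#' @export
gsea <- function(nm, group_a, group_b, sets, n_perm = 1000, weight_p = 1,
                 min_set_size = 5, seed = 0L) {
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("both groups need at least 3 observations")
  lfc <- apply(nm, 1, function(x) log2_fc(x[group_a], x[group_b]))
  ord <- order(-lfc, rownames(nm))
  ranked <- rownames(nm)[ord]
  metric <- unname(lfc[ord])
  set.seed(seed)
  out <- list()
  for (nm_set in names(sets)) {
    s <- intersect(sets[[nm_set]], ranked)
    if (length(s) < min_set_size) {
      warning("set ", nm_set, " has fewer than ", min_set_size,
              " genes in the ranked list; skipped")
      next
    }
    es <- as.numeric(gsea_es(ranked, metric, s, weight_p))
    if (n_perm > 0) {
      perm <- vapply(seq_len(n_perm), function(i) {
        as.numeric(gsea_es(ranked, metric, sample(ranked, length(s)),
                           weight_p))
      }, 0)
      same <- perm[sign(perm) == sign(es)]
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      nes <- if (length(same) > 0) es / mean(abs(same)) else NA_real_
    } else {
      p <- NA_real_
      nes <- NA_real_
    }
    out[[nm_set]] <- data.frame(set = nm_set, size = length(s), es = es,
                                nes = nes, p = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Over-representation analysis
#'
#' Hypergeometric enrichment of a gene list in each annotation set (the same
#' statistic as [hypergeom_enrichment()]), with Benjamini-Hochberg
#' adjustment across sets. Sets are intersected with the background first.
#'
#' @param gene_list character vector, a subset of `background`.
#' @param sets a `GeneSetCollection` of annotation sets.
#' @param background character vector: the gene universe.
#' @return A `data.frame` with columns `set`, `size`, `overlap`, `p`,
#'   `p_adj`.
#' @export
ora <- function(gene_list, sets, background) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background")
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, background)
  if (length(outside) > 0)
    stop("gene_list member(s) outside the background: ",
         paste(utils::head(outside, 10), collapse = ", "))
  rows <- lapply(names(sets), function(nm_set) {
    s <- intersect(sets[[nm_set]], background)
    p <- hypergeom_enrichment(gene_list, s, background)
    data.frame(set = nm_set, size = length(s),
               overlap = length(intersect(gene_list, s)), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, "BH")
  rownames(res) <- NULL
  res
}
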
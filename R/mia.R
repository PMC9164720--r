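#' One-sided hypergeometric enrichment of two gene sets
#'
#' The multimodal-intersection statistic: with a background of N genes, a
#' first set of size K, a second of size n and overlap k, returns the upper
#' tail P(X >= k) of the hypergeometric distribution, computed in log space
#' so values down to 1e-300 and below stay representable. Symmetric in its
#' two sets.
#'
#' @param set_a,set_b character vectors of gene ids, both subsets of
#'   `background`.
#' @param background character vector: the gene universe.
#' @param log10 if `TRUE`, return -log10(p) instead of p.
#' @return The enrichment P-value (or its -log10).
#' @export
hypergeom_enrichment <- function(set_a, set_b, background, log10 = FALSE) {
  background <- unique(background)
  set_a <- unique(set_a); set_b <- unique(set_b)
  out_a <- setdiff(set_a, background)
  out_b <- setdiff(set_b, background)
  if (length(out_a) + length(out_b) > 0)
    stop("gene(s) outside the background: ",
         paste(utils::head(c(out_a, out_b), 10), collapse = ", "))
  N <- length(background)
  if (N < 1) stop("empty background")
  K <- length(set_a); n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  log_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  if (log10) -log_p / log(10) else exp(log_p)
}

#' Multimodal intersection analysis matrix
#'
#' Crosses every cell-type-specific set against every spatial-cluster set:
#' element (i, j) is the -log10 one-sided hypergeometric P of their overlap
#' within a shared background. All sets are intersected with the background
#' first; the recommended background is the genes detected in both
#' modalities (see [detected_background()]).
#'
#' @param cell_sets `GeneSetCollection` of cell-type-specific genes
#'   (scRNA-seq side).
#' @param region_sets `GeneSetCollection` of region/cluster-specific genes
#'   (spatial side).
#' @param background character vector: the shared gene universe.
#' @param cap -log10 values are capped here in `neg_log10_p` (the raw log
#'   P-values are kept in `log_p`).
#' @return A list of class `MIAMatrix`: `neg_log10_p` and `overlap`
#'   (cell types x spatial clusters), `log_p` (natural-log, uncapped),
#'   `set_sizes_row`, `set_sizes_col`, `background_size`.
#' @export
mia_matrix <- function(cell_sets, region_sets, background, cap = 300) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background")
  cs <- lapply(cell_sets, intersect, background)
  rs <- lapply(region_sets, intersect, background)
  N <- length(background)
  nlp <- matrix(0, length(cs), length(rs),
                dimnames = list(names(cell_sets), names(region_sets)))
  logp <- nlp
  ov <- nlp
  for (i in seq_along(cs)) {
    for (j in seq_along(rs)) {
      k <- length(intersect(cs[[i]], rs[[j]]))
      lp <- stats::phyper(k - 1, length(cs[[i]]), N - length(cs[[i]]),
                          length(rs[[j]]), lower.tail = FALSE, log.p = TRUE)
      logp[i, j] <- lp
      nlp[i, j] <- min(-lp / log(10), cap)
      ov[i, j] <- k
    }
  }
  structure(list(neg_log10_p = nlp, overlap = ov, log_p = logp,
                 set_sizes_row = lengths(cs), set_sizes_col = lengths(rs),
                 background_size = N),
            class = "MIAMatrix")
}

#' Shared detected-gene background for MIA
#'
#' Genes with a count above zero in at least one observation of *both*
#' modalities -- the gene universe the hypergeometric test is computed on.
#'
#' @param m_a,m_b `CountMatrix` objects for the two modalities.
#' @return Character vector of background gene ids.
#' @export
detected_background <- function(m_a, m_b) {
  det_a <- rownames(m_a$counts)[Matrix::rowSums(m_a$counts > 0) > 0]
  det_b <- rownames(m_b$counts)[Matrix::rowSums(m_b$counts > 0) > 0]
  intersect(det_a, det_b)
}

#' Label spatial clusters by their best-matching cell type
#'
#' Each spatial cluster (column) is assigned the cell type with the largest
#' -log10 P in its column, provided that P < alpha; otherwise it is left
#' `UNASSIGNED`. Ties on P break towards the larger overlap count, then the
#' lexicographically smaller cell-type name.
#'
#' @param m a `MIAMatrix`.
#' @param alpha significance threshold on the raw hypergeometric P.
#' @return A `data.frame` with columns `st_cluster`, `cell_type`, `p`.
#' @export
assign_labels <- function(m, alpha = 0.01) {
  stopifnot(inherits(m, "MIAMatrix"))
  res <- lapply(colnames(m$log_p), function(j) {
    lp <- m$log_p[, j]
    ov <- m$overlap[, j]
    ord <- order(lp, -ov, names(lp))   # smallest log-p first
    best <- ord[1]
    p <- exp(lp[best])
    data.frame(st_cluster = j,
               cell_type = if (p < alpha) names(lp)[best] else "UNASSIGNED",
               p = unname(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
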
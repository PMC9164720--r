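#' Build cell-type expression signatures on the marker-gene union
#'
#' Rows are the union of all cell-type marker sets; column t is the mean
#' normalized expression of those genes over the reference cells labelled t.
#'
#' @param nm_ref normalized reference matrix (genes x cells).
#' @param labels cell-type labels named by cell id (or a `ClusterLabeling`).
#' @param markers `GeneSetCollection` of cell-type marker sets.
#' @return A genes x cell-types numeric matrix (`SignatureMatrix`). A
#'   condition-number warning is emitted when columns are (near-)collinear.
#' @export
build_signatures <- function(nm_ref, labels, markers) {
  if (inherits(labels, "ClusterLabeling")) labels <- labels$labels
  labels <- labels[colnames(nm_ref)]
  if (anyNA(labels)) stop("every reference cell needs a label")
  labels <- as.character(labels)
  genes <- sort(unique(unlist(markers)))
  missing <- setdiff(genes, rownames(nm_ref))
  if (length(missing) > 0)
    stop("marker gene(s) absent from the reference: ",
         paste(utils::head(missing, 10), collapse = ", "))
  types <- sort(unique(labels))
  sig <- vapply(types, function(t) {
    cells <- labels == t
    if (!any(cells)) stop("cell type ", t, " has zero cells")
    rowMeans(nm_ref[genes, cells, drop = FALSE])
  }, numeric(length(genes)))
  rownames(sig) <- genes
  if (any(colSums(sig) == 0)) stop("all-zero signature column")
  if (ncol(sig) > 1) {
    kappa_val <- kappa(sig, exact = TRUE)
    if (!is.finite(kappa_val) || kappa_val > 1e8)
      warning("signature matrix is ill-conditioned (condition number ",
              format(kappa_val, digits = 3),
              "); proportions may be non-identifiable")
  }
  sig
}

#' Deconvolve spot profiles into cell-type proportions
#'
#' Per spot, non-negative least squares of the spot's marker-gene profile on
#' the signature columns; coefficients are normalized to sum to one, entries
#' below `min_contribution` are zeroed, and (by default) the survivors are
#' renormalized to sum to one. Raw (unfiltered) proportions are retained.
#'
#' @param nm_spots normalized spot matrix (genes x spots).
#' @param sig a `SignatureMatrix` from [build_signatures()].
#' @param min_contribution minimum retained proportion (the >= 10% filter).
#' @param renormalize renormalize surviving proportions to sum 1.
#' @return A list of class `ProportionTable`: `proportions` (spots x cell
#'   types, filtered), `raw` (before the filter), `zero_spots` (ids with an
#'   all-zero marker profile).
#' @export
deconvolve_spots <- function(nm_spots, sig, min_contribution = 0.10,
                             renormalize = TRUE) {
  genes <- intersect(rownames(sig), rownames(nm_spots))
  if (length(genes) == 0) stop("no shared genes between spots and signatures")
  A <- sig[genes, , drop = FALSE]
  X <- nm_spots[genes, , drop = FALSE]
  n_types <- ncol(A)
  raw <- matrix(0, ncol(X), n_types,
                dimnames = list(colnames(X), colnames(A)))
  zero_spots <- character(0)
  for (j in seq_len(ncol(X))) {
    b <- X[, j]
    if (all(b == 0)) {
      zero_spots <- c(zero_spots, colnames(X)[j])
      next
    }
    coef <- pracma::lsqnonneg(A, b)$x
    if (sum(coef) > 0) raw[j, ] <- coef / sum(coef)
  }
  filt <- raw
  filt[filt < min_contribution] <- 0
  if (renormalize) {
    rs <- rowSums(filt)
    pos <- rs > 0
    filt[pos, ] <- filt[pos, , drop = FALSE] / rs[pos]
  }
  structure(list(proportions = filt, raw = raw, zero_spots = zero_spots,
                 min_contribution = min_contribution,
                 renormalized = renormalize),
            class = "ProportionTable")
}

#' Aggregate spot proportions into per-region fractions
#'
#' For each cell type, the summed (filtered) proportions within each region
#' divided by the summed proportions across all spots, so every cell type's
#' row is its distribution over regions and sums to one. Spots labelled
#' "unassigned" are excluded with a warning; cell types with zero total
#' proportion get an NA row.
#'
#' @param pt a `ProportionTable`.
#' @param geom spot geometry `data.frame` (`spot_id`, `x`, `y`, `region`).
#' @param regions the region vocabulary; a geometry label outside it is an
#'   error.
#' @return Cell types x regions numeric matrix of fractions.
#' @export
region_fractions <- function(pt, geom,
                             regions = c("cortex", "medulla", "pelvis")) {
  stopifnot(inherits(pt, "ProportionTable"))
  p <- pt$proportions
  reg <- stats::setNames(geom$region, geom$spot_id)[rownames(p)]
  if (anyNA(reg))
    stop("spot(s) missing from the geometry: ",
         paste(utils::head(rownames(p)[is.na(reg)], 5), collapse = ", "))
  if (any(reg == "unassigned")) {
    warning(sum(reg == "unassigned"),
            " spot(s) with unassigned region excluded")
    p <- p[reg != "unassigned", , drop = FALSE]
    reg <- reg[reg != "unassigned"]
  }
  bad <- setdiff(unique(reg), regions)
  if (length(bad) > 0)
    stop("region label(s) outside the declared vocabulary: ",
         paste(bad, collapse = ", "))
  tot <- colSums(p)
  frac <- vapply(regions, function(r) {
    colSums(p[reg == r, , drop = FALSE])
  }, numeric(ncol(p)))
  frac <- frac / ifelse(tot > 0, tot, NA_real_)
  rownames(frac) <- colnames(p)
  frac
}
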
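#' Construct a gene-by-observation count matrix container
#'
#' The canonical container for both modalities: an integer gene x observation
#' matrix (cells or Visium-style spots as columns) together with a per
#' observation metadata table. Genes are rows, following the 10x convention.
#'
#' @param counts integer matrix or `Matrix::sparseMatrix`, genes x observations,
#'   with unique rownames (gene ids) and colnames (observation ids).
#' @param obs_meta optional `data.frame` keyed by observation id (rownames must
#'   match `colnames(counts)`); holds cluster, region or cell-type columns when
#'   known.
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   (a `dgCMatrix`) and `obs_meta`.
#' @examples
#' m <- matrix(0:3, 2, 2, dimnames = list(c("G1", "G2"), c("c1", "c2")))
#' cm <- count_matrix(m)
#' dim(cm)
#' @export
count_matrix <- function(counts, obs_meta = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and observation colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate observation ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (min(counts) < 0) stop("counts must be non-negative")
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  if (is.null(obs_meta)) {
    obs_meta <- data.frame(row.names = colnames(counts))
  } else {
    obs_meta <- as.data.frame(obs_meta)
    if (!setequal(rownames(obs_meta), colnames(counts)))
      stop("obs_meta rownames must match observation ids")
    obs_meta <- obs_meta[colnames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, obs_meta = obs_meta), class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
dimnames.CountMatrix <- function(x) dimnames(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d observations (%d metadata columns)\n",
              nrow(x$counts), ncol(x$counts), ncol(x$obs_meta)))
  invisible(x)
}

#' Subset a CountMatrix by genes and/or observations
#'
#' @param x a `CountMatrix`.
#' @param genes,obs character, logical or integer index into rows/columns;
#'   `NULL` keeps everything.
#' @return A `CountMatrix` restricted to the requested rows/columns; values
#'   are untouched.
#' @export
subset_count_matrix <- function(x, genes = NULL, obs = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  counts <- x$counts
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(obs)) counts <- counts[, obs, drop = FALSE]
  meta <- x$obs_meta[colnames(counts), , drop = FALSE]
  structure(list(counts = counts, obs_meta = meta), class = "CountMatrix")
}

#' Construct a gene-set collection
#'
#' A named list of character vectors (unique gene ids per set), the carrier
#' for cell-type-specific and region-specific gene sets.
#'
#' @param sets named list of character vectors.
#' @return An object of class `GeneSetCollection` (a validated named list).
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    if (any(is.na(s) | s == "")) stop("gene ids must be non-empty strings")
    s
  })
  structure(sets, class = c("GeneSetCollection", "list"))
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, sizes %s\n", length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}

# internal: fraction of an observation's counts coming from mito genes
mito_fraction <- function(counts, mito_pattern = "^MT-") {
  mito <- grepl(mito_pattern, rownames(counts))
  tot <- Matrix::colSums(counts)
  mt <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else 0
  ifelse(tot > 0, mt / tot, 0)
}
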
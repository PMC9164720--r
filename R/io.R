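#' Read a gene x observation count matrix from disk
#'
#' Auto-detects the dialect: a directory (or prefix) containing `matrix.mtx`
#' plus `features.tsv` and `barcodes.tsv` in the 10x layout, or a single
#' dense CSV with gene rows and an id column first. Round-trips bit-exactly
#' with [write_count_matrix()] for integer data.
#'
#' @param path directory with the MatrixMarket triplet, or a `.csv` file.
#' @param transpose for the CSV dialect only: set `TRUE` if observations are
#'   rows.
#' @return A `CountMatrix`.
#' @export
read_count_matrix <- function(path, transpose = FALSE) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    bc <- file.path(path, "barcodes.tsv")
    if (!all(file.exists(c(mtx, feat, bc))))
      stop("format error: expected matrix.mtx, features.tsv and barcodes.tsv ",
           "under ", path)
    m <- Matrix::readMM(mtx)
    genes <- readLines(feat)
    barcodes <- readLines(bc)
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
      stop("format error: mtx header (", nrow(m), " x ", ncol(m),
           ") does not match features (", length(genes), ") / barcodes (",
           length(barcodes), ")")
    if (anyDuplicated(genes)) stop("format error: duplicate gene ids")
    if (anyDuplicated(barcodes)) stop("format error: duplicate barcodes")
    dimnames(m) <- list(genes, barcodes)
    return(count_matrix(m))
  }
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (transpose) m <- t(m)
  mode(m) <- "numeric"
  count_matrix(m)
}

#' Write a CountMatrix as MatrixMarket plus id files
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv` (10x layout) into
#' `path`, and the observation metadata as `obs_meta.csv` when non-empty.
#'
#' @param x a `CountMatrix`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "CountMatrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(path, "features.tsv"))
  writeLines(colnames(x$counts), file.path(path, "barcodes.tsv"))
  if (ncol(x$obs_meta) > 0)
    utils::write.csv(x$obs_meta, file.path(path, "obs_meta.csv"))
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' members. The description is discarded; duplicate members within a line are
#' deduplicated.
#'
#' @param path GMT file.
#' @return A `GeneSetCollection`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0)
    stop("format error: GMT line(s) ", paste(bad, collapse = ", "),
         " have fewer than 3 fields")
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm))
    stop("format error: duplicate gene-set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  if (any(lengths(sets) == 0)) stop("format error: empty gene set")
  gene_set_collection(sets)
}

#' Write a GeneSetCollection as GMT
#'
#' @param sets a `GeneSetCollection`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read spot positions and region annotation
#'
#' CSV with columns `spot_id`, `x`, `y` and optionally `region`
#' (cortex/medulla/pelvis). A missing region column yields "unassigned".
#' When a `CountMatrix` is supplied, spots absent from it are dropped with a
#' warning so geometry and matrix stay aligned.
#'
#' @param path CSV file.
#' @param counts optional paired `CountMatrix` to reconcile against.
#' @return A `data.frame` (`spot_id`, `x`, `y`, `region`).
#' @export
read_spot_positions <- function(path, counts = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("format error: columns spot_id, x, y are required")
  if (!is.numeric(df$x) || !is.numeric(df$y))
    stop("format error: non-numeric coordinates")
  if (!"region" %in% names(df)) df$region <- "unassigned"
  df$region[is.na(df$region) | df$region == ""] <- "unassigned"
  df <- df[, c("spot_id", "x", "y", "region")]
  if (!is.null(counts)) {
    missing <- setdiff(df$spot_id, colnames(counts))
    if (length(missing) > 0) {
      warning(length(missing), " spot(s) absent from the count matrix were ",
              "dropped: ", paste(utils::head(missing, 5), collapse = ", "))
      df <- df[!df$spot_id %in% missing, , drop = FALSE]
    }
  }
  df
}

#' Read a ligand-receptor pair list
#'
#' CSV with columns `ligand` and `receptor`; duplicate pairs are an error.
#'
#' @param path CSV file.
#' @return A `data.frame` with columns `ligand`, `receptor`.
#' @export
read_lr_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(df)))
    stop("format error: columns ligand and receptor are required")
  key <- paste(df$ligand, df$receptor, sep = "|")
  if (anyDuplicated(key))
    stop("format error: duplicate ligand-receptor pairs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  df[, c("ligand", "receptor")]
}
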
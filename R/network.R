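#' Pick the soft-thresholding power for a co-expression network
#'
#' For each candidate power, builds the unsigned adjacency |cor|^beta and
#' fits the scale-free topology criterion: connectivity values are binned,
#' and log10 p(k) is regressed on log10 k; the fit index is R^2 signed
#' negatively when the slope is positive (a scale-free degree distribution
#' has a negative slope). Returns the smallest power reaching `r2_target`,
#' or the best-fitting power with a warning if none does.
#'
#' @param nm normalized matrix (genes x observations); constant genes are
#'   dropped with a warning.
#' @param r2_target scale-free fit target.
#' @param powers candidate powers.
#' @param n_bins connectivity histogram bins.
#' @return A list: `power`, `fit_indices` (`data.frame` of power, r2, slope,
#'   mean_k), `reached_target`.
#' @export
pick_soft_power <- function(nm, r2_target = 0.80, powers = 1:20,
                            n_bins = 10) {
  v <- apply(nm, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant gene(s) removed before correlation")
    nm <- nm[v > 0, , drop = FALSE]
  }
  ac <- abs(stats::cor(t(nm)))
  diag(ac) <- 0
  fits <- lapply(powers, function(b) {
    k <- rowSums(ac^b)
    if (diff(range(k)) == 0)
      return(data.frame(power = b, r2 = 0, slope = NA_real_, mean_k = mean(k)))
    bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
    pk <- tapply(k, bin, length) / length(k)
    kc <- tapply(k, bin, mean)
    ok <- !is.na(pk) & pk > 0 & kc > 0
    if (sum(ok) < 3)
      return(data.frame(power = b, r2 = 0, slope = NA_real_, mean_k = mean(k)))
    fit <- stats::lm(log10(pk[ok]) ~ log10(kc[ok]))
    r2 <- summary(fit)$r.squared
    slope <- stats::coef(fit)[2]
    data.frame(power = b, r2 = if (!is.na(slope) && slope > 0) -r2 else r2,
               slope = unname(slope), mean_k = mean(k))
  })
  fits <- do.call(rbind, fits)
  hit <- which(fits$r2 >= r2_target)
  if (length(hit) > 0) {
    power <- fits$power[hit[1]]
    reached <- TRUE
  } else {
    power <- fits$power[which.max(fits$r2)]
    reached <- FALSE
    warning("no power reached scale-free fit R^2 >= ", r2_target,
            "; returning the best fit (power ", power, ", R^2 ",
            round(max(fits$r2), 3), ")")
  }
  list(power = power, fit_indices = fits, reached_target = reached)
}

#' Unsigned co-expression adjacency
#'
#' `a_ij = |pearson_cor(gene_i, gene_j)|^beta`, diagonal 1.
#'
#' @param nm normalized matrix (genes x observations).
#' @param beta soft-thresholding power (>= 1).
#' @return A symmetric genes x genes matrix in `[0, 1]` with attribute
#'   `beta`.
#' @export
build_adjacency <- function(nm, beta) {
  if (beta < 1) stop("beta must be >= 1")
  v <- apply(nm, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(nm)[v == 0], 5), collapse = ", "),
         " (filter before building the network)")
  a <- abs(stats::cor(t(nm)))^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

# internal: unsigned topological overlap matrix from an adjacency
tom_similarity <- function(a) {
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules
#'
#' Topological-overlap dissimilarity, average-linkage hierarchical
#' clustering, a static tree cut at `cut_height`, then iterative merging of
#' modules whose eigengenes correlate above `merge_cor`. Clusters smaller
#' than `min_size` go to module 0 (unassigned). Modules are numbered 1..M by
#' decreasing size.
#'
#' @param net adjacency matrix from [build_adjacency()].
#' @param nm the normalized matrix the adjacency came from (needed for
#'   eigengene-based merging).
#' @param min_size minimum module size.
#' @param cut_height static cut height on the dendrogram.
#' @param merge_cor eigengene correlation above which modules merge.
#' @return A list of class `ModuleSet`: `modules` (named integer vector,
#'   0 = unassigned), `eigengenes` (observations x modules, unit-norm
#'   columns), `variance_explained` per module.
#' @export
detect_modules <- function(net, nm, min_size = 30, cut_height = 0.99,
                           merge_cor = 0.85) {
  genes <- rownames(net)
  if (length(genes) < min_size) {
    modules <- stats::setNames(rep(0L, length(genes)), genes)
    return(structure(list(modules = modules,
                          eigengenes = NULL, variance_explained = numeric(0)),
                     class = "ModuleSet"))
  }
  diss <- 1 - tom_similarity(net)
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  modules <- ifelse(as.character(raw) %in% keep, raw, 0L)
  names(modules) <- genes
  # merge highly correlated modules by eigengene similarity
  repeat {
    ids <- setdiff(unique(modules), 0L)
    if (length(ids) < 2) break
    eg <- vapply(ids, function(m) {
      module_eigengene(nm[names(modules)[modules == m], , drop = FALSE])$eigengene
    }, numeric(ncol(nm)))
    cm <- stats::cor(eg)
    diag(cm) <- 0
    mx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    if (cm[mx[1], mx[2]] <= merge_cor) break
    modules[modules == ids[mx[2]]] <- ids[mx[1]]
  }
  # relabel by decreasing size
  ids <- setdiff(unique(modules), 0L)
  if (length(ids) > 0) {
    ord <- ids[order(-tabulate(match(modules, ids)))]
    relab <- stats::setNames(seq_along(ord), ord)
    modules <- ifelse(modules == 0L, 0L,
                      as.integer(relab[as.character(modules)]))
    names(modules) <- genes
  }
  me <- module_eigengenes(nm, modules)
  structure(list(modules = modules, eigengenes = me$eigengenes,
                 variance_explained = me$variance_explained),
            class = "ModuleSet")
}

# internal: first principal component of a gene-standardized submatrix
module_eigengene <- function(sub_nm) {
  x <- t(scale(t(sub_nm)))
  x[is.na(x)] <- 0                       # constant genes carry no signal
  sv <- svd(x, nu = 0, nv = 1)
  v <- sv$v[, 1]
  avg <- colMeans(x)
  if (stats::sd(avg) > 0 && stats::cor(v, avg) < 0) v <- -v
  list(eigengene = v,
       variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Module eigengenes
#'
#' Per module, the first principal component of the gene-standardized module
#' submatrix across observations, unit-norm and sign-oriented to correlate
#' positively with the module's mean standardized expression. A single-gene
#' module's eigengene is its standardized profile (scaled to unit norm).
#'
#' @param nm normalized matrix (genes x observations).
#' @param modules named integer vector from [detect_modules()] (or a
#'   `ModuleSet`).
#' @return A list: `eigengenes` (observations x modules, columns named
#'   `M1`, `M2`, ...), `variance_explained`.
#' @export
module_eigengenes <- function(nm, modules) {
  if (inherits(modules, "ModuleSet")) modules <- modules$modules
  ids <- sort(setdiff(unique(modules), 0L))
  if (length(ids) == 0)
    return(list(eigengenes = NULL, variance_explained = numeric(0)))
  res <- lapply(ids, function(m) {
    module_eigengene(nm[names(modules)[modules == m], , drop = FALSE])
  })
  eg <- vapply(res, `[[`, numeric(ncol(nm)), "eigengene")
  dimnames(eg) <- list(colnames(nm), paste0("M", ids))
  list(eigengenes = eg,
       variance_explained = stats::setNames(
         vapply(res, `[[`, 0, "variance_explained"), paste0("M", ids)))
}

#' Correlate module eigengenes with anatomical regions
#'
#' Point-biserial (Pearson on a 0/1 indicator) correlation of each eigengene
#' with each region across spots, with the t-distribution P-value on n - 2
#' degrees of freedom. The `strong` flag marks module-region pairs with
#' `r > r_min` and `p < p_max`.
#'
#' @param eigengenes observations x modules matrix (rows named by spot id).
#' @param geom spot geometry `data.frame` with `spot_id` and `region`.
#' @param r_min,p_max thresholds for the `strong` flag.
#' @return A `data.frame` with columns `module`, `region`, `r`, `p`,
#'   `strong`. Regions with fewer than 3 spots give NA with a warning.
#' @export
module_region_correlation <- function(eigengenes, geom, r_min = 0.4,
                                      p_max = 0.01) {
  reg <- stats::setNames(geom$region, geom$spot_id)[rownames(eigengenes)]
  if (anyNA(reg)) stop("eigengene observations missing from the geometry")
  regions <- sort(unique(reg))
  out <- list()
  for (m in colnames(eigengenes)) {
    for (r in regions) {
      ind <- as.numeric(reg == r)
      if (sum(ind) < 3 || sum(1 - ind) < 3) {
        warning("region ", r, " has fewer than 3 spots on one side; NA")
        out[[paste(m, r)]] <- data.frame(module = m, region = r,
                                         r = NA_real_, p = NA_real_,
                                         strong = FALSE)
        next
      }
      ct <- stats::cor.test(eigengenes[, m], ind)
      rr <- unname(ct$estimate)
      pp <- ct$p.value
      out[[paste(m, r)]] <- data.frame(module = m, region = r, r = rr, p = pp,
                                       strong = rr > r_min & pp < p_max)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank hub genes by intramodular connectivity
#'
#' Within each module, genes are ranked by the sum of their adjacency
#' weights to the other module members (the node's neighbour edge-weight
#' sum); ties break lexicographically.
#'
#' @param net adjacency matrix.
#' @param modules named integer module vector (or a `ModuleSet`).
#' @param top_n hubs reported per module.
#' @return A `data.frame` with columns `module`, `gene`, `connectivity`,
#'   `rank`.
#' @export
hub_genes <- function(net, modules, top_n = 10) {
  if (inherits(modules, "ModuleSet")) modules <- modules$modules
  ids <- sort(setdiff(unique(modules), 0L))
  out <- list()
  for (m in ids) {
    g <- names(modules)[modules == m]
    a <- net[g, g, drop = FALSE]
    k <- rowSums(a) - 1           # exclude the self-loop (diag = 1)
    ord <- order(-k, names(k))
    take <- utils::head(ord, top_n)
    out[[as.character(m)]] <- data.frame(module = m, gene = names(k)[take],
                                         connectivity = unname(k[take]),
                                         rank = seq_along(take),
                                         stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
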
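#' Configuration for the paired-modality simulator
#'
#' Defines a synthetic developing-tissue study: a single-cell reference with
#' planted cell-type markers, and a lattice of multi-cell spots whose
#' compositions depend on three concentric anatomical regions (pelvis at the
#' centre, medulla around it, cortex outermost). Defaults describe the regime
#' the package is validated in: 15 cell types, 20 markers each at 8-fold
#' elevation, negative-binomial counts, and a 3-region spot lattice.
#'
#' Counts are negative binomial in the mean/size parameterization:
#' `variance = mean + mean^2 / nb_dispersion` (larger `nb_dispersion` means
#' less overdispersion).
#'
#' @param n_genes total number of genes, including mitochondrial ones.
#' @param n_cell_types number of reference cell types.
#' @param markers_per_type planted marker genes per cell type (disjoint
#'   across types).
#' @param marker_fold_change expected-count fold elevation of a marker in its
#'   own type; 1 means no signal.
#' @param n_cells_per_type reference cells simulated per type.
#' @param nb_mean baseline expected count per gene per cell.
#' @param nb_dispersion negative-binomial size parameter.
#' @param grid_side spots are laid on a `grid_side` x `grid_side` lattice.
#' @param region_radii two strictly increasing fractions in (0,1); spots with
#'   normalized Chebyshev radius below the first are pelvis, below the second
#'   medulla, the rest cortex.
#' @param cells_per_spot cells pooled into each spot.
#' @param dirichlet_concentration Dirichlet concentration for the cell types
#'   native to a spot's region; non-native types receive 2% of it, so each
#'   region is dominated by its own types.
#' @param mito_gene_count number of genes named with the `MT-` prefix.
#' @param mito_boost_frac fraction of spots given elevated mitochondrial
#'   content (to exercise the QC filter); 0 disables.
#' @param mito_boost_factor fold elevation of mito-gene means in boosted spots.
#' @param seed integer seed; both generators are fully determined by it.
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(n_genes = 800, n_cell_types = 15, markers_per_type = 20,
                       marker_fold_change = 8, n_cells_per_type = 40,
                       nb_mean = 0.5, nb_dispersion = 2, grid_side = 16,
                       region_radii = c(0.35, 0.7), cells_per_spot = 10,
                       dirichlet_concentration = 1, mito_gene_count = 20,
                       mito_boost_frac = 0.05, mito_boost_factor = 25,
                       seed = 0L) {
  cfg <- list(n_genes = n_genes, n_cell_types = n_cell_types,
              markers_per_type = markers_per_type,
              marker_fold_change = marker_fold_change,
              n_cells_per_type = n_cells_per_type, nb_mean = nb_mean,
              nb_dispersion = nb_dispersion, grid_side = grid_side,
              region_radii = region_radii, cells_per_spot = cells_per_spot,
              dirichlet_concentration = dirichlet_concentration,
              mito_gene_count = mito_gene_count,
              mito_boost_frac = mito_boost_frac,
              mito_boost_factor = mito_boost_factor, seed = as.integer(seed))
  for (f in c("n_genes", "n_cell_types", "markers_per_type",
              "n_cells_per_type", "grid_side", "cells_per_spot"))
    if (cfg[[f]] < 1) stop(f, " must be >= 1")
  if (cfg$mito_gene_count < 0) stop("mito_gene_count must be >= 0")
  for (f in c("marker_fold_change", "nb_mean", "nb_dispersion",
              "dirichlet_concentration"))
    if (cfg[[f]] <= 0) stop(f, " must be positive")
  if (length(region_radii) != 2 || any(region_radii <= 0) ||
      any(region_radii >= 1) || diff(region_radii) <= 0)
    stop("region_radii must be two strictly increasing fractions in (0,1)")
  if (markers_per_type * n_cell_types > n_genes - mito_gene_count)
    stop("configuration error: markers_per_type * n_cell_types exceeds the ",
         "number of non-mitochondrial genes")
  class(cfg) <- "SimConfig"
  cfg
}

# internal: gene names (MT- prefixed mito genes first), marker assignment and
# the per-type mean matrix implied by a config. Deterministic, no RNG.
sim_model <- function(config) {
  n_mito <- config$mito_gene_count
  genes <- c(if (n_mito > 0) sprintf("MT-%d", seq_len(n_mito)),
             sprintf("G%04d", seq_len(config$n_genes - n_mito)))
  types <- sprintf("T%02d", seq_len(config$n_cell_types))
  nonmito <- genes[!grepl("^MT-", genes)]
  marker_map <- list()
  idx <- 1L
  for (t in types) {
    marker_map[[t]] <- nonmito[idx:(idx + config$markers_per_type - 1L)]
    idx <- idx + config$markers_per_type
  }
  means <- matrix(config$nb_mean, length(genes), length(types),
                  dimnames = list(genes, types))
  for (t in types)
    means[marker_map[[t]], t] <- config$nb_mean * config$marker_fold_change
  # each type is native to one region, round-robin over the three rings
  regions <- c("pelvis", "medulla", "cortex")
  home <- regions[((seq_along(types) - 1L) %% 3L) + 1L]
  names(home) <- types
  list(genes = genes, types = types, marker_map = marker_map, means = means,
       home_region = home, regions = regions)
}

#' Simulate a single-cell reference with planted cell-type markers
#'
#' Draws `n_cells_per_type` cells per type; every gene is NB(mean, size =
#' `nb_dispersion`) with marker genes elevated `marker_fold_change`-fold in
#' their own type. The RNG is seeded once from `config$seed`, so repeated
#' calls are bit-identical.
#'
#' @param config a [sim_config()].
#' @return A list with `counts` (a `CountMatrix` of cells, with a `cell_type`
#'   metadata column) and `truth` (partial ground truth: `cell_labels`,
#'   `marker_map`, `home_region`).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  model <- sim_model(config)
  set.seed(config$seed)
  n_cells <- config$n_cell_types * config$n_cells_per_type
  labels <- rep(model$types, each = config$n_cells_per_type)
  cells <- sprintf("cell%04d", seq_len(n_cells))
  counts <- matrix(0L, length(model$genes), n_cells,
                   dimnames = list(model$genes, cells))
  for (j in seq_len(n_cells)) {
    counts[, j] <- stats::rnbinom(length(model$genes),
                                  size = config$nb_dispersion,
                                  mu = model$means[, labels[j]])
  }
  meta <- data.frame(cell_type = labels, row.names = cells)
  truth <- list(cell_labels = stats::setNames(labels, cells),
                marker_map = model$marker_map,
                home_region = model$home_region)
  list(counts = count_matrix(counts, meta), truth = truth)
}

# internal: one Dirichlet draw via independent gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate spatial spots as region-dependent cell-type mixtures
#'
#' Spots sit on a square lattice split into three concentric regions (pelvis
#' centre, medulla ring, cortex rim) by normalized Chebyshev radius. Each
#' spot's intended composition is drawn from a region-specific Dirichlet in
#' which the region's native cell types carry the full concentration and the
#' others 2% of it; `cells_per_spot` cells are then sampled multinomially and
#' their NB expression summed. A deterministic subset of spots gets
#' mitochondrial means multiplied by `mito_boost_factor` so the 10% QC
#' threshold is exercised.
#'
#' @param config the same [sim_config()] used for the reference.
#' @param reference_truth the `truth` element returned by
#'   [generate_reference()]; its `marker_map` must be present.
#' @return A list with `counts` (`CountMatrix` of spots), `geometry` (a
#'   `data.frame` with columns `spot_id`, `x`, `y`, `region`) and `truth`
#'   (full ground truth: the reference fields plus `spot_compositions`, the
#'   realized spot x cell-type proportion matrix, `dirichlet_weights`, and
#'   `region_of_spot`).
#' @export
generate_spatial <- function(config, reference_truth) {
  stopifnot(inherits(config, "SimConfig"))
  if (is.null(reference_truth$marker_map))
    stop("reference_truth is missing marker_map; run generate_reference first")
  model <- sim_model(config)
  set.seed(config$seed + 1L)
  side <- config$grid_side
  xy <- expand.grid(x = seq_len(side), y = seq_len(side))
  ctr <- (side + 1) / 2
  r <- pmax(abs(xy$x - ctr), abs(xy$y - ctr)) / (side / 2 - 0.5)
  region <- ifelse(r <= config$region_radii[1], "pelvis",
                   ifelse(r <= config$region_radii[2], "medulla", "cortex"))
  n_spots <- nrow(xy)
  spots <- sprintf("spot%04d", seq_len(n_spots))
  geometry <- data.frame(spot_id = spots, x = xy$x, y = xy$y, region = region,
                         stringsAsFactors = FALSE)

  types <- model$types
  alpha_base <- config$dirichlet_concentration
  comp <- matrix(0, n_spots, length(types), dimnames = list(spots, types))
  weights <- comp
  counts <- matrix(0, length(model$genes), n_spots,
                   dimnames = list(model$genes, spots))
  boosted <- rep(FALSE, n_spots)
  if (config$mito_boost_frac > 0 && config$mito_gene_count > 0) {
    step <- max(1L, round(1 / config$mito_boost_frac))
    boosted[seq(step, n_spots, by = step)] <- TRUE
  }
  mito <- grepl("^MT-", model$genes)
  for (i in seq_len(n_spots)) {
    alpha <- ifelse(model$home_region == region[i], alpha_base,
                    0.02 * alpha_base)
    w <- rdirichlet1(alpha)
    weights[i, ] <- w
    n_per_type <- as.vector(stats::rmultinom(1, config$cells_per_spot, w))
    comp[i, ] <- n_per_type / config$cells_per_spot
    for (ti in which(n_per_type > 0)) {
      m <- n_per_type[ti]
      mu <- m * model$means[, ti]
      if (boosted[i]) mu[mito] <- mu[mito] * config$mito_boost_factor
      counts[, i] <- counts[, i] +
        stats::rnbinom(length(mu), size = m * config$nb_dispersion, mu = mu)
    }
  }
  truth <- c(reference_truth,
             list(spot_compositions = comp, dirichlet_weights = weights,
                  region_of_spot = stats::setNames(region, spots),
                  mito_boosted = stats::setNames(boosted, spots)))
  meta <- data.frame(region = region, row.names = spots)
  list(counts = count_matrix(counts, meta), geometry = geometry, truth = truth)
}
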
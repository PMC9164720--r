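#' End-to-end pipeline configuration
#'
#' Collects every stage parameter in one serializable list. Defaults are the
#' thresholds used throughout the analysis: QC at 10% mitochondrial fraction
#' and 200 detected genes, 30 principal components, Louvain resolution 0.9,
#' marker extraction at adjusted P < 0.05 and log2 FC > 0.25, MIA labelling
#' at P < 0.01, a 10% minimum deconvolution contribution, module-region
#' flags at r > 0.4 and P < 0.01, and ligand-receptor significance at
#' score > 1 and P < 0.01.
#'
#' @param synthetic run on simulated data (`sim`) instead of reading paths.
#' @param sim a [sim_config()] used when `synthetic = TRUE`.
#' @param sc_path,st_path,spot_positions_path input locations for real data
#'   (each a [read_count_matrix()] source; positions a CSV).
#' @param max_mito_frac,min_genes QC thresholds.
#' @param n_pcs,resolution,k_neighbors embedding / clustering settings.
#' @param st_test,st_logfc,st_min_pct spatial-side marker-calling settings.
#' @param sc_test reference-side marker test.
#' @param p_adj_max,log2fc_min marker-set extraction thresholds.
#' @param mia_alpha MIA label-assignment threshold.
#' @param min_contribution deconvolution contribution filter.
#' @param min_module_size,soft_powers,cut_height,module_r_min,module_p_max
#'   network settings; the demo default module size (15) suits the planted
#'   20-gene cell-type programs of the simulator.
#' @param lr_score_min,lr_alpha,n_perm crosstalk / GSEA settings.
#' @param seed global seed.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(synthetic = TRUE, sim = sim_config(seed = seed),
                            sc_path = NULL, st_path = NULL,
                            spot_positions_path = NULL,
                            max_mito_frac = 0.10, min_genes = 200,
                            n_pcs = 30, resolution = 0.9, k_neighbors = 20,
                            st_test = "bimod", st_logfc = 0.1,
                            st_min_pct = 0.01, sc_test = "wilcoxon",
                            p_adj_max = 0.05, log2fc_min = 0.25,
                            mia_alpha = 0.01, min_contribution = 0.10,
                            min_module_size = 15, soft_powers = 1:6,
                            cut_height = 0.995, module_r_min = 0.4,
                            module_p_max = 0.01, lr_score_min = 1,
                            lr_alpha = 0.01, n_perm = 200, seed = 0L) {
  cfg <- as.list(environment())
  stopifnot(max_mito_frac >= 0, max_mito_frac <= 1, min_genes >= 0,
            resolution > 0, p_adj_max > 0, p_adj_max <= 1,
            mia_alpha > 0, mia_alpha <= 1,
            min_contribution >= 0, min_contribution < 1,
            module_r_min >= -1, module_r_min <= 1, n_perm >= 0)
  if (!synthetic && (is.null(sc_path) || is.null(st_path)))
    stop("without synthetic data, sc_path and st_path are required")
  class(cfg) <- "PipelineConfig"
  cfg
}

# internal: demo ligand-receptor pairs planted on the simulated markers --
# one marker gene per sender type paired with one per receiver type
synthetic_lr_pairs <- function(marker_map) {
  types <- names(marker_map)
  n <- length(types)
  send <- types[seq_len(min(4, n))]
  recv <- types[((seq_len(min(4, n))) %% n) + 1]
  data.frame(ligand = vapply(send, function(t) marker_map[[t]][1], ""),
             receptor = vapply(recv, function(t) marker_map[[t]][2], ""),
             stringsAsFactors = FALSE)
}

#' Run the full spatial/single-cell integration pipeline
#'
#' Executes, in order: data generation or loading, spot QC, normalization,
#' PCA and graph clustering of the spots, spatial and reference marker
#' calling, MIA labelling, NNLS deconvolution with region fractions,
#' co-expression network analysis over the spatial marker genes,
#' ligand-receptor crosstalk on the reference, and a medulla-versus-rest
#' GSEA. All stage outputs are written as plain-text files under `out_dir`
#' together with `manifest.json` (configuration, seed, package version and
#' per-stage dimensions); reruns with the same configuration are
#' bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return A list with all stage results plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed (earlier stage outputs are ",
           "kept in the result): ", conditionMessage(e), call. = FALSE)
    })
  }
  res <- list()

  if (config$synthetic) {
    ref <- stage("simulate", generate_reference(config$sim))
    sp <- stage("simulate", generate_spatial(config$sim, ref$truth))
    sc <- ref$counts
    st <- sp$counts
    geom <- sp$geometry
    truth <- sp$truth
    sc_labels <- truth$cell_labels
    lr_pairs <- synthetic_lr_pairs(truth$marker_map)
  } else {
    sc <- stage("load", read_count_matrix(config$sc_path))
    st <- stage("load", read_count_matrix(config$st_path))
    geom <- stage("load",
                  read_spot_positions(config$spot_positions_path, st))
    truth <- NULL
    sc_labels <- NULL
    lr_pairs <- NULL
  }

  qc <- stage("qc", qc_filter(st, config$max_mito_frac, config$min_genes))
  st_f <- qc$filtered
  geom <- geom[geom$spot_id %in% colnames(st_f), , drop = FALSE]
  res$qc_report <- qc$report

  nm_st <- stage("normalize", normalize_cp10k(st_f))
  nm_sc <- stage("normalize", normalize_cp10k(sc))

  n_pcs <- min(config$n_pcs, dim(nm_st) - 1)
  emb <- stage("embed", embed_pca(nm_st, n_components = n_pcs))
  st_clusters <- stage("cluster",
                       cluster_graph(emb, resolution = config$resolution,
                                     k_neighbors = config$k_neighbors,
                                     seed = config$seed))
  res$st_clusters <- st_clusters

  st_markers <- stage("markers",
                      rank_markers(nm_st, st_clusters, test = config$st_test,
                                   logfc_threshold = config$st_logfc,
                                   min_pct = config$st_min_pct))
  region_sets <- stage("markers",
                       suppressWarnings(
                         extract_gene_sets(st_markers, config$p_adj_max,
                                           config$log2fc_min)))
  if (is.null(sc_labels)) {
    emb_sc <- stage("cluster", embed_pca(nm_sc, n_components = n_pcs))
    sc_labels <- stage("cluster",
                       cluster_graph(emb_sc, resolution = config$resolution,
                                     k_neighbors = config$k_neighbors,
                                     seed = config$seed))$labels
  }
  sc_markers <- stage("markers",
                      rank_markers(nm_sc, sc_labels, test = config$sc_test,
                                   logfc_threshold = config$st_logfc,
                                   min_pct = config$st_min_pct))
  cell_sets <- stage("markers",
                     suppressWarnings(
                       extract_gene_sets(sc_markers, config$p_adj_max,
                                         config$log2fc_min)))
  res$st_markers <- st_markers
  res$sc_markers <- sc_markers

  background <- stage("mia", detected_background(sc, st_f))
  mia <- stage("mia", mia_matrix(cell_sets, region_sets, background))
  res$mia <- mia
  res$labels <- stage("mia", assign_labels(mia, alpha = config$mia_alpha))

  sig <- stage("deconvolve", build_signatures(nm_sc, sc_labels, cell_sets))
  pt <- stage("deconvolve",
              deconvolve_spots(nm_st, sig,
                               min_contribution = config$min_contribution))
  res$proportions <- pt
  res$region_fractions <- stage("deconvolve",
                                region_fractions(pt, geom,
                                                 regions = unique(geom$region)))

  de_genes <- sort(unique(st_markers$gene[st_markers$p_adj < config$p_adj_max &
                                            st_markers$log2_fc > 0]))
  net <- NULL
  if (length(de_genes) >= config$min_module_size) {
    nm_net <- nm_st[de_genes, , drop = FALSE]
    nm_net <- nm_net[apply(nm_net, 1, stats::var) > 0, , drop = FALSE]
    sp_pick <- stage("network",
                     suppressWarnings(pick_soft_power(nm_net,
                                                      powers = config$soft_powers)))
    adj <- stage("network", build_adjacency(nm_net, sp_pick$power))
    mods <- stage("network",
                  detect_modules(adj, nm_net,
                                 min_size = config$min_module_size,
                                 cut_height = config$cut_height))
    mrc <- if (!is.null(mods$eigengenes))
      stage("network",
            module_region_correlation(mods$eigengenes, geom,
                                      r_min = config$module_r_min,
                                      p_max = config$module_p_max))
    net <- list(power = sp_pick$power, modules = mods,
                module_region = mrc,
                hubs = stage("network", hub_genes(adj, mods)))
  }
  res$network <- net

  if (!is.null(lr_pairs)) {
    res$crosstalk <- stage("crosstalk",
                           lr_scores(nm_sc, sc_labels, lr_pairs,
                                     n_perm = config$n_perm,
                                     seed = config$seed,
                                     score_min = config$lr_score_min,
                                     alpha = config$lr_alpha))
  }

  if ("medulla" %in% geom$region && config$synthetic) {
    med <- geom$spot_id[geom$region == "medulla"]
    rest <- geom$spot_id[geom$region != "medulla"]
    med_types <- names(truth$home_region)[truth$home_region == "medulla"]
    med_set <- unlist(truth$marker_map[med_types], use.names = FALSE)
    sets <- gene_set_collection(list(medulla_program = med_set))
    res$gsea <- stage("gsea",
                      gsea(nm_st, med, rest, sets, n_perm = config$n_perm,
                           seed = config$seed))
  }

  manifest <- list(
    package = "spatiomap",
    version = as.character(utils::packageVersion("spatiomap")),
    seed = config$seed,
    config = unclass(config[setdiff(names(config), "sim")]),
    sim = if (config$synthetic) unclass(config$sim),
    stages = list(
      n_spots_in = ncol(st$counts), n_spots_qc = ncol(st_f$counts),
      n_cells = ncol(sc$counts), n_genes = nrow(st$counts),
      n_st_clusters = length(unique(st_clusters$labels)),
      n_region_sets = length(region_sets),
      n_cell_sets = length(cell_sets),
      background_size = length(background),
      n_modules = if (!is.null(net))
        length(setdiff(unique(net$modules$modules), 0L)) else 0L,
      n_lr_rows = if (!is.null(res$crosstalk)) nrow(res$crosstalk) else 0L))
  res$manifest <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$qc_report, file.path(out_dir, "qc_report.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(obs_id = names(st_clusters$labels),
                                cluster = st_clusters$labels),
                     file.path(out_dir, "st_clusters.csv"), row.names = FALSE)
    utils::write.csv(st_markers, file.path(out_dir, "st_markers.csv"),
                     row.names = FALSE)
    write_gene_sets(gene_set_collection(
      region_sets[lengths(region_sets) > 0]),
      file.path(out_dir, "region_sets.gmt"))
    write_gene_sets(gene_set_collection(cell_sets[lengths(cell_sets) > 0]),
                    file.path(out_dir, "cell_sets.gmt"))
    utils::write.csv(res$mia$neg_log10_p, file.path(out_dir, "mia_matrix.csv"))
    utils::write.csv(res$labels, file.path(out_dir, "labels.csv"),
                     row.names = FALSE)
    utils::write.csv(res$proportions$proportions,
                     file.path(out_dir, "proportions.csv"))
    utils::write.csv(res$region_fractions,
                     file.path(out_dir, "region_fractions.csv"))
    if (!is.null(res$crosstalk))
      utils::write.csv(res$crosstalk, file.path(out_dir, "lr_scores.csv"),
                       row.names = FALSE)
    if (!is.null(res$gsea))
      utils::write.csv(res$gsea, file.path(out_dir, "gsea.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  invisible(res)
}
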
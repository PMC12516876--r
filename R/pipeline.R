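#' Pipeline configuration with the study's default parameters
#'
#' Collects every stage parameter with its default: k = 5 neighbours,
#' minimum projection similarity 0.3, informative-gene CV > 0.5 and sum in
#' [0.1, 20], co-expression threshold mean + 4 sd, strict marker thresholds
#' (pct1 > 0.10, pct2 < 0.10, adjusted P < 0.001, log2FC > 1). A resolved
#' snapshot of the configuration is written with every run.
#'
#' @param synth a \code{\link{synth_config}} describing the input dataset
#'   (the pipeline runs on generated data when no paths are given)
#' @param k,min_similarity integration parameters
#' @param layer similarity layer for cross-modal matching (\code{"cpm"})
#' @param cv_min,sum_min,sum_max informative-gene filter parameters
#' @param sd_mult co-expression threshold multiplier
#' @param marker_mode \code{"strict"} or \code{"relaxed"}
#' @param seed integer seed for stochastic steps
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(synth = synth_config(), k = 5, min_similarity = 0.3,
                            layer = c("cpm", "lognorm"),
                            cv_min = 0.5, sum_min = 0.1, sum_max = 20,
                            sd_mult = 4, marker_mode = "strict", seed = 1) {
  layer <- match.arg(layer)
  cfg <- list(synth = synth, k = k, min_similarity = min_similarity,
              layer = layer, cv_min = cv_min, sum_min = sum_min,
              sum_max = sum_max, sd_mult = sd_mult,
              marker_mode = marker_mode, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full integration pipeline on a generated dataset
#'
#' Wires the stages end to end: data generation, CPM/log normalization,
#' cosine-kNN imputation of non-panel genes into spatial cells, reverse
#' cluster-label projection with its contribution matrix, informative-gene
#' filtering and cluster correlations, marker detection, and (when plants
#' are configured) the co-expression screen. Results and a resolved
#' configuration snapshot are written under \code{out_dir} when given; the
#' full result list is returned invisibly. The run is idempotent for a
#' fixed configuration and seed.
#'
#' @param config a \code{\link{pipeline_config}}
#' @param out_dir optional output directory for CSV/MTX/JSON artifacts
#' @return invisible list with elements \code{data}, \code{imputed},
#'   \code{projection}, \code{contribution}, \code{informative_genes},
#'   \code{cluster_correlation}, \code{markers}, \code{marker_lists},
#'   \code{coexpression}
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  config$synth$seed <- config$seed
  ds <- generate_paired_dataset(config$synth)

  norm <- function(m) if (config$layer == "cpm") cpm(m) else lognormalize(m)
  sp_n <- norm(ds$spatial$counts)
  sc_n <- norm(ds$sc$counts)

  panel <- intersect(gene_ids(sp_n), gene_ids(sc_n))
  nm_fwd <- cosine_knn(sp_n, sc_n, shared_genes = panel, k = config$k)
  imputed <- impute_expression(nm_fwd, sc_n)

  nm_rev <- cosine_knn(sc_n, sp_n, shared_genes = panel, k = config$k)
  proj <- project_cluster_labels(nm_rev, ds$truth$spatial_cell_cluster,
                                 min_similarity = config$min_similarity)
  sizes <- table(ds$truth$spatial_cell_cluster)
  contrib <- contribution_matrix(proj, ds$truth$sc_cell_cluster,
                                 stats::setNames(as.numeric(sizes), names(sizes)))

  sc_log <- lognormalize(ds$sc$counts)
  prof <- cluster_average(sc_log, ds$truth$sc_cell_cluster)
  inf_genes <- informative_gene_filter(prof, cv_min = config$cv_min,
                                       sum_min = config$sum_min,
                                       sum_max = config$sum_max)
  ccm <- if (length(inf_genes) >= 3)
    cluster_correlation_matrix(prof, inf_genes) else NULL

  mk <- rank_markers(sc_log, ds$truth$sc_cell_cluster)
  mk_lists <- filter_markers(mk, mode = config$marker_mode)

  coex <- lapply(config$synth$coexpr_pairs, function(p)
    coexpression_screen(sc_log, p$gene_a, sd_mult = config$sd_mult))

  res <- list(data = ds, imputed = imputed, projection = proj,
              contribution = contrib, informative_genes = inf_genes,
              cluster_correlation = ccm, markers = mk,
              marker_lists = mk_lists, coexpression = coex)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    snap <- config
    snap$synth <- unclass(snap$synth)
    yaml::write_yaml(unclass(snap), file.path(out_dir, "config.yaml"))
    write_synth_dataset(ds, file.path(out_dir, "data"))
    write_table_csv(proj, file.path(out_dir, "projection.csv"))
    utils::write.csv(contrib$fractions, file.path(out_dir, "contribution.csv"))
    if (!is.null(ccm))
      utils::write.csv(ccm, file.path(out_dir, "cluster_correlation.csv"))
    write_table_csv(mk, file.path(out_dir, "markers.csv"))
  }
  invisible(res)
}
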
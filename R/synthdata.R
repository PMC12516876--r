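#' Configuration for the paired-modality synthetic data generator
#'
#' Defines a ground-truth world of K cell clusters whose expression profiles
#' are observed through two modalities that share a small gene panel: a
#' spatially resolved smFISH-like modality measuring only the panel, and an
#' scRNA-seq-like modality measuring a superset of genes. Counts are
#' negative binomial with variance mu + alpha * mu^2 (alpha = 0 degenerates
#' to Poisson). Gene base means are log-normal; panel genes are drawn more
#' highly expressed than the rest, mimicking a curated probe panel. Each
#' (cluster, gene) pair carries an independent log2 fold effect
#' N(0, de_log2_sd), giving every gene cluster structure the way a marker
#' panel selected for dynamic expression would. Per-cell library-size
#' factors are log-normal. Optional plants: co-expressed gene pairs coupled
#' through a shared per-cell log-normal latent factor with latent
#' correlation rho, and stress genes induced by a multiplier only in
#' designated clusters of the sc modality (emulating protoplasting
#' artifacts).
#'
#' @param n_clusters number of ground-truth clusters (default 6)
#' @param n_spatial_cells,n_sc_cells cells per modality (defaults 1500, 3000)
#' @param n_panel_genes shared panel size (default 95)
#' @param n_sc_genes total genes in the sc modality, superset of the panel
#'   (default 2000)
#' @param nb_dispersion negative-binomial dispersion alpha (default 0.3)
#' @param library_size_mean named mean library scaling per modality,
#'   \code{c(spatial = 1, sc = 1)}; the expected per-cell size factor
#' @param coexpr_pairs list of \code{list(gene_a=, gene_b=, rho=,
#'   base_mean=)} with rho in [0, 1]; the optional \code{base_mean} fixes
#'   both genes' expected expression (a pair planted in an unexpressed gene
#'   would be unobservable, so the plant controls its own abundance)
#' @param stress_genes list of \code{list(gene=, clusters=, multiplier=,
#'   base_mean=)}; \code{base_mean} overrides the gene's profile with a flat
#'   mean before induction
#' @param grid_extent side length of the square tissue domain in um
#'   (default 1000)
#' @param seed integer seed; fully determines all output
#' @param de_log2_sd sd of per-(cluster, gene) log2 fold effects (default 1.5)
#' @param lib_log_sd sd of per-cell log library factors (default 0.3)
#' @param latent_log_sd sd of the co-expression latent log factor (default 1)
#' @param panel_meanlog,panel_sdlog log-normal base-mean parameters for
#'   panel genes (defaults log(3), 0.8)
#' @param extra_meanlog,extra_sdlog same for non-panel genes (defaults
#'   log(1), 1.2)
#' @return validated list of class \code{synth_config}
#' @export
synth_config <- function(n_clusters = 6, n_spatial_cells = 1500,
                         n_sc_cells = 3000, n_panel_genes = 95,
                         n_sc_genes = 2000, nb_dispersion = 0.3,
                         library_size_mean = c(spatial = 1, sc = 1),
                         coexpr_pairs = list(), stress_genes = list(),
                         grid_extent = 1000, seed = 1,
                         de_log2_sd = 1.5, lib_log_sd = 0.3,
                         latent_log_sd = 1,
                         panel_meanlog = log(3), panel_sdlog = 0.8,
                         extra_meanlog = log(1), extra_sdlog = 1.2) {
  if (n_clusters < 1 || n_spatial_cells < 1 || n_sc_cells < 1 ||
      n_panel_genes < 1 || n_sc_genes < 1)
    stop("dimensions must be positive")
  if (n_panel_genes > n_sc_genes)
    stop("n_panel_genes must not exceed n_sc_genes")
  if (nb_dispersion < 0) stop("nb_dispersion must be nonnegative")
  if (any(library_size_mean <= 0)) stop("library_size_mean must be positive")
  if (grid_extent <= 0) stop("grid_extent must be positive")
  for (p in coexpr_pairs) {
    stopifnot(all(c("gene_a", "gene_b", "rho") %in% names(p)))
    if (p$rho < 0 || p$rho > 1) stop("latent correlation must be in [0, 1]")
  }
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

# Gene universe: panel genes PG###, extras EG####; planted genes are named
# by these ids.
synth_gene_ids <- function(cfg) {
  c(sprintf("PG%03d", seq_len(cfg$n_panel_genes)),
    if (cfg$n_sc_genes > cfg$n_panel_genes)
      sprintf("EG%04d", seq_len(cfg$n_sc_genes - cfg$n_panel_genes)))
}

#' Generate a paired smFISH-like and scRNA-seq-like dataset with ground truth
#'
#' Draws the cluster mean matrix, assigns cells to clusters (balanced),
#' samples negative-binomial counts for both modalities from the same means
#' restricted to each modality's gene set, lays spatial cells out in
#' cluster-assigned vertical tiles of the square domain (same-cluster cells
#' contiguous, jittered centres), applies planted co-expression latent
#' factors in both modalities and stress-gene induction in the sc modality
#' only. The same seed always reproduces the same output bit for bit.
#'
#' @param cfg a \code{\link{synth_config}}
#' @return list with elements \code{spatial} (list: \code{counts} raw
#'   \code{count_matrix}, \code{cells} \code{cell_table}), \code{sc} (list:
#'   \code{counts}, \code{stage} per-cell stage tags), and \code{truth}
#'   (list: \code{cluster_mean_matrix} clusters x genes expected counts at
#'   unit size factor, \code{spatial_cell_cluster}, \code{sc_cell_cluster},
#'   \code{planted_coexpr}, \code{planted_stress})
#' @export
generate_paired_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  K <- cfg$n_clusters
  genes <- synth_gene_ids(cfg)
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  G <- length(genes)
  panel <- genes[seq_len(cfg$n_panel_genes)]
  clusters <- sprintf("c%d", seq_len(K))

  base <- c(stats::rlnorm(cfg$n_panel_genes, cfg$panel_meanlog, cfg$panel_sdlog),
            stats::rlnorm(G - cfg$n_panel_genes, cfg$extra_meanlog, cfg$extra_sdlog))
  fold <- matrix(2^stats::rnorm(K * G, 0, cfg$de_log2_sd), K, G)
  M <- sweep(fold, 2, base, "*")
  dimnames(M) <- list(clusters, genes)

  # planted stress genes: flat profile (optionally overridden base mean),
  # induced by the multiplier only in designated clusters - and only in the
  # sc modality, applied at sampling time below
  stress_mult <- matrix(1, K, G, dimnames = dimnames(M))
  for (sg in cfg$stress_genes) {
    g <- sg$gene
    if (!g %in% genes) stop("planted stress gene not in gene universe: ", g)
    bm <- if (!is.null(sg$base_mean)) sg$base_mean else base[match(g, genes)]
    M[, g] <- bm
    cl <- paste0("c", sg$clusters)
    stress_mult[cl, g] <- sg$multiplier
  }
  for (p in cfg$coexpr_pairs)
    for (g in c(p$gene_a, p$gene_b)) {
      if (!g %in% genes) stop("planted co-expression gene not in gene universe: ", g)
      if (!is.null(p$base_mean)) M[, g] <- p$base_mean
    }

  sample_modality <- function(n, gene_set, lib_mean, stress = FALSE) {
    cl <- sample(rep_len(seq_len(K), n))              # balanced clusters
    s <- stats::rlnorm(n, log(lib_mean) - cfg$lib_log_sd^2 / 2, cfg$lib_log_sd)
    mu <- M[cl, gene_set, drop = FALSE] * s
    if (stress) mu <- mu * stress_mult[cl, gene_set, drop = FALSE]
    # per-cell latent factors couple planted co-expressed pairs
    for (p in cfg$coexpr_pairs) {
      u <- stats::rnorm(n)
      for (g in c(p$gene_a, p$gene_b)) {
        if (!g %in% gene_set) next
        e <- stats::rnorm(n)
        lf <- exp(cfg$latent_log_sd * (sqrt(p$rho) * u + sqrt(1 - p$rho) * e) -
                    cfg$latent_log_sd^2 / 2)
        mu[, g] <- mu[, g] * lf
      }
    }
    cnt <- if (cfg$nb_dispersion == 0) {
      stats::rpois(length(mu), lambda = mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    }
    cnt <- matrix(cnt, n, length(gene_set))
    colnames(cnt) <- gene_set
    list(cl = clusters[cl], counts = cnt)
  }

  sp <- sample_modality(cfg$n_spatial_cells, panel, cfg$library_size_mean[["spatial"]])
  sc <- sample_modality(cfg$n_sc_cells, genes, cfg$library_size_mean[["sc"]],
                        stress = TRUE)
  sp_ids <- sprintf("sp_%04d", seq_len(cfg$n_spatial_cells))
  sc_ids <- sprintf("sc_%05d", seq_len(cfg$n_sc_cells))
  rownames(sp$counts) <- sp_ids
  rownames(sc$counts) <- sc_ids

  # spatial layout: one vertical strip of the square domain per cluster,
  # cells uniform within their cluster's strip (contiguous by construction)
  strip_w <- cfg$grid_extent / K
  ci <- match(sp$cl, clusters)
  x <- (ci - 1) * strip_w + stats::runif(cfg$n_spatial_cells) * strip_w
  y <- stats::runif(cfg$n_spatial_cells) * cfg$grid_extent
  stages_sp <- sample(c("W2.5", "W3.5"), cfg$n_spatial_cells, replace = TRUE)
  stages_sc <- sample(c("W2.5", "W3.5"), cfg$n_sc_cells, replace = TRUE)
  cells <- cell_table(data.frame(
    cell_id = sp_ids, x = x, y = y, area = pi * 5^2,
    section_id = "S1", stage = stages_sp, cluster = sp$cl,
    stringsAsFactors = FALSE))

  list(
    spatial = list(
      counts = count_matrix(sp$counts, modality = "smFISH", stage = "mixed",
                            layer = "raw"),
      cells = cells),
    sc = list(
      counts = count_matrix(sc$counts, modality = "scRNA", stage = "mixed",
                            layer = "raw"),
      stage = stats::setNames(stages_sc, sc_ids)),
    truth = list(
      cluster_mean_matrix = M,
      spatial_cell_cluster = stats::setNames(sp$cl, sp_ids),
      sc_cell_cluster = stats::setNames(sc$cl, sc_ids),
      planted_coexpr = cfg$coexpr_pairs,
      planted_stress = cfg$stress_genes))
}

#' Scatter per-cell counts into a spot table
#'
#' For every (cell, gene) with count c, places exactly c spot records
#' uniformly at random within the cell's disc of radius \code{cell_radius}
#' around its centre. Total spots per gene equal the count-matrix column
#' sums, so spot-level and cell-level quantifications agree by construction.
#'
#' @param counts raw \code{\link{count_matrix}} (spatial modality)
#' @param cells \code{\link{cell_table}} with coordinates for every cell
#' @param cell_radius disc radius in um (default 5)
#' @param seed integer seed
#' @return a \code{\link{spot_table}}
#' @export
generate_spot_table <- function(counts, cells, cell_radius = 5, seed = 1) {
  stopifnot(inherits(counts, "count_matrix"), inherits(cells, "data.frame"))
  if (cell_radius < 0) stop("cell_radius must be nonnegative")
  miss <- setdiff(rownames(counts$values), cells$cell_id)
  if (length(miss)) stop("cells without coordinates: ",
                         paste(utils::head(miss), collapse = ", "))
  set.seed(seed)
  v <- as.matrix(counts$values)
  nz <- which(v > 0, arr.ind = TRUE)
  if (nrow(nz) == 0)
    return(spot_table(data.frame(gene_id = character(), x = numeric(),
                                 y = numeric(), section_id = character(),
                                 stringsAsFactors = FALSE)))
  reps <- v[nz]
  cell_idx <- match(rownames(v)[nz[, 1]], cells$cell_id)
  gene <- rep(colnames(v)[nz[, 2]], reps)
  cx <- rep(cells$x[cell_idx], reps)
  cy <- rep(cells$y[cell_idx], reps)
  sec <- if ("section_id" %in% names(cells))
    rep(as.character(cells$section_id[cell_idx]), reps) else "S1"
  n <- length(gene)
  r <- cell_radius * sqrt(stats::runif(n))    # uniform over the disc
  th <- stats::runif(n, 0, 2 * pi)
  spot_table(data.frame(gene_id = gene, x = cx + r * cos(th),
                        y = cy + r * sin(th), section_id = sec,
                        stringsAsFactors = FALSE))
}

#' Generate a region-level bulk expression table with known region effects
#'
#' Emulates the pre-normalized (TMM-scale) bulk expression input of the
#' region-assignment analysis: per gene, the base expression is the mean of
#' its cluster profile, multiplied by a per-region effect and log-normal
#' replicate noise. With \code{noise_sd = 0} the table is exact, which makes
#' the Tukey winner rule testable by construction.
#'
#' @param truth the \code{truth} element of
#'   \code{\link{generate_paired_dataset}} output
#' @param n_regions number of regions (default 3, named base/middle/tip)
#' @param n_reps replicates per region (default 3; at least 2)
#' @param region_effects genes x regions multiplier matrix, or named list
#'   gene -> multiplier vector; unlisted genes get multiplier 1
#' @param noise_sd sd of log-normal replicate noise (default 0.1)
#' @param seed integer seed
#' @param genes gene ids to include (default: all ground-truth genes)
#' @return a \code{\link{region_table}}
#' @export
generate_region_expression <- function(truth, n_regions = 3, n_reps = 3,
                                       region_effects = NULL, noise_sd = 0.1,
                                       seed = 1, genes = NULL) {
  if (n_reps < 2) stop("n_reps must be at least 2 (Tukey undefined)")
  M <- truth$cluster_mean_matrix
  if (is.null(genes)) genes <- colnames(M)
  regions <- if (n_regions == 3) c("base", "middle", "tip")
             else sprintf("region%d", seq_len(n_regions))
  eff <- matrix(1, length(genes), n_regions,
                dimnames = list(genes, regions))
  if (!is.null(region_effects)) {
    if (is.list(region_effects)) {
      for (g in names(region_effects)) eff[g, ] <- region_effects[[g]]
    } else {
      eff[rownames(region_effects), ] <- region_effects
    }
  }
  if (any(eff <= 0)) stop("region multipliers must be positive")
  set.seed(seed)
  base <- colMeans(M)[genes]
  out <- expand.grid(replicate = seq_len(n_reps), region = regions,
                     gene_id = genes, stringsAsFactors = FALSE)
  noise <- if (noise_sd == 0) 1 else stats::rlnorm(nrow(out), 0, noise_sd)
  out$value <- base[out$gene_id] * eff[cbind(out$gene_id, out$region)] * noise
  region_table(out[, c("gene_id", "region", "replicate", "value")])
}

#' Write a generated dataset to disk in standard formats
#'
#' Count matrices go to MTX trios, cell and spot tables to CSV, and the
#' ground truth to JSON, under one directory.
#'
#' @param ds output of \code{\link{generate_paired_dataset}}
#' @param dir output directory
#' @return \code{dir}, invisibly
#' @export
write_synth_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(ds$spatial$counts, file.path(dir, "spatial"))
  write_count_matrix(ds$sc$counts, file.path(dir, "sc"))
  write_table_csv(ds$spatial$cells, file.path(dir, "cells.csv"))
  truth <- ds$truth
  jsonlite::write_json(
    list(cluster_mean_matrix = as.data.frame(truth$cluster_mean_matrix),
         spatial_cell_cluster = as.list(truth$spatial_cell_cluster),
         sc_cell_cluster = as.list(truth$sc_cell_cluster),
         planted_coexpr = truth$planted_coexpr,
         planted_stress = truth$planted_stress),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
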
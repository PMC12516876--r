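#' Quality-control cell filtering on detected genes and total UMIs
#'
#' Retains cells whose number of detected genes (nonzero counts) and total
#' UMI count both fall inside closed intervals. The defaults are the bounds
#' used for droplet scRNA-seq of developing wheat spikes: 1500--25,000
#' expressed genes and 8000--300,000 UMIs per cell.
#'
#' @param m raw-layer \code{\link{count_matrix}}
#' @param min_genes,max_genes closed bounds on detected genes per cell
#' @param min_umi,max_umi closed bounds on total UMIs per cell
#' @return the filtered \code{count_matrix}; the gene set is unchanged
#' @export
qc_filter_cells <- function(m, min_genes = 1500, max_genes = 25000,
                            min_umi = 8000, max_umi = 300000) {
  stopifnot(inherits(m, "count_matrix"), m$layer == "raw",
            min_genes <= max_genes, min_umi <= max_umi)
  ngenes <- Matrix::rowSums(m$values > 0)
  numi <- Matrix::rowSums(m$values)
  keep <- ngenes >= min_genes & ngenes <= max_genes &
    numi >= min_umi & numi <= max_umi
  if (!any(keep)) stop("QC filter removed every cell")
  count_matrix(m$values[keep, , drop = FALSE],
               modality = m$modality, stage = m$stage, layer = "raw")
}

#' Counts-per-million normalization
#'
#' value(c, g) = raw(c, g) / total(c) * 1e6; each cell's values sum to one
#' million. CPM is the similarity layer used for cross-modal cosine matching.
#'
#' @param m raw-layer \code{\link{count_matrix}}
#' @return a \code{count_matrix} on the \code{cpm} layer
#' @export
cpm <- function(m) {
  stopifnot(inherits(m, "count_matrix"), m$layer == "raw")
  tot <- Matrix::rowSums(m$values)
  if (any(tot == 0)) stop("cell(s) with zero total count: ",
                          paste(utils::head(rownames(m$values)[tot == 0]), collapse = ", "))
  v <- m$values / tot * 1e6
  count_matrix(v, modality = m$modality, stage = m$stage, layer = "cpm")
}

#' Log-normalization (natural log of scaled counts plus one)
#'
#' value(c, g) = ln(1 + raw(c, g) / total(c) * scale_factor). With
#' \code{scale_factor = 1} this matches log-normalization of per-cell
#' proportions, the convention used for the smFISH panel; \code{1e4} is the
#' droplet scRNA-seq default.
#'
#' @param m raw-layer \code{\link{count_matrix}}
#' @param scale_factor positive scaling applied to per-cell proportions
#' @return a \code{count_matrix} on the \code{lognorm} layer
#' @export
lognormalize <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "count_matrix"), m$layer == "raw", scale_factor > 0)
  tot <- Matrix::rowSums(m$values)
  if (any(tot == 0)) stop("cell(s) with zero total count: ",
                          paste(utils::head(rownames(m$values)[tot == 0]), collapse = ", "))
  v <- log1p(m$values / tot * scale_factor)
  count_matrix(v, modality = m$modality, stage = m$stage, layer = "lognorm")
}

#' Per-cluster average expression profiles
#'
#' Arithmetic mean of normalized expression across the cells of each cluster,
#' one profile row per cluster, with cluster sizes recorded. These
#' pseudobulk profiles feed the informative-gene filter and all cluster
#' correlation analyses.
#'
#' @param m normalized (\code{cpm} or \code{lognorm}) \code{\link{count_matrix}}
#' @param labels cluster label per cell: named vector (names = cell ids) or
#'   vector in cell order
#' @return object of class \code{cluster_profile}: list with \code{means}
#'   (clusters x genes matrix) and \code{sizes} (named cell counts)
#' @export
cluster_average <- function(m, labels) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer == "raw") stop("cluster_average expects a normalized layer")
  labels <- align_labels(labels, rownames(m$values))
  cl <- sort(unique(labels))
  means <- do.call(rbind, lapply(cl, function(k) {
    Matrix::colMeans(m$values[labels == k, , drop = FALSE])
  }))
  rownames(means) <- cl
  sizes <- as.integer(table(factor(labels, levels = cl)))
  names(sizes) <- cl
  if (any(sizes == 0)) stop("cluster with zero cells")
  structure(list(means = as.matrix(means), sizes = sizes),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("<cluster_profile> %d clusters x %d genes (sizes %s)\n",
              nrow(x$means), ncol(x$means),
              paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' Sum normalized expression over homeolog groups
#'
#' Collapses the matrix to one column per homeolog group, each the sum of its
#' member columns. Members absent from the matrix contribute zero (panels
#' from different studies rarely measure all three wheat subgenome copies);
#' genes not mapped to any group are dropped. A member listed twice within
#' one group is an error.
#'
#' @param m normalized \code{\link{count_matrix}}
#' @param map named list: group id -> member gene ids
#'   (see \code{\link{read_homeolog_map}})
#' @return a \code{count_matrix} with group ids as gene ids
#' @export
aggregate_homeologs <- function(m, map) {
  stopifnot(inherits(m, "count_matrix"))
  groups <- names(map)
  out <- matrix(0, nrow(m$values), length(groups),
                dimnames = list(rownames(m$values), groups))
  for (i in seq_along(map)) {
    mem <- map[[i]]
    if (anyDuplicated(mem))
      stop("gene listed twice in homeolog group ", groups[i])
    present <- intersect(mem, colnames(m$values))
    if (length(present))
      out[, i] <- Matrix::rowSums(m$values[, present, drop = FALSE])
  }
  count_matrix(out, modality = m$modality, stage = m$stage, layer = m$layer)
}

#' Sum homeolog groups within a cluster profile
#'
#' Same aggregation as \code{\link{aggregate_homeologs}} but applied to
#' cluster-averaged profiles, which is where cross-study comparison needs it.
#'
#' @param p a \code{cluster_profile}
#' @inheritParams aggregate_homeologs
#' @return a \code{cluster_profile} over group ids
#' @export
aggregate_homeologs_profile <- function(p, map) {
  stopifnot(inherits(p, "cluster_profile"))
  groups <- names(map)
  out <- matrix(0, nrow(p$means), length(groups),
                dimnames = list(rownames(p$means), groups))
  for (i in seq_along(map)) {
    mem <- map[[i]]
    if (anyDuplicated(mem))
      stop("gene listed twice in homeolog group ", groups[i])
    present <- intersect(mem, colnames(p$means))
    if (length(present))
      out[, i] <- rowSums(p$means[, present, drop = FALSE])
  }
  structure(list(means = out, sizes = p$sizes), class = "cluster_profile")
}

# Resolve a per-cell label vector against the matrix's cell ids.
align_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    miss <- setdiff(ids, names(labels))
    if (length(miss)) stop("no cluster label for cell(s): ",
                           paste(utils::head(miss), collapse = ", "))
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("labels must be named by cell id or match the number of cells")
  }
  as.character(labels)
}
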
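#' Informative-gene filter for cluster correlation analyses
#'
#' Keeps genes whose expression varies meaningfully across cluster-average
#' profiles: the coefficient of variation (sample sd / mean over cluster
#' means) must exceed \code{cv_min}, and the total sum across clusters must
#' lie in the closed interval [\code{sum_min}, \code{sum_max}]. The lower
#' sum bound removes genes dominated by zeros; the upper bound removes very
#' highly expressed genes that would swamp Pearson correlations. Genes with
#' zero mean are excluded (CV undefined).
#'
#' @param p a \code{cluster_profile} (see \code{\link{cluster_average}})
#' @param cv_min strict lower bound on CV (default 0.5)
#' @param sum_min,sum_max closed bounds on the sum over cluster means
#'   (defaults 0.1 and 20)
#' @param sd_type \code{"sample"} (n-1 denominator, default) or
#'   \code{"population"}
#' @return character vector of retained gene ids
#' @export
informative_gene_filter <- function(p, cv_min = 0.5, sum_min = 0.1,
                                    sum_max = 20,
                                    sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(p, "cluster_profile"), sum_min < sum_max, cv_min >= 0)
  m <- p$means
  if (nrow(m) < 2) stop("need at least 2 clusters")
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  if (sd_type == "population")
    s <- s * sqrt((nrow(m) - 1) / nrow(m))
  cv <- ifelse(mu > 0, s / mu, NA_real_)
  tot <- colSums(m)
  keep <- !is.na(cv) & cv > cv_min & tot >= sum_min & tot <= sum_max
  colnames(m)[keep]
}

#' Pearson correlation matrix among cluster profiles
#'
#' Pairwise Pearson correlation between every pair of cluster-average
#' expression vectors over a chosen (typically informative-filtered) gene
#' set. The result is symmetric with an exact unit diagonal. A cluster with
#' zero variance over the gene set gets NA correlations and is reported in
#' \code{attr(, "degenerate_clusters")}.
#'
#' @param p a \code{cluster_profile}
#' @param genes gene ids to correlate over (at least 3)
#' @return square correlation matrix with attribute \code{n_genes}
#' @export
cluster_correlation_matrix <- function(p, genes = colnames(p$means)) {
  stopifnot(inherits(p, "cluster_profile"))
  if (length(genes) < 3) stop("need at least 3 genes")
  if (!all(genes %in% colnames(p$means))) stop("unknown gene id(s)")
  m <- p$means[, genes, drop = FALSE]
  v <- apply(m, 1, stats::var)
  degen <- rownames(m)[v == 0]
  r <- suppressWarnings(stats::cor(t(m)))
  diag(r) <- 1
  if (length(degen)) {
    r[degen, ] <- NA_real_
    r[, degen] <- NA_real_
    diag(r)[rownames(r) %in% degen] <- NA_real_
  }
  attr(r, "n_genes") <- length(genes)
  attr(r, "degenerate_clusters") <- degen
  r
}

#' Cross-study correlation between two cluster profile sets
#'
#' Rectangular Pearson matrix between every cluster of study a and every
#' cluster of study b over shared gene ids. When a homeolog map is supplied
#' the profile holding individual homeologs is aggregated first
#' (\code{\link{aggregate_homeologs_profile}}), so e.g. hexaploid-wheat
#' single-cell profiles summed over A/B/D copies can be compared with a
#' probe panel that detects all copies of a gene.
#'
#' @param a,b \code{cluster_profile} objects
#' @param shared gene ids to use; defaults to the intersection after any
#'   aggregation
#' @param homeolog_map optional named list group -> members, applied to the
#'   profile that still carries individual homeologs
#' @param aggregate_side which profile to aggregate: \code{"b"} (default),
#'   \code{"a"}, or \code{"none"}
#' @return clusters_a x clusters_b correlation matrix
#' @export
cross_study_correlation <- function(a, b, shared = NULL, homeolog_map = NULL,
                                    aggregate_side = c("b", "a", "none")) {
  aggregate_side <- match.arg(aggregate_side)
  stopifnot(inherits(a, "cluster_profile"), inherits(b, "cluster_profile"))
  if (!is.null(homeolog_map)) {
    if (aggregate_side == "a") a <- aggregate_homeologs_profile(a, homeolog_map)
    if (aggregate_side == "b") b <- aggregate_homeologs_profile(b, homeolog_map)
  }
  if (is.null(shared)) shared <- intersect(colnames(a$means), colnames(b$means))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  ra <- a$means[, shared, drop = FALSE]
  rb <- b$means[, shared, drop = FALSE]
  r <- suppressWarnings(stats::cor(t(ra), t(rb)))
  attr(r, "n_genes") <- length(shared)
  r
}

#' Hierarchical ordering of a correlation matrix for display
#'
#' Complete-linkage clustering on Euclidean distances between matrix rows,
#' the standard heatmap ordering; provided as an output convenience only.
#'
#' @param r correlation matrix
#' @return integer row order
#' @export
correlation_order <- function(r) {
  stats::hclust(stats::dist(r), method = "complete")$order
}
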
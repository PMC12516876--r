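#' One-vs-rest marker statistics for every (cluster, gene) pair
#'
#' For each cluster, compares each gene's log-normalized expression in the
#' cluster's cells against all other cells with a two-sided Wilcoxon
#' rank-sum test (normal approximation with tie correction, no continuity
#' correction), and reports:
#' \itemize{
#'   \item \code{pct1}, \code{pct2}: fraction of cells with nonzero
#'     expression inside / outside the cluster;
#'   \item \code{log2fc}: log2 of the ratio of de-logged group means with a
#'     pseudocount of 1 added at the group level,
#'     log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1));
#'   \item \code{p} and \code{p_adj}, Bonferroni-adjusted over all
#'     genes x clusters tests (BH optional).
#' }
#' Clusters with fewer than 3 cells still get records, with \code{p} and
#' \code{p_adj} missing.
#'
#' @param m lognorm-layer \code{\link{count_matrix}}
#' @param labels cluster label per cell (named vector or in cell order)
#' @param adjust \code{"bonferroni"} (default) or \code{"BH"}
#' @return data.frame of class \code{marker_table} with columns
#'   \code{cluster}, \code{gene_id}, \code{log2fc}, \code{pct1}, \code{pct2},
#'   \code{p}, \code{p_adj}
#' @export
rank_markers <- function(m, labels, adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(m, "count_matrix"))
  if (m$layer != "lognorm") stop("rank_markers expects the lognorm layer")
  labels <- align_labels(labels, rownames(m$values))
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("need at least 2 clusters")
  x <- as.matrix(m$values)
  n <- nrow(x)
  genes <- colnames(x)

  # per-gene ranks and tie corrections, shared across clusters
  ranks <- apply(x, 2, rank)
  tie_term <- apply(x, 2, function(col) {
    t <- table(col)
    sum(t^3 - t)
  })
  nz <- x > 0
  ex <- expm1(x)

  res <- vector("list", length(cl))
  for (ci in seq_along(cl)) {
    grp <- labels == cl[ci]
    n1 <- sum(grp); n2 <- n - n1
    pct1 <- colMeans(nz[grp, , drop = FALSE])
    pct2 <- colMeans(nz[!grp, , drop = FALSE])
    mean_in <- colMeans(ex[grp, , drop = FALSE])
    mean_out <- colMeans(ex[!grp, , drop = FALSE])
    log2fc <- log2((mean_in + 1) / (mean_out + 1))
    if (n1 >= 3 && n2 >= 3) {
      r1 <- colSums(ranks[grp, , drop = FALSE])
      u <- r1 - n1 * (n1 + 1) / 2
      mu <- n1 * n2 / 2
      sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
      p[sigma2 == 0] <- 1          # every value tied: no evidence
      p <- pmin(p, 1)
    } else {
      p <- rep(NA_real_, length(genes))
    }
    res[[ci]] <- data.frame(cluster = cl[ci], gene_id = genes,
                            log2fc = log2fc, pct1 = pct1, pct2 = pct2,
                            p = p, row.names = NULL,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = if (adjust == "BH") "BH" else "bonferroni")
  class(out) <- c("marker_table", class(out))
  out
}

#' Filter a marker table with the strict or relaxed predicate
#'
#' Strict (the default marker definition): pct1 > 0.10, pct2 < 0.10,
#' adjusted P < 0.001, log2FC > 1. Relaxed (for clusters with few enriched
#' genes): log2FC > 1, no pct1 requirement, pct2 < 0.2, adjusted P < 0.01.
#' All inequalities are strict, as printed.
#'
#' @param t \code{marker_table} from \code{\link{rank_markers}}
#' @param mode \code{"strict"} or \code{"relaxed"}
#' @return named list: cluster -> character vector of marker gene ids
#' @export
filter_markers <- function(t, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(t, "data.frame"))
  keep <- if (mode == "strict") {
    t$pct1 > 0.10 & t$pct2 < 0.10 & !is.na(t$p_adj) & t$p_adj < 0.001 & t$log2fc > 1
  } else {
    t$log2fc > 1 & t$pct2 < 0.2 & !is.na(t$p_adj) & t$p_adj < 0.01
  }
  keep[is.na(keep)] <- FALSE
  sel <- t[keep, , drop = FALSE]
  clusters <- sort(unique(t$cluster))
  out <- lapply(clusters, function(cl) sel$gene_id[sel$cluster == cl])
  names(out) <- clusters
  out
}

#' Genome-wide co-expression screen around a target gene
#'
#' Computes the Pearson correlation across all cells between a target gene
#' and every other detected gene (detected = nonzero in at least
#' \code{min_cells} cells), then selects genes whose correlation exceeds the
#' mean plus \code{sd_mult} standard deviations of the correlation
#' distribution. The target itself and constant genes are excluded from the
#' distribution, so the trivial r = 1 self-term cannot inflate the
#' threshold. Homeologs of the target remain in the screen: with shared
#' regulation they are expected top hits and serve as positive controls.
#'
#' @param m normalized \code{\link{count_matrix}}
#' @param target target gene id (must be non-constant)
#' @param sd_mult threshold multiplier (default 4)
#' @param min_cells detection floor in cells (default 3)
#' @return object of class \code{coexpression_result}: list with
#'   \code{target}, \code{r} (named, NA for constant genes), \code{mean_r},
#'   \code{sd_r}, \code{threshold}, \code{selected} (gene ids sorted by
#'   decreasing r), \code{n_cells}
#' @export
coexpression_screen <- function(m, target, sd_mult = 4, min_cells = 3) {
  stopifnot(inherits(m, "count_matrix"))
  if (!target %in% gene_ids(m)) stop("target gene not in matrix: ", target)
  x <- as.matrix(m$values)
  detected <- colSums(x > 0) >= min_cells
  detected[target] <- TRUE
  x <- x[, detected, drop = FALSE]
  tv <- x[, target]
  if (stats::sd(tv) == 0) stop("target gene is constant across cells")
  r <- suppressWarnings(stats::cor(x, tv))[, 1]
  r <- r[names(r) != target]
  ok <- !is.na(r)
  mean_r <- mean(r[ok])
  sd_r <- stats::sd(r[ok])
  threshold <- mean_r + sd_mult * sd_r
  sel <- r[ok & r > threshold]
  sel <- sel[order(-sel)]
  structure(list(target = target, r = r, mean_r = mean_r, sd_r = sd_r,
                 threshold = threshold, selected = names(sel),
                 selected_r = sel, n_cells = nrow(x)),
            class = "coexpression_result")
}

#' @export
print.coexpression_result <- function(x, ...) {
  cat(sprintf("<coexpression_result> target %s: %d/%d genes above mean+%.3g (threshold r > %.4f)\n",
              x$target, length(x$selected), sum(!is.na(x$r)),
              (x$threshold - x$mean_r) / x$sd_r, x$threshold))
  invisible(x)
}

#' Protoplasting-artifact scores per cluster
#'
#' Protoplast isolation (enzymatic cell-wall digestion) can induce stress
#' responses that masquerade as cluster markers. Two independent signals are
#' computed per cluster from its preferentially expressed genes: the
#' percentage overlapping a known stress-gene list, and the percentage
#' absent from bulk RNA-seq of intact tissue. Clusters driven by the
#' protoplasting artifact score high on both, and across clusters the two
#' percentages should correlate.
#'
#' @param marker_lists named list: cluster -> marker gene ids (e.g. from
#'   \code{\link{filter_markers}})
#' @param stress_list character vector of stress-response gene ids
#' @param bulk_detected character vector of genes detected in bulk RNA-seq
#'   of intact tissue
#' @return object of class \code{protoplasting_report}: data.frame
#'   \code{scores} (cluster, n_markers, pct_stress_overlap,
#'   pct_bulk_absent) plus \code{correlation}, the Pearson r between the two
#'   percentage vectors over clusters with markers
#' @export
protoplasting_scores <- function(marker_lists, stress_list, bulk_detected) {
  clusters <- names(marker_lists)
  nmk <- lengths(marker_lists)
  pct_stress <- vapply(marker_lists, function(g) {
    if (length(g) == 0) return(NA_real_)
    100 * length(intersect(g, stress_list)) / length(g)
  }, 0)
  pct_absent <- vapply(marker_lists, function(g) {
    if (length(g) == 0) return(NA_real_)
    100 * length(setdiff(g, bulk_detected)) / length(g)
  }, 0)
  ok <- !is.na(pct_stress) & !is.na(pct_absent)
  corr <- if (sum(ok) >= 3 &&
              stats::sd(pct_stress[ok]) > 0 && stats::sd(pct_absent[ok]) > 0)
    stats::cor(pct_stress[ok], pct_absent[ok]) else NA_real_
  structure(list(
    scores = data.frame(cluster = clusters, n_markers = as.integer(nmk),
                        pct_stress_overlap = pct_stress,
                        pct_bulk_absent = pct_absent,
                        row.names = NULL, stringsAsFactors = FALSE),
    correlation = corr), class = "protoplasting_report")
}

#' @export
print.protoplasting_report <- function(x, ...) {
  cat(sprintf("<protoplasting_report> %d clusters, stress/bulk-absent correlation r = %.3f\n",
              nrow(x$scores), x$correlation))
  invisible(x)
}
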
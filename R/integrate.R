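#' Exact cosine k-nearest-neighbour search between two modalities
#'
#' For every query cell, finds the k reference cells maximizing cosine
#' similarity s(q, r) = (q.r)/(|q||r|) over a shared gene panel, computed on
#' the declared normalization layer (CPM by default for cross-modal
#' matching). The search is exact: all pairwise similarities are computed in
#' chunks, never approximated. For nonnegative expression vectors s lies in
#' [0, 1] (1 = identical direction, 0 = orthogonal). Ties are broken by
#' lexicographic reference cell id so results are fully deterministic.
#'
#' Cells that are all-zero over the shared panel have undefined cosine
#' similarity; they are excluded from the result and listed in the
#' \code{excluded_queries} / \code{excluded_refs} fields rather than silently
#' dropped.
#'
#' @param query,reference \code{\link{count_matrix}} objects on the same
#'   layer; typically smFISH query vs scRNA reference (imputation) or the
#'   reverse (label projection)
#' @param shared_genes gene ids present in both matrices; defaults to the
#'   full intersection
#' @param k number of neighbours (default 5)
#' @param chunk query rows per block of the similarity computation
#' @return object of class \code{neighbor_map}: list with \code{ref_id}
#'   (query x k character matrix), \code{sim} (query x k numeric, rows
#'   non-increasing), \code{excluded_queries}, \code{excluded_refs},
#'   \code{params}
#' @export
cosine_knn <- function(query, reference, shared_genes = NULL, k = 5, chunk = 512) {
  stopifnot(inherits(query, "count_matrix"), inherits(reference, "count_matrix"),
            k >= 1)
  if (is.null(shared_genes))
    shared_genes <- intersect(gene_ids(query), gene_ids(reference))
  if (length(shared_genes) == 0) stop("no shared genes")
  if (!all(shared_genes %in% gene_ids(query)) ||
      !all(shared_genes %in% gene_ids(reference)))
    stop("shared_genes must be present in both matrices")

  q <- as.matrix(query$values[, shared_genes, drop = FALSE])
  r <- as.matrix(reference$values[, shared_genes, drop = FALSE])
  qn <- sqrt(rowSums(q^2)); rn <- sqrt(rowSums(r^2))
  excl_q <- rownames(q)[qn == 0]
  excl_r <- rownames(r)[rn == 0]
  q <- q[qn > 0, , drop = FALSE] / qn[qn > 0]
  r <- r[rn > 0, , drop = FALSE] / rn[rn > 0]
  k_eff <- min(k, nrow(r))

  # reference order for deterministic tie-breaks
  ref_ord <- order(rownames(r))
  r <- r[ref_ord, , drop = FALSE]
  rids <- rownames(r)

  nq <- nrow(q)
  ref_id <- matrix(NA_character_, nq, k_eff, dimnames = list(rownames(q), NULL))
  sim <- matrix(NA_real_, nq, k_eff, dimnames = list(rownames(q), NULL))
  rt <- t(r)
  for (start in seq(1, nq, by = chunk)) {
    idx <- start:min(start + chunk - 1, nq)
    s <- q[idx, , drop = FALSE] %*% rt          # block of cosine similarities
    for (ii in seq_along(idx)) {
      o <- order(-s[ii, ], rids)[seq_len(k_eff)] # ties -> lexicographic ref id
      ref_id[idx[ii], ] <- rids[o]
      sim[idx[ii], ] <- s[ii, o]
    }
  }
  sim[sim > 1] <- 1  # guard against rounding just above 1
  structure(list(ref_id = ref_id, sim = sim,
                 excluded_queries = excl_q, excluded_refs = excl_r,
                 params = list(k = k, shared_genes = shared_genes,
                               layer = query$layer)),
            class = "neighbor_map")
}

#' @export
print.neighbor_map <- function(x, ...) {
  cat(sprintf("<neighbor_map> %d query cells, k=%d over %d shared genes (%d/%d cells excluded)\n",
              nrow(x$ref_id), ncol(x$ref_id), length(x$params$shared_genes),
              length(x$excluded_queries), length(x$excluded_refs)))
  invisible(x)
}

#' Impute whole-transcriptome expression into query cells
#'
#' Each query cell receives, for every gene of the reference matrix, the
#' similarity-weighted average of its k nearest reference cells:
#' value(q, g) = sum_i s_i ref(r_i, g) / sum_i s_i (normalized mode). Every
#' imputed value is therefore a convex combination of neighbour values. The
#' reference matrix normally carries far more genes than the shared panel
#' used to find the neighbours - that is the point of the imputation.
#'
#' @param nm \code{neighbor_map} from \code{\link{cosine_knn}}
#' @param reference_full \code{\link{count_matrix}} containing every
#'   reference cell of \code{nm} (any gene set)
#' @param weight_mode \code{"normalized"} (weights sum to one; default) or
#'   \code{"unnormalized"} (plain similarity-weighted sum, for sensitivity
#'   checks)
#' @return a \code{count_matrix} with modality \code{"imputed"}; query cells
#'   whose similarity weights sum to zero get all-NA rows and are listed in
#'   \code{attr(, "missing_cells")}
#' @export
impute_expression <- function(nm, reference_full,
                              weight_mode = c("normalized", "unnormalized")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(nm, "neighbor_map"), inherits(reference_full, "count_matrix"))
  refs <- unique(as.vector(nm$ref_id))
  refs <- refs[!is.na(refs)]
  miss <- setdiff(refs, cell_ids(reference_full))
  if (length(miss)) stop("reference cell(s) absent from reference_full: ",
                         paste(utils::head(miss), collapse = ", "))
  qids <- rownames(nm$ref_id)
  nq <- length(qids)
  rid_index <- stats::setNames(seq_along(cell_ids(reference_full)),
                               cell_ids(reference_full))
  k <- ncol(nm$ref_id)
  wsum <- rowSums(nm$sim, na.rm = TRUE)
  missing_cells <- qids[wsum == 0]

  # sparse weights (query x reference cells), then one matrix product
  ii <- rep(seq_len(nq), k)
  jj <- rid_index[as.vector(nm$ref_id)]
  ww <- as.vector(nm$sim)
  keep <- !is.na(jj) & !is.na(ww)
  if (weight_mode == "normalized") ww <- ww / wsum[ii]
  W <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = ww[keep],
                            dims = c(nq, length(rid_index)))
  v <- as.matrix(W %*% reference_full$values)
  dimnames(v) <- list(qids, gene_ids(reference_full))
  v[missing_cells, ] <- NA_real_
  out <- structure(list(values = v, modality = "imputed",
                        stage = reference_full$stage,
                        layer = reference_full$layer),
                   class = "count_matrix")
  attr(out, "missing_cells") <- missing_cells
  attr(out, "params") <- c(nm$params, list(weight_mode = weight_mode))
  out
}

#' Project spatial cluster labels onto single cells by neighbour vote
#'
#' Reverse direction of the integration: each scRNA-seq cell queries its k
#' nearest smFISH cells and adopts the most frequent smFISH cluster label
#' among qualifying neighbours. Neighbours with cosine similarity at or
#' below \code{min_similarity} are discarded first (they are too different
#' to vote). A cell gets no projection when no neighbour qualifies, when
#' every remaining label occurs once (no common cluster among the
#' neighbours), or when a frequency tie persists after comparing summed
#' similarities.
#'
#' @param nm \code{neighbor_map} with scRNA cells as queries and smFISH cells
#'   as references, built per stage
#' @param smfish_clusters smFISH cluster label per reference cell: named
#'   vector (names = cell ids)
#' @param min_similarity strict lower bound for a neighbour to vote
#'   (default 0.3)
#' @return data.frame of class \code{projection_table} with columns
#'   \code{cell_id}, \code{label} (NA = no projection), \code{votes},
#'   \code{sum_sim}
#' @export
project_cluster_labels <- function(nm, smfish_clusters, min_similarity = 0.3) {
  stopifnot(inherits(nm, "neighbor_map"),
            min_similarity >= 0, min_similarity <= 1)
  if (is.null(names(smfish_clusters)))
    stop("smfish_clusters must be named by cell id")
  refs <- unique(as.vector(nm$ref_id))
  refs <- refs[!is.na(refs)]
  unknown <- setdiff(refs, names(smfish_clusters))
  if (length(unknown)) stop("no cluster label for reference cell(s): ",
                            paste(utils::head(unknown), collapse = ", "))
  qids <- rownames(nm$ref_id)
  lab <- rep(NA_character_, length(qids))
  votes <- integer(length(qids))
  ssim <- rep(NA_real_, length(qids))
  for (i in seq_along(qids)) {
    s <- nm$sim[i, ]
    keep <- !is.na(s) & s > min_similarity
    if (!any(keep)) next
    labs <- as.character(smfish_clusters[nm$ref_id[i, keep]])
    tab <- table(labs)
    top <- max(tab)
    if (top < 2) next                       # all labels unique: no projection
    cand <- names(tab)[tab == top]
    if (length(cand) > 1) {                 # frequency tie: summed similarity
      sums <- vapply(cand, function(l) sum(s[keep][labs == l]), 0)
      best <- sums == max(sums)
      if (sum(best) > 1) next               # exact tie: no projection
      cand <- cand[best]
    }
    lab[i] <- cand
    votes[i] <- top
    ssim[i] <- sum(s[keep][labs == cand])
  }
  out <- data.frame(cell_id = qids, label = lab, votes = votes,
                    sum_sim = ssim, stringsAsFactors = FALSE)
  class(out) <- c("projection_table", class(out))
  out
}

#' Contribution matrix between smFISH and scRNA-seq clusterings
#'
#' Cross-tabulates projected smFISH cluster labels against the scRNA-seq
#' cells' own cluster labels: count(i, j) = number of scRNA cells of cluster
#' j projected onto smFISH cluster i. Counts are normalized by the total
#' number of cells of each smFISH cluster, giving the fraction of that
#' cluster "contributed" by each scRNA cluster and correcting for cluster
#' size differences. Unprojected cells are excluded.
#'
#' @param pt \code{projection_table} from \code{\link{project_cluster_labels}}
#' @param sc_clusters scRNA cluster label per cell (named vector)
#' @param smfish_cluster_sizes named vector: smFISH cluster -> total cell
#'   count used for that cluster
#' @return object of class \code{contribution_matrix}: list with
#'   \code{counts}, \code{fractions} (smFISH clusters x scRNA clusters) and
#'   \code{sizes}
#' @export
contribution_matrix <- function(pt, sc_clusters, smfish_cluster_sizes) {
  stopifnot(inherits(pt, "data.frame"))
  if (is.null(names(sc_clusters))) stop("sc_clusters must be named by cell id")
  proj <- pt[!is.na(pt$label), , drop = FALSE]
  missing_sz <- setdiff(unique(proj$label), names(smfish_cluster_sizes))
  if (length(missing_sz))
    stop("no size for projected smFISH cluster(s): ",
         paste(missing_sz, collapse = ", "))
  if (any(smfish_cluster_sizes <= 0)) stop("cluster sizes must be positive")
  unknown <- setdiff(proj$cell_id, names(sc_clusters))
  if (length(unknown)) stop("no scRNA cluster for cell(s): ",
                            paste(utils::head(unknown), collapse = ", "))
  ilev <- sort(names(smfish_cluster_sizes))
  jlev <- sort(unique(as.character(sc_clusters)))
  counts <- table(factor(proj$label, levels = ilev),
                  factor(as.character(sc_clusters[proj$cell_id]), levels = jlev))
  counts <- matrix(as.integer(counts), length(ilev), length(jlev),
                   dimnames = list(ilev, jlev))
  fractions <- counts / as.numeric(smfish_cluster_sizes[ilev])
  structure(list(counts = counts, fractions = fractions,
                 sizes = smfish_cluster_sizes[ilev]),
            class = "contribution_matrix")
}

#' @export
print.contribution_matrix <- function(x, ...) {
  cat(sprintf("<contribution_matrix> %d smFISH x %d scRNA clusters\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Merge per-stage imputed matrices
#'
#' Imputation runs per developmental stage; this joins two stages into one
#' matrix over the union of cells and the union of genes. A gene imputed in
#' only one stage is missing (NA), not zero, for the other stage's cells.
#' Cell sets must be disjoint.
#'
#' @param a,b \code{count_matrix} objects (typically modality
#'   \code{"imputed"}) with disjoint cell ids
#' @return merged \code{count_matrix} with stage \code{"mixed"}
#' @export
merge_stage_results <- function(a, b) {
  stopifnot(inherits(a, "count_matrix"), inherits(b, "count_matrix"))
  overlap <- intersect(cell_ids(a), cell_ids(b))
  if (length(overlap)) stop("overlapping cell ids: ",
                            paste(utils::head(overlap), collapse = ", "))
  genes <- union(gene_ids(a), gene_ids(b))
  cells <- c(cell_ids(a), cell_ids(b))
  v <- matrix(NA_real_, length(cells), length(genes),
              dimnames = list(cells, genes))
  v[cell_ids(a), gene_ids(a)] <- as.matrix(a$values)
  v[cell_ids(b), gene_ids(b)] <- as.matrix(b$values)
  structure(list(values = v, modality = a$modality, stage = "mixed",
                 layer = a$layer),
            class = "count_matrix")
}
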
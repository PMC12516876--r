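# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive per-element loops so they share no code path with the package.

mk_profile <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("k%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("g%d", seq_len(ncol(m)))
  structure(list(means = m, sizes = setNames(rep(10L, nrow(m)), rownames(m))),
            class = "cluster_profile")
}

make_cm <- function(v, modality = "scRNA", stage = "mixed", layer = "raw") {
  if (is.null(rownames(v))) rownames(v) <- sprintf("cell%d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("g%d", seq_len(ncol(v)))
  count_matrix(v, modality = modality, stage = stage, layer = layer)
}

# brute-force cosine kNN: per-query loop, full sort
brute_knn <- function(q, r, k) {
  rids <- rownames(r)
  lapply(seq_len(nrow(q)), function(i) {
    s <- vapply(seq_len(nrow(r)), function(j) {
      sum(q[i, ] * r[j, ]) / (sqrt(sum(q[i, ]^2)) * sqrt(sum(r[j, ]^2)))
    }, 0)
    o <- order(-s, rids)[seq_len(k)]
    list(ids = rids[o], sim = s[o])
  })
}

# textbook Pearson r
manual_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# small paired dataset reused across integration tests
small_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_paired_dataset(synth_config(
        n_clusters = 4, n_spatial_cells = 240, n_sc_cells = 400,
        n_panel_genes = 30, n_sc_genes = 120, seed = 42))
    cache
  }
})

# square polygon fixture (0,0)-(10,0)-(10,10)-(0,10)
unit_square10 <- function() polygon_region(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                                           name = "sq")
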
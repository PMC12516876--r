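test_that("the same config and seed reproduce the dataset bit for bit", {
  cfg <- synth_config(n_clusters = 3, n_spatial_cells = 60, n_sc_cells = 80,
                      n_panel_genes = 12, n_sc_genes = 40, seed = 7)
  a <- generate_paired_dataset(cfg)
  b <- generate_paired_dataset(cfg)
  expect_identical(as.matrix(a$spatial$counts$values), as.matrix(b$spatial$counts$values))
  expect_identical(as.matrix(a$sc$counts$values), as.matrix(b$sc$counts$values))
  expect_identical(a$spatial$cells$x, b$spatial$cells$x)
  expect_identical(a$truth$cluster_mean_matrix, b$truth$cluster_mean_matrix)
})

test_that("config validation rejects bad dimensions and bad plants", {
  expect_error(synth_config(n_clusters = 0), "positive")
  expect_error(synth_config(n_panel_genes = 50, n_sc_genes = 40), "exceed")
  expect_error(synth_config(coexpr_pairs = list(list(gene_a = "a", gene_b = "b", rho = 1.2))),
               "\\[0, 1\\]")
  cfg <- synth_config(n_clusters = 2, n_spatial_cells = 10, n_sc_cells = 10,
                      n_panel_genes = 5, n_sc_genes = 10,
                      stress_genes = list(list(gene = "NOPE", clusters = 1, multiplier = 5)))
  expect_error(generate_paired_dataset(cfg), "gene universe")
})

test_that("in the Poisson limit cluster means converge to the ground-truth profile", {
  # nb_dispersion = 0 and no library variation: counts are Poisson(mu),
  # so the within-cluster sample mean is within 3*sqrt(mu/n) of mu
  cfg <- synth_config(n_clusters = 2, n_spatial_cells = 10, n_sc_cells = 2000,
                      n_panel_genes = 10, n_sc_genes = 30, nb_dispersion = 0,
                      lib_log_sd = 0, seed = 11)
  ds <- generate_paired_dataset(cfg)
  v <- as.matrix(ds$sc$counts$values)
  cl <- ds$truth$sc_cell_cluster
  M <- ds$truth$cluster_mean_matrix
  for (k in rownames(M)) {
    idx <- names(cl)[cl == k]
    emp <- colMeans(v[idx, , drop = FALSE])
    tol <- 3 * sqrt(M[k, ] / length(idx)) + 1e-9
    expect_true(all(abs(emp - M[k, ]) <= tol))
  }
})

test_that("cluster means converge under the default noise model", {
  # with NB dispersion and unit-mean library factors the expected count is
  # still the ground-truth mean; check within 3 empirical standard errors
  cfg <- synth_config(n_clusters = 2, n_spatial_cells = 10, n_sc_cells = 3000,
                      n_panel_genes = 10, n_sc_genes = 20, seed = 5)
  ds <- generate_paired_dataset(cfg)
  v <- as.matrix(ds$sc$counts$values)
  cl <- ds$truth$sc_cell_cluster
  M <- ds$truth$cluster_mean_matrix
  for (k in rownames(M)) {
    idx <- names(cl)[cl == k]
    emp <- colMeans(v[idx, , drop = FALSE])
    se <- apply(v[idx, , drop = FALSE], 2, sd) / sqrt(length(idx))
    expect_true(all(abs(emp - M[k, ]) <= 3 * se + 1e-9))
  }
})

test_that("a planted pair with latent correlation 0.7 is visibly co-expressed", {
  cfg <- synth_config(n_clusters = 1, n_spatial_cells = 10, n_sc_cells = 3000,
                      n_panel_genes = 95, n_sc_genes = 120, seed = 1,
                      coexpr_pairs = list(list(gene_a = "PG001", gene_b = "PG002",
                                               rho = 0.7, base_mean = 3)))
  ds <- generate_paired_dataset(cfg)
  v <- as.matrix(ds$sc$counts$values)
  expect_gt(cor(log1p(v[, "PG001"]), log1p(v[, "PG002"])), 0.3)
})

test_that("stress genes with zero base mean are silent outside designated clusters", {
  cfg <- synth_config(n_clusters = 3, n_spatial_cells = 10, n_sc_cells = 300,
                      n_panel_genes = 5, n_sc_genes = 20, seed = 3,
                      stress_genes = list(list(gene = "EG0001", clusters = 2,
                                               multiplier = 50, base_mean = 0)))
  ds <- generate_paired_dataset(cfg)
  v <- as.matrix(ds$sc$counts$values)
  cl <- ds$truth$sc_cell_cluster
  expect_true(all(v[cl != "c2", "EG0001"] == 0))
})

test_that("stress induction raises expression only in designated sc clusters", {
  cfg <- synth_config(n_clusters = 3, n_spatial_cells = 300, n_sc_cells = 600,
                      n_panel_genes = 5, n_sc_genes = 20, seed = 3,
                      stress_genes = list(list(gene = "PG001", clusters = 2,
                                               multiplier = 30, base_mean = 0.5)))
  ds <- generate_paired_dataset(cfg)
  v <- as.matrix(ds$sc$counts$values)
  cl <- ds$truth$sc_cell_cluster
  expect_gt(mean(v[cl == "c2", "PG001"]), 5 * mean(v[cl != "c2", "PG001"]))
  # the spatial modality is untouched by stress induction
  vs <- as.matrix(ds$spatial$counts$values)
  cls <- ds$truth$spatial_cell_cluster
  expect_lt(mean(vs[cls == "c2", "PG001"]), 5)
})

test_that("spatial layout keeps same-cluster cells contiguous in cluster strips", {
  ds <- small_synth()
  cells <- ds$spatial$cells
  K <- length(unique(cells$cluster))
  strip <- 1000 / K
  ci <- as.integer(sub("c", "", cells$cluster))
  expect_true(all(cells$x >= (ci - 1) * strip & cells$x <= ci * strip))
})

test_that("spot tables conserve counts per cell and per gene", {
  ds <- small_synth()
  st <- generate_spot_table(ds$spatial$counts, ds$spatial$cells,
                            cell_radius = 4, seed = 2)
  v <- as.matrix(ds$spatial$counts$values)
  expect_equal(nrow(st), sum(v))
  per_gene <- table(st$gene_id)
  cs <- colSums(v)
  expect_equal(as.integer(per_gene[names(cs)[cs > 0]]),
               unname(as.integer(cs[cs > 0])))
  # spots stay within the cell radius of their cell centre (cell of count 7)
  cell <- ds$spatial$cells[1, ]
  g <- names(which(v[cell$cell_id, ] > 0))[1]
  d2 <- (st$x - cell$x)^2 + (st$y - cell$y)^2
  near <- st$gene_id == g & d2 <= 4^2 + 1e-9
  expect_gte(sum(near), v[cell$cell_id, g])
})

test_that("an all-zero count matrix yields an empty spot table", {
  v <- matrix(0L, 3, 2, dimnames = list(paste0("c", 1:3), paste0("g", 1:2)))
  cm <- count_matrix(v, modality = "smFISH")
  cells <- cell_table(data.frame(cell_id = paste0("c", 1:3),
                                 x = c(0, 100, 200), y = 0))
  st <- generate_spot_table(cm, cells, 5, seed = 1)
  expect_equal(nrow(st), 0)
  expect_error(generate_spot_table(cm, cells, -1), "nonnegative")
})

test_that("a polygon covering one of two disjoint cells captures exactly its spots", {
  v <- matrix(c(3L, 5L), 2, 1, dimnames = list(c("a", "b"), "G"))
  cm <- count_matrix(v, modality = "smFISH")
  cells <- cell_table(data.frame(cell_id = c("a", "b"), x = c(10, 200), y = c(10, 10)))
  st <- generate_spot_table(cm, cells, cell_radius = 5, seed = 4)
  box <- polygon_region(rbind(c(0, 0), c(50, 0), c(50, 50), c(0, 50)))
  inside <- point_in_polygon(st$x, st$y, box$vertices)
  expect_equal(sum(inside & st$gene_id == "G"), 3)
})

test_that("region expression honours exact multipliers at zero noise and is seeded", {
  ds <- small_synth()
  rt <- generate_region_expression(ds$truth, noise_sd = 0,
                                   region_effects = list(PG001 = c(2, 1, 1)),
                                   genes = c("PG001", "PG002"), seed = 1)
  base <- mean(ds$truth$cluster_mean_matrix[, "PG001"])
  v_base <- rt$value[rt$gene_id == "PG001" & rt$region == "base"]
  v_mid <- rt$value[rt$gene_id == "PG001" & rt$region == "middle"]
  expect_equal(unique(v_base), 2 * unique(v_mid))
  expect_equal(unique(v_base), 2 * base)
  # all multipliers 1, zero noise: identical everywhere
  v2 <- rt$value[rt$gene_id == "PG002"]
  expect_equal(length(unique(v2)), 1L)
  # seeded determinism with noise
  r1 <- generate_region_expression(ds$truth, noise_sd = 0.1, seed = 9,
                                   genes = "PG001")
  r2 <- generate_region_expression(ds$truth, noise_sd = 0.1, seed = 9,
                                   genes = "PG001")
  expect_identical(r1$value, r2$value)
  expect_error(generate_region_expression(ds$truth, n_reps = 1), "at least 2")
  expect_error(generate_region_expression(ds$truth, noise_sd = 0,
                                          region_effects = list(PG001 = c(-1, 1, 1)),
                                          genes = "PG001"),
               "positive")
})
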
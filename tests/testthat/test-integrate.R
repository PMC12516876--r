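test_that("cosine similarity matches hand values and ranks deterministically", {
  q <- rbind(c(1, 1))
  r <- rbind(ref_a = c(1, 0), ref_b = c(1, 1))
  colnames(q) <- colnames(r) <- c("g1", "g2")
  rownames(q) <- "q1"
  nm <- cosine_knn(make_cm(q, layer = "cpm"), make_cm(r, layer = "cpm"), k = 2)
  expect_identical(nm$ref_id["q1", ], c("ref_b", "ref_a"))
  expect_equal(nm$sim["q1", ], c(1, 1 / sqrt(2)))
  # orthogonal vectors score 0; identical vectors score 1 and rank first
  q2 <- rbind(q1 = c(1, 0), q2 = c(0, 1))
  colnames(q2) <- c("g1", "g2")
  nm2 <- cosine_knn(make_cm(q2, layer = "cpm"), make_cm(r, layer = "cpm"), k = 2)
  expect_equal(unname(nm2$sim["q2", 2]), 0)
  expect_identical(unname(nm2$ref_id["q1", 1]), "ref_a")
  expect_equal(unname(nm2$sim["q1", 1]), 1)
})

test_that("exact ties are broken by lexicographic reference id", {
  q <- rbind(q1 = c(1, 0))
  r <- rbind(zeb = c(2, 0), alp = c(3, 0), mid = c(1, 1))
  colnames(q) <- colnames(r) <- c("g1", "g2")
  nm <- cosine_knn(make_cm(q, layer = "cpm"), make_cm(r, layer = "cpm"), k = 3)
  expect_identical(nm$ref_id["q1", 1:2], c("alp", "zeb"))  # both sim 1
})

test_that("cosine kNN agrees with a brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:3) {
    q <- matrix(rexp(60 * 25), 60, 25)
    r <- matrix(rexp(150 * 25), 150, 25)
    dimnames(q) <- list(sprintf("q%03d", 1:60), sprintf("g%d", 1:25))
    dimnames(r) <- list(sprintf("r%03d", 1:150), sprintf("g%d", 1:25))
    nm <- cosine_knn(make_cm(q, layer = "cpm"), make_cm(r, layer = "cpm"), k = 7)
    oracle <- brute_knn(q, r, 7)
    for (i in seq_len(nrow(q))) {
      expect_identical(unname(nm$ref_id[i, ]), oracle[[i]]$ids)
      expect_true(all(abs(nm$sim[i, ] - oracle[[i]]$sim) <= 1e-12))
    }
  }
})

test_that("all-zero cells over the shared panel are excluded with a report", {
  q <- rbind(ok = c(1, 2), zero = c(0, 0))
  r <- rbind(r1 = c(1, 1), r2 = c(2, 1))
  colnames(q) <- colnames(r) <- c("g1", "g2")
  nm <- cosine_knn(make_cm(q, layer = "cpm"), make_cm(r, layer = "cpm"), k = 1)
  expect_identical(nm$excluded_queries, "zero")
  expect_identical(rownames(nm$ref_id), "ok")
})

test_that("imputation is the similarity-weighted average with convexity", {
  # two neighbours with values {2, 4} at equal similarity -> 3;
  # values {0, 4} with similarities {3, 1} -> 1
  nm <- structure(list(
    ref_id = matrix(c("r1", "r2"), 1, 2, dimnames = list("q1", NULL)),
    sim = matrix(c(0.5, 0.5), 1, 2, dimnames = list("q1", NULL)),
    excluded_queries = character(), excluded_refs = character(),
    params = list(k = 2, shared_genes = "g1", layer = "cpm")),
    class = "neighbor_map")
  ref <- make_cm(matrix(c(2, 4, 0, 4), 2, 2,
                        dimnames = list(c("r1", "r2"), c("gA", "gB"))),
                 layer = "cpm")
  imp <- impute_expression(nm, ref)
  expect_equal(as.vector(imp$values["q1", "gA"]), 3)
  nm$sim[] <- c(3, 1) / 4  # weights proportional to 3:1
  imp2 <- impute_expression(nm, ref)
  expect_equal(as.vector(imp2$values["q1", "gB"]), (3 * 0 + 1 * 4) / 4)
  expect_identical(imp$modality, "imputed")
})

test_that("a single neighbour copies its full profile; k = 1 self-match is exact", {
  ds <- small_synth()
  sc_cpm <- cpm(ds$sc$counts)
  # query a reference cell against the reference itself
  sub <- make_cm(as.matrix(sc_cpm$values[5:8, , drop = FALSE]), layer = "cpm")
  rownames(sub$values) <- paste0("copy_", rownames(sub$values))
  nm <- cosine_knn(sub, sc_cpm, k = 1)
  imp <- impute_expression(nm, sc_cpm)
  for (i in 1:4) {
    self <- sub("copy_", "", rownames(sub$values)[i])
    expect_identical(unname(nm$ref_id[i, 1]), self)
    expect_equal(unname(as.vector(imp$values[i, ])),
                 unname(as.vector(sc_cpm$values[self, ])))
  }
})

test_that("every imputed value lies within its neighbours' min/max", {
  ds <- small_synth()
  sp_cpm <- cpm(ds$spatial$counts)
  sc_cpm <- cpm(ds$sc$counts)
  nm <- cosine_knn(sp_cpm, sc_cpm, k = 5)
  imp <- impute_expression(nm, sc_cpm)
  ref <- as.matrix(sc_cpm$values)
  set.seed(8)
  for (i in sample(nrow(imp$values), 25)) {
    nb <- ref[nm$ref_id[i, ], , drop = FALSE]
    lo <- apply(nb, 2, min); hi <- apply(nb, 2, max)
    v <- as.vector(imp$values[i, ])
    expect_true(all(v >= lo - 1e-9 & v <= hi + 1e-9))
  }
})

test_that("label projection follows majority, uniqueness and tie rules", {
  mk_nm <- function(ids, sims) structure(list(
    ref_id = matrix(ids, 1, 5, dimnames = list("sc1", NULL)),
    sim = matrix(sims, 1, 5, dimnames = list("sc1", NULL)),
    excluded_queries = character(), excluded_refs = character(),
    params = list(k = 5)), class = "neighbor_map")
  labs <- c(f1 = "c8", f2 = "c8", f3 = "c3", f4 = "c14", f5 = "c16",
            f6 = "c3", f7 = "c1", f8 = "c2", f9 = "c4", f10 = "c5")
  # majority: [c8, c8, c3, c14, c16] -> c8
  p1 <- project_cluster_labels(mk_nm(c("f1", "f2", "f3", "f4", "f5"),
                                     rep(0.9, 5)), labs)
  expect_identical(p1$label, "c8")
  expect_identical(p1$votes, 2L)
  # all five labels unique -> no projection
  p2 <- project_cluster_labels(mk_nm(c("f7", "f8", "f3", "f9", "f10"),
                                     rep(0.9, 5)), labs)
  expect_true(is.na(p2$label))
  # 2-2-1 frequency tie -> larger summed similarity wins
  p3 <- project_cluster_labels(mk_nm(c("f1", "f2", "f3", "f6", "f5"),
                                     c(0.7, 0.7, 0.6, 0.5, 0.4)), labs)
  expect_identical(p3$label, "c8")
  expect_equal(p3$sum_sim, 1.4)
  # exact tie in summed similarity -> none
  p4 <- project_cluster_labels(mk_nm(c("f1", "f2", "f3", "f6", "f5"),
                                     c(0.6, 0.5, 0.6, 0.5, 0.4)), labs)
  expect_true(is.na(p4$label))
  # similarity filter: neighbours at or below 0.3 cannot vote
  p5 <- project_cluster_labels(mk_nm(c("f1", "f2", "f3", "f4", "f5"),
                                     c(0.3, 0.3, 0.9, 0.9, 0.9)), labs)
  expect_true(is.na(p5$label))   # remaining c3, c14, c16 all unique
  p6 <- project_cluster_labels(mk_nm(c("f1", "f2", "f3", "f4", "f5"),
                                     c(0.31, 0.31, 0.1, 0.1, 0.1)), labs)
  expect_identical(p6$label, "c8")
  expect_error(project_cluster_labels(mk_nm(c("nope", "f2", "f3", "f4", "f5"),
                                            rep(0.9, 5)), labs),
               "no cluster label")
})

test_that("contribution matrices normalize counts by smFISH cluster size", {
  pt <- data.frame(cell_id = sprintf("s%d", 1:120),
                   label = c(rep("c8", 114), rep("c3", 6)),
                   votes = 3L, sum_sim = 1)
  sc_cl <- setNames(rep("sc5", 120), pt$cell_id)
  cmx <- contribution_matrix(pt, sc_cl, c(c8 = 2151, c3 = 500))
  expect_equal(cmx$counts["c8", "sc5"], 114L)
  expect_equal(cmx$fractions["c8", "sc5"], 114 / 2151, tolerance = 1e-12)
  # counts reconstruct exactly from fractions
  expect_equal(cmx$fractions * as.numeric(cmx$sizes), cmx$counts + 0)
  # unprojected cells are excluded; empty rows are zero
  pt$label[1:114] <- NA
  cmx2 <- contribution_matrix(pt, sc_cl, c(c8 = 2151, c3 = 500))
  expect_true(all(cmx2$counts["c8", ] == 0))
  expect_error(contribution_matrix(pt, sc_cl, c(c8 = 2151)), "no size")
})

test_that("stage merging obeys inclusion-exclusion and keeps NA semantics", {
  a <- make_cm(matrix(1, 2, 3, dimnames = list(c("w2a", "w2b"), c("a", "b", "c"))),
               layer = "cpm")
  b <- make_cm(matrix(2, 2, 3, dimnames = list(c("w3a", "w3b"), c("b", "c", "d"))),
               layer = "cpm")
  m <- merge_stage_results(a, b)
  expect_equal(ncol(m$values), 4)   # |A| + |B| - |A n B| = 3 + 3 - 2
  expect_equal(nrow(m$values), 4)
  # gene only in A is missing, not zero, for B-stage cells
  expect_true(is.na(m$values["w3a", "a"]))
  expect_equal(m$values["w2a", "a"], 1)
  same <- merge_stage_results(
    a, make_cm(matrix(2, 1, 3, dimnames = list("w3x", c("a", "b", "c"))),
               layer = "cpm"))
  expect_identical(sort(colnames(same$values)), c("a", "b", "c"))
  expect_error(merge_stage_results(a, a), "overlapping")
})
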
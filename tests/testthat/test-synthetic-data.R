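test_that("synthetic connectomes satisfy the structural contract", {
  C <- make_connectome(74, density = 0.3, seed = 1)
  expect_equal(dim(C$C), c(74, 74))
  expect_true(isSymmetric(C$C))
  expect_true(all(diag(C$C) == 0))
  expect_true(all(C$C >= 0))
  nz <- C$C[upper.tri(C$C)] > 0
  expect_equal(mean(nz), 0.3, tolerance = 0.1)
  expect_equal(mean(C$C[upper.tri(C$C)][nz]), 1)

  # two regions at full density: rescaling forces both entries to 1
  C2 <- make_connectome(2, density = 1, seed = 7)
  expect_equal(unname(C2$C[1, 2]), 1)
  expect_equal(unname(C2$C[2, 1]), 1)

  expect_identical(make_connectome(10, 0.5, seed = 3)$C,
                   make_connectome(10, 0.5, seed = 3)$C)
  expect_error(make_connectome(1, 0.5, 1), "n_regions")
})

test_that("connectome normalization fixes the spectral radius", {
  C <- normalize_connectome(make_connectome(20, 0.3, seed = 2),
                            spectral_radius = 2.4)
  rho <- max(abs(eigen(C$C, symmetric = TRUE, only.values = TRUE)$values))
  expect_equal(rho, 2.4, tolerance = 1e-10)
  expect_true(isSymmetric(C$C))
})

test_that("uncoupled group BOLD has near-zero mean FC and is reproducible", {
  C <- tiny_connectome(6)
  grp <- make_group_bold(C, g_values = c(0, 0), duration_s = 240, tr_s = 1,
                         seed = 5)
  expect_length(grp$bold, 2)
  expect_equal(grp$ground_truth$planted_G, c(0, 0))
  for (b in grp$bold) {
    # null r has SE ~ 1/sqrt(T); the mean over 15 pairs is tighter
    expect_lt(abs(fc_summary(fc_matrix(b$Y))), 3 / sqrt(ncol(b$Y)))
  }
  grp2 <- make_group_bold(C, g_values = c(0, 0), duration_s = 240, tr_s = 1,
                          seed = 5)
  expect_identical(grp$bold[[1]]$Y, grp2$bold[[1]]$Y)
})

test_that("mean FC increases with the planted coupling", {
  C <- normalize_connectome(make_connectome(12, density = 0.8, seed = 4))
  wins <- 0
  for (s in 1:10) {
    grp <- make_group_bold(C, g_values = c(0.3, 0.6), duration_s = 300,
                           tr_s = 1, seed = 40 + s)
    fcs <- vapply(grp$bold, function(b) fc_summary(fc_matrix(b$Y)), numeric(1))
    wins <- wins + (fcs[2] > fcs[1])
  }
  expect_gte(wins, 9)
})

test_that("voxel datasets plant the advertised structure", {
  # noise-free single region: all voxel pairs perfectly correlated
  vd <- make_voxel_dataset(n_voxels_per_region = 5, n_regions = 1,
                           n_subjects = 2, group_effect = 0, noise_sd = 0,
                           seed = 1, n_timepoints = 50)
  R <- cor(t(vd$group1[[1]]$data))
  expect_equal(max(abs(R - 1)), 0, tolerance = 1e-12)

  # null construction: Cohen's d maps centred on zero. A single dataset's
  # mean d fluctuates like one t draw (per-subject GC offsets are shared
  # across voxels), so the check averages over replicate datasets.
  dbar <- vapply(1:12, function(s) {
    vd0 <- make_voxel_dataset(n_voxels_per_region = 4, n_regions = 4,
                              n_subjects = 10, group_effect = 0, seed = s,
                              n_timepoints = 80)
    gc1 <- t(sapply(vd0$group1, global_connectivity))
    gc2 <- t(sapply(vd0$group2, global_connectivity))
    mean(cohen_d_map(gc2, gc1))
  }, numeric(1))
  expect_lt(abs(mean(dbar)), 0.3)

  # planted hyperconnectivity: positive group t in >= 95% of 20 seeds
  hits <- 0
  for (s in 1:20) {
    vd1 <- make_voxel_dataset(n_voxels_per_region = 4, n_regions = 4,
                              n_subjects = 8, group_effect = 0.4,
                              noise_sd = 0.4, seed = s, n_timepoints = 100)
    g1 <- t(sapply(vd1$group1, global_connectivity))
    g2 <- t(sapply(vd1$group2, global_connectivity))
    tm <- group_tmap(g2, g1)
    hits <- hits + (mean(tm$t) > 0)
  }
  expect_gte(hits, 19)

  # geometry carries physical units
  expect_equal(sort(unique(diff(sort(unique(vd$group1[[1]]$coords[, 1])))))[1],
               300)
})

test_that("expression atlas plants exact slopes and shapes", {
  at <- make_expression_atlas(n_donors = 6, n_genes = 1000, n_locations = 200,
                              n_coupled = 50, beta = 2, noise_sd = 0, seed = 1)
  expect_equal(dim(at$X), c(6, 1000, 200))
  sl <- donor_slopes(at, at$map)
  g <- at$ground_truth$planted_gene_indices[1]
  expect_equal(unname(sl[, g]), rep(2, 6), tolerance = 1e-10)
  # uncoupled genes are map-independent noise: zero slope without noise
  expect_error(make_expression_atlas(n_genes = 10, n_coupled = 11), "n_coupled")
})

test_that("atlas with no coupled genes yields no decoded survivors", {
  survivors <- vapply(1:20, function(s) {
    at <- make_expression_atlas(n_genes = 300, n_locations = 100,
                                n_coupled = 0, noise_sd = 0.2, seed = s)
    sum(decode_genes(donor_slopes(at, at$map))$retained)
  }, numeric(1))
  expect_lte(mean(survivors), 1)
})

test_that("gene lists have exactly the planted overlap", {
  gl <- make_gene_lists(100, 20, 10, 5, seed = 1)
  expect_length(intersect(gl$list_a, gl$list_b), 5)
  expect_length(gl$list_a, 20)
  expect_length(gl$list_b, 10)
  expect_true(all(c(gl$list_a, gl$list_b) %in% gl$universe))

  gl0 <- make_gene_lists(50, 10, 10, 0, seed = 2)
  expect_length(intersect(gl0$list_a, gl0$list_b), 0)

  expect_error(make_gene_lists(10, 5, 4, 5, 1))
})

test_that("subject maps place prototypes at the planted separation", {
  sm <- make_subject_maps(cluster_sizes = c(3, 3, 4), n_features = 10,
                          separation = 6, noise_sd = 0, seed = 1)
  D <- distance_matrix(sm$M)
  lab <- sm$ground_truth$planted_cluster_labels
  same <- outer(lab, lab, "==")
  expect_equal(max(D[same]), 0)
  expect_equal(unique(round(D[!same], 10)), 6)

  # the cohort-sized configuration used in the subtype analysis
  sm2 <- make_subject_maps(c(19, 21, 19, 102), n_features = 50,
                           separation = 8, noise_sd = 1, seed = 2)
  expect_equal(nrow(sm2$M), 161)
  expect_equal(as.numeric(table(sm2$ground_truth$planted_cluster_labels)),
               c(19, 21, 19, 102))
})

test_that("generators are pure functions of their seed", {
  expect_identical(make_voxel_dataset(seed = 9)$group2[[2]]$data,
                   make_voxel_dataset(seed = 9)$group2[[2]]$data)
  expect_identical(make_expression_atlas(seed = 9)$X,
                   make_expression_atlas(seed = 9)$X)
  expect_identical(make_subject_maps(c(4, 4), 6, 3, 0.5, seed = 9)$M,
                   make_subject_maps(c(4, 4), 6, 3, 0.5, seed = 9)$M)
})
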
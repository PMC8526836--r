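test_that("FC matrices reproduce exact correlations and flag degeneracies", {
  B <- orthonormal_basis(2, 60, seed = 1)
  ts <- rbind(B[1, ], 2 * B[1, ] + 1, -B[1, ], B[2, ])
  fc <- fc_matrix(ts)
  expect_equal(unname(fc$R[1, 2]), 1)
  expect_equal(unname(fc$R[1, 3]), -1)
  expect_equal(unname(fc$R[1, 4]), 0, tolerance = 1e-12)
  expect_true(isSymmetric(fc$R))
  expect_equal(unname(diag(fc$R)), rep(1, 4))

  expect_warning(fc_matrix(rbind(B[1, ], rep(2, 60))), "constant")
})

test_that("independent long series are near-uncorrelated", {
  set.seed(10)
  hits <- vapply(1:50, function(s) {
    x <- matrix(rnorm(2000), 2, 1000)
    abs(cor(x[1, ], x[2, ])) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("Fisher transform matches atanh with clipping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(0.3), -fisher_z(-0.3))
  expect_true(is.finite(fisher_z(1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_error(fisher_z(1.2), "<= 1")
  # invariance of fc + fisher under affine rescaling of a timeseries
  B <- orthonormal_basis(2, 40, seed = 2)
  ts <- rbind(B[1, ], 0.6 * B[1, ] + 0.8 * B[2, ])
  z1 <- fisher_z(fc_matrix(ts)$R[1, 2])
  z2 <- fisher_z(fc_matrix(rbind(5 * ts[1, ] - 2, ts[2, ]))$R[1, 2])
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("global connectivity equals the mean Fisher-z with exclusion rules", {
  B <- orthonormal_basis(3, 80, seed = 3)
  data <- rbind(B[1, ],                      # v1
                0.8 * B[1, ] + 0.6 * B[2, ], # r(v1,v2) = 0.8
                B[3, ])                      # orthogonal
  coords <- matrix(c(0, 0, 0, 400, 0, 0, 2000, 0, 0), 3, 3, byrow = TRUE)
  ds <- list(data = data, coords = coords, mask = rep(TRUE, 3))
  gc <- global_connectivity(ds)
  expect_equal(gc[1], (atanh(0.8) + 0) / 2, tolerance = 1e-10)  # 0.549306
  # excluding the neighbour within 600 um leaves only the orthogonal voxel
  gc_lr <- global_connectivity(ds, exclusion_radius_um = 600)
  expect_equal(gc_lr[1], 0, tolerance = 1e-10)

  # degenerate input: identical voxels exercise the clipped-z path
  ds_id <- list(data = rbind(B[1, ], B[1, ], B[1, ]), coords = coords,
                mask = rep(TRUE, 3))
  expect_true(all(is.finite(global_connectivity(ds_id))))
})

test_that("global connectivity matches the brute-force oracle", {
  set.seed(4)
  n <- 40
  data <- matrix(rnorm(n * 60), n, 60)
  data[1:10, ] <- data[1:10, ] + rep(rnorm(60), each = 10)
  coords <- as.matrix(expand.grid(x = 1:4, y = 1:5, z = 1:2)) * 300
  ds <- list(data = data, coords = coords, mask = rep(TRUE, n))
  expect_equal(global_connectivity(ds), gc_oracle(data), tolerance = 1e-10)
  expect_equal(global_connectivity(ds, exclusion_radius_um = 600),
               gc_oracle(data, coords, 600), tolerance = 1e-10)
})

test_that("seed maps are Fisher-z correlations with the seed mean", {
  B <- orthonormal_basis(3, 100, seed = 5)
  data <- rbind(B[1, ], B[1, ], B[2, ], 0.6 * B[1, ] + 0.8 * B[3, ])
  ds <- list(data = data, coords = NULL, mask = rep(TRUE, 4))
  sm <- seed_map(ds, seed_voxels = c(1, 2))
  expect_equal(sm[1], atanh(1 - 1e-7))            # voxel equal to seed mean
  expect_equal(sm[3], 0, tolerance = 1e-10)       # orthogonal voxel
  expect_equal(sm[4], atanh(0.6), tolerance = 1e-10)
  expect_identical(sm, seed_map(ds, c(1, 2)))
  expect_error(seed_map(ds, integer(0)), "empty")
})

test_that("Cohen's d uses the df-pooled standard deviation", {
  A <- matrix(c(1, 2), 2, 1)
  B <- matrix(c(3, 4), 2, 1)
  expect_equal(cohen_d_map(A, B), -2.828427, tolerance = 1e-6)
  expect_equal(cohen_d_map(B, A), 2.828427, tolerance = 1e-6)
  expect_equal(cohen_d_map(rbind(c(1, 5), c(2, 6)), rbind(c(1, 5), c(2, 6))),
               c(0, 0))
  expect_warning(cohen_d_map(matrix(1, 3, 1), matrix(1, 3, 1)), "zero pooled")
})

test_that("occurrence maps count suprathreshold sites", {
  expect_equal(occurrence_map(list(0.25, 0.19, 0.21)), 2)
  expect_equal(occurrence_map(list(0.1, 0.15, -0.3)), 0)
  expect_equal(occurrence_map(matrix(0.5, 7, 1)), 7)
})

test_that("group t maps are pooled-variance Student t", {
  A <- matrix(c(1, 2, 3), 3, 1)
  B <- matrix(c(4, 5, 6), 3, 1)
  tm <- group_tmap(A, B)
  expect_equal(tm$t, -3.674235, tolerance = 1e-6)
  expect_equal(tm$df, 4)
  expect_equal(group_tmap(B, A)$t, 3.674235, tolerance = 1e-6)
  expect_equal(group_tmap(A, A)$t, 0)
  expect_error(group_tmap(matrix(1, 1, 1), B), ">= 2")
  expect_true(tm$suprathreshold)
})

test_that("Dice coefficient handles the standard cases", {
  expect_equal(dice(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE)), 1)
  expect_equal(dice(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, TRUE)), 0)
  expect_equal(dice(c(1, 2, 3, 4), c(3, 4, 5, 6)), 0.5)  # index-set form
  expect_warning(d0 <- dice(logical(3), logical(3)), "empty")
  expect_true(is.na(d0))
})

test_that("frame censoring drops high-motion frames and can exclude subjects", {
  ts <- matrix(1:9, 3, 3)
  out <- censor_frames(ts, fd = c(0.1, 0.3, 0.15), fd_threshold_mm = 0.2)
  expect_equal(attr(out, "kept"), c(1L, 3L))
  expect_equal(ncol(out), 2)

  all_low <- censor_frames(ts, fd = c(0.1, 0.1, 0.1))
  expect_equal(ncol(all_low), 3)

  expect_error(censor_frames(ts, fd = c(0.5, 0.5, 0.5), min_fraction = 0.5),
               class = "subject_excluded")
})

test_that("residualization removes site offsets and is idempotent", {
  set.seed(6)
  n <- 30
  cov <- data.frame(site = factor(rep(c("a", "b", "c"), each = 10)),
                    age = rnorm(n), sex = rbinom(n, 1, 0.5), iq = rnorm(n))
  maps <- matrix(rnorm(n * 5), n, 5) +
    c(2, -1, 3)[as.integer(cov$site)]  # site-specific constant offsets
  adj <- residualize(maps, cov)
  for (s in levels(cov$site))
    expect_equal(colMeans(adj[cov$site == s, , drop = FALSE]), rep(0, 5),
                 tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(max(abs(crossprod(cov$age, adj))), 1e-8)
  expect_lt(max(abs(crossprod(cov$iq, adj))), 1e-8)
  expect_equal(residualize(adj, cov), adj, tolerance = 1e-9)

  cov$dup <- cov$age
  expect_error(residualize(maps, cov), "dup|collinear")
})

test_that("cluster correction detects planted effects but not isolated voxels", {
  coords <- as.matrix(expand.grid(x = 1:4, y = 1:4, z = 1:3))
  adj <- grid_adjacency(coords, spacing = 1)
  nf <- nrow(coords)
  set.seed(7)
  # a planted 2x2x2 block with a large shift is recovered
  block <- which(coords[, 1] <= 2 & coords[, 2] <= 2 & coords[, 3] <= 2)
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    A <- matrix(rnorm(12 * nf), 12, nf)
    B <- matrix(rnorm(12 * nf), 12, nf)
    B[, block] <- B[, block] + 2
    res <- permutation_cluster_correct(A, B, adj, alpha = 0.05,
                                       n_perm = 199, seed = s)
    found <- any(vapply(res$clusters, function(cl)
      length(intersect(cl$features, block)) >= 4, logical(1)))
    hits <- hits + found
  }
  expect_gte(hits, 19)

  # an isolated suprathreshold voxel amid noise is not significant
  set.seed(8)
  isolated <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    A <- matrix(rnorm(10 * nf), 10, nf)
    B <- matrix(rnorm(10 * nf), 10, nf)
    B[, 1] <- B[, 1] + 3.5
    B[, c(2, 5, 17)] <- B[, c(2, 5, 17)] - 0  # neighbours stay null
    res <- permutation_cluster_correct(A, B, adj, alpha = 0.01,
                                       n_perm = 199, seed = s)
    single <- vapply(res$clusters, function(cl)
      identical(cl$features, 1L), logical(1))
    isolated <- isolated + any(single)
  }
  expect_lte(isolated, 2)
})

test_that("cluster correction controls family-wise error on null data", {
  coords <- as.matrix(expand.grid(x = 1:4, y = 1:4, z = 1:3))
  adj <- grid_adjacency(coords, spacing = 1)
  nf <- nrow(coords)
  alpha <- 0.05
  rejections <- vapply(1:150, function(s) {
    set.seed(300 + s)
    A <- matrix(rnorm(10 * nf), 10, nf)
    B <- matrix(rnorm(10 * nf), 10, nf)
    res <- permutation_cluster_correct(A, B, adj, alpha = alpha,
                                       n_perm = 149, seed = s)
    length(res$clusters) > 0
  }, logical(1))
  rate <- mean(rejections)
  se <- sqrt(alpha * (1 - alpha) / 150)
  expect_lte(rate, alpha + 2 * se)
})

test_that("cluster correction and GC reject degenerate inputs", {
  A <- matrix(rnorm(40), 4, 10); B <- matrix(rnorm(40), 4, 10)
  bad_adj <- diag(10)  # nonzero diagonal
  expect_error(permutation_cluster_correct(A, B, bad_adj, n_perm = 100),
               "adjacency")
  expect_error(permutation_cluster_correct(A, B, matrix(0, 10, 10),
                                           n_perm = 50), "n_perm")
  ds1 <- list(data = matrix(rnorm(20), 1, 20), coords = matrix(0, 1, 3),
              mask = TRUE)
  expect_error(global_connectivity(ds1), "admissible")
})
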
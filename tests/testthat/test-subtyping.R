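test_that("distance matrices are Euclidean and match a brute-force loop", {
  M <- rbind(c(0, 0), c(3, 4), c(0, 0))
  D <- distance_matrix(M)
  expect_equal(D[1, 2], 5)
  expect_equal(D[1, 3], 0)
  expect_identical(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))

  set.seed(1)
  M2 <- matrix(rnorm(60 * 8), 60, 8)
  D2 <- distance_matrix(M2)
  brute <- matrix(0, 60, 60)
  for (i in 1:60) for (j in 1:60)
    brute[i, j] <- sqrt(sum((M2[i, ] - M2[j, ])^2))
  expect_equal(unname(D2), brute, tolerance = 1e-10)
})

test_that("hierarchical clustering is deterministic and recovers planted blobs", {
  sm <- make_subject_maps(c(10, 10), n_features = 5, separation = 20,
                          noise_sd = 0.5, seed = 3)
  D <- distance_matrix(sm$M)
  sol <- hierarchical_cluster(D, k = 2)
  expect_true(same_partition(sol$labels, sm$ground_truth$planted_cluster_labels))
  expect_identical(sol$labels, hierarchical_cluster(D, k = 2)$labels)

  n <- nrow(sm$M)
  expect_equal(length(unique(hierarchical_cluster(D, k = n)$labels)), n)
  expect_error(hierarchical_cluster(D, k = n + 1), "between")
})

test_that("clustering is invariant to subject ordering", {
  sm <- make_subject_maps(c(8, 8, 8), n_features = 6, separation = 15,
                          noise_sd = 0.5, seed = 4)
  set.seed(5)
  perm <- sample.int(24)
  l1 <- hierarchical_cluster(distance_matrix(sm$M), 3)$labels
  l2 <- hierarchical_cluster(distance_matrix(sm$M[perm, ]), 3)$labels
  expect_true(same_partition(l1[perm], l2))
})

test_that("majority vote picks the modal k with ties to the smaller k", {
  # the index tally pattern from a 16-index screen: 6 votes for 4, 5 for 2
  noms <- c(rep(4, 6), rep(2, 5), 3, 5, 6, 7, 8)
  expect_equal(majority_vote(noms), 4)
  expect_equal(majority_vote(c(2, 2, 2)), 2)
  expect_equal(majority_vote(c(3, 3, 5, 5)), 3)  # tie -> parsimony
})

test_that("index majority vote selects the planted number of clusters", {
  hits <- 0
  for (s in 1:20) {
    sm <- make_subject_maps(c(12, 12, 12, 12), n_features = 10,
                            separation = 12, noise_sd = 1, seed = s)
    sel <- select_k(sm$M, k_candidates = 2:10, seed = s)
    hits <- hits + (sel$k == 4)
    if (sel$k == 4)
      expect_true(same_partition(sel$labels,
                                 sm$ground_truth$planted_cluster_labels))
  }
  expect_gte(hits, 18)
})

test_that("subtype contrasts compare each cluster against controls", {
  sm <- make_subject_maps(c(6, 6), n_features = 8, separation = 10,
                          noise_sd = 0.5, seed = 6)
  controls <- matrix(rnorm(10 * 8, sd = 0.5), 10, 8)
  # make cluster 1 identical in distribution to controls
  labels <- sm$ground_truth$planted_cluster_labels
  M <- sm$M
  M[labels == 1, ] <- matrix(rnorm(sum(labels == 1) * 8, sd = 0.5),
                             ncol = 8)
  res <- subtype_contrasts(M, labels, controls)
  expect_named(res, c("cluster1", "cluster2"))
  expect_lt(mean(abs(res$cluster1$t)), 2)
  expect_gt(max(abs(res$cluster2$t)), 2)

  expect_error(subtype_contrasts(M, c(1, rep(2, nrow(M) - 1)), controls),
               ">= 2")
})

test_that("per-subtype enrichment flags only the spatially coupled cluster", {
  hits <- 0
  for (s in 1:20) {
    # four orthogonal cluster t-maps over 60 features; genes coupled to
    # map 2 only (orthogonality keeps the planted signal cluster-specific)
    B <- orthonormal_basis(4, 60, seed = 1000 + s) * sqrt(60)
    maps <- lapply(1:4, function(i) B[i, ])
    at <- make_expression_atlas(n_donors = 6, n_genes = 400,
                                n_locations = 60, n_coupled = 0,
                                noise_sd = 0.2, seed = s)
    coupled <- 1:40
    for (g in coupled)
      at$X[, g, ] <- at$X[, g, ] + matrix(maps[[2]], 6, 60, byrow = TRUE)
    target <- list(members = at$genes[coupled], universe = at$genes)
    res <- subtype_enrichment(stats::setNames(maps, paste0("cluster", 1:4)),
                              at, target)
    hits <- hits + (res$q[2] < 0.05 && all(res$q[-2] >= 0.05))
  }
  expect_gte(hits, 18)
})

test_that("null data do not produce spurious subtype enrichment", {
  flagged <- 0
  n_total <- 0
  for (s in 1:50) {
    set.seed(2000 + s)
    maps <- lapply(1:2, function(i) rnorm(50))
    at <- make_expression_atlas(n_donors = 6, n_genes = 200,
                                n_locations = 50, n_coupled = 0,
                                noise_sd = 0.2, seed = 500 + s)
    target <- list(members = at$genes[1:20], universe = at$genes)
    res <- subtype_enrichment(maps, at, target)
    flagged <- flagged + sum(res$q < 0.05)
    n_total <- n_total + nrow(res)
  }
  expect_lte(flagged / n_total, 0.05 + 2 * sqrt(0.05 * 0.95 / n_total))
})

test_that("single-cluster enrichment leaves the p value unadjusted", {
  at <- make_expression_atlas(n_donors = 6, n_genes = 100, n_locations = 40,
                              n_coupled = 0, noise_sd = 0.2, seed = 9)
  res <- subtype_enrichment(list(rnorm(40)), at,
                            list(members = at$genes[1:10],
                                 universe = at$genes))
  expect_equal(res$q, res$p)
})

test_that("cluster-count selection needs at least two indices", {
  sm <- make_subject_maps(c(5, 5), 4, 8, 0.5, seed = 1)
  expect_error(select_k(sm$M, indices = "silhouette"), "2 usable")
})
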
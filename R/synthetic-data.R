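#' @useDynLib dmfconn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom cor pt sd p.adjust phyper cutree
#'   hclust as.dist dist qnorm pnorm quantile
NULL

# Counter-based seed splitting: every generator derives independent substream
# seeds from one master seed, so adding subjects/streams later does not
# perturb earlier draws. Kept below 2^31 (R integers are 32-bit).
split_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 12345) %%
               2147483629)
}

#' Synthetic weighted structural connectome
#'
#' Generates a symmetric, nonnegative random connectome with zero diagonal.
#' Off-diagonal edges are present independently with probability
#' \code{density}; weights are drawn log-normal (meanlog 0, sdlog 1) --
#' heavy-tailed, as in biological connectomes -- then rescaled so the mean
#' nonzero weight equals 1.
#'
#' @param n_regions number of regions (>= 2); 74 matches a whole-brain mouse
#'   parcellation.
#' @param density expected fraction of nonzero off-diagonal entries, in
#'   (0, 1]. The default 0.8 mimics dense weighted mesoscale connectomes
#'   (most region pairs connected, strength carried by the weights).
#' @param seed integer seed.
#' @return object of class \code{connectome}: list with \code{labels} and the
#'   weight matrix \code{C}.
#' @export
#' @examples
#' C <- make_connectome(10, density = 0.5, seed = 1)
#' isSymmetric(C$C)
make_connectome <- function(n_regions = 74, density = 0.8, seed = 1) {
  if (n_regions < 2) stop("n_regions must be >= 2")
  stopifnot(density > 0, density <= 1)
  set.seed(split_seed(seed, 1L))
  n <- n_regions
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  m <- sum(ut)
  present <- runif(m) < density
  w <- exp(rnorm(m))
  w[!present] <- 0
  if (any(present)) w <- w / mean(w[present])
  W[ut] <- w
  W <- W + t(W)
  labels <- sprintf("R%02d", seq_len(n))
  dimnames(W) <- list(labels, labels)
  structure(list(labels = labels, C = W), class = "connectome")
}

#' Normalize a connectome to a reference spectral radius
#'
#' Rescales the coupling matrix so that its spectral radius equals
#' \code{spectral_radius}. The balanced low-firing state of the mean-field
#' model loses stability when the product of the global coupling G and the
#' spectral radius of C reaches a critical value (about 2 for the standard
#' parameter set), so fixing the radius fixes the location of the critical
#' coupling: the default 2.4 places it near G = 0.83, just above the
#' conventional search grid \[0, 0.75\], which therefore spans the
#' subcritical branch the way empirical whole-brain studies arrange their
#' structural matrices.
#'
#' @param connectome a \code{connectome} or square matrix.
#' @param spectral_radius target spectral radius of the rescaled matrix.
#' @return same type as the input, rescaled.
#' @export
normalize_connectome <- function(connectome, spectral_radius = 2.4) {
  M <- connectome_matrix(connectome)
  rho <- max(abs(eigen(M, symmetric = isSymmetric(M),
                       only.values = TRUE)$values))
  if (rho == 0) stop("cannot normalize an empty connectome")
  M <- M * spectral_radius / rho
  if (inherits(connectome, "connectome")) {
    connectome$C <- M
    connectome
  } else M
}

# Accepts a connectome object or a plain square matrix.
connectome_matrix <- function(C) {
  if (inherits(C, "connectome")) C <- C$C
  if (!is.matrix(C) || nrow(C) != ncol(C)) stop("C must be a square matrix")
  if (any(C < 0)) stop("connectome weights must be nonnegative")
  C
}

#' @export
print.connectome <- function(x, ...) {
  nz <- mean(x$C[upper.tri(x$C)] > 0)
  cat("connectome:", length(x$labels), "regions, density",
      format(nz, digits = 3), "\n")
  invisible(x)
}

#' Simulate a group of subjects' BOLD data at planted couplings
#'
#' Drives the full forward model (FIC calibration, neural simulation,
#' hemodynamic transform) once per subject at that subject's planted global
#' coupling value, fabricating an "empirical" BOLD dataset with known ground
#' truth for parameter-recovery studies.
#'
#' @param connectome a \code{connectome} or matrix.
#' @param g_values planted coupling per subject.
#' @param duration_s scan length per subject, seconds.
#' @param tr_s repetition time, seconds.
#' @param seed master seed; per-subject streams are split deterministically.
#' @param params,hemo model parameter lists.
#' @param dt_s integration step, seconds.
#' @return list with \code{bold} (list of \code{bold_timeseries}) and
#'   \code{ground_truth} (data.frame subject, planted_G).
#' @export
make_group_bold <- function(connectome, g_values, duration_s, tr_s = 1,
                            seed = 1, params = dmf_parameters(),
                            hemo = balloon_parameters(), dt_s = 0.0012) {
  C <- connectome_matrix(connectome)
  n_tp <- floor(duration_s / tr_s)
  bold <- vector("list", length(g_values))
  for (s in seq_along(g_values)) {
    g <- g_values[s]
    fic <- calibrate_fic(params, C, G = g, seed = split_seed(seed, 100L + s),
                         dt_s = dt_s)
    bold[[s]] <- simulate_bold(params, hemo, C, G = g, J = fic,
                               n_timepoints = n_tp, tr_s = tr_s,
                               seed = split_seed(seed, 200L + s), dt_s = dt_s)
  }
  list(bold = bold,
       ground_truth = data.frame(subject = seq_along(g_values),
                                 planted_G = g_values))
}

#' Synthetic voxelwise rsfMRI dataset with planted group hyperconnectivity
#'
#' Builds two groups of voxel timeseries on a regular 3-D grid. Voxels within
#' a region share a latent signal plus i.i.d. Gaussian noise; latent signals
#' across regions share a common component whose loading is larger in group 2
#' by \code{group_effect}, planting diffuse hyperconnectivity. Physical voxel
#' coordinates (index x \code{voxel_size_um}) support distance-based
#' exclusion rules.
#'
#' @param n_voxels_per_region,n_regions,n_subjects counts (per group for
#'   subjects).
#' @param group_effect increase in cross-region latent correlation loading for
#'   group 2 (0 = null construction).
#' @param voxel_size_um voxel edge length, micrometres.
#' @param noise_sd voxel-level noise standard deviation.
#' @param seed integer seed.
#' @param n_timepoints frames per subject.
#' @param base_corr common-signal loading shared by both groups.
#' @param tr_s repetition time, seconds.
#' @param affected_regions region indices receiving the group-2 effect
#'   (default: all regions; a subset plants a focal hyperconnectivity
#'   footprint for cluster-level inference).
#' @return list with \code{group1}, \code{group2} (lists of
#'   \code{voxel_dataset}), \code{coords}, \code{region} (voxel labels), and
#'   \code{ground_truth}.
#' @export
make_voxel_dataset <- function(n_voxels_per_region = 8, n_regions = 6,
                               n_subjects = 10, group_effect = 0.3,
                               voxel_size_um = 300, noise_sd = 0.5,
                               seed = 1, n_timepoints = 150,
                               base_corr = 0.2, tr_s = 1,
                               affected_regions = NULL) {
  stopifnot(n_voxels_per_region >= 1, n_regions >= 1, n_subjects >= 1,
            noise_sd >= 0, base_corr >= 0, base_corr + group_effect < 1)
  if (is.null(affected_regions)) affected_regions <- seq_len(n_regions)
  stopifnot(all(affected_regions %in% seq_len(n_regions)))
  nv <- n_voxels_per_region * n_regions
  # regular 3-D grid, near-cubic, regions as contiguous index blocks
  side <- ceiling(nv^(1 / 3))
  idx <- seq_len(nv) - 1L
  coords <- cbind(x = idx %% side,
                  y = (idx %/% side) %% side,
                  z = idx %/% (side * side)) * voxel_size_um
  region <- rep(seq_len(n_regions), each = n_voxels_per_region)
  gen_subject <- function(w_by_region, sd_seed) {
    set.seed(sd_seed)
    common <- rnorm(n_timepoints)
    lat <- sapply(seq_len(n_regions), function(r) {
      w <- w_by_region[r]
      sqrt(1 - w^2) * rnorm(n_timepoints) + w * common
    })
    data <- lat[, region, drop = FALSE]  # timepoints x voxels
    data <- t(data) + matrix(rnorm(nv * n_timepoints, sd = noise_sd),
                             nv, n_timepoints)
    structure(list(data = data, coords = coords, mask = rep(TRUE, nv),
                   region = region, tr_s = tr_s), class = "voxel_dataset")
  }
  w1 <- rep(sqrt(base_corr), n_regions)
  w2 <- w1
  w2[affected_regions] <- sqrt(base_corr + group_effect)
  g1 <- lapply(seq_len(n_subjects), function(s)
    gen_subject(w1, split_seed(seed, 1000L + s)))
  g2 <- lapply(seq_len(n_subjects), function(s)
    gen_subject(w2, split_seed(seed, 2000L + s)))
  list(group1 = g1, group2 = g2, coords = coords, region = region,
       ground_truth = list(group_effect = group_effect,
                           affected_regions = affected_regions))
}

#' Synthetic donor-wise spatial gene-expression atlas
#'
#' Emulates a multi-donor spatial expression resource: for a planted subset
#' of genes, expression at each location is \code{beta} times a reference
#' spatial map plus Gaussian noise, in every donor; the remaining genes are
#' map-independent noise.
#'
#' @param n_donors,n_genes,n_locations table dimensions.
#' @param n_coupled number of genes spatially coupled to the map.
#' @param beta planted regression slope of coupled genes on the map.
#' @param noise_sd expression noise SD.
#' @param seed integer seed.
#' @param donor_sd SD of donor-level deviations around \code{beta} (0 =
#'   identical coupling in every donor; positive values emulate biological
#'   donor-to-donor variability, which widens the across-donor t-test SE).
#' @return list of class \code{expression_atlas}: \code{X} (donor x gene x
#'   location array), \code{donors}, \code{genes}, \code{locations},
#'   \code{map} (reference spatial map), \code{ground_truth} (planted gene
#'   indices).
#' @export
make_expression_atlas <- function(n_donors = 6, n_genes = 1000,
                                  n_locations = 200, n_coupled = 50,
                                  beta = 1, noise_sd = 0.2, seed = 1,
                                  donor_sd = 0) {
  if (n_coupled > n_genes) stop("n_coupled must not exceed n_genes")
  stopifnot(n_donors >= 1, n_locations >= 3, noise_sd >= 0, donor_sd >= 0)
  set.seed(split_seed(seed, 5L))
  map <- rnorm(n_locations)
  coupled <- sort(sample.int(n_genes, n_coupled))
  X <- array(rnorm(n_donors * n_genes * n_locations, sd = noise_sd),
             dim = c(n_donors, n_genes, n_locations))
  for (g in coupled) {
    betas <- beta + rnorm(n_donors, 0, donor_sd)
    X[, g, ] <- X[, g, ] + outer(betas, map)
  }
  genes <- sprintf("gene%04d", seq_len(n_genes))
  structure(list(X = X, donors = sprintf("donor%d", seq_len(n_donors)),
                 genes = genes,
                 locations = sprintf("loc%04d", seq_len(n_locations)),
                 map = map,
                 ground_truth = list(planted_gene_indices = coupled,
                                     beta = beta)),
            class = "expression_atlas")
}

#' Synthetic gene lists with an exact planted overlap
#'
#' Draws two gene lists from a universe such that their intersection has
#' exactly \code{overlap_k} members.
#'
#' @param n_universe universe size.
#' @param size_a,size_b list sizes.
#' @param overlap_k planted overlap, \code{<= min(size_a, size_b)}.
#' @param seed integer seed.
#' @return list with \code{universe}, \code{list_a}, \code{list_b},
#'   \code{ground_truth}.
#' @export
make_gene_lists <- function(n_universe, size_a, size_b, overlap_k, seed = 1) {
  stopifnot(overlap_k <= min(size_a, size_b),
            size_a + size_b - overlap_k <= n_universe)
  set.seed(split_seed(seed, 6L))
  universe <- sprintf("g%05d", seq_len(n_universe))
  pick <- sample(universe, size_a + size_b - overlap_k)
  shared <- pick[seq_len(overlap_k)]
  only_a <- pick[seq_len(size_a - overlap_k) + overlap_k]
  only_b <- pick[seq_len(size_b - overlap_k) + size_a]
  list(universe = universe,
       list_a = sort(c(shared, only_a)),
       list_b = sort(c(shared, only_b)),
       ground_truth = list(overlap_k = overlap_k))
}

#' Synthetic subject-by-feature connectivity maps with planted clusters
#'
#' Subjects in the same planted cluster share a prototype vector; prototypes
#' are placed so that every pair is separated by exactly \code{separation} in
#' Euclidean norm, and isotropic Gaussian noise is added per subject.
#'
#' @param cluster_sizes vector of cluster sizes (one entry per cluster).
#' @param n_features feature dimension (>= number of clusters).
#' @param separation pairwise Euclidean distance between prototypes.
#' @param noise_sd per-feature noise SD.
#' @param seed integer seed.
#' @return list with \code{M} (subject x feature matrix) and
#'   \code{ground_truth} (planted labels).
#' @export
make_subject_maps <- function(cluster_sizes, n_features, separation,
                              noise_sd, seed = 1) {
  k <- length(cluster_sizes)
  stopifnot(k >= 1, n_features >= k, all(cluster_sizes >= 1),
            separation >= 0, noise_sd >= 0)
  set.seed(split_seed(seed, 7L))
  # scaled standard-basis prototypes: pairwise distance = separation exactly
  proto <- diag(k) * separation / sqrt(2)
  proto <- cbind(proto, matrix(0, k, n_features - k))
  labels <- rep(seq_len(k), times = cluster_sizes)
  n <- length(labels)
  M <- proto[labels, , drop = FALSE] +
    matrix(rnorm(n * n_features, sd = noise_sd), n, n_features)
  rownames(M) <- sprintf("subj%03d", seq_len(n))
  list(M = M, ground_truth = list(planted_cluster_labels = labels))
}
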
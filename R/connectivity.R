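#' Pearson functional connectivity matrix
#'
#' Pairwise temporal Pearson correlation between region (or voxel)
#' timeseries. Constant rows are flagged with a warning and their
#' correlations set to NA.
#'
#' @param ts regions x time matrix (>= 3 timepoints).
#' @return object of class \code{fc_matrix}: list with \code{R} (correlation
#'   matrix, unit diagonal) and \code{labels}.
#' @export
fc_matrix <- function(ts) {
  if (inherits(ts, "bold_timeseries")) ts <- ts$Y
  stopifnot(is.matrix(ts), ncol(ts) >= 3)
  const <- apply(ts, 1, function(x) sd(x) == 0 || !is.finite(sd(x)))
  if (any(const))
    warning("constant timeseries in region(s) ",
            paste(which(const), collapse = ", "), "; correlations set to NA")
  R <- suppressWarnings(cor(t(ts)))
  diag(R) <- 1
  labels <- rownames(ts)
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(nrow(ts)))
  structure(list(R = R, labels = labels), class = "fc_matrix")
}

#' Fisher r-to-z transform
#'
#' Variance-stabilising transform \eqn{z = \mathrm{atanh}(r)}. Correlations
#' with \eqn{|r| \ge 1 - 10^{-7}} are clipped to that bound first so the
#' result is always finite.
#'
#' @param r correlation value(s) in \[-1, 1\].
#' @return z score(s).
#' @export
#' @examples
#' fisher_z(0.5)  # 0.549306
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must be <= 1")
  bound <- 1 - 1e-7
  atanh(pmax(pmin(r, bound), -bound))
}

# coerce list-of-vectors or matrix to subjects x features matrix
as_map_matrix <- function(maps) {
  if (is.list(maps) && !is.data.frame(maps)) maps <- do.call(rbind, maps)
  if (is.vector(maps)) maps <- matrix(maps, nrow = 1)
  stopifnot(is.matrix(maps))
  maps
}

#' Voxelwise global (weighted-degree) connectivity map
#'
#' For every in-mask voxel, the mean Fisher-z correlation between that voxel
#' and all other in-mask voxels. With \code{exclusion_radius_um > 0} only
#' voxels strictly farther than the radius contribute, giving the long-range
#' variant (e.g. the > 600 um rule); voxels with no admissible partner get NA
#' with a warning.
#'
#' @param ds a \code{voxel_dataset} (fields \code{data}, \code{coords},
#'   \code{mask}).
#' @param exclusion_radius_um exclusion radius in micrometres (0 = none).
#' @return numeric vector, one value per masked voxel (NA outside the mask),
#'   in Fisher-z units.
#' @export
global_connectivity <- function(ds, exclusion_radius_um = 0) {
  stopifnot(!is.null(ds$data), !is.null(ds$mask))
  mask <- which(ds$mask)
  if (!length(mask)) stop("mask is empty")
  if (exclusion_radius_um > 0 && is.null(ds$coords))
    stop("coords with physical units are required for distance exclusion")
  Z <- fisher_z(suppressWarnings(cor(t(ds$data[mask, , drop = FALSE]))))
  diag(Z) <- NA
  if (exclusion_radius_um > 0) {
    D <- as.matrix(dist(ds$coords[mask, , drop = FALSE]))
    Z[D <= exclusion_radius_um] <- NA
  }
  gc <- rowMeans(Z, na.rm = TRUE)
  none <- apply(Z, 1, function(x) all(is.na(x)))
  if (all(none)) stop("no voxel has any admissible partner")
  if (any(none)) {
    warning(sum(none), " voxel(s) have no admissible partner; set to NA")
    gc[none] <- NA
  }
  out <- rep(NA_real_, nrow(ds$data))
  out[mask] <- gc
  out
}

#' Seed-based connectivity map
#'
#' Fisher-z correlation between the mean timeseries of a seed voxel set and
#' every in-mask voxel.
#'
#' @param ds a \code{voxel_dataset}.
#' @param seed_voxels indices of seed voxels (subset of the mask).
#' @return numeric vector of z values per voxel (NA outside the mask).
#' @export
seed_map <- function(ds, seed_voxels) {
  if (!length(seed_voxels)) stop("seed is empty")
  mask <- which(ds$mask)
  if (!all(seed_voxels %in% mask)) stop("seed voxels must lie within the mask")
  seed_ts <- colMeans(ds$data[seed_voxels, , drop = FALSE])
  r <- suppressWarnings(as.numeric(cor(seed_ts, t(ds$data[mask, , drop = FALSE]))))
  out <- rep(NA_real_, nrow(ds$data))
  out[mask] <- fisher_z(r)
  out
}

#' Cohen's d group-difference map
#'
#' Per feature, \eqn{(\bar A - \bar B) / s_p} with the pooled standard
#' deviation from (n-1)-denominator variances weighted by degrees of freedom.
#'
#' @param mapsA,mapsB subject x feature matrices (or lists of per-subject
#'   vectors), >= 2 subjects each.
#' @return numeric vector of d values (NaN with a warning where the pooled SD
#'   is zero).
#' @export
cohen_d_map <- function(mapsA, mapsB) {
  A <- as_map_matrix(mapsA); B <- as_map_matrix(mapsB)
  if (nrow(A) < 2 || nrow(B) < 2) stop("need >= 2 subjects per group")
  na <- nrow(A); nb <- nrow(B)
  va <- apply(A, 2, var); vb <- apply(B, 2, var)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  if (any(sp == 0)) warning("zero pooled SD at ", sum(sp == 0), " feature(s)")
  (colMeans(A) - colMeans(B)) / sp
}

#' Across-site occurrence map
#'
#' Per feature, the number of site-level effect-size maps exceeding a
#' Cohen's d threshold (reproducibility count across datasets).
#'
#' @param site_d_maps list of per-site d vectors (or site x feature matrix).
#' @param d_threshold effect-size threshold (default 0.2).
#' @return integer vector of counts per feature.
#' @export
occurrence_map <- function(site_d_maps, d_threshold = 0.2) {
  D <- as_map_matrix(site_d_maps)
  colSums(D > d_threshold, na.rm = TRUE)
}

#' Two-sample pooled-variance t map
#'
#' Unpaired two-tailed Student's t per feature (pooled variance, not Welch),
#' with a companion suprathreshold mask at |t| > \code{t_threshold}.
#'
#' @param mapsA,mapsB subject x feature matrices or lists, >= 2 subjects each.
#' @param t_threshold threshold for the suprathreshold mask.
#' @return list with \code{t} (vector), \code{suprathreshold} (logical
#'   vector), \code{df}.
#' @export
group_tmap <- function(mapsA, mapsB, t_threshold = 2) {
  A <- as_map_matrix(mapsA); B <- as_map_matrix(mapsB)
  if (nrow(A) < 2 || nrow(B) < 2) stop("need >= 2 subjects per group")
  na <- nrow(A); nb <- nrow(B)
  va <- apply(A, 2, var); vb <- apply(B, 2, var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  tt <- (colMeans(A) - colMeans(B)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, suprathreshold = abs(tt) > t_threshold & is.finite(tt),
       df = na + nb - 2)
}

# connected components of the suprathreshold set under an adjacency matrix /
# edge list; returns integer component label per suprathreshold feature
supra_clusters <- function(supra, adjacency) {
  idx <- which(supra)
  if (!length(idx)) return(integer(0))
  sub <- adjacency[idx, idx, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub > 0, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

#' Build a 6-connectivity voxel adjacency matrix from grid coordinates
#'
#' @param coords voxel x 3 matrix of physical coordinates on a regular grid.
#' @param spacing grid spacing (same units as \code{coords}); inferred from
#'   the smallest nonzero coordinate difference when NULL.
#' @return sparse-style logical adjacency matrix (voxel x voxel).
#' @export
grid_adjacency <- function(coords, spacing = NULL) {
  coords <- as.matrix(coords)
  if (is.null(spacing)) {
    d <- unique(sort(abs(diff(sort(unique(c(coords)))))))
    d <- d[d > 0]
    if (!length(d)) stop("degenerate coordinates")
    spacing <- min(d)
  }
  D <- as.matrix(dist(coords))
  A <- abs(D - spacing) < spacing * 1e-6
  diag(A) <- FALSE
  A
}

#' Permutation cluster-extent correction of a two-sample t map
#'
#' Thresholds the t map at \code{cluster_forming_t}, groups contiguous
#' suprathreshold features into clusters via the supplied adjacency, and
#' retains clusters whose extent (voxel count; optionally mass, the summed
#' |t|) exceeds the (1 - alpha) quantile of the maximal-cluster null obtained
#' by permuting group labels.
#'
#' @param mapsA,mapsB subject x feature matrices.
#' @param adjacency feature x feature adjacency (logical/0-1 matrix), e.g.
#'   from \code{\link{grid_adjacency}}.
#' @param cluster_forming_t cluster-forming threshold on |t| (default 2).
#' @param alpha cluster-level significance (default 0.01).
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer RNG seed.
#' @param statistic \code{"extent"} (count) or \code{"mass"} (summed |t|).
#' @return list with \code{clusters} (list of significant clusters: feature
#'   indices, size, statistic, p), \code{tmap}, \code{null_quantile},
#'   \code{null} (permutation maxima).
#' @export
permutation_cluster_correct <- function(mapsA, mapsB, adjacency,
                                        cluster_forming_t = 2, alpha = 0.01,
                                        n_perm = 1000, seed = 1,
                                        statistic = c("extent", "mass")) {
  statistic <- match.arg(statistic)
  A <- as_map_matrix(mapsA); B <- as_map_matrix(mapsB)
  if (n_perm < 100) stop("n_perm must be >= 100")
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(A) || any(adjacency[row(adjacency) == col(adjacency)] != 0))
    stop("adjacency must be feature x feature with empty diagonal")
  pooled <- rbind(A, B)
  na <- nrow(A)
  cluster_stats <- function(M1, M2) {
    tm <- group_tmap(M1, M2, t_threshold = cluster_forming_t)
    memb <- supra_clusters(tm$suprathreshold, adjacency)
    if (!length(memb)) return(list(stats = numeric(0), memb = memb, tm = tm))
    idx <- which(tm$suprathreshold)
    st <- if (statistic == "extent") as.numeric(table(memb))
          else as.numeric(tapply(abs(tm$t[idx]), memb, sum))
    list(stats = st, memb = memb, tm = tm)
  }
  obs <- cluster_stats(A, B)
  set.seed(as.integer(seed))
  null_max <- vapply(seq_len(n_perm), function(p) {
    perm <- sample.int(nrow(pooled))
    st <- cluster_stats(pooled[perm[seq_len(na)], , drop = FALSE],
                        pooled[perm[-seq_len(na)], , drop = FALSE])$stats
    if (length(st)) max(st) else 0
  }, numeric(1))
  thr <- as.numeric(quantile(null_max, 1 - alpha, type = 1))
  clusters <- list()
  if (length(obs$stats)) {
    idx <- which(obs$tm$suprathreshold)
    for (k in seq_along(obs$stats)) {
      if (obs$stats[k] > thr) {
        feats <- idx[obs$memb == k]
        pval <- (1 + sum(null_max >= obs$stats[k])) / (n_perm + 1)
        clusters[[length(clusters) + 1]] <-
          list(features = feats, size = length(feats),
               statistic = obs$stats[k], p = pval)
      }
    }
  }
  list(clusters = clusters, tmap = obs$tm$t, null_quantile = thr,
       null = null_max)
}

#' Dice similarity coefficient of two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}. Two empty masks give NA with a warning.
#'
#' @param maskA,maskB logical vectors of equal length, or index sets.
#' @return fraction in \[0, 1\].
#' @export
dice <- function(maskA, maskB) {
  if (!is.logical(maskA)) {
    u <- union(maskA, maskB)
    maskA <- u %in% maskA; maskB <- u %in% maskB
  }
  stopifnot(length(maskA) == length(maskB))
  denom <- sum(maskA) + sum(maskB)
  if (denom == 0) { warning("both masks empty"); return(NA_real_) }
  2 * sum(maskA & maskB) / denom
}

#' Motion censoring by framewise displacement
#'
#' Drops frames whose framewise displacement exceeds the threshold (strictly
#' greater). If the surviving fraction falls below \code{min_fraction} the
#' subject is excluded via a condition of class \code{subject_excluded}.
#'
#' @param ts regions x time matrix.
#' @param fd per-frame framewise displacement, mm.
#' @param fd_threshold_mm censoring threshold (default 0.2 mm).
#' @param min_fraction minimum surviving fraction of frames.
#' @return censored matrix (columns = surviving frames), with attribute
#'   \code{kept} (surviving frame indices).
#' @export
censor_frames <- function(ts, fd, fd_threshold_mm = 0.2, min_fraction = 0) {
  stopifnot(ncol(ts) == length(fd))
  keep <- which(fd <= fd_threshold_mm)
  if (length(keep) / length(fd) < min_fraction)
    stop(structure(class = c("subject_excluded", "error", "condition"),
                   list(message = sprintf(
                     "only %d/%d frames survive censoring (min_fraction = %g)",
                     length(keep), length(fd), min_fraction),
                     call = sys.call())))
  out <- ts[, keep, drop = FALSE]
  attr(out, "kept") <- keep
  out
}

#' Residualize subject maps on nuisance covariates
#'
#' Per feature, ordinary least-squares residuals after regressing on an
#' intercept plus the supplied covariates; factors (e.g. site) are expanded
#' to indicator codes. Residuals are orthogonal to the design, so applying
#' the operation twice is a no-op.
#'
#' @param maps subject x feature matrix.
#' @param covariates data.frame of per-subject covariates (site, age, sex,
#'   IQ, ...); factors/characters become indicators.
#' @return adjusted subject x feature matrix of residuals.
#' @export
residualize <- function(maps, covariates) {
  maps <- as_map_matrix(maps)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(maps) == nrow(covariates))
  X <- stats::model.matrix(~ ., data = covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  maps - X %*% qr.coef(qx, maps)
}
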
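#' Subject-by-subject Euclidean distance matrix
#'
#' @param M subject x feature matrix.
#' @return symmetric nonnegative matrix with zero diagonal.
#' @export
distance_matrix <- function(M) {
  M <- as_map_matrix(M)
  as.matrix(dist(M, method = "euclidean"))
}

#' Agglomerative hierarchical clustering of subjects
#'
#' Deterministic agglomerative merge of the distance matrix under the chosen
#' linkage, cut at \code{k} clusters.
#'
#' @param D distance matrix (subject x subject) or \code{dist}.
#' @param k number of clusters, \code{1 <= k <= n}.
#' @param linkage \code{"complete"} (default), \code{"average"} or
#'   \code{"ward"} (Ward.D2).
#' @return list of class \code{cluster_solution}: \code{labels}, \code{k},
#'   \code{linkage}, \code{tree} (the hclust object).
#' @export
hierarchical_cluster <- function(D, k, linkage = c("complete", "average", "ward")) {
  linkage <- match.arg(linkage)
  d <- if (inherits(D, "dist")) D else as.dist(D)
  n <- attr(d, "Size")
  if (k < 1 || k > n) stop("k must be between 1 and the number of subjects")
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- hclust(d, method = method)
  labels <- cutree(tree, k = k)
  structure(list(labels = unname(labels), k = k, linkage = linkage,
                 tree = tree), class = "cluster_solution")
}

# ---- internal validity indices (computed on data M and/or distances D) ----

within_between <- function(M, labels) {
  ctr <- rowsum(M, labels) / as.numeric(table(labels))
  gmean <- colMeans(M)
  W <- sum((M - ctr[labels, , drop = FALSE])^2)
  B <- sum(as.numeric(table(labels)) * rowSums(sweep(ctr, 2, gmean)^2))
  list(W = W, B = B)
}

index_ch <- function(M, D, labels) {
  k <- length(unique(labels)); n <- nrow(M)
  wb <- within_between(M, labels)
  (wb$B / (k - 1)) / (wb$W / (n - k))
}

index_silhouette <- function(M, D, labels) {
  mean(cluster::silhouette(labels, dmatrix = D)[, "sil_width"])
}

index_db <- function(M, D, labels) {
  ks <- sort(unique(labels))
  ctr <- rowsum(M, labels) / as.numeric(table(labels))
  s <- vapply(ks, function(c) {
    rows <- labels == c
    mean(sqrt(rowSums(sweep(M[rows, , drop = FALSE], 2, ctr[as.character(c), ])^2)))
  }, numeric(1))
  cd <- as.matrix(dist(ctr))
  mean(vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j) (s[i] + s[j]) / cd[i, j],
               numeric(1)))
  }, numeric(1)))
}

index_dunn <- function(M, D, labels) {
  ks <- sort(unique(labels))
  diam <- max(vapply(ks, function(c) {
    d <- D[labels == c, labels == c, drop = FALSE]
    if (nrow(d) < 2) 0 else max(d)
  }, numeric(1)))
  sep <- min(vapply(seq_along(ks)[-1], function(i) {
    min(vapply(seq_len(i - 1), function(j)
      min(D[labels == ks[i], labels == ks[j], drop = FALSE]), numeric(1)))
  }, numeric(1)))
  if (diam == 0) Inf else sep / diam
}

index_cindex <- function(M, D, labels) {
  dv <- D[upper.tri(D)]
  same <- outer(labels, labels, "==")[upper.tri(D)]
  nw <- sum(same)
  if (nw == 0) return(NA_real_)
  sw <- sum(dv[same])
  ds <- sort(dv)
  smin <- sum(ds[seq_len(nw)])
  smax <- sum(ds[seq(length(ds) - nw + 1, length(ds))])
  if (smax == smin) return(NA_real_)
  (sw - smin) / (smax - smin)
}

log_wk <- function(M, labels) {
  log(max(within_between(M, labels)$W, .Machine$double.eps))
}

#' Choose the number of clusters by index majority vote
#'
#' Every internal validity index nominates its best k over the candidate
#' range; the chosen k is the mode of the nominations, ties broken toward
#' smaller k (parsimony). Implemented indices: silhouette, Calinski-Harabasz,
#' Davies-Bouldin, Dunn, C-index, and the gap statistic (uniform reference
#' over the bounding box; Tibshirani one-standard-error rule).
#'
#' @param M subject x feature matrix.
#' @param k_candidates candidate cluster counts (default 2:10).
#' @param linkage linkage for \code{\link{hierarchical_cluster}}.
#' @param indices subset of \code{c("silhouette", "ch", "db", "dunn",
#'   "cindex", "gap")} (>= 2 required).
#' @param n_gap_ref reference datasets for the gap statistic.
#' @param seed RNG seed (gap references only).
#' @return list of class \code{k_selection}: \code{k} (chosen),
#'   \code{votes} (per-candidate tally), \code{nominations} (per index),
#'   \code{labels} (clustering at the chosen k).
#' @export
select_k <- function(M, k_candidates = 2:10,
                     linkage = "complete",
                     indices = c("silhouette", "ch", "db", "dunn",
                                 "cindex", "gap"),
                     n_gap_ref = 20, seed = 1) {
  M <- as_map_matrix(M)
  indices <- match.arg(indices, several.ok = TRUE)
  if (length(indices) < 2) stop("need at least 2 usable indices")
  k_candidates <- k_candidates[k_candidates >= 2 & k_candidates < nrow(M)]
  if (!length(k_candidates)) stop("no admissible candidate k")
  D <- distance_matrix(M)
  sols <- lapply(k_candidates, function(k)
    hierarchical_cluster(D, k, linkage)$labels)
  better_max <- c(silhouette = TRUE, ch = TRUE, db = FALSE, dunn = TRUE,
                  cindex = FALSE, gap = TRUE)
  fns <- list(silhouette = index_silhouette, ch = index_ch, db = index_db,
              dunn = index_dunn, cindex = index_cindex)
  nominations <- integer(0)
  for (ix in setdiff(indices, "gap")) {
    vals <- vapply(sols, function(l) fns[[ix]](M, D, l), numeric(1))
    if (all(is.na(vals))) next
    best <- if (better_max[ix]) which.max(vals) else which.min(vals)
    nominations[ix] <- k_candidates[best]
  }
  if ("gap" %in% indices) {
    set.seed(as.integer(seed))
    obs <- vapply(sols, function(l) log_wk(M, l), numeric(1))
    lo <- apply(M, 2, min); hi <- apply(M, 2, max)
    ref <- matrix(NA_real_, n_gap_ref, length(k_candidates))
    for (b in seq_len(n_gap_ref)) {
      Mb <- sapply(seq_len(ncol(M)), function(j)
        runif(nrow(M), lo[j], hi[j]))
      Db <- distance_matrix(Mb)
      ref[b, ] <- vapply(seq_along(k_candidates), function(i)
        log_wk(Mb, hierarchical_cluster(Db, k_candidates[i], linkage)$labels),
        numeric(1))
    }
    gap <- colMeans(ref) - obs
    se <- apply(ref, 2, sd) * sqrt(1 + 1 / n_gap_ref)
    pick <- NA_integer_
    for (i in seq_len(length(k_candidates) - 1)) {
      if (gap[i] >= gap[i + 1] - se[i + 1]) { pick <- i; break }
    }
    if (is.na(pick)) pick <- which.max(gap)
    nominations["gap"] <- k_candidates[pick]
  }
  if (length(nominations) < 2) stop("fewer than 2 usable indices")
  votes <- table(factor(nominations, levels = sort(unique(nominations))))
  chosen <- majority_vote(nominations)
  structure(list(k = chosen, votes = votes, nominations = nominations,
                 labels = sols[[match(chosen, k_candidates)]]),
            class = "k_selection")
}

#' Majority vote over per-index k nominations
#'
#' The mode of the nominated cluster counts, ties broken toward smaller k.
#'
#' @param nominations integer vector of nominated k values (one per index),
#'   or a named tally (votes per k, names = k).
#' @return chosen k.
#' @export
#' @examples
#' majority_vote(c(4, 4, 4, 4, 4, 4, 2, 2, 2, 2, 2, 3, 5, 6, 7, 8))  # 4
majority_vote <- function(nominations) {
  if (!is.null(names(nominations)) && !anyNA(suppressWarnings(as.integer(names(nominations))))) {
    tally <- nominations
    ks <- as.integer(names(tally))
  } else {
    tab <- table(nominations)
    tally <- as.integer(tab)
    ks <- as.integer(names(tab))
  }
  winners <- ks[tally == max(tally)]
  min(winners)
}

#' Per-subtype group contrasts against controls
#'
#' For each cluster of cases, a pooled-variance two-sample t map versus the
#' control group (suprathreshold mask at |t| > 2).
#'
#' @param M_cases case subject x feature matrix.
#' @param labels per-case cluster labels (or a \code{cluster_solution}).
#' @param M_controls control subject x feature matrix.
#' @param t_threshold suprathreshold cutoff.
#' @return named list (one entry per cluster) of \code{\link{group_tmap}}
#'   results.
#' @export
subtype_contrasts <- function(M_cases, labels, M_controls, t_threshold = 2) {
  M_cases <- as_map_matrix(M_cases); M_controls <- as_map_matrix(M_controls)
  if (inherits(labels, "cluster_solution")) labels <- labels$labels
  if (inherits(labels, "k_selection")) labels <- labels$labels
  stopifnot(length(labels) == nrow(M_cases))
  ks <- sort(unique(labels))
  if (any(table(labels) < 2))
    stop("every cluster needs >= 2 subjects for a t contrast")
  out <- lapply(ks, function(c)
    group_tmap(M_cases[labels == c, , drop = FALSE], M_controls,
               t_threshold = t_threshold))
  names(out) <- paste0("cluster", ks)
  out
}

#' Gene decoding and enrichment per subtype
#'
#' Runs the imaging-transcriptomics pipeline (donor slopes, one-sample t
#' decoding, target-set enrichment) for each cluster's contrast map, then
#' Benjamini-Hochberg adjusts the enrichment p values across clusters.
#'
#' @param per_cluster_maps list of per-cluster unthresholded t maps, aligned
#'   to the atlas locations (e.g. \code{$t} of
#'   \code{\link{subtype_contrasts}} entries).
#' @param atlas an \code{expression_atlas}.
#' @param target gene set (list with \code{members}/\code{universe}).
#' @param q_threshold decoding FDR threshold (default 0.05).
#' @return data.frame, one row per cluster: overlap, odds ratio, p, q.
#' @export
subtype_enrichment <- function(per_cluster_maps, atlas, target,
                               q_threshold = 0.05) {
  res <- lapply(per_cluster_maps, function(m) {
    if (is.list(m) && !is.null(m$t)) m <- m$t
    dec <- decode_genes(donor_slopes(atlas, m), q_threshold = q_threshold)
    enrich(dec, list(members = target$members, universe = atlas$genes))
  })
  p <- vapply(res, function(r) r$p_hypergeometric, numeric(1))
  data.frame(cluster = names(per_cluster_maps) %||% seq_along(res),
             n_decoded = vapply(res, function(r) r$size_A, numeric(1)),
             overlap_k = vapply(res, function(r) r$overlap_k, numeric(1)),
             odds_ratio = vapply(res, function(r) r$odds_ratio, numeric(1)),
             p = p, q = fdr_bh(p), row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
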
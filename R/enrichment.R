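#' Donor-specific regression slopes of expression on an imaging map
#'
#' For every donor and gene, the least-squares slope of expression regressed
#' on the mean-centred imaging map across shared locations. The slope encodes
#' how similar the gene's spatial expression pattern is to the map.
#'
#' @param atlas an \code{expression_atlas} (donor x gene x location array in
#'   \code{X}).
#' @param map imaging map values at the atlas locations (unthresholded
#'   statistic), non-constant.
#' @param z_score z-score each donor's expression per gene before the
#'   regression (normalisation knob; default FALSE).
#' @return donor x gene slope matrix.
#' @export
donor_slopes <- function(atlas, map, z_score = FALSE) {
  X <- atlas$X
  stopifnot(length(dim(X)) == 3, dim(X)[3] == length(map),
            all(is.finite(map)))
  if (dim(X)[3] < 3) stop("need >= 3 shared locations")
  if (sd(map) == 0) stop("imaging map is constant")
  mc <- map - mean(map)
  ss <- sum(mc^2)
  n_donors <- dim(X)[1]; n_genes <- dim(X)[2]
  out <- matrix(NA_real_, n_donors, n_genes,
                dimnames = list(atlas$donors, atlas$genes))
  for (d in seq_len(n_donors)) {
    E <- X[d, , , drop = TRUE]           # genes x locations
    if (n_genes == 1) E <- matrix(E, nrow = 1)
    if (z_score) {
      sds <- apply(E, 1, sd)
      E <- (E - rowMeans(E)) / ifelse(sds == 0, 1, sds)
    }
    out[d, ] <- as.numeric(E %*% mc) / ss
  }
  out
}

#' Decode map-coupled genes from donor slopes
#'
#' Per gene, a one-sample two-sided t test of the donor slopes against zero;
#' Benjamini-Hochberg adjustment across all genes; genes are retained when
#' their t statistic is positive and q falls below the threshold (spatially
#' similar, consistently across donors). Genes with zero across-donor
#' variance are excluded with a warning.
#'
#' @param slopes donor x gene matrix from \code{\link{donor_slopes}}.
#' @param q_threshold FDR threshold (default 0.05).
#' @return data.frame of class \code{decoded_genes} with columns gene, t, p,
#'   q, retained; the retained set is also in \code{attr(, "genes")}.
#' @export
decode_genes <- function(slopes, q_threshold = 0.05) {
  stopifnot(is.matrix(slopes), nrow(slopes) >= 2)
  n <- nrow(slopes)
  mu <- colMeans(slopes)
  s <- apply(slopes, 2, sd)
  degenerate <- s == 0
  if (any(degenerate))
    warning(sum(degenerate), " gene(s) with zero across-donor variance excluded")
  t <- ifelse(degenerate, NA_real_, mu / (s / sqrt(n)))
  p <- 2 * pt(abs(t), df = n - 1, lower.tail = FALSE)
  q <- fdr_bh(p)
  retained <- !is.na(t) & t > 0 & q < q_threshold
  genes <- colnames(slopes)
  if (is.null(genes)) genes <- sprintf("gene%04d", seq_along(t))
  out <- data.frame(gene = genes, t = t, p = p, q = q, retained = retained,
                    row.names = NULL)
  attr(out, "genes") <- genes[retained]
  class(out) <- c("decoded_genes", class(out))
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q values (monotone after sorting, capped at 1). NAs are
#' preserved and do not count toward the number of tests.
#'
#' @param pvals raw p values.
#' @return q values, same length and order.
#' @export
fdr_bh <- function(pvals) p.adjust(pvals, method = "BH")

#' Odds ratio for the overlap of two gene lists in a universe
#'
#' Cross-product ratio of the 2x2 table (in list A and B; A only; B only;
#' neither): \eqn{OR = k(N - A - B + k) / ((A - k)(B - k))}. When any cell is
#' zero, 0.5 is added to all four cells first (Haldane-Anscombe correction).
#'
#' @param k overlap count.
#' @param size_A,size_B list sizes.
#' @param N universe size.
#' @return odds ratio (dimensionless, >= 0).
#' @export
#' @examples
#' odds_ratio(3, 5, 4, 10)  # 6
odds_ratio <- function(k, size_A, size_B, N) {
  if (k > min(size_A, size_B) || size_A + size_B - k > N)
    stop("inconsistent contingency counts")
  a <- k
  b <- size_A - k
  c <- size_B - k
  d <- N - size_A - size_B + k
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  (a * d) / (b * c)
}

#' Hypergeometric overlap probability (inclusive upper tail)
#'
#' \eqn{P(X \ge k)} for X hypergeometric: population N containing
#' \code{size_B} successes, \code{size_A} draws without replacement. This is
#' the standard over-representation p value for a list overlap.
#'
#' @inheritParams odds_ratio
#' @return probability.
#' @export
#' @examples
#' hypergeom_p(3, 5, 4, 10)  # 66/252
hypergeom_p <- function(k, size_A, size_B, N) {
  if (k > min(size_A, size_B) || size_A + size_B - k > N)
    stop("inconsistent contingency counts")
  if (k == 0) return(1)
  phyper(k - 1, size_B, N - size_B, size_A, lower.tail = FALSE)
}

#' Enrichment of a decoded gene list in a target set
#'
#' Counts the overlap between the decoded list and the target set within the
#' universe and reports the odds ratio and inclusive hypergeometric p value.
#'
#' @param decoded a \code{decoded_genes} result, or a character vector of
#'   gene ids.
#' @param target list with \code{members} and \code{universe} (a gene set),
#'   or a character vector (then \code{universe} must be given).
#' @param universe universe gene ids when \code{target} is a plain vector.
#' @return list of class \code{enrichment_result}: \code{overlap_k},
#'   \code{size_A}, \code{size_B}, \code{N}, \code{odds_ratio},
#'   \code{p_hypergeometric}.
#' @export
enrich <- function(decoded, target, universe = NULL) {
  genes_a <- if (inherits(decoded, "decoded_genes")) attr(decoded, "genes")
             else as.character(decoded)
  if (is.list(target)) {
    members <- target$members
    if (is.null(members)) members <- target$list_b
    if (is.null(universe)) universe <- target$universe
  } else members <- as.character(target)
  if (is.null(universe)) stop("a gene universe is required")
  if (!all(genes_a %in% universe))
    stop("decoded genes must be contained in the universe")
  members <- intersect(members, universe)
  k <- length(intersect(genes_a, members))
  res <- list(overlap_k = k, size_A = length(genes_a),
              size_B = length(members), N = length(universe),
              odds_ratio = odds_ratio(k, length(genes_a), length(members),
                                      length(universe)),
              p_hypergeometric = hypergeom_p(k, length(genes_a),
                                             length(members),
                                             length(universe)))
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: overlap %d (A = %d, B = %d, N = %d), OR = %.3g, p = %.4g\n",
              x$overlap_k, x$size_A, x$size_B, x$N, x$odds_ratio,
              x$p_hypergeometric))
  invisible(x)
}

#' Prune an interactome gene set to its dysregulated members
#'
#' Set intersection of two gene sets (e.g. protein-level interactors of a
#' seed gene, restricted to genes dysregulated in the condition), preserving
#' the universe.
#'
#' @param interactors,dysregulated gene sets: lists with \code{members} (and
#'   \code{universe} for \code{interactors}) or character vectors.
#' @return list with \code{members} (the intersection) and \code{universe}.
#' @export
prune_interactome <- function(interactors, dysregulated) {
  mem_a <- if (is.list(interactors)) interactors$members else interactors
  mem_b <- if (is.list(dysregulated)) dysregulated$members else dysregulated
  universe <- if (is.list(interactors)) interactors$universe else NULL
  out <- intersect(mem_a, mem_b)
  if (!length(out)) warning("empty intersection")
  list(members = out, universe = universe)
}
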
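#' Grid of candidate global coupling values
#'
#' @param g_min,g_max,step arithmetic-sequence bounds and increment; the
#'   default grid \[0, 0.75\] in steps of 0.005 spans the stable coupling
#'   range of the model.
#' @return numeric vector (inclusive of both ends when commensurate).
#' @export
g_grid <- function(g_min = 0, g_max = 0.75, step = 0.005) {
  stopifnot(step > 0, g_max >= g_min)
  seq(g_min, g_max, by = step)
}

#' Scalar summary of a functional connectivity matrix
#'
#' Mean of the strictly upper-triangular Pearson correlations -- the quantity
#' matched between empirical and simulated data when fitting the coupling.
#'
#' @param fc an \code{fc_matrix}, or a square correlation matrix.
#' @param scale \code{"r"} (default) or \code{"z"} to average Fisher-z values.
#' @return scalar mean.
#' @export
fc_summary <- function(fc, scale = c("r", "z")) {
  scale <- match.arg(scale)
  R <- if (inherits(fc, "fc_matrix")) fc$R else fc
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  v <- R[upper.tri(R)]
  if (scale == "z") v <- fisher_z(v)
  mean(v, na.rm = TRUE)
}

#' Fit the global coupling G by grid search
#'
#' For each candidate G: calibrate feedback inhibition, run \code{n_repeats}
#' BOLD simulations, and average the mean upper-triangular FC over repeats.
#' The fitness is the absolute difference between that simulated summary and
#' the empirical one; the optimal G minimises it (ties broken toward smaller
#' G). A grid value where the simulator diverges is marked invalid and
#' skipped with a warning.
#'
#' @param empirical_fc \code{fc_matrix} (or square correlation matrix) of the
#'   subject being fitted.
#' @param C connectome (same parcellation size as \code{empirical_fc}).
#' @param grid candidate G values, e.g. \code{\link{g_grid}()}.
#' @param n_repeats simulations averaged per grid value.
#' @param sim_config list of simulation settings: \code{n_timepoints},
#'   \code{tr_s}, \code{dt_s}, \code{drive}, plus optional \code{params} and
#'   \code{hemo} parameter lists.
#' @param seed master seed; FIC and every repeat get split substreams.
#' @param scale FC averaging scale passed to \code{\link{fc_summary}}.
#' @return list of class \code{fit_result}: \code{optimal_G},
#'   \code{fitness_curve}, \code{grid}, \code{sim_summary},
#'   \code{empirical_summary}, \code{n_repeats}, \code{seed}.
#' @export
fit_G <- function(empirical_fc, C, grid = g_grid(), n_repeats = 10,
                  sim_config = list(), seed = 1, scale = "r") {
  Cm <- connectome_matrix(C)
  R <- if (inherits(empirical_fc, "fc_matrix")) empirical_fc$R else empirical_fc
  if (nrow(R) != nrow(Cm))
    stop("empirical FC and connectome must share the parcellation size")
  cfg <- modifyList(list(n_timepoints = 300, tr_s = 1, dt_s = 0.0012,
                         drive = "gating", params = dmf_parameters(),
                         hemo = balloon_parameters(),
                         fic_tol_hz = 0.15, fic_max_iter = 100), sim_config)
  emp <- fc_summary(R, scale = scale)
  sim_summary <- rep(NA_real_, length(grid))
  for (k in seq_along(grid)) {
    g <- grid[k]
    reps <- numeric(n_repeats)
    ok <- TRUE
    fic <- tryCatch(
      calibrate_fic(cfg$params, Cm, G = g, tol_hz = cfg$fic_tol_hz,
                    max_iter = cfg$fic_max_iter,
                    seed = split_seed(seed, 10000L), dt_s = cfg$dt_s),
      error = function(e) { ok <<- FALSE; NULL })
    if (ok) {
      for (r in seq_len(n_repeats)) {
        # common random numbers across grid values: repeat r reuses one
        # noise stream at every g, so the fitness curve varies smoothly in g
        # and the argmin is not dominated by independent per-g noise
        sim <- tryCatch(
          simulate_bold(cfg$params, cfg$hemo, Cm, G = g, J = fic,
                        n_timepoints = cfg$n_timepoints, tr_s = cfg$tr_s,
                        seed = split_seed(seed, 20000L + r),
                        dt_s = cfg$dt_s, drive = cfg$drive),
          error = function(e) { ok <<- FALSE; NULL })
        if (!ok) break
        reps[r] <- fc_summary(fc_matrix(sim$Y), scale = scale)
      }
    }
    if (!ok) {
      warning("simulation failed at G = ", g, "; grid value skipped")
      next
    }
    sim_summary[k] <- mean(reps)
  }
  fitness <- abs(sim_summary - emp)
  if (all(is.na(fitness))) stop("all grid values failed")
  best <- which.min(fitness)  # first minimum = smallest G on an ascending grid
  structure(list(optimal_G = grid[best], fitness_curve = fitness,
                 grid = grid, sim_summary = sim_summary,
                 empirical_summary = emp, n_repeats = n_repeats,
                 seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("coupling fit: optimal G =", x$optimal_G, "over",
      length(x$grid), "grid values (", x$n_repeats, "repeats )\n")
  invisible(x)
}

#' Permutation-based group comparison of fitted couplings
#'
#' Two-sample pooled-variance t statistic on per-subject optimal G values,
#' with a two-sided p value from random label permutations:
#' \eqn{p = (1 + \#\{|t_{perm}| \ge |t_{obs}|\}) / (n_{perm} + 1)}.
#'
#' @param optG_A,optG_B optimal-G vectors for the two groups (>= 2 each).
#' @param n_perm number of permutations (a warning below 100).
#' @param seed integer RNG seed.
#' @return list of class \code{group_comparison}: \code{g_diff}
#'   (mean B - mean A), \code{t_obs}, \code{p_two_sided}, \code{n_perm}.
#' @export
compare_groups <- function(optG_A, optG_B, n_perm = 10000, seed = 1) {
  stopifnot(length(optG_A) >= 2, length(optG_B) >= 2)
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p value")
  pooled <- c(optG_A, optG_B)
  na <- length(optG_A); n <- length(pooled)
  tstat <- function(x, ia) {
    a <- x[ia]; b <- x[-ia]
    sp2 <- ((na - 1) * var(a) + (n - na - 1) * var(b)) / (n - 2)
    if (sp2 == 0) return(0)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / (n - na)))
  }
  t_obs <- tstat(pooled, seq_len(na))
  set.seed(as.integer(seed))
  exceed <- 0L
  for (p in seq_len(n_perm)) {
    ia <- sample.int(n, na)
    if (abs(tstat(pooled, ia)) >= abs(t_obs)) exceed <- exceed + 1L
  }
  pval <- (1 + exceed) / (n_perm + 1)
  if (sd(pooled) == 0) pval <- 1
  structure(list(g_diff = mean(optG_B) - mean(optG_A), t_obs = t_obs,
                 p_two_sided = pval, n_perm = n_perm),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group comparison: G_diff = %.4g, t = %.3f, p = %.4g (%d permutations)\n",
              x$g_diff, x$t_obs, x$p_two_sided, x$n_perm))
  invisible(x)
}
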
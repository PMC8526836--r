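#' Balloon-Windkessel hemodynamic parameters
#'
#' Canonical parameterisation of the balloon model used throughout the
#' whole-brain modeling literature: signal decay \eqn{\kappa = 0.65}
#' s\eqn{^{-1}}, flow-dependent elimination \eqn{\gamma = 0.41}
#' s\eqn{^{-1}}, hemodynamic transit time \eqn{\tau = 0.98} s, vessel
#' stiffness exponent \eqn{\alpha = 0.32}, resting oxygen extraction
#' \eqn{\rho = 0.34}, resting venous volume fraction \eqn{V_0 = 0.02}, and
#' BOLD coefficients \eqn{k_1 = 7\rho}, \eqn{k_2 = 2}, \eqn{k_3 = 2\rho - 0.2}.
#'
#' @param ... named overrides.
#' @return named list of class \code{balloon_parameters}.
#' @export
balloon_parameters <- function(...) {
  rho <- 0.34
  p <- list(kappa = 0.65, gamma_h = 0.41, tau_h = 0.98, alpha = 0.32,
            rho = rho, V0 = 0.02, k1 = 7 * rho, k2 = 2, k3 = 2 * rho - 0.2)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown balloon parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  with(p, stopifnot(kappa > 0, gamma_h > 0, tau_h > 0, alpha > 0, rho > 0, V0 > 0))
  structure(p, class = "balloon_parameters")
}

#' Balloon-Windkessel transform of a neural drive
#'
#' Per region, integrates the hemodynamic state (vasodilatory signal s,
#' inflow f, venous volume v, deoxyhemoglobin q) driven by neural activity z:
#' \deqn{\dot s = z - \kappa s - \gamma(f - 1), \quad \dot f = s}
#' \deqn{\tau \dot v = f - v^{1/\alpha}, \quad
#'       \tau \dot q = f\,\frac{1 - (1-\rho)^{1/f}}{\rho} - v^{1/\alpha} q / v}
#' and reads out fractional BOLD signal change
#' \eqn{V_0 (k_1(1-q) + k_2(1 - q/v) + k_3(1 - v))} from the resting initial
#' state (0, 1, 1, 1). Zero drive therefore yields identically zero BOLD.
#'
#' @param drive regions x steps matrix (or vector for one region) of neural
#'   input sampled at \code{dt_s}.
#' @param dt_s sampling/integration step in seconds.
#' @param params a \code{\link{balloon_parameters}} list.
#' @return regions x steps matrix of BOLD at \code{dt_s} resolution.
#' @export
balloon_bold <- function(drive, dt_s, params = balloon_parameters()) {
  if (is.vector(drive)) drive <- matrix(drive, nrow = 1)
  stopifnot(is.matrix(drive), all(is.finite(drive)), dt_s > 0)
  cpp_balloon(drive, dt_s, unclass(params))
}

#' Simulate BOLD timeseries from the whole-brain model
#'
#' Runs the neural mean-field dynamics and the Balloon-Windkessel transform
#' jointly, discards an initial burn-in, and samples the BOLD output at the
#' scanner repetition time. The balloon input is the excitatory synaptic
#' gating by default (\code{drive = "gating"}), with the excitatory firing
#' rate available as an alternative.
#'
#' @param params \code{\link{dmf_parameters}}.
#' @param hemo \code{\link{balloon_parameters}}.
#' @param C connectivity matrix or \code{connectome}.
#' @param G global coupling.
#' @param J inhibitory weights (vector or \code{fic_solution}).
#' @param n_timepoints number of BOLD samples to return per region.
#' @param tr_s repetition time, seconds.
#' @param seed integer RNG seed.
#' @param dt_s integration step, seconds.
#' @param burn_s discarded initial transient, seconds. The default (20 s)
#'   covers the hemodynamic settling time: the balloon states relax to their
#'   baseline over ~10 s, and that shared transient would otherwise dominate
#'   interareal correlations.
#' @param drive \code{"gating"} (S_E) or \code{"rate"} (r_E) as balloon input.
#' @return list of class \code{bold_timeseries}: \code{t} (s), \code{Y}
#'   (regions x timepoints), \code{tr_s}, and \code{mean_rE} (Hz, mean
#'   post-burn-in excitatory rate per region).
#' @export
simulate_bold <- function(params = dmf_parameters(), hemo = balloon_parameters(),
                          C, G, J, n_timepoints, tr_s = 1, seed = 1,
                          dt_s = 0.0012, burn_s = 20,
                          drive = c("gating", "rate")) {
  drive <- match.arg(drive)
  C <- connectome_matrix(C)
  if (inherits(J, "fic_solution")) J <- J$J
  stopifnot(n_timepoints >= 2, tr_s > 0, length(J) == nrow(C))
  set.seed(as.integer(seed))
  out <- cpp_simulate_bold(C, G, as.numeric(J), unclass(params), unclass(hemo),
                           as.integer(n_timepoints), tr_s, dt_s, burn_s,
                           drive == "rate")
  structure(list(t = seq_len(n_timepoints) * tr_s, Y = out$Y, tr_s = tr_s,
                 mean_rE = as.numeric(out$mean_rE), G = G),
            class = "bold_timeseries")
}

#' @export
print.bold_timeseries <- function(x, ...) {
  cat("BOLD timeseries:", nrow(x$Y), "regions x", ncol(x$Y),
      "timepoints (TR =", x$tr_s, "s)\n")
  invisible(x)
}
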
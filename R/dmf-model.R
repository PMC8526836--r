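#' Default parameters of the dynamic mean-field model
#'
#' Returns the standard parameter set of the reduced (dynamic mean-field)
#' whole-brain model, in which every brain region is a reciprocally coupled
#' pair of excitatory (E) and inhibitory (I) neural pools. Values are the
#' conventional ones for this model family: external input current
#' \eqn{I_0 = 0.382} nA split by pool weights \eqn{W_E = 1}, \eqn{W_I = 0.7};
#' excitatory synaptic coupling \eqn{J_{NMDA} = 0.15} nA with recurrent weight
#' \eqn{w_+ = 1.4}; sigmoidal transfer-function constants
#' (\eqn{a_E = 310} nC\eqn{^{-1}}, \eqn{b_E = 125} Hz, \eqn{d_E = 0.16} s;
#' \eqn{a_I = 615} nC\eqn{^{-1}}, \eqn{b_I = 177} Hz, \eqn{d_I = 0.087} s);
#' gating kinetics \eqn{\gamma = 0.641}, \eqn{\tau_{NMDA} = 0.1} s,
#' \eqn{\tau_{GABA} = 0.01} s; and noise amplitude \eqn{\sigma = 0.01} nA.
#'
#' @param ... named overrides for individual parameters.
#' @return A named list of class \code{dmf_parameters}.
#' @export
#' @examples
#' p <- dmf_parameters()
#' p$I_0
dmf_parameters <- function(...) {
  p <- list(
    W_E = 1, W_I = 0.7, I_0 = 0.382, w_plus = 1.4, J_NMDA = 0.15,
    a_E = 310, b_E = 125, d_E = 0.16,
    a_I = 615, b_I = 177, d_I = 0.087,
    gamma = 0.641, tau_NMDA = 0.1, tau_GABA = 0.01, sigma = 0.01
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown DMF parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(all(vapply(p, is.numeric, logical(1))))
  structure(p, class = "dmf_parameters")
}

#' Sigmoidal input-output transfer function of a neural pool
#'
#' Converts total synaptic input current into a population firing rate via
#' \eqn{H(I) = (aI - b) / (1 - e^{-d(aI - b)})}. The singularity at
#' \eqn{aI = b} is removable; the limit \eqn{1/d} is returned there.
#'
#' @param I input current in nA (vectorised).
#' @param pool \code{"E"} or \code{"I"}, selecting the pool's (a, b, d).
#' @param params a \code{\link{dmf_parameters}} list.
#' @return Firing rate(s) in Hz, nonnegative.
#' @export
#' @examples
#' transfer_rate(0.4, "E")   # 5.7634 Hz
transfer_rate <- function(I, pool = c("E", "I"), params = dmf_parameters()) {
  pool <- match.arg(pool)
  if (!all(is.finite(I))) stop("input current must be finite")
  if (pool == "E") {
    cpp_transfer(as.numeric(I), params$a_E, params$b_E, params$d_E)
  } else {
    cpp_transfer(as.numeric(I), params$a_I, params$b_I, params$d_I)
  }
}

#' Total input currents to the excitatory and inhibitory pools
#'
#' Computes, for the current gating state, the pool input currents
#' \deqn{I^{(E)}_i = W_E I_0 + w_+ J_{NMDA} S^{(E)}_i +
#'       G J_{NMDA} \sum_j C_{ij} S^{(E)}_j - J_i S^{(I)}_i}
#' \deqn{I^{(I)}_i = W_I I_0 + J_{NMDA} S^{(E)}_i - S^{(I)}_i}
#' where \code{G} scales all long-range excitatory couplings \code{C} and
#' \code{J} is the per-region feedback-inhibition weight.
#'
#' @param S_E,S_I excitatory / inhibitory gating vectors in \[0, 1\].
#' @param params a \code{\link{dmf_parameters}} list.
#' @param G global coupling scalar (dimensionless).
#' @param C structural connectivity matrix (regions x regions) or a
#'   \code{connectome} object.
#' @param J per-region inhibitory weight vector (nA), or a
#'   \code{fic_solution}.
#' @return list with components \code{I_E} and \code{I_I} (nA vectors).
#' @export
input_currents <- function(S_E, S_I, params = dmf_parameters(), G, C, J) {
  C <- connectome_matrix(C)
  if (inherits(J, "fic_solution")) J <- J$J
  n <- nrow(C)
  if (length(S_E) != n || length(S_I) != n || length(J) != n)
    stop("state and J must match the connectome dimension (", n, " regions)")
  I_E <- params$W_E * params$I_0 + params$w_plus * params$J_NMDA * S_E +
    G * params$J_NMDA * as.numeric(C %*% S_E) - J * S_I
  I_I <- params$W_I * params$I_0 + params$J_NMDA * S_E - S_I
  list(I_E = I_E, I_I = I_I)
}

#' Integrate the neural gating equations
#'
#' Euler-Maruyama integration of the coupled gating dynamics
#' \deqn{dS^{(E)}/dt = -S^{(E)}/\tau_{NMDA} + (1 - S^{(E)})\gamma r^{(E)} + \sigma v(t)}
#' \deqn{dS^{(I)}/dt = -S^{(I)}/\tau_{GABA} + r^{(I)} + \sigma v(t)}
#' with rates from \code{\link{transfer_rate}} at every step and gating
#' clamped to \[0, 1\] after each step. Noise enters as independent standard
#' normal draws scaled by \eqn{\sigma\sqrt{dt}}.
#'
#' @param params a \code{\link{dmf_parameters}} list.
#' @param C connectivity matrix or \code{connectome}.
#' @param G global coupling.
#' @param J per-region inhibitory weights (vector or \code{fic_solution}).
#' @param duration_s,dt_s simulated time and integration step, seconds.
#' @param seed integer seed (R RNG; identical seed gives identical paths).
#' @param sigma noise amplitude override (nA); default from \code{params}.
#' @param record_every record the state every this many steps.
#' @param pin_rE,pin_rI optional fixed firing rates (Hz) replacing the
#'   transfer function, used to probe the gating fixed points in isolation.
#' @param S_E0,S_I0 initial gating values (recycled per region).
#' @return list of class \code{neural_timeseries}: \code{t}, matrices
#'   \code{S_E}, \code{S_I}, \code{r_E}, \code{r_I} (regions x samples),
#'   and \code{dt}.
#' @export
dmf_integrate <- function(params = dmf_parameters(), C, G = 0, J = NULL,
                          duration_s, dt_s = 0.0012, seed = 1,
                          sigma = params$sigma, record_every = 1L,
                          pin_rE = NULL, pin_rI = NULL,
                          S_E0 = 0.1, S_I0 = 0.1) {
  C <- connectome_matrix(C)
  n <- nrow(C)
  if (is.null(J)) J <- rep(1, n)
  if (inherits(J, "fic_solution")) J <- J$J
  stopifnot(dt_s > 0, duration_s >= dt_s)
  n_steps <- floor(duration_s / dt_s)
  set.seed(as.integer(seed))
  out <- cpp_dmf_integrate(C, G, as.numeric(J), unclass(params),
                           as.integer(n_steps), dt_s,
                           as.integer(record_every), sigma,
                           if (is.null(pin_rE)) -1 else pin_rE,
                           if (is.null(pin_rI)) -1 else pin_rI,
                           rep_len(S_E0, n), rep_len(S_I0, n))
  n_rec <- ncol(out$S_E)
  structure(list(t = seq_len(n_rec) * dt_s * record_every,
                 S_E = out$S_E, S_I = out$S_I,
                 r_E = out$r_E, r_I = out$r_I,
                 S_E_end = out$S_E_end, S_I_end = out$S_I_end,
                 dt = dt_s * record_every),
            class = "neural_timeseries")
}

#' Calibrate feedback inhibition control (FIC)
#'
#' Tunes the per-region inhibitory-to-excitatory weight \eqn{J_i} so that the
#' long-run mean excitatory firing rate of every region sits near a low
#' target (~3 Hz) regardless of the excitatory input it receives through the
#' connectome. Starting from \eqn{J_i = 1} nA, each iteration simulates a
#' short epoch (after a settling burn-in), measures the mean excitatory rate,
#' mean input current and mean inhibitory gating per region, and applies a
#' damped Newton step
#' \eqn{J_i \leftarrow J_i + \lambda (\bar r_i - r^*) / (H'(\bar I_i) \bar S^I_i)}
#' based on the analytic local sensitivity of the rate to the inhibitory
#' weight (steps clipped to +-1 nA).
#'
#' @param params a \code{\link{dmf_parameters}} list.
#' @param C connectivity matrix or \code{connectome}.
#' @param G global coupling.
#' @param target_hz target excitatory rate, Hz.
#' @param tol_hz convergence tolerance on the max regional deviation, Hz.
#' @param max_iter iteration cap; on exhaustion \code{converged} is FALSE
#'   (no error).
#' @param seed integer RNG seed.
#' @param damping Newton step damping factor in (0, 1].
#' @param epoch_s,burn_s measurement epoch and per-iteration burn-in, s.
#' @param dt_s integration step, s.
#' @return list of class \code{fic_solution}: \code{J} (nA), \code{converged},
#'   \code{achieved_rates} (Hz), \code{n_iter}.
#' @export
calibrate_fic <- function(params = dmf_parameters(), C, G,
                          target_hz = 3, tol_hz = 0.15, max_iter = 100,
                          seed = 1, damping = 0.8, epoch_s = 10, burn_s = 2,
                          dt_s = 0.0012) {
  C <- connectome_matrix(C)
  stopifnot(target_hz > 0, max_iter >= 1, tol_hz > 0)
  set.seed(as.integer(seed))
  out <- cpp_calibrate_fic(C, G, unclass(params), target_hz, tol_hz, damping,
                           as.integer(max_iter), epoch_s, burn_s, dt_s,
                           fic_fixed_point(params, C, G, target_hz))
  structure(list(J = as.numeric(out$J),
                 achieved_rates = as.numeric(out$achieved_rates),
                 converged = isTRUE(out$converged),
                 n_iter = out$n_iter,
                 target_hz = target_hz, tol_hz = tol_hz, G = G),
            class = "fic_solution")
}

#' Deterministic balanced-state inhibitory weights
#'
#' Closed-form feedback-inhibition initialisation: assuming every region sits
#' at the target excitatory rate, the excitatory gating is
#' \eqn{S^{E*} = \gamma r^* \tau_{NMDA} / (1 + \gamma r^* \tau_{NMDA})}, the
#' inhibitory gating solves its own scalar fixed point, and
#' \eqn{J_i = (W_E I_0 + w_+ J_{NMDA} S^{E*} +
#'       G J_{NMDA} \sum_j C_{ij} S^{E*} - I^*) / S^{I*}}
#' with \eqn{I^* = H_E^{-1}(r^*)}. This is the noise-free solution of the
#' balance condition; \code{\link{calibrate_fic}} refines it against the
#' stochastic dynamics.
#'
#' @inheritParams calibrate_fic
#' @return numeric vector of per-region inhibitory weights (nA).
#' @export
fic_fixed_point <- function(params = dmf_parameters(), C, G, target_hz = 3) {
  C <- connectome_matrix(C)
  I_star <- stats::uniroot(function(I) transfer_rate(I, "E", params) - target_hz,
                           c(0, 2), tol = 1e-12)$root
  ge <- params$gamma * target_hz * params$tau_NMDA
  SE_star <- ge / (1 + ge)
  SI_star <- stats::uniroot(function(s)
    params$tau_GABA * transfer_rate(params$W_I * params$I_0 +
                                      params$J_NMDA * SE_star - s, "I",
                                    params) - s,
    c(0, 1), tol = 1e-12)$root
  J <- (params$W_E * params$I_0 + params$w_plus * params$J_NMDA * SE_star +
          G * params$J_NMDA * rowSums(C) * SE_star - I_star) / SI_star
  pmax(J, 1e-3)
}

#' @export
print.fic_solution <- function(x, ...) {
  cat("FIC solution:", length(x$J), "region(s), G =", x$G,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  J range:", format(range(x$J), digits = 4), "nA\n")
  cat("  achieved rates:", format(range(x$achieved_rates), digits = 4),
      "Hz (target", x$target_hz, "Hz)\n")
  invisible(x)
}
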
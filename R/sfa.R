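#' Jacobian of the ensemble with spike-frequency adaptation
#'
#' The 3D system (rE, rI, a) with adaptation current `a` obeying
#' `tau_a da/dt = -a + b*rE` has Jacobian rows
#' `[(JEE*kE - 1)/tauE, -JEI*kE/tauE, -1/tauE]`,
#' `[JIE*kI/tauI, -(1 + JII*kI)/tauI, 0]`,
#' `[b/tau_a, 0, -1/tau_a]`.
#'
#' @inheritParams jacobian_2d
#' @param b Adaptation strength (>= 0).
#' @param tau_a Adaptation time constant (s).
#' @return An `nta_jacobian` with a 3x3 `entries` matrix.
#' @export
jacobian_sfa <- function(weights, params, gain, b, tau_a, rE, rI) {
  if (rE < 0 || rI < 0) stop("rates must be >= 0")
  if (b < 0 || tau_a <= 0) stop("need b >= 0 and tau_a > 0")
  kE <- gain_slope(rE, gain$alphaE)
  kI <- gain_slope(rI, gain$alphaI)
  M <- matrix(c(
    (weights$JEE * kE - 1) / params$tauE,
    -weights$JEI * kE / params$tauE,
    -1 / params$tauE,
    weights$JIE * kI / params$tauI,
    -(1 + weights$JII * kI) / params$tauI,
    0,
    b / tau_a, 0, -1 / tau_a),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("rE", "rI", "a"), c("rE", "rI", "a")))
  structure(list(entries = M, eigenvalues = eigen(M)$values,
                 context = list(rE = rE, rI = rI, b = b, tau_a = tau_a)),
            class = "nta_jacobian")
}

#' Characteristic polynomial of the SFA system
#'
#' Coefficients of `lambda^3 - tr*lambda^2 + A*lambda - det = 0` for the
#' 3D adaptation system, computed literally from the trace, the sum of
#' the three principal 2x2 cofactors, and the determinant of the
#' Jacobian. With adaptation decoupled (`b = 0`) the roots are
#' `-1/tau_a` together with the eigenvalues of the 2D ensemble.
#'
#' The determinant condition shows why weak adaptation cannot stabilize
#' runaway excitation: in the large-rate limit, `-det` turns negative
#' whenever `b` is below a rate-dependent bound, so the Jacobian always
#' retains a positive eigenvalue. Strong adaptation instead destabilizes
#' the fixed point through a Hopf bifurcation (the complex pair crosses
#' the imaginary axis where `tr * A = det`), producing a stable limit
#' cycle rather than a steady state.
#'
#' @inheritParams jacobian_sfa
#' @return Object of class `sfa_polynomial`: list with `tr`,
#'   `cofactor_sum`, `det`, `coefficients` (of the monic cubic, constant
#'   term first), `roots` (complex), `discriminant`, and `hopf_gap`
#'   (`tr * cofactor_sum - det`; zero at the Hopf point).
#' @export
sfa_characteristic_poly <- function(weights, params, gain, b, tau_a,
                                    rE, rI) {
  kE <- gain_slope(rE, gain$alphaE)
  kI <- gain_slope(rI, gain$alphaI)
  tE <- 1 / params$tauE; tI <- 1 / params$tauI; ta <- 1 / tau_a
  gEE <- weights$JEE * kE - 1     # tauE * M11
  gII <- 1 + weights$JII * kI     # -tauI * M22
  tr <- tE * gEE - tI * gII - ta
  A11 <- tI * gII * ta
  A22 <- -tE * gEE * ta + ta * b * tE
  A33 <- -tE * gEE * tI * gII +
    tE * weights$JEI * kE * tI * weights$JIE * kI
  A <- A11 + A22 + A33
  det <- tE * gEE * tI * gII * ta -
    tE * weights$JEI * kE * tI * weights$JIE * kI * ta -
    ta * b * tE * tI * gII
  coef <- c(-det, A, -tr, 1)
  roots <- polyroot(coef)
  disc <- tr^2 * A^2 - 4 * A^3 - 4 * tr^3 * det - 27 * det^2 +
    18 * tr * A * det
  structure(list(tr = tr, cofactor_sum = A, det = det,
                 coefficients = coef, roots = roots,
                 discriminant = disc,
                 hopf_gap = tr * A - det,
                 context = list(rE = rE, rI = rI, b = b, tau_a = tau_a)),
            class = "sfa_polynomial")
}

#' Fixed point of the ensemble with SFA
#'
#' At steady state the adaptation current equals `b*rE`, so the
#' excitatory nullcline becomes `(1 + b)*rE = [z]_+^alphaE`. The solver
#' scans `rE`, resolving the inhibitory steady state by bracketed 1D
#' root finding, and refines each crossing by bisection. Returns the
#' lowest-rate fixed point (the one continuously connected to baseline)
#' or `NULL` if none exists below `rE_max`.
#'
#' Note that with adaptation the fixed-point rate is not the raw gain
#' output: `[z]_+^alphaE = (1 + b)*rE`. The Jacobian slope factors are
#' therefore evaluated at the effective rate `rE_gain = (1 + b)*rE`,
#' which the result reports alongside the state.
#'
#' @inheritParams jacobian_sfa
#' @param gE,gI External drives.
#' @param rE_max Upper end of the scan (default 1e4 Hz).
#' @return List with `rE`, `rI`, `a`, `rE_gain`, or `NULL`.
#' @export
sfa_fixed_point <- function(weights, params, gain, b, gE, gI,
                            rE_max = 1e4) {
  rI_of <- function(rE) {
    wfun <- function(rI) rI - powerlaw_gain(
      weights$JIE * rE - weights$JII * rI + gI, gain$alphaI)
    hi <- 1
    while (wfun(hi) < 0 && hi < 1e12) hi <- hi * 2
    stats::uniroot(wfun, lower = 0, upper = hi, tol = 1e-12)$root
  }
  resid <- function(rE) {
    powerlaw_gain(weights$JEE * rE - weights$JEI * rI_of(rE) + gE,
                  gain$alphaE) - (1 + b) * rE
  }
  grid <- c(0, 10^seq(-6, log10(rE_max), length.out = 400))
  vals <- vapply(grid, resid, numeric(1))
  sgn <- sign(vals)
  i <- which(sgn[-length(sgn)] * sgn[-1] < 0 | sgn[-length(sgn)] == 0)[1]
  if (is.na(i)) return(NULL)
  rE <- if (sgn[i] == 0) grid[i] else
    stats::uniroot(resid, lower = grid[i], upper = grid[i + 1],
                   tol = 1e-12)$root
  rI <- rI_of(rE)
  list(rE = rE, rI = rI, a = b * rE, rE_gain = (1 + b) * rE)
}

#' Classify stimulated dynamics of the SFA-stabilized ensemble
#'
#' Simulates the ensemble with SFA under the given protocol and
#' classifies the during-stimulus epoch: `"runaway"` if the trajectory
#' diverges, `"limit_cycle"` if, after a settling window, the excitatory
#' rate oscillates with peak-to-trough amplitude above 5% of its mean
#' and at least three full periods are present, `"stable"` otherwise.
#' Oscillations are detected by peak counting on the last half of the
#' stimulus window, which is robust and solver-independent.
#'
#' When a limit cycle is reported, the Hopf condition is cross-checked
#' at the stimulated fixed point of the 3D system (located with
#' [sfa_fixed_point()]): the `hopf_gap` of [sfa_characteristic_poly()]
#' is negative at a stable focus and crosses zero at the Hopf
#' bifurcation, so a positive value there confirms the oscillation
#' arises from an unstable focus encircled by the cycle.
#'
#' @inheritParams simulate_ensemble
#' @param mech A [mech_sfa()] object.
#' @param settle Settling window in seconds discarded at stimulus onset
#'   before oscillation analysis (default 1).
#' @return List with `class`, `oscillation_frequency` (Hz, NA unless a
#'   limit cycle), `amplitude_ratio`, `hopf_gap`, and the trajectory.
#' @export
classify_sfa_dynamics <- function(weights, params, gain, mech, protocol,
                                  duration = NULL, dt = 1e-4,
                                  settle = 1) {
  stopifnot(inherits(mech, "mechanism"))
  if (mech$variant != "sfa") stop("mech must be an SFA configuration")
  if (length(protocol$episodes) == 0)
    stop("protocol must include a stimulation episode")
  ep <- protocol$episodes[[1]]
  if (ep$t_end - ep$t_start <= settle)
    stop("stimulus window must be longer than the settling window")
  if (is.null(duration)) duration <- ep$t_end + 1

  tr <- simulate_ensemble(weights, params, gain, mech, protocol,
                          duration = duration, dt = dt)
  if (tr$diverged &&
      (is.na(tr$divergence_time) || tr$divergence_time <= ep$t_end)) {
    return(list(class = "runaway", oscillation_frequency = NA_real_,
                amplitude_ratio = NA_real_, hopf_gap = NA_real_,
                trajectory = tr))
  }
  # analyse the last 50% of the stimulus window, after settling
  t0 <- max(ep$t_start + settle, (ep$t_start + ep$t_end) / 2)
  idx <- tr$t >= t0 & tr$t < ep$t_end
  rE <- tr$rE[idx]; tt <- tr$t[idx]
  amp <- (max(rE) - min(rE)) / max(mean(rE), .Machine$double.eps)

  # interior strict local maxima above the midline
  mid <- (max(rE) + min(rE)) / 2
  n <- length(rE)
  pk <- which(rE[2:(n - 1)] > rE[1:(n - 2)] &
                rE[2:(n - 1)] >= rE[3:n]) + 1L
  pk <- pk[rE[pk] > mid]
  # collapse plateau-adjacent detections
  if (length(pk) > 1) pk <- pk[c(TRUE, diff(tt[pk]) > 10 * dt)]

  if (amp > 0.05 && length(pk) >= 3) {
    freq <- 1 / mean(diff(tt[pk]))
    gE_stim <- params$gE + if (is.null(ep$delta_gE)) 0 else ep$delta_gE
    gI_stim <- params$gI + if (is.null(ep$delta_gI)) 0 else ep$delta_gI
    fp <- sfa_fixed_point(weights, params, gain, mech$b, gE_stim, gI_stim)
    hopf <- if (is.null(fp)) NA_real_ else
      sfa_characteristic_poly(weights, params, gain, mech$b, mech$tau_a,
                              fp$rE_gain, fp$rI)$hopf_gap
    return(list(class = "limit_cycle", oscillation_frequency = freq,
                amplitude_ratio = amp, hopf_gap = hopf, trajectory = tr))
  }
  list(class = "stable", oscillation_frequency = NA_real_,
       amplitude_ratio = amp, hopf_gap = NA_real_, trajectory = tr)
}

#' Classification sweep over adaptation strengths
#'
#' Runs [classify_sfa_dynamics()] for each value of a `b` grid with the
#' canonical stimulation protocol.
#'
#' @inheritParams classify_sfa_dynamics
#' @param b_grid Numeric grid of adaptation strengths.
#' @param tau_a Adaptation time constant (s).
#' @return Data frame with columns `b`, `class`,
#'   `oscillation_frequency`.
#' @export
sfa_classification_sweep <- function(weights, params, gain, b_grid,
                                     tau_a = 0.2, protocol, dt = 1e-4) {
  rows <- lapply(b_grid, function(b) {
    cl <- classify_sfa_dynamics(weights, params, gain,
                                mech_sfa(b = b, tau_a = tau_a),
                                protocol, dt = dt)
    data.frame(b = b, class = cl$class,
               oscillation_frequency = cl$oscillation_frequency)
  })
  do.call(rbind, rows)
}
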
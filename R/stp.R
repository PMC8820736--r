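#' Steady state of a short-term plasticity variable
#'
#' Closed-form steady state of the depression or facilitation variable
#' when the presynaptic excitatory rate is held at `rE`:
#' `x* = 1 / (1 + Ud*rE*tau_x)` for STD and
#' `u* = (1 + Uf*Umax*rE*tau_u) / (1 + Uf*rE*tau_u)` for STF.
#'
#' @param mech A [mech_std()] or [mech_stf()] object.
#' @param rE Presynaptic excitatory rate (Hz, >= 0). Vectorized.
#' @return Steady-state variable value(s).
#' @examples
#' stp_steady_state(mech_std(Ud = 1, tau_x = 0.2), 20)              # 0.2
#' stp_steady_state(mech_stf(Uf = 1, Umax = 6, tau_u = 0.2), 20)    # 5
#' @export
stp_steady_state <- function(mech, rE) {
  stopifnot(inherits(mech, "mechanism"))
  if (any(rE < 0)) stop("rE must be >= 0")
  switch(mech$variant,
    std = 1 / (1 + mech$Ud * rE * mech$tau_x),
    stf = (1 + mech$Uf * mech$Umax * rE * mech$tau_u) /
      (1 + mech$Uf * rE * mech$tau_u),
    stop("mech must be an STD or STF configuration"))
}

#' Simulate a short-term plasticity variable under clamped rate
#'
#' Euler-integrates only the STP variable with the presynaptic rate held
#' constant, e.g. to check convergence to the closed-form steady state.
#'
#' @inheritParams stp_steady_state
#' @param rE Clamped rate (Hz).
#' @param duration,dt Simulation time and step (s).
#' @param init Initial value (default: rest value 1).
#' @return List with `t` and `aux`.
#' @export
simulate_stp_clamped <- function(mech, rE, duration, dt = 1e-4, init = 1) {
  stopifnot(inherits(mech, "mechanism"),
            mech$variant %in% c("std", "stf"))
  n <- as.integer(round(duration / dt))
  aux <- numeric(n)
  v <- init
  if (mech$variant == "std") {
    for (i in seq_len(n)) {
      aux[i] <- v
      v <- v + dt * ((1 - v) / mech$tau_x - mech$Ud * v * rE)
      v <- min(max(v, 1e-12), 1)
    }
  } else {
    for (i in seq_len(n)) {
      aux[i] <- v
      v <- v + dt * ((1 - v) / mech$tau_u + mech$Uf * (mech$Umax - v) * rE)
      v <- min(max(v, 1), mech$Umax)
    }
  }
  list(t = (seq_len(n) - 1) * dt, aux = aux)
}

#' Jacobian of the ensemble with E-to-E short-term depression
#'
#' The 3D system (rE, rI, x) in which the depression variable scales the
#' E-to-E weight inside the excitatory bracket. With
#' `kE = alphaE * rE^((alphaE-1)/alphaE)` the rows are
#' `[(x*JEE*kE - 1)/tauE, -JEI*kE/tauE, JEE*rE*kE/tauE]`,
#' `[JIE*kI/tauI, -(1 + JII*kI)/tauI, 0]`,
#' `[-Ud*x, 0, -1/tau_x - Ud*rE]`.
#' The characteristic-polynomial pieces (trace, principal-cofactor sum,
#' determinant) are returned alongside; by Descartes' rule all three
#' keep stabilizing signs in the large-`rE` limit with `x = x*(rE)`,
#' which is why depression re-stabilizes runaway excitation at a fixed
#' point (unlike adaptation).
#'
#' @inheritParams jacobian_2d
#' @param mech A [mech_std()] object.
#' @param x Depression variable in (0, 1].
#' @return An `nta_jacobian` with 3x3 `entries` plus fields `tr`,
#'   `cofactor_sum`, `det`.
#' @export
jacobian_std_3d <- function(weights, params, gain, mech, rE, rI, x) {
  stopifnot(inherits(mech, "mechanism"))
  if (mech$variant != "std") stop("mech must be an STD configuration")
  if (x <= 0 || x > 1) stop("x must lie in (0, 1]")
  if (rE < 0 || rI < 0) stop("rates must be >= 0")
  kE <- gain_slope(rE, gain$alphaE)
  kI <- gain_slope(rI, gain$alphaI)
  tE <- 1 / params$tauE; tI <- 1 / params$tauI
  JEE <- weights$JEE; JEI <- weights$JEI
  JIE <- weights$JIE; JII <- weights$JII
  M <- matrix(c(
    tE * (x * JEE * kE - 1), -tE * JEI * kE, tE * JEE * rE * kE,
    tI * JIE * kI, -tI * (1 + JII * kI), 0,
    -mech$Ud * x, 0, -1 / mech$tau_x - mech$Ud * rE),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("rE", "rI", "x"), c("rE", "rI", "x")))
  dx <- 1 / mech$tau_x + mech$Ud * rE
  tr <- tE * (x * JEE * kE - 1) - tI * (1 + JII * kI) - dx
  A11 <- tI * (1 + JII * kI) * dx
  A22 <- tE * (x * JEE * kE - 1) * (-dx) -
    tE * JEE * rE * kE * (-mech$Ud * x)
  A33 <- -tE * (x * JEE * kE - 1) * tI * (1 + JII * kI) +
    tE * JEI * kE * tI * JIE * kI
  det <- tE * (x * JEE * kE - 1) * tI * (1 + JII * kI) * dx -
    tE * JEI * kE * tI * JIE * kI * dx -
    tE * JEE * rE * kE * mech$Ud * x * tI * (1 + JII * kI)
  structure(list(entries = M, eigenvalues = eigen(M)$values,
                 tr = tr, cofactor_sum = A11 + A22 + A33, det = det,
                 context = list(rE = rE, rI = rI, x = x)),
            class = "nta_jacobian")
}

#' Characteristic function with depressed E-to-E weights
#'
#' The frozen-x reduction: because the depression variable changes
#' slowly relative to the rates, it can be held at a constant value
#' `x`, which rescales `JEE` and hence the effective determinant
#' `det(J_STD) = -x*JEE*JII + JIE*JEI`. Depression can flip this sign,
#' bending the characteristic function downward at large `z` and
#' creating the stable stimulated fixed point that terminates the onset
#' transient. At `x = 1` this reduces exactly to
#' [characteristic_function()].
#'
#' @inheritParams characteristic_function
#' @param x Depression factor in (0, 1].
#' @return A `characteristic_curve`.
#' @export
characteristic_function_std <- function(weights, params, gain, gE, gI,
                                        x, z_grid) {
  if (x <= 0 || x > 1) stop("x must lie in (0, 1]")
  characteristic_function(weights, params, gain, gE, gI, z_grid, x = x)
}

#' ISN index of the ensemble with E-to-E STD
#'
#' The largest real part of the eigenvalues of the frozen-inhibition
#' Jacobian `M1` (the 2x2 rE/x subsystem). A positive value means the
#' excitatory subnetwork with its depression dynamics is unstable
#' without inhibition: the ensemble is inhibition stabilized.
#'
#' @inheritParams jacobian_std_3d
#' @return The scalar ISN index (1/s). Vectorized over `rE` and `x` of
#'   equal length.
#' @export
isn_index_std <- function(weights, params, gain, mech, rE, x) {
  kE <- gain_slope(rE, gain$alphaE)
  a <- (x * weights$JEE * kE - 1) / params$tauE
  cc <- 1 / mech$tau_x + mech$Ud * rE
  disc <- as.complex(0.25 * (a + cc)^2 -
    weights$JEE * kE * rE * mech$Ud * x / params$tauE)
  Re((a - cc) / 2 + sqrt(disc))
}

#' ISN and paradoxical-effect analysis for E-to-E STD
#'
#' Evaluates, at a reference state `(rE, x)` (inhibitory rate `rI_ref`
#' for the nullcline slopes), the analytic regime conditions of the
#' depressed ensemble:
#'
#' * ISN: instability of the frozen-inhibition subsystem `M1`, via
#'   `x > min(1/(JEE*kE), (tau_x + tauE + tauE*tau_x*Ud*rE)/(tau_x*JEE*kE))`
#'   with `kE = alphaE * rE^((alphaE-1)/alphaE)`; the index itself is
#'   [isn_index_std()].
#' * Paradoxical response (inhibitory rate decreasing under excitatory
#'   drive to the inhibitory population): requires a positive excitatory
#'   nullcline slope at the fixed point, `x > 1/(JEE*kE)`, together with
#'   the slope-ordering condition (inhibitory nullcline steeper than
#'   excitatory in the rE/rI plane, with the depression variable at its
#'   steady state). The ordering condition coincides with the
#'   determinant stability condition of the 3D system, so it holds at
#'   any stable fixed point; it is evaluated explicitly here rather
#'   than assumed, and reported as `slope_condition`.
#'
#' The paradoxical region is therefore a subset of the ISN region:
#' having a paradoxical response implies inhibition stabilization, but
#' not conversely.
#'
#' @inheritParams jacobian_std_3d
#' @param rE Reference excitatory rate (> 0).
#' @param x Depression variable in (0, 1].
#' @param rI_ref Reference inhibitory rate for the nullcline slopes
#'   (default 1).
#' @return List with `isn`, `isn_index`, `paradoxical`,
#'   `paradox_threshold` (the x threshold), `isn_threshold`,
#'   `slope_condition`, `kE_nullcline`, `kI_nullcline`.
#' @export
isn_paradox_analysis_std <- function(weights, params, gain, mech, rE, x,
                                     rI_ref = 1) {
  if (rE <= 0) stop("rE must be positive")
  if (x <= 0 || x > 1) stop("x must lie in (0, 1]")
  kE <- gain_slope(rE, gain$alphaE)
  kI <- gain_slope(rI_ref, gain$alphaI)
  JEE <- weights$JEE; JEI <- weights$JEI
  JIE <- weights$JIE; JII <- weights$JII
  tauE <- params$tauE; tau_x <- mech$tau_x; Ud <- mech$Ud

  isn_threshold <- min(1 / (JEE * kE),
                       (tau_x + tauE + tauE * tau_x * Ud * rE) /
                         (tau_x * JEE * kE))
  paradox_threshold <- 1 / (JEE * kE)

  # nullcline slopes in the rE/rI plane, depression at steady state
  s <- 1 + tau_x * Ud * rE
  kE_null <- (1 / JEI) * (-JEE * tau_x * Ud * rE / s^2 + JEE / s -
                            (1 / gain$alphaE) * rE^(1 / gain$alphaE - 1))
  kI_null <- JIE / (JII + (1 / gain$alphaI) *
                      rI_ref^((1 - gain$alphaI) / gain$alphaI))

  dx <- 1 / tau_x + Ud * rE
  lhs <- JEI * kE * JIE * kI * dx
  rhs <- (1 + JII * kI) *
    (-JEE * Ud * rE / s * kE + JEE / s * kE * dx - dx)
  slope_condition <- lhs > rhs

  idx <- isn_index_std(weights, params, gain, mech, rE, x)
  list(isn = x > isn_threshold,
       isn_index = idx,
       paradoxical = (x > paradox_threshold) && slope_condition,
       paradox_threshold = paradox_threshold,
       isn_threshold = isn_threshold,
       slope_condition = slope_condition,
       kE_nullcline = kE_null,
       kI_nullcline = kI_null)
}

#' Regime map over (JEE, x) for E-to-E STD
#'
#' Evaluates [isn_paradox_analysis_std()] on a grid, at the reference
#' rate (default `rE = 1`).
#'
#' @inheritParams isn_paradox_analysis_std
#' @param JEE_grid,x_grid Numeric grids (x values in (0, 1]).
#' @return Data frame with columns `JEE`, `x`, `isn`, `paradoxical`,
#'   `isn_index`.
#' @export
std_regime_map <- function(weights, params, gain, mech, JEE_grid, x_grid,
                           rE = 1, rI_ref = 1) {
  out <- expand.grid(JEE = JEE_grid, x = x_grid)
  out$isn <- NA; out$paradoxical <- NA; out$isn_index <- NA_real_
  for (i in seq_len(nrow(out))) {
    w <- ensemble_weights(out$JEE[i], weights$JIE, weights$JEI,
                          weights$JII)
    a <- isn_paradox_analysis_std(w, params, gain, mech, rE, out$x[i],
                                  rI_ref = rI_ref)
    out$isn[i] <- a$isn
    out$paradoxical[i] <- a$paradoxical
    out$isn_index[i] <- a$isn_index
  }
  out
}

#' ISN index along an STD trajectory
#'
#' Evaluates [isn_index_std()] along `(rE(t), x(t))` of a simulated
#' trajectory and reports sign changes, tracking how stimulation can
#' move an ensemble from the non-ISN into the ISN regime and back.
#'
#' @param trajectory A `rate_trajectory` from an STD simulation.
#' @inheritParams jacobian_std_3d
#' @return Data frame with columns `t`, `isn_index`, `isn`; attribute
#'   `sign_changes` holds the crossing times.
#' @export
isn_trajectory_index <- function(trajectory, weights, params, gain, mech) {
  stopifnot(inherits(trajectory, "rate_trajectory"))
  if (trajectory$variant != "std")
    stop("trajectory must come from an STD simulation")
  idx <- isn_index_std(weights, params, gain, mech,
                       trajectory$rE, trajectory$aux)
  sgn <- sign(idx)
  ch <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  out <- data.frame(t = trajectory$t, isn_index = idx, isn = idx > 0)
  attr(out, "sign_changes") <- trajectory$t[ch]
  out
}
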
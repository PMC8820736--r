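#' Power-law gain parameters
#'
#' Exponents of the rectified power-law input-output functions of the
#' excitatory and inhibitory populations. The supralinear regime that
#' supports input-dependent stability requires exponents above one; the
#' canonical choice is a rectified quadratic (`alphaE = alphaI = 2`).
#'
#' @param alphaE Exponent of the excitatory input-output function (> 0).
#' @param alphaI Exponent of the inhibitory input-output function (> 0).
#' @return An object of class `gain_params`.
#' @examples
#' gain_params()          # rectified quadratic
#' gain_params(1, 1)      # linear network
#' @export
gain_params <- function(alphaE = 2, alphaI = 2) {
  stopifnot(is.numeric(alphaE), length(alphaE) == 1L,
            is.numeric(alphaI), length(alphaI) == 1L)
  if (alphaE <= 0 || alphaI <= 0)
    stop("gain exponents must be positive")
  structure(list(alphaE = alphaE, alphaI = alphaI), class = "gain_params")
}

#' Synaptic weight magnitudes of a single E/I ensemble
#'
#' Magnitudes of the four population-level synaptic couplings. Signs are
#' applied inside the rate equations (inhibitory weights enter with a
#' minus sign), so all entries must be non-negative.
#'
#' @param JEE E-to-E connection strength.
#' @param JIE E-to-I connection strength.
#' @param JEI I-to-E connection strength.
#' @param JII I-to-I connection strength.
#' @return An object of class `ensemble_weights`.
#' @seealso [weights_det()] for the signed determinant that controls
#'   whether the ensemble can generate positive-feedback dynamics.
#' @export
ensemble_weights <- function(JEE, JIE, JEI, JII) {
  w <- c(JEE = JEE, JIE = JIE, JEI = JEI, JII = JII)
  if (!all(is.finite(w)) || any(w < 0))
    stop("all weight magnitudes must be finite and >= 0")
  structure(as.list(w), class = "ensemble_weights")
}

#' Determinant of the signed ensemble weight matrix
#'
#' The weight matrix of the compound system is
#' `[[JEE, -JEI], [JIE, -JII]]`, whose determinant
#' `det(J) = -JEE*JII + JIE*JEI` determines whether recurrent excitation
#' can outrun feedback inhibition: ensembles with `det(J) < 0` admit
#' positive-feedback runaway above a critical input, whereas `det(J) > 0`
#' with fast inhibition guarantees stability at any input.
#'
#' @param weights An [ensemble_weights()] object.
#' @return The scalar determinant.
#' @export
weights_det <- function(weights) {
  stopifnot(inherits(weights, "ensemble_weights"))
  -weights$JEE * weights$JII + weights$JIE * weights$JEI
}

#' Rate-dynamics parameters
#'
#' Time constants and external drives of the two populations. Internal
#' units are seconds and Hz throughout; millisecond table values must be
#' converted on entry (see [nta_preset()], which does this for you).
#'
#' @param tauE,tauI Time constants of the excitatory/inhibitory rate
#'   dynamics, in seconds (> 0).
#' @param gE,gI External inputs to the excitatory/inhibitory population
#'   (dimensionless drive).
#' @param rate_cap Optional maximum firing rate in Hz applied to the gain
#'   output (`NULL` for the unbounded power law).
#' @return An object of class `rate_params`.
#' @export
rate_params <- function(tauE = 0.020, tauI = 0.010, gE = 0, gI = 0,
                        rate_cap = NULL) {
  if (tauE <= 0 || tauI <= 0) stop("time constants must be positive")
  if (!is.null(rate_cap)) {
    stopifnot(is.numeric(rate_cap), length(rate_cap) == 1L)
    if (rate_cap <= 0) stop("rate_cap must be positive")
  }
  structure(list(tauE = tauE, tauI = tauI, gE = gE, gI = gI,
                 rate_cap = rate_cap), class = "rate_params")
}

#' Stabilization mechanism configurations
#'
#' Select the slow negative-feedback process coupled to the rate
#' dynamics: none, spike-frequency adaptation (SFA), E-to-E short-term
#' depression (STD), or E-to-I short-term facilitation (STF).
#'
#' SFA adds an adaptation current `a` with `tau_a da/dt = -a + b*rE`.
#' STD multiplies the E-to-E weight by a depression variable
#' `x` in (0, 1] with `dx/dt = (1-x)/tau_x - Ud*x*rE`.
#' STF multiplies the E-to-I weight by a facilitation variable
#' `u` in \[1, Umax\] with `du/dt = (1-u)/tau_u + Uf*(Umax-u)*rE`.
#'
#' @param b Adaptation strength (>= 0).
#' @param tau_a Adaptation time constant in seconds (> 0).
#' @param Ud Depression rate (> 0).
#' @param tau_x Depression time constant in seconds (> 0).
#' @param Uf Facilitation rate (> 0).
#' @param Umax Maximal facilitation value (>= 1).
#' @param tau_u Facilitation time constant in seconds (> 0).
#' @return An object of class `mechanism` with a `variant` field in
#'   `{"none", "sfa", "std", "stf"}`.
#' @name mechanism
NULL

#' @rdname mechanism
#' @export
mech_none <- function() {
  structure(list(variant = "none"), class = "mechanism")
}

#' @rdname mechanism
#' @export
mech_sfa <- function(b = 1.0, tau_a = 0.200) {
  if (b < 0) stop("adaptation strength b must be >= 0")
  if (tau_a <= 0) stop("tau_a must be positive")
  structure(list(variant = "sfa", b = b, tau_a = tau_a), class = "mechanism")
}

#' @rdname mechanism
#' @export
mech_std <- function(Ud = 1.0, tau_x = 0.200) {
  if (Ud <= 0) stop("depression rate Ud must be positive")
  if (tau_x <= 0) stop("tau_x must be positive")
  structure(list(variant = "std", Ud = Ud, tau_x = tau_x), class = "mechanism")
}

#' @rdname mechanism
#' @export
mech_stf <- function(Uf = 1.0, Umax = 6.0, tau_u = 0.200) {
  if (Uf <= 0) stop("facilitation rate Uf must be positive")
  if (Umax < 1) stop("Umax must be >= 1")
  if (tau_u <= 0) stop("tau_u must be positive")
  structure(list(variant = "stf", Uf = Uf, Umax = Umax, tau_u = tau_u),
            class = "mechanism")
}

#' Stimulation protocol
#'
#' A protocol is a set of stimulation episodes (additive changes of the
#' external drives during a time window) plus optional probes that
#' override parts of the dynamics:
#'
#' * `inactivate_inhibition(t0, t1)`: clamp `rI` to zero in the window.
#' * `freeze_inhibition(t0, t1)`: hold `rI` at its pre-probe value.
#' * `perturb_rE(t, magnitude)`: one-off additive kick to `rE` at time t.
#' * `inject_to_I(t0, t1, magnitude)`: additional drive to the inhibitory
#'   population during the window (the paradoxical-effect probe).
#'
#' @param episodes A list of episodes, each a list with fields
#'   `t_start`, `t_end` (seconds) and `delta_gE`, `delta_gI`
#'   (additive drives, default 0).
#' @param probes Optional list of probes, each a list with a `type` field
#'   naming one of the probes above and the corresponding time/magnitude
#'   fields (`t0`, `t1`, `t`, `magnitude`).
#' @return An object of class `stim_protocol`.
#' @examples
#' stim_protocol(list(list(t_start = 2, t_end = 4, delta_gE = 1.45)))
#' @export
stim_protocol <- function(episodes = list(), probes = list()) {
  for (ep in episodes) {
    if (is.null(ep$t_start) || is.null(ep$t_end) || ep$t_start >= ep$t_end)
      stop("each episode needs t_start < t_end")
  }
  valid <- c("inactivate_inhibition", "freeze_inhibition",
             "perturb_rE", "inject_to_I")
  for (pr in probes) {
    if (is.null(pr$type) || !pr$type %in% valid)
      stop("unknown probe type: ", pr$type)
    if (pr$type %in% c("inactivate_inhibition", "freeze_inhibition",
                       "inject_to_I")) {
      if (is.null(pr$t0) || is.null(pr$t1) || pr$t0 >= pr$t1)
        stop("probe ", pr$type, " needs t0 < t1")
    }
    if (pr$type == "perturb_rE" &&
        (is.null(pr$t) || is.null(pr$magnitude)))
      stop("perturb_rE probe needs fields t and magnitude")
    if (pr$type == "inject_to_I" && is.null(pr$magnitude))
      stop("inject_to_I probe needs field magnitude")
  }
  structure(list(episodes = episodes, probes = probes),
            class = "stim_protocol")
}

#' @export
print.ensemble_weights <- function(x, ...) {
  cat("E/I ensemble weights: JEE =", x$JEE, " JIE =", x$JIE,
      " JEI =", x$JEI, " JII =", x$JII, "\n")
  cat("det(J) =", weights_det(x), "\n")
  invisible(x)
}
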
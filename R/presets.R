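#' Published parameter presets
#'
#' Named parameter sets used throughout the package's worked examples and
#' protocol runner. Time constants are converted from milliseconds to
#' seconds on load; everything downstream works in seconds and Hz.
#'
#' Available presets:
#' * `"ensemble"` - the canonical single E/I ensemble with strong
#'   recurrent excitation (`det(J) < 0`): weights (1.8, 1.0, 1.0, 0.6),
#'   `tauE` = 20 ms, `tauI` = 10 ms, baseline `gE` = 1.55, stimulation
#'   `gE` = 3.0, `gI` = 2.0.
#' * `"ensemble_map"` - variant used for the (JEE, gE) regime map:
#'   `JIE` = 0.45, `JEI` = 1.0, `JII` = 1.5.
#' * `"mechanism"` - slow-variable defaults: `tau_a` = 200 ms, `b` = 1.0,
#'   `tau_x` = 200 ms, `Ud` = 1.0, `tau_u` = 200 ms, `Uf` = 1.0,
#'   `Umax` = 6.0.
#' * `"two_ensemble_attractor"` - two-ensemble network with effectively
#'   global inhibition; `JEE` = 1.4 yields bi/multi-stable dynamics and
#'   the listed `JEE_uni` = 1.3 / `JEEp_uni` = 0.13 the uni-stable one.
#' * `"two_ensemble_cotuned"` - co-tuned two-ensemble network used for
#'   pattern completion/separation, per-connection weights with
#'   `NE` = 200, `NI` = 50.
#' * `"spiking"` - conductance-based LIF network defaults
#'   (`NE` = 400, `NI` = 100; see [spiking_params()]).
#'
#' @param name Preset name.
#' @return A named list of parameters (structure depends on the preset).
#' @export
nta_preset <- function(name = c("ensemble", "ensemble_map", "mechanism",
                                "two_ensemble_attractor",
                                "two_ensemble_cotuned", "spiking")) {
  name <- match.arg(name)
  switch(name,
    ensemble = list(
      weights = ensemble_weights(JEE = 1.8, JIE = 1.0, JEI = 1.0, JII = 0.6),
      gain = gain_params(2, 2),
      params = rate_params(tauE = 0.020, tauI = 0.010, gE = 1.55, gI = 2.0),
      gE_baseline = 1.55, gE_stim = 3.0, gI = 2.0),
    ensemble_map = list(
      weights = ensemble_weights(JEE = 1.8, JIE = 0.45, JEI = 1.0, JII = 1.5),
      gain = gain_params(2, 2),
      params = rate_params(tauE = 0.020, tauI = 0.010, gE = 1.55, gI = 2.0)),
    mechanism = list(
      sfa = mech_sfa(b = 1.0, tau_a = 0.200),
      std = mech_std(Ud = 1.0, tau_x = 0.200),
      stf = mech_stf(Uf = 1.0, Umax = 6.0, tau_u = 0.200)),
    two_ensemble_attractor = list(
      weights = two_ensemble_weights(
        JEE = 1.4, JIE = 0.6, JEI = 1.0, JII = 0.6,
        JEEp = 0.14, JIEp = 0.6, JEIp = 1.0, JIIp = 0.6),
      weights_uni = two_ensemble_weights(
        JEE = 1.3, JIE = 0.6, JEI = 1.0, JII = 0.6,
        JEEp = 0.13, JIEp = 0.6, JEIp = 1.0, JIIp = 0.6),
      gain = gain_params(2, 2),
      tauE = 0.020, tauI = 0.010,
      gE1_baseline = 2.2, gE1_stim = 3.0, gE2 = 2.2, gI = 2.0),
    two_ensemble_cotuned = list(
      NE = 200, NI = 50,
      weights = two_ensemble_weights(
        JEE = 1.2 / 99, JIE = 1.0 / 100, JEI = 1.0 / 25, JII = 1.0 / 24,
        JEEp = 0.36 / 99, JIEp = 0.4 / 100, JEIp = 0.1 / 25,
        JIIp = 0.1 / 25, per_connection = TRUE, NE = 200, NI = 50),
      gain = gain_params(2, 2),
      tauE = 0.020, tauI = 0.010,
      gE1_baseline = 1.35, gE1_stim = 4.0, gE2 = 1.35, gI = 2.0),
    spiking = spiking_params())
}
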
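#' Run a named reproduction protocol
#'
#' One-call reproductions of the canonical experiments, each wired to
#' the published parameter presets (see [nta_preset()]) with seeding
#' and optional overrides. Available protocols:
#'
#' * `"fig1c"` - single ensemble, no mechanism: runaway under
#'   stimulation (gE 1.55 -> 3.0 during 2-4 s).
#' * `"fig1f"` - (JEE, gE) regime scan of fixed-point structure.
#' * `"fig2a"` - SFA classification at weak (and a strong) adaptation.
#' * `"fig2b"` - E-to-E STD: onset transient, stimulated fixed point,
#'   return to baseline; plus the inhibition-inactivated variant.
#' * `"fig2e"` - E-to-I STF version of fig2b.
#' * `"fig2g"` - (JEE, x) ISN/paradoxical regime map at rE = 1.
#' * `"fig2h"` - paradoxical-effect probes at baseline and during
#'   stimulation.
#' * `"fig3b"` - two-ensemble attractor demo (bi/multi-stable JEE = 1.4
#'   vs uni-stable JEE = 1.3).
#' * `"fig3c"` - uni-stability maps for global and co-tuned inhibition
#'   (k = 0.1, m = 0.5, b*c = 0.9*a*d).
#' * `"fig4"` - pattern completion / selectivity: subset stimulation
#'   across a gE1 grid, Association index and decision distance for
#'   onset vs fixed point.
#' * `"fig5"` - morphing experiment across p.
#' * `"fig6"` - spiking network, five overlapping ensembles.
#'
#' @param protocol Protocol name.
#' @param overrides Named list of protocol-specific overrides (e.g.
#'   `duration`, `dt`, `seed`, weight or drive values).
#' @param seed Integer seed for any randomness.
#' @param outdir Optional directory: results are additionally written
#'   as CSV/JSON files.
#' @param dt Euler step (s).
#' @return A named list of results (protocol-specific), invisibly also
#'   written to `outdir` when given.
#' @export
run_protocol <- function(protocol, overrides = list(), seed = 1,
                         outdir = NULL, dt = 1e-4) {
  known <- c("fig1c", "fig1f", "fig2a", "fig2b", "fig2e", "fig2g",
             "fig2h", "fig3b", "fig3c", "fig4", "fig5", "fig6")
  if (!protocol %in% known)
    stop("unknown protocol: ", protocol,
         " (known: ", paste(known, collapse = ", "), ")")
  ov <- function(name, default)
    if (!is.null(overrides[[name]])) overrides[[name]] else default

  ps <- nta_preset("ensemble")
  mechs <- nta_preset("mechanism")
  stim_default <- stim_protocol(list(list(
    t_start = 2, t_end = 4,
    delta_gE = ps$gE_stim - ps$gE_baseline)))

  out <- switch(protocol,
    fig1c = {
      tr <- simulate_ensemble(ps$weights, ps$params, ps$gain,
                              mech_none(), stim_default,
                              duration = ov("duration", 6), dt = dt)
      list(trajectory = tr)
    },
    fig1f = {
      scan <- regime_scan_2d(ps$weights, ps$params, ps$gain,
                             gI = ps$gI,
                             JEE_grid = ov("JEE_grid",
                                           seq(1.0, 2.4, by = 0.1)),
                             gE_grid = ov("gE_grid",
                                          seq(0.5, 3.5, by = 0.25)))
      list(scan = scan)
    },
    fig2a = {
      prot <- stim_protocol(list(list(t_start = 2, t_end = 6,
                                      delta_gE = 1.45)))
      weak <- classify_sfa_dynamics(ps$weights, ps$params, ps$gain,
                                    mechs$sfa, prot, duration = 7,
                                    dt = dt)
      strong <- classify_sfa_dynamics(ps$weights, ps$params, ps$gain,
                                      mech_sfa(b = ov("b_strong", 200),
                                               tau_a = 0.2),
                                      prot, duration = 7, dt = dt)
      list(weak = weak, strong = strong)
    },
    fig2b = {
      tr <- simulate_ensemble(ps$weights, ps$params, ps$gain,
                              mechs$std, stim_default,
                              duration = ov("duration", 6), dt = dt)
      prot_inact <- stim_protocol(
        list(list(t_start = 2, t_end = 4, delta_gE = 1.45)),
        list(list(type = "inactivate_inhibition", t0 = 2.5, t1 = 3.5)))
      tr_inact <- simulate_ensemble(ps$weights, ps$params, ps$gain,
                                    mechs$std, prot_inact,
                                    duration = 6, dt = dt)
      list(trajectory = tr, inactivated = tr_inact)
    },
    fig2e = {
      tr <- simulate_ensemble(ps$weights, ps$params, ps$gain,
                              mechs$stf, stim_default,
                              duration = ov("duration", 6), dt = dt)
      prot_inact <- stim_protocol(
        list(list(t_start = 2, t_end = 4, delta_gE = 1.45)),
        list(list(type = "inactivate_inhibition", t0 = 2.5, t1 = 3.5)))
      tr_inact <- simulate_ensemble(ps$weights, ps$params, ps$gain,
                                    mechs$stf, prot_inact,
                                    duration = 6, dt = dt)
      list(trajectory = tr, inactivated = tr_inact)
    },
    fig2g = {
      map <- std_regime_map(ps$weights, ps$params, ps$gain, mechs$std,
                            JEE_grid = ov("JEE_grid",
                                          seq(0.1, 3, by = 0.05)),
                            x_grid = ov("x_grid",
                                        seq(0.02, 1, by = 0.02)),
                            rE = ov("rE", 1))
      list(map = map)
    },
    fig2h = {
      base <- stim_protocol(
        list(list(t_start = 6, t_end = 8, delta_gE = 1.45)),
        list(list(type = "inject_to_I", t0 = 2, t1 = 3,
                  magnitude = 0.3)))
      stim <- stim_protocol(
        list(list(t_start = 2, t_end = 6, delta_gE = 1.45)),
        list(list(type = "inject_to_I", t0 = 4, t1 = 5,
                  magnitude = 0.3)))
      list(baseline_probe = simulate_ensemble(
             ps$weights, ps$params, ps$gain, mechs$std, base,
             duration = 9, dt = dt),
           stimulated_probe = simulate_ensemble(
             ps$weights, ps$params, ps$gain, mechs$std, stim,
             duration = 7, dt = dt))
    },
    fig3b = {
      pa <- nta_preset("two_ensemble_attractor")
      eps <- list(list(t_start = 4, t_end = 6, target = "E1",
                       delta_g = pa$gE1_stim - pa$gE1_baseline))
      args <- list(gE1 = pa$gE1_baseline, gE2 = pa$gE2, gI = pa$gI,
                   episodes = eps, mech = mech_std(1, 0.2),
                   init_noise = 1e-3, seed = seed,
                   duration = ov("duration", 9), dt = dt,
                   record_every = 10L)
      list(multistable = do.call(simulate_two_ensembles,
                                 c(list(pa$weights), args)),
           unistable = do.call(simulate_two_ensembles,
                               c(list(pa$weights_uni), args)))
    },
    fig3c = {
      a_grid <- ov("a_grid", seq(0, 150, length.out = 31))
      d_grid <- ov("d_grid", seq(0, 150, length.out = 31))
      list(map = unistability_map(a_grid, d_grid, k = ov("k", 0.1),
                                  m = ov("m", 0.5)))
    },
    fig4 = {
      gE1_grid <- ov("gE1_grid", seq(2.0, 4.0, by = 0.5))
      list(result = pattern_completion_experiment(
        gE1_grid, seed = seed, dt = dt))
    },
    fig5 = {
      p_grid <- ov("p_grid", seq(0, 1, by = 0.25))
      list(result = morphing_experiment(p_grid,
                                        JEE = ov("JEE", 1.2),
                                        dt = dt))
    },
    fig6 = {
      sps <- spiking_params()
      lay <- ensemble_layout(sps, seed = seed)
      sched <- five_ensemble_schedule()
      sp <- simulate_spiking_network(sps, lay, sched,
                                     duration = ov("duration", 26),
                                     dt = dt, seed = seed)
      act <- ensemble_activity(sp)
      list(spikes = sp, activity = act,
           differences = activity_differences(act, sched[1:5], lay),
           pca = pca_variance(sp, c(0, 10)))
    })

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      obj <- out[[nm]]
      f <- file.path(outdir, paste0(protocol, "_", nm))
      if (inherits(obj, "rate_trajectory")) {
        write_trajectory(obj, paste0(f, ".csv"))
      } else if (inherits(obj, "network_trajectory")) {
        utils::write.csv(data.frame(t = obj$t, obj$rates),
                         paste0(f, ".csv"), row.names = FALSE)
      } else if (inherits(obj, "spike_data")) {
        utils::write.csv(obj$events, paste0(f, ".csv"),
                         row.names = FALSE)
      } else if (is.data.frame(obj)) {
        utils::write.csv(obj, paste0(f, ".csv"), row.names = FALSE)
      } else {
        jsonlite::write_json(obj, paste0(f, ".json"),
                             auto_unbox = TRUE, digits = NA,
                             force = TRUE, null = "null")
      }
    }
    snap <- list(protocol = protocol, seed = seed, dt = dt,
                 overrides = overrides)
    jsonlite::write_json(snap,
                         file.path(outdir,
                                   paste0(protocol, "_config.json")),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(out)
}

#' Pattern-completion and selectivity experiment
#'
#' The two-phase partial-cue protocol on the co-tuned two-ensemble
#' network with E-to-E STD: in Phase one (2-4 s) 75% of ensemble E1
#' (Subset 1) receives the extra drive and the Association index is
#' computed from Subset 1 vs Subset 2 activity; in Phase two (6-8 s)
#' all of E1 is stimulated and the distance of `(rE1, rE2)` to the
#' symmetric decision boundary is computed. Both are evaluated at the
#' onset peak and at the fixed point (middle second), for each value of
#' the drive grid.
#'
#' @param gE1_grid Grid of stimulation drives to E1.
#' @param weights,gE_base,gI Network configuration (defaults: the
#'   co-tuned per-connection preset).
#' @param mech Plasticity mechanism (default E-to-E STD).
#' @param seed Seed (unused by the deterministic rate network; kept for
#'   interface symmetry).
#' @param dt Euler step (s).
#' @return Data frame with one row per drive: association/distance at
#'   onset and fixed point.
#' @export
pattern_completion_experiment <- function(gE1_grid = seq(2, 4, by = 0.5),
                                          weights = NULL,
                                          gE_base = 1.35, gI = 2.0,
                                          mech = mech_std(1, 0.2),
                                          seed = 1, dt = 1e-4) {
  pc <- nta_preset("two_ensemble_cotuned")
  if (is.null(weights)) weights <- pc$weights
  rows <- lapply(gE1_grid, function(g1) {
    eps <- list(
      list(t_start = 2, t_end = 4, target = "E1a",
           delta_g = g1 - gE_base),
      list(t_start = 6, t_end = 8, target = "E1",
           delta_g = g1 - gE_base))
    tr <- simulate_two_ensembles(weights, gE1 = gE_base,
                                 gE2 = pc$gE2, gI = gI,
                                 episodes = eps, mech = mech,
                                 subset_split = c(0.75, 0.25),
                                 duration = 9, dt = dt,
                                 record_every = 10L)
    f11 <- extract_features(tr, c(2, 4), pop = "E1a")
    f12 <- extract_features(tr, c(2, 4), pop = "E1b")
    fE1 <- extract_features(tr, c(6, 8), pop = "E1a")
    fE2 <- extract_features(tr, c(6, 8), pop = "E2")
    data.frame(
      gE1 = g1,
      assoc_onset = association_index(f11$onset_peak, f12$onset_peak),
      assoc_fixed = if (f11$fixed_point + f12$fixed_point > 0)
        association_index(f11$fixed_point, f12$fixed_point)
      else NA_real_,
      dist_onset = decision_distance(fE1$onset_peak, fE2$onset_peak),
      dist_fixed = decision_distance(fE1$fixed_point, fE2$fixed_point),
      rE11_onset = f11$onset_peak, rE12_onset = f12$onset_peak,
      rE11_fixed = f11$fixed_point, rE12_fixed = f12$fixed_point)
  })
  do.call(rbind, rows)
}

#' Morphing experiment
#'
#' Interpolates the extra drive between the two ensembles with the
#' morph fraction `p` and records each ensemble's onset peak and
#' fixed-point activity plus the decision-boundary distances.
#'
#' @param p_grid Grid of morph fractions.
#' @param JEE Within-ensemble E-to-E strength (population level); the
#'   inter-ensemble strength is scaled proportionally from the
#'   canonical 1.2/0.36 ratio by default.
#' @param JEEp Optional explicit inter-ensemble strength.
#' @param JIEp Inter-ensemble E-to-I strength factor (population
#'   level, default 0.4).
#' @param mech Plasticity mechanism (default E-to-E STD).
#' @param dt Euler step (s).
#' @return Data frame with one row per `p`.
#' @export
morphing_experiment <- function(p_grid = seq(0, 1, by = 0.25),
                                JEE = 1.2, JEEp = NULL, JIEp = 0.4,
                                mech = mech_std(1, 0.2), dt = 1e-4) {
  pc <- nta_preset("two_ensemble_cotuned")
  if (is.null(JEEp)) JEEp <- JEE * 0.3
  w <- two_ensemble_weights(
    JEE = JEE / 99, JIE = 1.0 / 100, JEI = 1.0 / 25, JII = 1.0 / 24,
    JEEp = JEEp / 99, JIEp = JIEp / 100, JEIp = 0.1 / 25,
    JIIp = 0.1 / 25, per_connection = TRUE, NE = 200, NI = 50)
  rows <- lapply(p_grid, function(p) {
    mp <- morph_beta_params(p, beta = JEE / (JEE + JEEp),
                            Jtot = JEE + JEEp)
    eps <- list(
      list(t_start = 2, t_end = 4, target = "E1",
           delta_g = mp$gE1_stim - 1.35),
      list(t_start = 2, t_end = 4, target = "E2",
           delta_g = mp$gE2_stim - 1.35))
    tr <- simulate_two_ensembles(w, gE1 = 1.35, gE2 = 1.35, gI = 2.0,
                                 episodes = eps, mech = mech,
                                 duration = 5, dt = dt,
                                 record_every = 10L)
    f1 <- extract_features(tr, c(2, 4), pop = "E1")
    f2 <- extract_features(tr, c(2, 4), pop = "E2")
    data.frame(
      p = p,
      peak_E1 = f1$onset_peak, peak_E2 = f2$onset_peak,
      fixed_E1 = f1$fixed_point, fixed_E2 = f2$fixed_point,
      dist_onset = decision_distance(f1$onset_peak, f2$onset_peak),
      dist_fixed = decision_distance(f1$fixed_point, f2$fixed_point))
  })
  do.call(rbind, rows)
}
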
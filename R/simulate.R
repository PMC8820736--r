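#' Simulate a single E/I ensemble with supralinear dynamics
#'
#' Integrates the two-population rate model
#' \deqn{\tau_E \dot r_E = -r_E + [J_{EE} r_E - J_{EI} r_I + g_E]_+^{\alpha_E}}
#' \deqn{\tau_I \dot r_I = -r_I + [J_{IE} r_E - J_{II} r_I + g_I]_+^{\alpha_I}}
#' by fixed-step explicit Euler, optionally coupled to one slow
#' stabilization mechanism (SFA current, E-to-E short-term depression, or
#' E-to-I short-term facilitation; see [mechanism]). The depression
#' variable multiplies `JEE` inside the excitatory rectification bracket;
#' the facilitation variable multiplies `JIE` inside the inhibitory
#' bracket; the SFA current is subtracted outside the excitatory bracket.
#'
#' Stimulation episodes add their `delta_gE`/`delta_gI` to the drives
#' during their windows. Probes override the dynamics (see
#' [stim_protocol()]). An optional `rate_cap` in `params` clips the gain
#' output, leaving sub-cap dynamics untouched. The uncapped supralinear
#' model genuinely diverges in finite time for suprathreshold input, so
#' integration stops cleanly once `rE` exceeds `divergence_bound` (or the
#' state overflows) and the trajectory is flagged.
#'
#' @param weights An [ensemble_weights()] object.
#' @param params A [rate_params()] object (its `gE`, `gI` are the
#'   baseline drives).
#' @param gain A [gain_params()] object.
#' @param mech A [mechanism] object (default none).
#' @param protocol A [stim_protocol()] (default: no stimulation).
#' @param duration Total simulated time in seconds.
#' @param dt Euler time step in seconds (default 1e-4, i.e. 0.1 ms).
#' @param init Optional named list with initial `rE`, `rI`, `aux`
#'   (defaults: 0, 0, and the mechanism rest value, i.e. `a = 0`,
#'   `x = 1`, `u = 1`).
#' @param divergence_bound Firing rate (Hz) above which the trajectory is
#'   declared divergent (default 1e6).
#' @param record_every Store every k-th step (default 1; thinning only
#'   affects the returned arrays, not the integration).
#' @return An object of class `rate_trajectory`: list with `t`, `rE`,
#'   `rI`, `aux` (NULL when `mech` is none), `variant`, `diverged`,
#'   `divergence_time`, and the call parameters.
#' @examples
#' ps <- nta_preset("ensemble")
#' tr <- simulate_ensemble(ps$weights, ps$params, ps$gain,
#'                         duration = 1, dt = 1e-3)
#' tail(tr$rE, 1)  # settles at the low-activity baseline fixed point
#' @export
simulate_ensemble <- function(weights, params, gain, mech = mech_none(),
                              protocol = stim_protocol(),
                              duration, dt = 1e-4, init = NULL,
                              divergence_bound = 1e6, record_every = 1L) {
  stopifnot(inherits(weights, "ensemble_weights"),
            inherits(params, "rate_params"),
            inherits(gain, "gain_params"),
            inherits(mech, "mechanism"),
            inherits(protocol, "stim_protocol"))
  if (dt <= 0) stop("dt must be positive")
  if (duration < dt) stop("duration must be at least dt")

  n_steps <- as.integer(round(duration / dt))
  variant <- mech$variant
  aux_rest <- switch(variant, none = NA_real_, sfa = 0, std = 1, stf = 1)

  rE <- 0; rI <- 0; aux <- aux_rest
  if (!is.null(init)) {
    if (!is.null(init$rE)) rE <- init$rE
    if (!is.null(init$rI)) rI <- init$rI
    if (!is.null(init$aux)) aux <- init$aux
    if (rE < 0 || rI < 0) stop("initial rates must be >= 0")
  }

  # precompute drive time courses and probe masks on the step grid
  tgrid <- (seq_len(n_steps) - 1L) * dt
  gEt <- rep(params$gE, n_steps)
  gIt <- rep(params$gI, n_steps)
  for (ep in protocol$episodes) {
    idx <- tgrid >= ep$t_start & tgrid < ep$t_end
    if (!is.null(ep$delta_gE)) gEt[idx] <- gEt[idx] + ep$delta_gE
    if (!is.null(ep$delta_gI)) gIt[idx] <- gIt[idx] + ep$delta_gI
  }
  inact <- rep(FALSE, n_steps)
  freeze <- rep(FALSE, n_steps)
  kick <- rep(0, n_steps)
  for (pr in protocol$probes) {
    switch(pr$type,
      inactivate_inhibition = {
        inact[tgrid >= pr$t0 & tgrid < pr$t1] <- TRUE
      },
      freeze_inhibition = {
        freeze[tgrid >= pr$t0 & tgrid < pr$t1] <- TRUE
      },
      inject_to_I = {
        idx <- tgrid >= pr$t0 & tgrid < pr$t1
        gIt[idx] <- gIt[idx] + pr$magnitude
      },
      perturb_rE = {
        i <- which(tgrid >= pr$t)[1]
        if (!is.na(i)) kick[i] <- kick[i] + pr$magnitude
      })
  }

  JEE <- weights$JEE; JEI <- weights$JEI
  JIE <- weights$JIE; JII <- weights$JII
  aE <- gain$alphaE; aI <- gain$alphaI
  tauE <- params$tauE; tauI <- params$tauI
  cap <- params$rate_cap

  keep <- seq(1L, n_steps, by = as.integer(record_every))
  n_keep <- length(keep)
  out_rE <- numeric(n_keep); out_rI <- numeric(n_keep)
  out_aux <- if (variant == "none") NULL else numeric(n_keep)
  k_out <- 1L
  next_keep <- keep[1L]

  diverged <- FALSE
  divergence_time <- NA_real_
  rI_frozen <- NA_real_
  last_step <- n_steps

  for (i in seq_len(n_steps)) {
    if (kick[i] != 0) rE <- max(rE + kick[i], 0)

    if (i == next_keep) {
      out_rE[k_out] <- rE; out_rI[k_out] <- rI
      if (!is.null(out_aux)) out_aux[k_out] <- aux
      k_out <- k_out + 1L
      next_keep <- if (k_out <= n_keep) keep[k_out] else NA_integer_
    }

    zE <- switch(variant,
      std = aux * JEE * rE - JEI * rI + gEt[i],
      JEE * rE - JEI * rI + gEt[i])
    zI <- switch(variant,
      stf = aux * JIE * rE - JII * rI + gIt[i],
      JIE * rE - JII * rI + gIt[i])

    phiE <- if (zE > 0) zE^aE else 0
    phiI <- if (zI > 0) zI^aI else 0
    if (!is.null(cap)) {
      phiE <- min(phiE, cap)
      phiI <- min(phiI, cap)
    }
    drE <- (-rE + phiE - if (variant == "sfa") aux else 0) / tauE

    if (inact[i]) {
      rI_new <- 0
    } else if (freeze[i]) {
      if (is.na(rI_frozen)) rI_frozen <- rI
      rI_new <- rI_frozen
    } else {
      rI_frozen <- NA_real_
      rI_new <- rI + dt * (-rI + phiI) / tauI
    }
    rE_new <- rE + dt * drE

    aux_new <- switch(variant,
      none = aux,
      sfa = aux + dt * (-aux + mech$b * rE) / mech$tau_a,
      std = {
        v <- aux + dt * ((1 - aux) / mech$tau_x - mech$Ud * aux * rE)
        min(max(v, 1e-12), 1)
      },
      stf = {
        v <- aux + dt * ((1 - aux) / mech$tau_u +
                           mech$Uf * (mech$Umax - aux) * rE)
        min(max(v, 1), mech$Umax)
      })

    rE <- max(rE_new, 0); rI <- max(rI_new, 0); aux <- aux_new

    if (!is.finite(rE) || !is.finite(rI) || rE > divergence_bound) {
      diverged <- TRUE
      divergence_time <- tgrid[i]
      last_step <- i
      break
    }
  }

  kept <- keep[keep <= last_step & seq_along(keep) < k_out]
  n_final <- length(kept)
  traj <- structure(list(
    t = tgrid[kept],
    rE = out_rE[seq_len(n_final)],
    rI = out_rI[seq_len(n_final)],
    aux = if (is.null(out_aux)) NULL else out_aux[seq_len(n_final)],
    variant = variant,
    diverged = diverged,
    divergence_time = divergence_time,
    dt = dt,
    weights = weights, params = params, gain = gain, mech = mech,
    protocol = protocol),
    class = "rate_trajectory")
  traj
}

#' @export
print.rate_trajectory <- function(x, ...) {
  cat("E/I rate trajectory (", x$variant, "): ",
      length(x$t), " samples over ", signif(max(x$t), 4), " s\n", sep = "")
  if (x$diverged)
    cat("  DIVERGED at t =", signif(x$divergence_time, 6), "s\n")
  else
    cat("  final rE =", signif(utils::tail(x$rE, 1), 6),
        "Hz, rI =", signif(utils::tail(x$rI, 1), 6), "Hz\n")
  invisible(x)
}

#' @export
as.data.frame.rate_trajectory <- function(x, ...) {
  d <- data.frame(t = x$t, rE = x$rE, rI = x$rI)
  if (!is.null(x$aux)) d$aux <- x$aux
  d
}

#' Write a trajectory to CSV with a JSON parameter sidecar
#'
#' The CSV holds columns `t, rE, rI[, aux]`; the sidecar
#' (`<file>.json`) records weights, rate parameters, gain exponents,
#' mechanism, and divergence status for provenance.
#'
#' @param traj A `rate_trajectory`.
#' @param file Output CSV path.
#' @return Invisibly, the sidecar path.
#' @export
write_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "rate_trajectory"))
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE)
  sidecar <- paste0(file, ".json")
  meta <- list(
    weights = unclass(traj$weights),
    params = unclass(traj$params),
    gain = unclass(traj$gain),
    mechanism = unclass(traj$mech),
    dt = traj$dt,
    diverged = traj$diverged,
    divergence_time = traj$divergence_time)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(sidecar)
}
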
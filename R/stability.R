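#' Jacobian of the 2D supralinear ensemble
#'
#' Evaluates the Jacobian of the two-population rate system at a given
#' state. With the gain-derivative factor
#' `k_X = alpha_X * r_X^((alpha_X-1)/alpha_X)` the entries are
#' `M11 = (JEE*kE - 1)/tauE`, `M12 = -JEI*kE/tauE`,
#' `M21 = JIE*kI/tauI`, `M22 = -(1 + JII*kI)/tauI`.
#' At zero rate the derivative factor vanishes for supralinear gain
#' (one-sided convention at the rectification corner), so the silent
#' state has `M = diag(-1/tauE, -1/tauI)`.
#'
#' An optional depression factor `x` scales `JEE` (the frozen-x reduction
#' used by the characteristic-function approximation with E-to-E STD).
#'
#' @param weights,params,gain See [simulate_ensemble()].
#' @param rE,rI Rates (Hz, >= 0) at which to evaluate.
#' @param x Optional E-to-E depression factor in (0, 1] (default 1).
#' @return An object of class `nta_jacobian`: list with `entries` (2x2
#'   matrix), `eigenvalues` (complex), and the evaluation `context`.
#' @export
jacobian_2d <- function(weights, params, gain, rE, rI, x = 1) {
  if (rE < 0 || rI < 0) stop("rates must be >= 0")
  kE <- gain_slope(rE, gain$alphaE)
  kI <- gain_slope(rI, gain$alphaI)
  M <- matrix(c(
    (x * weights$JEE * kE - 1) / params$tauE,
    -weights$JEI * kE / params$tauE,
    weights$JIE * kI / params$tauI,
    -(1 + weights$JII * kI) / params$tauI),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("rE", "rI"), c("rE", "rI")))
  structure(list(entries = M, eigenvalues = eigen(M)$values,
                 context = list(rE = rE, rI = rI, x = x)),
            class = "nta_jacobian")
}

#' Stability conditions of the 2D ensemble
#'
#' Literal evaluation of the two conditions for a stable fixed point:
#' `det(M) > 0` (product of eigenvalues positive) and `tr(M) < 0` (sum
#' negative). For linear gain (`alpha = 1`) the conditions are
#' input-independent; for supralinear gain they depend on the rates and
#' hence on the input.
#'
#' @inheritParams jacobian_2d
#' @return List with `detM_positive`, `trM_negative`, `stable`, and the
#'   numeric `detM`, `trM`.
#' @export
stability_conditions_2d <- function(weights, params, gain, rE, rI, x = 1) {
  J <- jacobian_2d(weights, params, gain, rE, rI, x = x)$entries
  detM <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  trM <- J[1, 1] + J[2, 2]
  list(detM_positive = detM > 0, trM_negative = trM < 0,
       stable = detM > 0 && trM < 0, detM = detM, trM = trM)
}

#' ISN index of the 2D ensemble
#'
#' The real part of the leading eigenvalue of the excitatory-to-
#' excitatory subnetwork Jacobian,
#' `tauE^-1 * (JEE * alphaE * rE^((alphaE-1)/alphaE) - 1)`.
#' A positive index means the excitatory subnetwork is unstable on its
#' own and requires feedback inhibition: the ensemble is an
#' inhibition-stabilized network (ISN). For supralinear gain the index is
#' rate-dependent, so inputs can switch an ensemble from non-ISN to ISN;
#' for linear gain it is rate-independent.
#'
#' @inheritParams jacobian_2d
#' @return The scalar ISN index (1/s).
#' @export
isn_index_2d <- function(weights, params, gain, rE) {
  if (any(rE < 0)) stop("rE must be >= 0")
  (weights$JEE * gain_slope(rE, gain$alphaE) - 1) / params$tauE
}

# Characteristic-function evaluator. The inhibitory steady state is
# folded into a single bracket, giving a one-dimensional reduction in
# the total excitatory input current z. An optional depression factor x
# scales JEE (and hence det(J)) for the frozen-x STD approximation.
char_fun_value <- function(z, weights, gain, gE, gI, x = 1) {
  JEE <- x * weights$JEE; JEI <- weights$JEI
  JIE <- weights$JIE; JII <- weights$JII
  if (JEI == 0) stop("JEI must be nonzero for the characteristic function")
  detJ <- -JEE * JII + JIE * JEI
  rE <- powerlaw_gain(z, gain$alphaE)
  inner <- detJ / JEI * rE + JII / JEI * z - JII / JEI * gE + gI
  JEE * rE - JEI * powerlaw_gain(inner, gain$alphaI) - z + gE
}

#' Characteristic function of the 2D ensemble
#'
#' One-dimensional reduction of the E/I system in the total excitatory
#' input current `z`: zero crossings of `F(z)` are the fixed points of
#' the full system, and the sign of `dF/dz` at a root classifies it
#' (positive slope: saddle). Increasing `gE` shifts `F` upward
#' everywhere, which is how suprathreshold input annihilates all fixed
#' points in ensembles with `det(J) < 0`.
#'
#' @inheritParams jacobian_2d
#' @param gE,gI External drives at which to evaluate.
#' @param z_grid Strictly increasing grid of current values.
#' @param x Optional E-to-E depression factor (see
#'   [characteristic_function_std()]).
#' @return Object of class `characteristic_curve`: list with `z`, `F`,
#'   and the parameters used.
#' @export
characteristic_function <- function(weights, params, gain, gE, gI,
                                    z_grid, x = 1) {
  if (any(!is.finite(z_grid)) || is.unsorted(z_grid, strictly = TRUE))
    stop("z_grid must be finite and strictly increasing")
  Fz <- char_fun_value(z_grid, weights, gain, gE, gI, x = x)
  structure(list(z = z_grid, F = Fz, gE = gE, gI = gI, x = x,
                 weights = weights, gain = gain),
            class = "characteristic_curve")
}

# Map a root z of the characteristic function back to rates. On the
# excitatory nullcline rI = (JEE rE - z + gE)/JEI, which at a root also
# satisfies the inhibitory steady state (the reduction encodes it).
root_to_rates <- function(z, weights, gain, gE, x = 1) {
  rE <- powerlaw_gain(z, gain$alphaE)
  rI <- (x * weights$JEE * rE - z + gE) / weights$JEI
  c(rE = rE, rI = rI)
}

# residuals of the two steady-state equations at (rE, rI)
steady_state_residual <- function(weights, gain, gE, gI, rE, rI, x = 1) {
  resE <- -rE + powerlaw_gain(x * weights$JEE * rE - weights$JEI * rI + gE,
                              gain$alphaE)
  resI <- -rI + powerlaw_gain(weights$JIE * rE - weights$JII * rI + gI,
                              gain$alphaI)
  c(resE, resI)
}

#' Locate and classify all fixed points of the 2D ensemble
#'
#' Scans the characteristic function on a dense grid, refines each sign
#' change by bisection, maps each root back to `(rE, rI)`, and
#' classifies it from the eigenvalues of the full 2D Jacobian. The upper
#' end of the scan doubles adaptively until `F` is clearly beyond its
#' last crossing, so all finite-rate fixed points are bracketed.
#'
#' @inheritParams characteristic_function
#' @param z_max Initial upper end of the root scan (doubled adaptively,
#'   capped at 1e7).
#' @param n_grid Number of scan points (default 4000).
#' @param tol Residual tolerance for accepting a back-mapped fixed point.
#' @return Object of class `fixed_point_report`: `points` data frame
#'   with columns `rE`, `rI`, `z`, `stability`, `lambda1`, `lambda2`
#'   (complex), and `n_points`. Zero rows when all fixed points have
#'   vanished (the runaway regime).
#' @examples
#' ps <- nta_preset("ensemble")
#' find_fixed_points(ps$weights, ps$params, ps$gain,
#'                   gE = 1.55, gI = 2)$n_points  # 2
#' find_fixed_points(ps$weights, ps$params, ps$gain,
#'                   gE = 3.0, gI = 2)$n_points   # 0
#' @export
find_fixed_points <- function(weights, params, gain, gE, gI,
                              z_max = 1000, n_grid = 4000, tol = 1e-8,
                              x = 1) {
  z_lo <- min(0, gE) - 10 * (1 + abs(gE))
  f <- function(z) char_fun_value(z, weights, gain, gE, gI, x = x)
  # adaptive doubling: extend until F keeps one sign and grows in
  # magnitude over the last decade of the grid (no further crossings)
  repeat {
    zg <- seq(z_lo, z_max, length.out = n_grid)
    Fz <- f(zg)
    tail_idx <- zg > z_max / 2
    tail_ok <- all(sign(Fz[tail_idx]) == sign(Fz[n_grid])) &&
      abs(Fz[n_grid]) > abs(Fz[which(tail_idx)[1]])
    if (tail_ok || z_max >= 1e7) break
    z_max <- z_max * 2
  }
  sgn <- sign(Fz)
  # treat exact zeros as crossings
  crossings <- which(sgn[-n_grid] * sgn[-1] < 0 | sgn[-n_grid] == 0)
  roots <- numeric(0)
  for (i in crossings) {
    if (sgn[i] == 0) { roots <- c(roots, zg[i]); next }
    r <- stats::uniroot(f, lower = zg[i], upper = zg[i + 1],
                        tol = 1e-12)$root
    roots <- c(roots, r)
  }
  roots <- sort(unique(roots))

  if (length(roots) == 0) {
    return(structure(list(points = data.frame(
      rE = numeric(0), rI = numeric(0), z = numeric(0),
      stability = character(0)), n_points = 0L,
      gE = gE, gI = gI, x = x), class = "fixed_point_report"))
  }

  rows <- lapply(roots, function(z) {
    rr <- root_to_rates(z, weights, gain, gE, x = x)
    res <- steady_state_residual(weights, gain, gE, gI, rr["rE"], rr["rI"],
                                 x = x)
    if (max(abs(res)) > max(tol, 1e-6 * (1 + abs(rr["rE"])))) {
      stop("fixed-point back-mapping failed: residual ",
           format(max(abs(res))), " at z = ", format(z))
    }
    J <- jacobian_2d(weights, params, gain, max(rr["rE"], 0),
                     max(rr["rI"], 0), x = x)
    ev <- J$eigenvalues
    re <- Re(ev)
    cls <- if (all(re < 0)) {
      if (any(Im(ev) != 0)) "stable-spiral" else "stable"
    } else if (all(re > 0)) {
      if (any(Im(ev) != 0)) "unstable-spiral" else "unstable"
    } else "saddle"
    data.frame(rE = unname(rr["rE"]), rI = unname(rr["rI"]), z = z,
               stability = cls,
               lambda1 = ev[1], lambda2 = ev[2])
  })
  pts <- do.call(rbind, rows)
  structure(list(points = pts, n_points = nrow(pts), gE = gE, gI = gI,
                 x = x), class = "fixed_point_report")
}

#' @export
print.fixed_point_report <- function(x, ...) {
  cat("Fixed points at gE =", x$gE, ", gI =", x$gI,
      if (x$x != 1) paste0(", x = ", x$x) else "", ":\n")
  if (x$n_points == 0) cat("  none (runaway regime)\n")
  else print(x$points[, c("rE", "rI", "z", "stability")], ...)
  invisible(x)
}

#' Critical input for loss of all fixed points
#'
#' For an ensemble with `det(J) < 0`, increasing `gE` monotonically
#' shifts the characteristic function upward until all zero crossings
#' vanish; this function locates that threshold by bisection on the
#' number of crossings. For `det(J) >= 0` no finite positive-feedback
#' threshold is guaranteed and `NA` is returned (with attribute
#' `reason`).
#'
#' @inheritParams find_fixed_points
#' @param bracket Numeric length-2 search interval for `gE`.
#' @param tol Bisection tolerance on `gE` (default 1e-6).
#' @return The critical `gE`, or `NA` if `det(J) >= 0`.
#' @export
critical_input <- function(weights, params, gain, gI,
                           bracket = c(0, 10), tol = 1e-6, x = 1) {
  detJ <- -x * weights$JEE * weights$JII + weights$JIE * weights$JEI
  if (detJ >= 0) {
    out <- NA_real_
    attr(out, "reason") <- "no positive-feedback threshold: det(J) >= 0"
    return(out)
  }
  n_fp <- function(gE) find_fixed_points(weights, params, gain, gE, gI,
                                         x = x)$n_points
  lo <- bracket[1]; hi <- bracket[2]
  if (n_fp(lo) == 0) stop("lower bracket already has no fixed points")
  if (n_fp(hi) > 0) stop("upper bracket still has fixed points")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (n_fp(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Regime scan over (JEE, gE)
#'
#' Grid scan reproducing the structure of the evoked-rate map: for each
#' combination of recurrent strength `JEE` and drive `gE`, report the
#' number of fixed points and the excitatory rate of the stable fixed
#' point (NA in the unstable/runaway region).
#'
#' @inheritParams find_fixed_points
#' @param JEE_grid,gE_grid Numeric grids.
#' @return Data frame with columns `JEE`, `gE`, `n_fixed_points`,
#'   `stable_rE`.
#' @export
regime_scan_2d <- function(weights, params, gain, gI, JEE_grid, gE_grid) {
  out <- expand.grid(JEE = JEE_grid, gE = gE_grid)
  out$n_fixed_points <- NA_integer_
  out$stable_rE <- NA_real_
  for (i in seq_len(nrow(out))) {
    w <- ensemble_weights(out$JEE[i], weights$JIE, weights$JEI, weights$JII)
    fp <- find_fixed_points(w, params, gain, out$gE[i], gI)
    out$n_fixed_points[i] <- fp$n_points
    st <- fp$points$stability %in% c("stable", "stable-spiral")
    if (any(st)) out$stable_rE[i] <- max(fp$points$rE[st])
  }
  out
}
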
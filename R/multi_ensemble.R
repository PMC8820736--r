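#' Block-network specification for N-ensemble eigenvalue theory
#'
#' The linearized N-ensemble network is described by gain-scaled weight
#' terms evaluated at a common operating point: `a = JEE*alphaE*zE^+ /
#' tauE` and analogously `b` (I-to-E), `c` (E-to-I), `d` (I-to-I), plus
#' leak rates `e = 1/tauE`, `f = 1/tauI`, the inter-ensemble E-to-E
#' factor `k`, and the co-tuning degree `m` (0 = perfectly co-tuned,
#' independent ensembles; 1 = global inhibition).
#'
#' @param N Number of ensembles (>= 2).
#' @param a,b,c,d Gain-scaled weight terms (>= 0).
#' @param e,f Leak rates 1/tauE, 1/tauI (> 0).
#' @param k Inter-ensemble E-to-E factor.
#' @param m Co-tuning degree in \[0, 1\].
#' @return Object of class `block_network_spec`.
#' @export
block_network_spec <- function(N, a, b, c, d, e, f, k, m = 1) {
  if (N < 2) stop("N must be >= 2")
  vals <- c(a = a, b = b, c = c, d = d, e = e, f = f)
  if (any(vals < 0)) stop("a, b, c, d, e, f must be >= 0")
  if (m < 0 || m > 1) stop("m must lie in [0, 1]")
  structure(list(N = as.integer(N), a = a, b = b, c = c, d = d,
                 e = e, f = f, k = k, m = m),
            class = "block_network_spec")
}

#' Assemble the 2N x 2N block Jacobian
#'
#' Builds the Jacobian of the linearized N-ensemble network. With
#' `m = 1` the co-tuned blocks reduce entrywise to the global-inhibition
#' form (E-to-I and I-to-E blocks of constants, shared I-to-I block);
#' with `m = 0` the network decouples into N independent 2x2 ensembles.
#' Ordering: N excitatory populations first, then N inhibitory.
#'
#' @param spec A [block_network_spec()].
#' @return A 2N x 2N numeric matrix.
#' @export
build_block_jacobian <- function(spec) {
  stopifnot(inherits(spec, "block_network_spec"))
  N <- spec$N
  ones <- matrix(1, N, N)
  EE <- spec$k * spec$a * ones
  diag(EE) <- spec$a - spec$e
  if (spec$m == 1) {
    EI <- -spec$b * ones
    IE <- spec$c * ones
    II <- -spec$d * ones
    diag(II) <- -spec$d - spec$f
  } else {
    m <- spec$m
    EI <- -m * spec$b * ones
    diag(EI) <- -N * spec$b + (N - 1) * m * spec$b
    IE <- m * spec$c * ones
    diag(IE) <- N * spec$c - (N - 1) * m * spec$c
    II <- -m * spec$d * ones
    diag(II) <- -N * spec$d + (N - 1) * m * spec$d - spec$f
  }
  rbind(cbind(EE, EI), cbind(IE, II))
}

#' Closed-form eigenvalues of the block Jacobian
#'
#' The 2N x 2N Jacobian has four distinct eigenvalues. For global
#' inhibition (`m = 1`): `lambda1 = a - e - k*a` and `lambda2 = -f`,
#' each with multiplicity N-1, plus the simple pair `lambda3/4` solving
#' the rank-one compound quadratic. For co-tuned inhibition (`m < 1`)
#' the degenerate pair becomes
#' `lambda1/2' = ((a-e-ka-Nd+Nmd-f) +/- sqrt((a-e-ka+Nd-Nmd+f)^2 -
#' 4*N^2*b*c*(1-m)^2))/2`, while `lambda3/4` are unchanged. Since
#' `Re(lambda1') < lambda1` whenever `m < 1`, co-tuning strictly
#' enlarges the uni-stable (single fixed point) parameter regime.
#'
#' @param spec A [block_network_spec()].
#' @return Object of class `block_eigenvalues`: list with complex
#'   `lambda1`, `lambda2` (multiplicity N-1 each), `lambda3`, `lambda4`
#'   (multiplicity 1), `variant` (`"global"` or `"cotuned"`), and
#'   `values` (the full multiset of 2N eigenvalues).
#' @export
analytic_block_eigenvalues <- function(spec) {
  stopifnot(inherits(spec, "block_network_spec"))
  N <- spec$N; a <- spec$a; b <- spec$b; c <- spec$c; d <- spec$d
  e <- spec$e; f <- spec$f; k <- spec$k; m <- spec$m

  s34 <- a - e - f - N * d + (N - 1) * k * a
  q34 <- (-a * f + e * f + k * a * f) - N * (a - e) * d - N * k * a * f -
    N * (N - 1) * k * a * d + N^2 * b * c
  rt34 <- sqrt(as.complex(s34^2 - 4 * q34))
  lambda3 <- (s34 + rt34) / 2
  lambda4 <- (s34 - rt34) / 2

  if (spec$m == 1) {
    lambda1 <- as.complex(a - e - k * a)
    lambda2 <- as.complex(-f)
    variant <- "global"
  } else {
    s12 <- a - e - k * a - N * d + N * m * d - f
    rt12 <- sqrt(as.complex((a - e - k * a + N * d - N * m * d + f)^2 -
                              4 * N^2 * b * c * (1 - m)^2))
    lambda1 <- (s12 + rt12) / 2
    lambda2 <- (s12 - rt12) / 2
    variant <- "cotuned"
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 lambda3 = lambda3, lambda4 = lambda4,
                 variant = variant,
                 values = c(rep(lambda1, N - 1), rep(lambda2, N - 1),
                            lambda3, lambda4)),
            class = "block_eigenvalues")
}

#' Uni-stability map over (a, d)
#'
#' Labels each point of an (a, d) grid as uni-stable when the leading
#' analytic eigenvalue of the block Jacobian has negative real part,
#' for both the global-inhibition spectrum and the co-tuned spectrum
#' with the given `m`. The product `b*c` is supplied as a function of
#' `(a, d)` (default `0.9*a*d`).
#'
#' @param a_grid,d_grid Numeric grids of the gain-scaled E-to-E and
#'   I-to-I terms.
#' @param k Inter-ensemble E-to-E factor (default 0.1).
#' @param m Co-tuning degree for the co-tuned variant (default 0.5).
#' @param bc_rule Function of `(a, d)` returning the product `b*c`.
#' @param e,f Leak rates (defaults 1/0.020 and 1/0.010).
#' @param N Number of ensembles (default 2).
#' @return Data frame with columns `a`, `d`, `unistable_global`,
#'   `unistable_cotuned`, `lead_global`, `lead_cotuned`.
#' @export
unistability_map <- function(a_grid, d_grid, k = 0.1, m = 0.5,
                             bc_rule = function(a, d) 0.9 * a * d,
                             e = 50, f = 100, N = 2) {
  out <- expand.grid(a = a_grid, d = d_grid)
  lead <- function(spec) {
    ev <- analytic_block_eigenvalues(spec)
    max(Re(c(ev$lambda1, ev$lambda2, ev$lambda3, ev$lambda4)))
  }
  out$lead_global <- NA_real_; out$lead_cotuned <- NA_real_
  for (i in seq_len(nrow(out))) {
    bc <- bc_rule(out$a[i], out$d[i])
    b <- sqrt(bc); cc <- sqrt(bc)     # only the product enters
    out$lead_global[i] <- lead(block_network_spec(
      N, out$a[i], b, cc, out$d[i], e, f, k, m = 1))
    out$lead_cotuned[i] <- lead(block_network_spec(
      N, out$a[i], b, cc, out$d[i], e, f, k, m = m))
  }
  out$unistable_global <- out$lead_global < 0
  out$unistable_cotuned <- out$lead_cotuned < 0
  out
}

#' Two-ensemble population weights
#'
#' Weight magnitudes for a network of two interacting E/I ensembles:
#' within-ensemble `JEE, JIE, JEI, JII` and inter-ensemble primed
#' versions. Weights may be given directly at population level, or as
#' per-connection strengths of a homogeneous all-to-all network of `NE`
#' excitatory and `NI` inhibitory neurons split into two ensembles (the
#' per-connection form is resolved to effective population weights when
#' the network is assembled, excluding self-connections).
#'
#' @param JEE,JIE,JEI,JII Within-ensemble strengths.
#' @param JEEp,JIEp,JEIp,JIIp Inter-ensemble strengths.
#' @param per_connection Logical; `TRUE` when values are per-connection.
#' @param NE,NI Neuron counts (used only with `per_connection`).
#' @return Object of class `two_ensemble_weights`.
#' @export
two_ensemble_weights <- function(JEE, JIE, JEI, JII,
                                 JEEp, JIEp, JEIp, JIIp,
                                 per_connection = FALSE,
                                 NE = NULL, NI = NULL) {
  w <- c(JEE, JIE, JEI, JII, JEEp, JIEp, JEIp, JIIp)
  if (any(!is.finite(w)) || any(w < 0))
    stop("all weight magnitudes must be finite and >= 0")
  if (per_connection && (is.null(NE) || is.null(NI)))
    stop("per-connection weights need NE and NI")
  structure(list(JEE = JEE, JIE = JIE, JEI = JEI, JII = JII,
                 JEEp = JEEp, JIEp = JIEp, JEIp = JEIp, JIIp = JIIp,
                 per_connection = per_connection, NE = NE, NI = NI),
            class = "two_ensemble_weights")
}

#' Simulate a general multi-population supralinear rate network
#'
#' Fixed-step Euler integration of K interacting populations, each with
#' a rectified power-law gain. The signed effective weight matrix `W`
#' (rows: postsynaptic) already carries inhibitory minus signs.
#' Mechanisms act presynaptically: with STD every E-to-E entry is scaled
#' by the presynaptic depression variable `x_j`; with STF every E-to-I
#' entry is scaled by the presynaptic facilitation variable `u_j`
#' (variables attach to presynaptic excitatory populations, shared by
#' all their targets, as in the homogeneous all-to-all case).
#'
#' @param W K x K signed effective weight matrix.
#' @param type Character vector of population types, `"E"` or `"I"`.
#' @param tau Length-K time constants (s).
#' @param alpha Length-K gain exponents.
#' @param g_baseline Length-K baseline drives.
#' @param episodes List of episodes `list(t_start, t_end, delta)` with
#'   `delta` a length-K additive drive vector.
#' @param mech A [mechanism] (none, std or stf).
#' @param duration,dt Simulation time and step (s).
#' @param init Optional initial rate vector (default zeros).
#' @param divergence_bound As in [simulate_ensemble()].
#' @param record_every Thinning factor for the stored trajectory.
#' @return Object of class `network_trajectory`: list with `t`, `rates`
#'   (samples x K matrix), `aux` (samples x K or NULL), `diverged`,
#'   `divergence_time`.
#' @export
simulate_rate_network <- function(W, type, tau, alpha, g_baseline,
                                  episodes = list(), mech = mech_none(),
                                  duration, dt = 1e-4, init = NULL,
                                  divergence_bound = 1e6,
                                  record_every = 1L) {
  K <- nrow(W)
  stopifnot(ncol(W) == K, length(type) == K, length(tau) == K,
            length(alpha) == K, length(g_baseline) == K)
  if (!all(type %in% c("E", "I"))) stop("type entries must be 'E' or 'I'")
  n_steps <- as.integer(round(duration / dt))
  variant <- mech$variant
  isE <- type == "E"

  r <- if (is.null(init)) numeric(K) else as.numeric(init)
  if (any(r < 0)) stop("initial rates must be >= 0")
  aux <- if (variant %in% c("std", "stf")) rep(1, K) else NULL

  tgrid <- (seq_len(n_steps) - 1L) * dt
  # per-episode index ranges resolved once
  eps <- lapply(episodes, function(ep) {
    list(i0 = findInterval(ep$t_start, tgrid) + 1L,
         i1 = findInterval(ep$t_end - dt / 2, tgrid),
         delta = as.numeric(ep$delta))
  })

  keep <- seq(1L, n_steps, by = as.integer(record_every))
  R <- matrix(NA_real_, length(keep), K)
  A <- if (is.null(aux)) NULL else matrix(NA_real_, length(keep), K)
  k_out <- 1L
  diverged <- FALSE; divergence_time <- NA_real_; last <- n_steps

  # masks for mechanism-scaled connections
  EE_mask <- outer(isE, isE, `&`)       # E -> E entries
  EI_mask <- outer(!isE, isE, `&`)      # E -> I entries (post I, pre E)
  dt_tau <- dt / tau

  for (i in seq_len(n_steps)) {
    if (k_out <= length(keep) && i == keep[k_out]) {
      R[k_out, ] <- r
      if (!is.null(A)) A[k_out, ] <- aux
      k_out <- k_out + 1L
    }
    g <- g_baseline
    for (ep in eps) if (i >= ep$i0 && i <= ep$i1) g <- g + ep$delta

    Weff <- W
    if (variant == "std") {
      Weff[EE_mask] <- W[EE_mask] *
        rep(aux, each = K)[EE_mask]
    } else if (variant == "stf") {
      Weff[EI_mask] <- W[EI_mask] *
        rep(aux, each = K)[EI_mask]
    }
    z <- as.numeric(Weff %*% r) + g
    phi <- ifelse(z > 0, z^alpha, 0)
    r_new <- r + dt_tau * (-r + phi)

    if (variant == "std") {
      aux <- aux + dt * ((1 - aux) / mech$tau_x - mech$Ud * aux * r)
      aux <- pmin(pmax(aux, 1e-12), 1)
      aux[!isE] <- 1
    } else if (variant == "stf") {
      aux <- aux + dt * ((1 - aux) / mech$tau_u +
                           mech$Uf * (mech$Umax - aux) * r)
      aux <- pmin(pmax(aux, 1), mech$Umax)
      aux[!isE] <- 1
    }
    r <- pmax(r_new, 0)
    if (any(!is.finite(r)) || max(r) > divergence_bound) {
      diverged <- TRUE; divergence_time <- tgrid[i]; last <- i
      break
    }
  }
  kept <- which(keep <= last & seq_along(keep) < k_out)
  structure(list(t = tgrid[keep[kept]],
                 rates = R[kept, , drop = FALSE],
                 aux = if (is.null(A)) NULL else A[kept, , drop = FALSE],
                 type = type, diverged = diverged,
                 divergence_time = divergence_time, dt = dt),
            class = "network_trajectory")
}

#' @export
print.network_trajectory <- function(x, ...) {
  cat("Rate-network trajectory:", ncol(x$rates), "populations,",
      length(x$t), "samples over", signif(max(x$t), 4), "s\n")
  if (x$diverged)
    cat("  DIVERGED at t =", signif(x$divergence_time, 6), "s\n")
  invisible(x)
}

# resolve a two_ensemble_weights object plus optional E1 subset split
# into population-level effective weights.
# populations: E1 (or E1a/E1b), E2, I1, I2
resolve_two_ensemble_network <- function(weights, subset_split = NULL,
                                         tauE = 0.020, tauI = 0.010,
                                         alphaE = 2, alphaI = 2) {
  pc <- weights$per_connection
  if (!is.null(subset_split)) {
    if (!pc)
      stop("subset stimulation requires per-connection weights")
    if (any(subset_split <= 0) || any(subset_split >= 1) ||
        abs(sum(subset_split) - 1) > 1e-12)
      stop("subset fractions must lie in (0,1) and sum to 1")
  }
  if (pc) {
    nE <- weights$NE / 2; nI <- weights$NI / 2
  } else {
    nE <- 1; nI <- 1
  }
  # effective weight from a presynaptic group of n neurons with
  # per-connection strength j; subtract one self-partner when the
  # postsynaptic population is the same group
  eff <- function(j, n, same) if (pc) j * (n - as.integer(same)) else j

  if (is.null(subset_split)) {
    names_ <- c("E1", "E2", "I1", "I2")
    type <- c("E", "E", "I", "I")
    sizes <- c(nE, nE, nI, nI)
    W <- matrix(0, 4, 4, dimnames = list(names_, names_))
    W["E1", "E1"] <- eff(weights$JEE, nE, TRUE)
    W["E2", "E2"] <- eff(weights$JEE, nE, TRUE)
    W["E1", "E2"] <- eff(weights$JEEp, nE, FALSE)
    W["E2", "E1"] <- eff(weights$JEEp, nE, FALSE)
    W["I1", "E1"] <- eff(weights$JIE, nE, FALSE)
    W["I2", "E2"] <- eff(weights$JIE, nE, FALSE)
    W["I1", "E2"] <- eff(weights$JIEp, nE, FALSE)
    W["I2", "E1"] <- eff(weights$JIEp, nE, FALSE)
    W["E1", "I1"] <- -eff(weights$JEI, nI, FALSE)
    W["E2", "I2"] <- -eff(weights$JEI, nI, FALSE)
    W["E1", "I2"] <- -eff(weights$JEIp, nI, FALSE)
    W["E2", "I1"] <- -eff(weights$JEIp, nI, FALSE)
    W["I1", "I1"] <- -eff(weights$JII, nI, TRUE)
    W["I2", "I2"] <- -eff(weights$JII, nI, TRUE)
    W["I1", "I2"] <- -eff(weights$JIIp, nI, FALSE)
    W["I2", "I1"] <- -eff(weights$JIIp, nI, FALSE)
  } else {
    nA <- nE * subset_split[1]; nB <- nE * subset_split[2]
    names_ <- c("E1a", "E1b", "E2", "I1", "I2")
    type <- c("E", "E", "E", "I", "I")
    sizes <- c(nA, nB, nE, nI, nI)
    W <- matrix(0, 5, 5, dimnames = list(names_, names_))
    # within-E1 couplings split across subsets
    W["E1a", "E1a"] <- weights$JEE * (nA - 1)
    W["E1b", "E1b"] <- weights$JEE * (nB - 1)
    W["E1a", "E1b"] <- weights$JEE * nB
    W["E1b", "E1a"] <- weights$JEE * nA
    W["E2", "E2"] <- weights$JEE * (nE - 1)
    W["E1a", "E2"] <- weights$JEEp * nE
    W["E1b", "E2"] <- weights$JEEp * nE
    W["E2", "E1a"] <- weights$JEEp * nA
    W["E2", "E1b"] <- weights$JEEp * nB
    W["I1", "E1a"] <- weights$JIE * nA
    W["I1", "E1b"] <- weights$JIE * nB
    W["I2", "E2"] <- weights$JIE * nE
    W["I1", "E2"] <- weights$JIEp * nE
    W["I2", "E1a"] <- weights$JIEp * nA
    W["I2", "E1b"] <- weights$JIEp * nB
    W[c("E1a", "E1b"), "I1"] <- -weights$JEI * nI
    W["E2", "I2"] <- -weights$JEI * nI
    W[c("E1a", "E1b"), "I2"] <- -weights$JEIp * nI
    W["E2", "I1"] <- -weights$JEIp * nI
    W["I1", "I1"] <- -weights$JII * (nI - 1)
    W["I2", "I2"] <- -weights$JII * (nI - 1)
    W["I1", "I2"] <- -weights$JIIp * nI
    W["I2", "I1"] <- -weights$JIIp * nI
  }
  isE <- type == "E"
  list(W = W, names = names_, type = type, sizes = sizes,
       tau = ifelse(isE, tauE, tauI),
       alpha = ifelse(isE, alphaE, alphaI))
}

#' Simulate two interacting E/I ensembles
#'
#' Integrates the 4-population (E1, E2, I1, I2) rate network, or a
#' 5-population version in which E1 is split into two subsets (default
#' 75%/25%) so that a partial-cue stimulus can target Subset 1 while
#' Subset 2 reports pattern completion. Subset simulation requires
#' per-connection weights (see [two_ensemble_weights()]); the split
#' resolves the homogeneous all-to-all connectivity exactly.
#'
#' @param weights A [two_ensemble_weights()].
#' @param gE1,gE2,gI Baseline drives (scalars; `gI` applies to both
#'   inhibitory populations).
#' @param episodes List of episodes `list(t_start, t_end, target,
#'   delta_g)` where `target` is a population name (`"E1"`, `"E2"`,
#'   `"E1a"`, ...; `"E1"` targets both subsets when split).
#' @param mech A [mechanism].
#' @param subset_split `NULL` or fractions of E1 in Subset 1 and 2.
#' @param init_noise Magnitude of a seeded uniform perturbation of the
#'   initial rates (used to break symmetry in attractor demos).
#' @param seed Seed for the initial noise (ignored when `init_noise`
#'   is 0).
#' @param tauE,tauI,alphaE,alphaI Population parameters.
#' @inheritParams simulate_rate_network
#' @return A `network_trajectory` whose `rates` columns are named.
#' @export
simulate_two_ensembles <- function(weights, gE1, gE2, gI,
                                   episodes = list(),
                                   mech = mech_none(),
                                   subset_split = NULL,
                                   init_noise = 0, seed = NULL,
                                   duration, dt = 1e-4,
                                   tauE = 0.020, tauI = 0.010,
                                   alphaE = 2, alphaI = 2,
                                   divergence_bound = 1e6,
                                   record_every = 1L) {
  stopifnot(inherits(weights, "two_ensemble_weights"))
  net <- resolve_two_ensemble_network(weights, subset_split,
                                      tauE, tauI, alphaE, alphaI)
  K <- length(net$names)
  g <- numeric(K)
  g[net$names %in% c("E1", "E1a", "E1b")] <- gE1
  g[net$names == "E2"] <- gE2
  g[net$type == "I"] <- gI

  eps <- lapply(episodes, function(ep) {
    delta <- numeric(K)
    tgt <- ep$target
    hit <- if (tgt == "E1") net$names %in% c("E1", "E1a", "E1b")
           else net$names == tgt
    if (!any(hit)) stop("unknown episode target: ", tgt)
    delta[hit] <- ep$delta_g
    list(t_start = ep$t_start, t_end = ep$t_end, delta = delta)
  })

  init <- numeric(K)
  if (init_noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    init <- stats::runif(K, 0, init_noise)
  }
  tr <- simulate_rate_network(net$W, net$type, net$tau, net$alpha, g,
                              episodes = eps, mech = mech,
                              duration = duration, dt = dt, init = init,
                              divergence_bound = divergence_bound,
                              record_every = record_every)
  colnames(tr$rates) <- net$names
  if (!is.null(tr$aux)) colnames(tr$aux) <- net$names
  tr
}

#' Linear response of the unstimulated ensemble
#'
#' First-order change of the second ensemble's excitatory rate under a
#' small change of drive to the first, from the linearization
#' `delta_r = (I - F J)^-1 F delta_g` of the 4-population system, where
#' `F` is the diagonal matrix of gain derivatives at the operating
#' point. Returns the full cofactor-expansion value together with its
#' weak-cross-coupling approximation (cross-ensemble terms beyond first
#' order dropped). Large `JIE'` (the E1-I2-E2 pathway) or `JEI'` (the
#' E1-I1-E2 pathway) make the response negative, identifying the
#' inhibitory routes that suppress unwanted coactivation.
#'
#' @param weights A [two_ensemble_weights()] (population-level
#'   magnitudes; per-connection weights are resolved first).
#' @param f_derivs Numeric length-4 gain derivatives
#'   `(fE1', fE2', fI1', fI2')` at the operating point.
#' @param delta_gE1 Drive increment to E1.
#' @return List with `delta_rE2` (full), `delta_rE2_approx`
#'   (weak-coupling), and `det_IFJ`.
#' @export
delta_rE2_linear_response <- function(weights, f_derivs, delta_gE1) {
  stopifnot(inherits(weights, "two_ensemble_weights"),
            length(f_derivs) == 4)
  w <- if (weights$per_connection) {
    net <- resolve_two_ensemble_network(weights)
    list(JEE = net$W["E1", "E1"], JEEp = net$W["E1", "E2"],
         JIE = net$W["I1", "E1"], JIEp = net$W["I2", "E1"],
         JEI = -net$W["E1", "I1"], JEIp = -net$W["E1", "I2"],
         JII = -net$W["I1", "I1"], JIIp = -net$W["I1", "I2"])
  } else weights
  fE1 <- f_derivs[1]; fE2 <- f_derivs[2]
  fI1 <- f_derivs[3]; fI2 <- f_derivs[4]
  J <- matrix(c(
    w$JEE,  w$JEEp, -w$JEI,  -w$JEIp,
    w$JEEp, w$JEE,  -w$JEIp, -w$JEI,
    w$JIE,  w$JIEp, -w$JII,  -w$JIIp,
    w$JIEp, w$JIE,  -w$JIIp, -w$JII), 4, byrow = TRUE)
  FF <- diag(c(fE1, fE2, fI1, fI2))
  IFJ <- diag(4) - FF %*% J
  dIFJ <- det(IFJ)
  if (abs(dIFJ) < 1e-12)
    stop("singular (I - F J): the operating point is not stable")

  bracket_full <-
    (-fE2 * w$JEEp) * fI1 * w$JIIp * fI2 * w$JIIp +
    fE2 * w$JEIp * (-fI1 * w$JIE) * (1 + fI2 * w$JII) +
    fE2 * w$JEI * (1 + fI1 * w$JII) * (-fI2 * w$JIEp) -
    (-fE2 * w$JEEp) * (1 + fI1 * w$JII) * (1 + fI2 * w$JII) -
    fE2 * w$JEIp * fI1 * w$JIIp * (-fI2 * w$JIEp) -
    fE2 * w$JEI * (-fI1 * w$JIE) * fI2 * w$JIIp
  bracket_approx <-
    fE2 * w$JEIp * (-fI1 * w$JIE) * (1 + fI2 * w$JII) +
    fE2 * w$JEI * (1 + fI1 * w$JII) * (-fI2 * w$JIEp) -
    (-fE2 * w$JEEp) * (1 + fI1 * w$JII) * (1 + fI2 * w$JII) -
    fE2 * w$JEI * (-fI1 * w$JIE) * fI2 * w$JIIp
  list(delta_rE2 = bracket_full / dIFJ * fE1 * delta_gE1,
       delta_rE2_approx = bracket_approx / dIFJ * fE1 * delta_gE1,
       det_IFJ = dIFJ)
}

#' Morphing / tuning parameterization of the two-ensemble network
#'
#' Resolves the morph fraction `p` (0: all extra drive to E1; 1: all to
#' E2; 0.5: symmetric) and the recurrent tuning fraction `beta`
#' (within-ensemble share of the fixed total E-to-E budget
#' `Jtot = JEE + JEE'`) into concrete weights and stimulation drives:
#' `gE1_stim = g_base + (g_max - g_base)*(1 - p)`,
#' `gE2_stim = g_base + (g_max - g_base)*p`,
#' `JEE = beta*Jtot`, `JEE' = (1 - beta)*Jtot`.
#'
#' @param p Morph fraction in \[0, 1\].
#' @param beta Tuning fraction in \[0, 1\].
#' @param Jtot Total E-to-E budget (default 1.56, the canonical
#'   1.2 + 0.36 split at beta ~ 0.77).
#' @param g_base,g_max Baseline and maximal drive (defaults 1.35, 4.0).
#' @return List with `JEE`, `JEEp`, `gE1_stim`, `gE2_stim`, `p`,
#'   `beta`, `Jtot`.
#' @export
morph_beta_params <- function(p, beta, Jtot = 1.56,
                              g_base = 1.35, g_max = 4.0) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  list(JEE = beta * Jtot, JEEp = (1 - beta) * Jtot,
       gE1_stim = g_base + (g_max - g_base) * (1 - p),
       gE2_stim = g_base + (g_max - g_base) * p,
       p = p, beta = beta, Jtot = Jtot)
}
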
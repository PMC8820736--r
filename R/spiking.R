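#' Conductance-based LIF network parameters
#'
#' Parameters of the spiking network: leaky integrate-and-fire neurons
#' with conductance-based synapses in which excitatory transmission has
#' a fast AMPA and a slow NMDA component (`g_exc = xi*g_ampa +
#' (1-xi)*g_nmda`, the NMDA conductance low-pass filtering the AMPA
#' one) and inhibition a single GABA conductance. A presynaptic spike
#' makes the corresponding conductance jump by the synaptic weight.
#'
#' Synaptic weights and time constants follow the published parameter
#' table. Network size defaults to 800 excitatory / 200 inhibitory
#' neurons: the published sources give both 800/200 and a table entry
#' of 400/100, and with five overlapping 200-neuron ensembles only the
#' larger network keeps ensembles distinct enough (about 25% pairwise
#' membership overlap rather than 50%) for stimulation to evoke
#' ensemble-selective onset transients; sizes remain fully
#' configurable. The spiking threshold is not part of the published
#' table and defaults to the conventional -50 mV (20 mV above rest);
#' the external-input synaptic weight (`w_ext`) is likewise unpublished
#' and its default is calibrated so that 300 Poisson sources at 0.1 Hz
#' per neuron produce sparse (~1 Hz) spontaneous baseline activity
#' while ensemble stimulation evokes a pronounced onset transient that
#' settles into a much lower stimulus-evoked steady state.
#'
#' @param NE,NI Numbers of excitatory/inhibitory neurons.
#' @param p_conn Connection probability (0.2).
#' @param Urest,Uexc,Uinh,Uthr Resting, excitatory-reversal,
#'   inhibitory-reversal and threshold potentials (mV).
#' @param tau_m_exc,tau_m_inh Membrane time constants (s).
#' @param tau_ref Refractory period (s).
#' @param tau_ampa,tau_gaba,tau_nmda Synaptic time constants (s).
#' @param xi AMPA/NMDA weighting in \[0, 1\].
#' @param JEE,JIE,JEI,JII Within-ensemble synaptic weights.
#' @param JEEp,JIEp,JEIp,JIIp Inter-ensemble synaptic weights.
#' @param w_ext External-input synaptic weight.
#' @param n_ext Number of external Poisson sources per neuron.
#' @param rate_baseline,rate_stim Baseline and stimulation Poisson rate
#'   per source (Hz).
#' @param mech A [mechanism] for the synaptic dynamics: `mech_std()`
#'   applies per-synapse depression to E-to-E connections (the variable
#'   depends only on the presynaptic spike train, so one variable per
#'   presynaptic neuron is exact), `mech_stf()` facilitation to E-to-I
#'   connections, `mech_sfa()` an adaptation conductance with reversal
#'   `Uinh` incremented by `b` at each spike of the neuron itself.
#' @return Object of class `spiking_params`.
#' @export
spiking_params <- function(NE = 800, NI = 200, p_conn = 0.2,
                           Urest = -70, Uexc = 0, Uinh = -80,
                           Uthr = -50,
                           tau_m_exc = 0.020, tau_m_inh = 0.010,
                           tau_ref = 0.003,
                           tau_ampa = 0.005, tau_gaba = 0.010,
                           tau_nmda = 0.100, xi = 0.5,
                           JEE = 0.19, JIE = 0.10, JEI = 0.10,
                           JII = 0.06,
                           JEEp = 0.019, JIEp = 0.05, JEIp = 0.04,
                           JIIp = 0.006,
                           w_ext = 1.1, n_ext = 300,
                           rate_baseline = 0.1, rate_stim = 0.5,
                           mech = mech_std(Ud = 1.0, tau_x = 0.200)) {
  if (!(Uinh < Urest && Urest < Uthr && Uthr < Uexc))
    stop("potentials must satisfy Uinh < Urest < Uthr < Uexc")
  if (xi < 0 || xi > 1) stop("xi must lie in [0, 1]")
  if (p_conn <= 0 || p_conn > 1) stop("p_conn must lie in (0, 1]")
  structure(list(NE = NE, NI = NI, p_conn = p_conn,
                 Urest = Urest, Uexc = Uexc, Uinh = Uinh, Uthr = Uthr,
                 tau_m_exc = tau_m_exc, tau_m_inh = tau_m_inh,
                 tau_ref = tau_ref, tau_ampa = tau_ampa,
                 tau_gaba = tau_gaba, tau_nmda = tau_nmda, xi = xi,
                 JEE = JEE, JIE = JIE, JEI = JEI, JII = JII,
                 JEEp = JEEp, JIEp = JIEp, JEIp = JEIp, JIIp = JIIp,
                 w_ext = w_ext, n_ext = n_ext,
                 rate_baseline = rate_baseline, rate_stim = rate_stim,
                 mech = mech),
            class = "spiking_params")
}

#' Overlapping ensemble layout
#'
#' Draws `n_ensembles` overlapping ensembles of `size_E` excitatory
#' neurons each (uniformly at random, so neurons typically belong to
#' several ensembles). For the co-tuned weight classes, inhibitory
#' neurons are given random ensemble labels too (`size_I` each): a
#' synapse uses the within-ensemble weight when pre- and postsynaptic
#' neuron share at least one ensemble, otherwise the inter-ensemble
#' (primed) weight. The published description assigns membership only
#' on the excitatory side, so the inhibitory labels are this package's
#' convention; the default covers 75% of the inhibitory population per
#' ensemble, making inhibition broadly shared (largely global with
#' residual co-tuning), which keeps unstimulated ensembles suppressed
#' during another ensemble's onset transient.
#'
#' @param params A [spiking_params()].
#' @param n_ensembles Number of ensembles (default 5).
#' @param size_E Excitatory neurons per ensemble (default 200).
#' @param size_I Inhibitory neurons per ensemble (default
#'   `round(0.75 * NI)`).
#' @param seed Optional seed for the membership draw.
#' @return Object of class `ensemble_layout`: list with `membership`
#'   (list of excitatory id vectors), `membership_I`, `n_ensembles`.
#' @export
ensemble_layout <- function(params, n_ensembles = 5, size_E = 200,
                            size_I = NULL, seed = NULL) {
  stopifnot(inherits(params, "spiking_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(size_I)) size_I <- round(0.75 * params$NI)
  if (size_E < 1 || size_E > params$NE) stop("invalid ensemble size")
  membership <- lapply(seq_len(n_ensembles), function(k)
    sort(sample.int(params$NE, size_E)))
  membership_I <- lapply(seq_len(n_ensembles), function(k)
    sort(sample.int(params$NI, size_I)))
  structure(list(membership = membership, membership_I = membership_I,
                 n_ensembles = n_ensembles, NE = params$NE,
                 NI = params$NI),
            class = "ensemble_layout")
}

#' Homogeneous Poisson spike trains
#'
#' Independent homogeneous Poisson processes, e.g. for external drive.
#'
#' @param n_sources Number of sources.
#' @param rate Rate per source (Hz, >= 0).
#' @param duration Duration (s).
#' @param seed Optional seed (same seed gives identical trains).
#' @return Object of class `spike_data`: data frame `events` with
#'   columns `neuron`, `time`, plus metadata.
#' @export
generate_poisson_input <- function(n_sources, rate, duration,
                                   seed = NULL) {
  if (rate < 0) stop("rate must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rpois(n_sources, rate * duration)
  neuron <- rep(seq_len(n_sources), counts)
  time <- stats::runif(sum(counts), 0, duration)
  o <- order(time)
  structure(list(events = data.frame(neuron = neuron[o],
                                     time = time[o]),
                 n_neurons = n_sources, duration = duration,
                 seed = seed),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat("Spike data:", nrow(x$events), "events from", x$n_neurons,
      "neurons over", x$duration, "s\n")
  invisible(x)
}

# schedule entry: list(t0, t1, ensemble = k, fraction = 1)
# fraction < 1 stimulates only the first fraction of the ensemble's
# (sorted) members: the deterministic Subset 1; the rest is Subset 2.
resolve_schedule <- function(schedule, layout) {
  lapply(schedule, function(s) {
    if (is.null(s$ensemble) || s$ensemble < 1 ||
        s$ensemble > layout$n_ensembles)
      stop("schedule references unknown ensemble")
    mem <- layout$membership[[s$ensemble]]
    frac <- if (is.null(s$fraction)) 1 else s$fraction
    if (frac <= 0 || frac > 1) stop("fraction must lie in (0, 1]")
    n_stim <- round(length(mem) * frac)
    list(t0 = s$t0, t1 = s$t1, ensemble = s$ensemble,
         neurons = mem[seq_len(n_stim)])
  })
}

#' Canonical five-ensemble stimulation schedule
#'
#' Ensembles 1-5 stimulated for 2 s each at 2-4, 6-8, ..., 18-20 s,
#' followed by stimulation of 75% of ensemble 5 (Subset 1) at 22-24 s.
#'
#' @return List of schedule entries for
#'   [simulate_spiking_network()].
#' @export
five_ensemble_schedule <- function() {
  c(lapply(1:5, function(k)
      list(t0 = 2 + (k - 1) * 4, t1 = 4 + (k - 1) * 4, ensemble = k)),
    list(list(t0 = 22, t1 = 24, ensemble = 5, fraction = 0.75)))
}

#' Simulate the conductance-based spiking network
#'
#' Fixed-step Euler integration (default 0.1 ms) of the LIF network
#' with AMPA/NMDA/GABA conductances and the selected synaptic
#' mechanism. Connectivity is drawn once per seed with probability
#' `p_conn`, excluding self-connections; synaptic weights follow the
#' within/inter-ensemble rule of [ensemble_layout()]. Every neuron
#' receives an independent aggregate of `n_ext` external Poisson
#' sources at `rate_baseline`, delivered through the AMPA/NMDA cascade
#' with weight `w_ext`; schedule entries switch the per-source rate of
#' targeted neurons to `rate_stim` during their windows. On threshold
#' crossing a spike is recorded, the membrane is reset to `Urest` and
#' clamped for `tau_ref`.
#'
#' @param params A [spiking_params()].
#' @param layout An [ensemble_layout()].
#' @param schedule List of entries `list(t0, t1, ensemble, fraction)`.
#' @param duration Simulated time (s).
#' @param dt Time step (s, default 1e-4).
#' @param seed Seed controlling connectivity and Poisson drive.
#' @return A `spike_data` object; neuron ids 1..NE are excitatory,
#'   NE+1..NE+NI inhibitory. Metadata fields include `layout`,
#'   `params`, `schedule`, `clipped_steps` (membrane clipped to the
#'   conductance reversal bounds after Euler overshoot).
#' @export
simulate_spiking_network <- function(params, layout, schedule = list(),
                                     duration, dt = 1e-4, seed = 1) {
  stopifnot(inherits(params, "spiking_params"),
            inherits(layout, "ensemble_layout"))
  set.seed(seed)
  NE <- params$NE; NI <- params$NI; N <- NE + NI
  mech <- params$mech
  sched <- resolve_schedule(schedule, layout)

  # ensemble co-membership -> within/inter weight classes
  shares <- function(mem_list, n) {
    S <- matrix(FALSE, n, length(mem_list))
    for (k in seq_along(mem_list)) S[mem_list[[k]], k] <- TRUE
    tcrossprod(S) > 0          # n x n: share at least one ensemble
  }
  shareE <- shares(layout$membership, NE)
  shareI <- shares(layout$membership_I, NI)
  shareEI <- matrix(FALSE, NI, NE)   # I row, E col
  for (k in seq_len(layout$n_ensembles)) {
    shareEI[layout$membership_I[[k]], layout$membership[[k]]] <- TRUE
  }

  conn <- function(npost, npre) {
    matrix(stats::runif(npost * npre) < params$p_conn, npost, npre)
  }
  # weight matrices, rows postsynaptic
  W_EE <- ifelse(shareE, params$JEE, params$JEEp) * conn(NE, NE)
  diag(W_EE) <- 0
  W_IE <- ifelse(shareEI, params$JIE, params$JIEp) * conn(NI, NE)
  W_EI <- ifelse(t(shareEI), params$JEI, params$JEIp) * conn(NE, NI)
  W_II <- ifelse(shareI, params$JII, params$JIIp) * conn(NI, NI)
  diag(W_II) <- 0

  n_steps <- as.integer(round(duration / dt))
  tau_m <- c(rep(params$tau_m_exc, NE), rep(params$tau_m_inh, NI))
  dt_tau_m <- dt / tau_m
  ref_steps <- as.integer(round(params$tau_ref / dt))

  U <- rep(params$Urest, N)
  g_ampa <- numeric(N); g_nmda <- numeric(N); g_gaba <- numeric(N)
  refc <- integer(N)
  x <- rep(1, NE)                       # per-presynaptic STD variable
  u <- rep(1, NE)                       # per-presynaptic STF variable
  a <- numeric(NE)                      # SFA conductance
  sfa_on <- mech$variant == "sfa"
  std_on <- mech$variant == "std"
  stf_on <- mech$variant == "stf"

  dec_ampa <- dt / params$tau_ampa
  dec_gaba <- dt / params$tau_gaba
  dec_nmda <- dt / params$tau_nmda

  # per-neuron external rate trace: baseline everywhere, stimulated
  # neurons boosted inside their windows (resolved per step below)
  lam_base <- params$n_ext * params$rate_baseline * dt
  lam_stim <- params$n_ext * params$rate_stim * dt
  sched_steps <- lapply(sched, function(s)
    list(i0 = as.integer(floor(s$t0 / dt)) + 1L,
         i1 = as.integer(ceiling(s$t1 / dt)),
         neurons = s$neurons))

  sp_neuron <- vector("list", n_steps)
  clipped <- 0L
  lam <- rep(lam_base, N)

  for (i in seq_len(n_steps)) {
    # external Poisson events (aggregated across sources)
    lam[] <- lam_base
    for (s in sched_steps)
      if (i >= s$i0 && i <= s$i1) lam[s$neurons] <- lam_stim
    next_ext <- stats::rpois(N, lam)
    if (any(next_ext > 0))
      g_ampa <- g_ampa + params$w_ext * next_ext

    g_exc <- params$xi * g_ampa + (1 - params$xi) * g_nmda
    g_inh <- g_gaba
    if (sfa_on) g_inh[1:NE] <- g_inh[1:NE] + a

    dU <- dt_tau_m * ((params$Urest - U) + g_exc * (params$Uexc - U) +
                        g_inh * (params$Uinh - U))
    active <- refc == 0L
    U[active] <- U[active] + dU[active]
    refc[!active] <- refc[!active] - 1L
    # clip Euler overshoot beyond the conductance reversal bounds
    over <- U > params$Uexc | U < params$Uinh
    if (any(over)) {
      clipped <- clipped + sum(over)
      U <- pmin(pmax(U, params$Uinh), params$Uexc)
    }

    sp <- which(U >= params$Uthr & active)
    if (length(sp)) {
      U[sp] <- params$Urest
      refc[sp] <- ref_steps
      sp_neuron[[i]] <- sp

      spE <- sp[sp <= NE]
      spI <- sp[sp > NE] - NE
      if (length(spE)) {
        wEE <- W_EE[, spE, drop = FALSE]
        wIE <- W_IE[, spE, drop = FALSE]
        fac_std <- if (std_on) x[spE] else rep(1, length(spE))
        fac_stf <- if (stf_on) u[spE] else rep(1, length(spE))
        g_ampa[1:NE] <- g_ampa[1:NE] +
          as.numeric(wEE %*% fac_std)
        g_ampa[(NE + 1):N] <- g_ampa[(NE + 1):N] +
          as.numeric(wIE %*% fac_stf)
        if (std_on) x[spE] <- pmax(x[spE] - mech$Ud * x[spE], 1e-12)
        if (stf_on) u[spE] <- pmin(u[spE] +
                                     mech$Uf * (mech$Umax - u[spE]),
                                   mech$Umax)
        if (sfa_on) a[spE] <- a[spE] + mech$b
      }
      if (length(spI)) {
        g_gaba[1:NE] <- g_gaba[1:NE] +
          rowSums(W_EI[, spI, drop = FALSE])
        g_gaba[(NE + 1):N] <- g_gaba[(NE + 1):N] +
          rowSums(W_II[, spI, drop = FALSE])
      }
    }

    g_ampa <- g_ampa * (1 - dec_ampa)
    g_gaba <- g_gaba * (1 - dec_gaba)
    g_nmda <- g_nmda + dec_nmda * (g_ampa - g_nmda)
    if (std_on) x <- pmin(x + dt * (1 - x) / mech$tau_x, 1)
    if (stf_on) u <- pmax(u + dt * (1 - u) / mech$tau_u, 1)
    if (sfa_on) a <- a * (1 - dt / mech$tau_a)
  }

  steps_with <- which(lengths(sp_neuron) > 0)
  neuron <- unlist(sp_neuron[steps_with], use.names = FALSE)
  time <- rep((steps_with - 1L) * dt, lengths(sp_neuron[steps_with]))
  structure(list(events = data.frame(neuron = neuron, time = time),
                 n_neurons = N, NE = NE, NI = NI, duration = duration,
                 dt = dt, seed = seed, layout = layout,
                 params = params, schedule = sched,
                 clipped_steps = clipped),
            class = "spike_data")
}

#' Binned ensemble activity
#'
#' Population rate of each ensemble: spike count of the ensemble's
#' excitatory members per bin, divided by `bin * size`, in Hz.
#'
#' @param spikes A `spike_data` from [simulate_spiking_network()].
#' @param layout An [ensemble_layout()] (defaults to the one stored in
#'   `spikes`).
#' @param bin Bin width (s, default 0.01).
#' @return List with `t` (bin centers) and `activity` (bins x
#'   ensembles matrix, Hz).
#' @export
ensemble_activity <- function(spikes, layout = NULL, bin = 0.01) {
  stopifnot(inherits(spikes, "spike_data"))
  if (bin <= 0) stop("bin must be positive")
  if (is.null(layout)) layout <- spikes$layout
  if (is.null(layout)) stop("no ensemble layout available")
  breaks <- seq(0, spikes$duration + bin, by = bin)
  nb <- length(breaks) - 1L
  act <- matrix(0, nb, layout$n_ensembles)
  for (k in seq_len(layout$n_ensembles)) {
    mem <- layout$membership[[k]]
    if (length(mem) == 0) stop("empty ensemble ", k)
    ev <- spikes$events[spikes$events$neuron %in% mem, "time"]
    counts <- tabulate(findInterval(ev, breaks,
                                    rightmost.closed = TRUE), nb)
    act[, k] <- counts / (bin * length(mem))
  }
  list(t = breaks[-length(breaks)] + bin / 2, activity = act)
}

#' Onset and fixed-point activity differences per stimulation period
#'
#' For each 2-s stimulation period: the onset difference is the maximal
#' ensemble activity of the stimulated ensemble minus the average of
#' the maximal activities of the unstimulated ensembles; the
#' fixed-point difference subtracts the unstimulated ensembles' mean
#' activity from the stimulated ensemble's, both averaged over the
#' middle 1 s of the period.
#'
#' @param activity Result of [ensemble_activity()].
#' @param schedule Schedule entries (with `ensemble` fields); entries
#'   stimulating a fraction < 1 are included with their full ensemble.
#' @param layout The [ensemble_layout()] (for the ensemble count).
#' @return Data frame with columns `t0`, `t1`, `ensemble`,
#'   `onset_diff`, `fixedpoint_diff`.
#' @export
activity_differences <- function(activity, schedule, layout) {
  if (layout$n_ensembles < 2)
    stop("need at least two ensembles for a difference")
  rows <- lapply(schedule, function(s) {
    win <- activity$t >= s$t0 & activity$t < s$t1
    mid <- activity$t >= s$t0 + (s$t1 - s$t0 - 1) / 2 &
      activity$t < s$t0 + (s$t1 - s$t0 + 1) / 2
    k <- s$ensemble
    others <- setdiff(seq_len(layout$n_ensembles), k)
    onset <- max(activity$activity[win, k]) -
      mean(apply(activity$activity[win, others, drop = FALSE], 2, max))
    fpd <- mean(activity$activity[mid, k]) -
      mean(colMeans(activity$activity[mid, others, drop = FALSE]))
    data.frame(t0 = s$t0, t1 = s$t1, ensemble = k,
               onset_diff = onset, fixedpoint_diff = fpd)
  })
  do.call(rbind, rows)
}

#' PCA of binned spiking activity
#'
#' Bins the excitatory spike trains per neuron inside a window,
#' mean-centers each neuron, and computes principal components of the
#' bins x neurons matrix.
#'
#' @param spikes A `spike_data`.
#' @param window Numeric `c(t0, t1)` within the simulation.
#' @param bin Bin width (s, default 0.01).
#' @return List with `explained` (variance fractions), `projection`
#'   (bins x 2 trajectory in the first two PCs), `t` (bin centers),
#'   `var12` (summed fraction of the first two components).
#' @export
pca_variance <- function(spikes, window, bin = 0.01) {
  stopifnot(inherits(spikes, "spike_data"))
  t0 <- window[1]; t1 <- window[2]
  if (t0 < 0 || t1 > spikes$duration || t0 >= t1)
    stop("window must lie within the simulation")
  breaks <- seq(t0, t1, by = bin)
  nb <- length(breaks) - 1L
  if (nb < 2) stop("window must contain at least 2 bins")
  NE <- if (!is.null(spikes$NE)) spikes$NE else spikes$n_neurons
  ev <- spikes$events[spikes$events$neuron <= NE &
                        spikes$events$time >= t0 &
                        spikes$events$time < t1, ]
  X <- matrix(0, nb, NE)
  if (nrow(ev)) {
    bi <- findInterval(ev$time, breaks, rightmost.closed = TRUE)
    for (j in seq_len(nrow(ev))) X[bi[j], ev$neuron[j]] <-
        X[bi[j], ev$neuron[j]] + 1
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(explained = expl,
       projection = pc$x[, 1:2, drop = FALSE],
       t = breaks[-length(breaks)] + bin / 2,
       var12 = sum(expl[1:2]))
}
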
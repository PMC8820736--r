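# canonical single-ensemble configuration used across tests
canon <- function() {
  list(weights = ensemble_weights(JEE = 1.8, JIE = 1.0, JEI = 1.0,
                                  JII = 0.6),
       gain = gain_params(2, 2),
       params = rate_params(tauE = 0.020, tauI = 0.010,
                            gE = 1.55, gI = 2.0),
       gI = 2.0, gE_base = 1.55, gE_stim = 3.0)
}

# canonical stimulation episode: drive raised 1.55 -> 3.0 during [2, 4) s
canon_protocol <- function(t0 = 2, t1 = 4, delta = 1.45) {
  stim_protocol(list(list(t_start = t0, t_end = t1, delta_gE = delta)))
}

# central-difference Jacobian of a vector field
fd_jacobian <- function(f, s0, h = 1e-6) {
  n <- length(s0)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h
    J[, j] <- (f(s0 + e) - f(s0 - e)) / (2 * h)
  }
  J
}

# vector field of the plain 2D ensemble
vf_2d <- function(w, p, g) {
  function(s) c(
    (-s[1] + powerlaw_gain(w$JEE * s[1] - w$JEI * s[2] + p$gE,
                           g$alphaE)) / p$tauE,
    (-s[2] + powerlaw_gain(w$JIE * s[1] - w$JII * s[2] + p$gI,
                           g$alphaI)) / p$tauI)
}

random_weights <- function() {
  ensemble_weights(JEE = runif(1, 0.1, 3), JIE = runif(1, 0, 2),
                   JEI = runif(1, 0.1, 2), JII = runif(1, 0, 2))
}
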
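test_that("block Jacobian structure at the co-tuning extremes", {
  # m = 1 equals the global-inhibition matrix entrywise
  s1 <- block_network_spec(3, 2, 1, 1.5, 2, 0.5, 1, 0.1, m = 1)
  Q <- build_block_jacobian(s1)
  expect_equal(Q[1:3, 4:6], matrix(-1, 3, 3))
  expect_equal(Q[4:6, 1:3], matrix(1.5, 3, 3))
  expect_equal(diag(Q[4:6, 4:6]), rep(-2 - 1, 3))
  # m = 0 with k = 0 decouples into independent 2x2 ensembles
  s0 <- block_network_spec(3, 2, 1, 1.5, 2, 0.5, 1, 0, m = 0)
  Q0 <- build_block_jacobian(s0)
  off <- Q0[1:3, 4:6]; diag(off) <- 0
  expect_true(all(off == 0))
  expect_error(block_network_spec(1, 1, 1, 1, 1, 1, 1, 0.1), "N")
  expect_error(block_network_spec(2, -1, 1, 1, 1, 1, 1, 0.1), ">= 0")
  expect_error(block_network_spec(2, 1, 1, 1, 1, 1, 1, 0.1, m = 2),
               "m must")
})

test_that("analytic eigenvalues match the numeric eigensolver", {
  set.seed(21)
  for (i in 1:1000) {
    N <- sample(2:8, 1)
    m <- sample(c(1, runif(1)), 1)
    sp <- block_network_spec(N, a = runif(1, 0, 100),
                             b = runif(1, 0, 50), c = runif(1, 0, 50),
                             d = runif(1, 0, 100), e = runif(1, 1, 100),
                             f = runif(1, 1, 150),
                             k = runif(1, 0, 0.9), m = m)
    ev <- analytic_block_eigenvalues(sp)
    expect_length(ev$values, 2 * N)
    num <- eigen(build_block_jacobian(sp), only.values = TRUE)$values
    expect_equal(sort(Re(ev$values)), sort(Re(num)), tolerance = 1e-10)
    expect_equal(sort(abs(Im(ev$values))), sort(abs(Im(num))),
                 tolerance = 1e-10)
  }
})

test_that("the simple eigenvalue pair is shared between variants", {
  sp_g <- block_network_spec(4, 60, 30, 30, 40, 50, 100, 0.1, m = 1)
  sp_c <- block_network_spec(4, 60, 30, 30, 40, 50, 100, 0.1, m = 0.5)
  eg <- analytic_block_eigenvalues(sp_g)
  ec <- analytic_block_eigenvalues(sp_c)
  expect_equal(eg$lambda3, ec$lambda3)
  expect_equal(eg$lambda4, ec$lambda4)
  expect_lt(Re(ec$lambda1), Re(eg$lambda1))   # co-tuning shifts lead down
})

test_that("co-tuned uni-stable region contains the global one", {
  map <- unistability_map(seq(0, 150, length.out = 16),
                          seq(0, 150, length.out = 16))
  expect_true(all(map$unistable_cotuned[map$unistable_global]))
  expect_gt(sum(map$unistable_cotuned), sum(map$unistable_global))
  # a = 0 row: no recurrent excitation, always uni-stable
  expect_true(all(map$unistable_global[map$a == 0]))
  # the lambda1 boundary sits at a = e/(1-k), independent of d
  e <- 50; k <- 0.1
  a_crit <- e / (1 - k)
  sp_lo <- block_network_spec(2, a_crit - 1, 1, 1, 10, e, 100, k, m = 1)
  sp_hi <- block_network_spec(2, a_crit + 1, 1, 1, 10, e, 100, k, m = 1)
  expect_lt(Re(analytic_block_eigenvalues(sp_lo)$lambda1), 0)
  expect_gt(Re(analytic_block_eigenvalues(sp_hi)$lambda1), 0)
})

test_that("uni-stability verdicts agree with brute-force simulation", {
  # small networks built from concrete weights: compare the analytic
  # verdict on gain-scaled terms with multi-start simulation
  set.seed(31)
  e <- 50; f <- 100
  for (a in c(20, 60, 110)) for (d in c(30, 90)) {
    bc <- 0.9 * a * d
    sp <- block_network_spec(2, a, sqrt(bc), sqrt(bc), d, e, f, 0.1,
                             m = 1)
    # linear rate network with the same Jacobian, 50 random starts
    Q <- build_block_jacobian(sp)
    finals <- replicate(20, {
      s <- runif(4, 0, 1)
      for (i in 1:4000) {
        s <- s + 1e-4 * as.numeric(Q %*% s)
        s <- pmin(pmax(s, -1e6), 1e6)
      }
      s
    })
    collapsed <- max(abs(finals)) < 1e-3
    expect_identical(collapsed,
                     max(Re(analytic_block_eigenvalues(sp)$values)) < 0,
                     label = sprintf("a=%g d=%g", a, d))
  }
})

test_that("attractor demo: strong recurrence persists, weak returns", {
  pa <- nta_preset("two_ensemble_attractor")
  eps <- list(list(t_start = 4, t_end = 6, target = "E1",
                   delta_g = 0.8))
  tr <- simulate_two_ensembles(pa$weights, gE1 = 2.2, gE2 = 2.2,
                               gI = 2.0, episodes = eps,
                               mech = mech_std(1, 0.2),
                               init_noise = 1e-3, seed = 42,
                               duration = 9, record_every = 10L)
  pre <- colMeans(tr$rates[tr$t > 3.5 & tr$t < 4, c("E1", "E2")])
  post <- colMeans(tr$rates[tr$t > 8.5, c("E1", "E2")])
  # symmetric start splits into a persistent asymmetric state
  expect_gt(max(pre) / max(min(pre), 1e-6), 5)
  expect_gt(max(post) / max(min(post), 1e-6), 5)
  tru <- simulate_two_ensembles(pa$weights_uni, gE1 = 2.2, gE2 = 2.2,
                                gI = 2.0, episodes = eps,
                                mech = mech_std(1, 0.2),
                                init_noise = 1e-3, seed = 42,
                                duration = 9, record_every = 10L)
  preu <- colMeans(tru$rates[tru$t > 3.5 & tru$t < 4, c("E1", "E2")])
  postu <- colMeans(tru$rates[tru$t > 8.5, c("E1", "E2")])
  expect_lt(abs(preu[1] - preu[2]) / mean(preu), 0.05)
  expect_lt(abs(postu[1] - postu[2]) / mean(postu), 0.05)
  # stimulated ensemble rose during stimulation, then came back
  stim_lvl <- mean(tru$rates[tru$t > 4.5 & tru$t < 5.5, "E1"])
  expect_gt(stim_lvl, 2 * preu[1])
  expect_lt(abs(mean(postu) - mean(preu)) / mean(preu), 0.05)
})

test_that("decoupled identical ensembles stay exactly symmetric", {
  w0 <- two_ensemble_weights(1.2, 1, 1, 0.6, 0, 0, 0, 0)
  eps <- list(list(t_start = 1, t_end = 2, target = "E1", delta_g = 0.5),
              list(t_start = 1, t_end = 2, target = "E2", delta_g = 0.5))
  tr <- simulate_two_ensembles(w0, gE1 = 1.3, gE2 = 1.3, gI = 2,
                               episodes = eps, mech = mech_std(1, 0.2),
                               duration = 3, record_every = 10L)
  expect_equal(tr$rates[, "E1"], tr$rates[, "E2"])
  expect_equal(tr$rates[, "I1"], tr$rates[, "I2"])
})

test_that("subset split resolves the all-to-all network consistently", {
  pc <- nta_preset("two_ensemble_cotuned")
  # stimulating both subsets equally must reproduce the unsplit network
  eps_split <- list(list(t_start = 1, t_end = 2, target = "E1",
                         delta_g = 1.0))
  tr_split <- simulate_two_ensembles(pc$weights, gE1 = 1.35,
                                     gE2 = 1.35, gI = 2,
                                     episodes = eps_split,
                                     mech = mech_std(1, 0.2),
                                     subset_split = c(0.75, 0.25),
                                     duration = 3, record_every = 10L)
  tr_full <- simulate_two_ensembles(pc$weights, gE1 = 1.35,
                                    gE2 = 1.35, gI = 2,
                                    episodes = eps_split,
                                    mech = mech_std(1, 0.2),
                                    duration = 3, record_every = 10L)
  expect_equal(tr_split$rates[, "E1a"], tr_full$rates[, "E1"],
               tolerance = 1e-10)
  expect_equal(tr_split$rates[, "E1b"], tr_full$rates[, "E1"],
               tolerance = 1e-10)
  expect_error(simulate_two_ensembles(
    pc$weights, 1.35, 1.35, 2, subset_split = c(0.75, 0.3),
    duration = 1), "sum to 1")
})

test_that("linear response of the unstimulated ensemble", {
  fd <- c(0.8, 0.7, 0.9, 0.85)
  # decoupled ensembles: exactly zero response
  w0 <- two_ensemble_weights(1.2, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(delta_rE2_linear_response(w0, fd, 0.01)$delta_rE2, 0)
  # full expression equals the (I - FJ)^{-1} F linear solve
  w <- two_ensemble_weights(1.2, 1, 1, 1, 0.36, 0.4, 0.1, 0.1)
  out <- delta_rE2_linear_response(w, fd, 0.01)
  J <- matrix(c(1.2, 0.36, -1, -0.1,
                0.36, 1.2, -0.1, -1,
                1, 0.4, -1, -0.1,
                0.4, 1, -0.1, -1), 4, byrow = TRUE)
  FF <- diag(fd)
  oracle <- solve(diag(4) - FF %*% J, FF %*% c(0.01, 0, 0, 0))[2]
  expect_equal(out$delta_rE2, oracle, tolerance = 1e-12)
  # weak-coupling approximation converges to the full value
  ratios <- vapply(c(0.2, 0.1, 0.02), function(s) {
    ws <- two_ensemble_weights(1.2, 1, 1, 1, 0.36 * s, 0.4 * s,
                               0.1 * s, 0.1 * s)
    o <- delta_rE2_linear_response(ws, fd, 0.01)
    o$delta_rE2_approx / o$delta_rE2
  }, numeric(1))
  expect_true(all(abs(ratios - 1) < 1e-2))
  expect_lt(abs(ratios[3] - 1), abs(ratios[1] - 1))
  # growing cross E-to-I (or cross I-to-E) coupling suppresses the
  # response, within the stable regime det(I - FJ) > 0
  for (cross in c("JIEp", "JEIp")) {
    vals <- vapply(c(0.1, 0.6, 1.2), function(jx) {
      args <- list(JEE = 1.2, JIE = 1, JEI = 1, JII = 1,
                   JEEp = 0.05, JIEp = 0.05, JEIp = 0.05, JIIp = 0.05)
      args[[cross]] <- jx
      o <- delta_rE2_linear_response(do.call(two_ensemble_weights, args),
                                     fd, 0.01)
      expect_gt(o$det_IFJ, 0)
      o$delta_rE2
    }, numeric(1))
    expect_true(all(diff(vals) < 0))
    expect_lt(vals[3], 0)
  }
})

test_that("morph/beta parameterization", {
  m0 <- morph_beta_params(0, 0.6)
  expect_equal(c(m0$gE1_stim, m0$gE2_stim), c(4.0, 1.35))
  m5 <- morph_beta_params(0.5, 0.6)
  expect_equal(c(m5$gE1_stim, m5$gE2_stim), c(2.675, 2.675))
  for (beta in c(0, 0.3, 0.77, 1)) {
    m <- morph_beta_params(0.2, beta)
    expect_equal(m$JEE + m$JEEp, m$Jtot)
  }
  expect_error(morph_beta_params(1.2, 0.5), "p must")
})
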
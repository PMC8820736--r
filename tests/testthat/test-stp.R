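test_that("closed-form STP steady states", {
  expect_equal(stp_steady_state(mech_std(1, 0.2), 20), 0.2)
  expect_equal(stp_steady_state(mech_std(1, 0.2), 0), 1)
  expect_equal(stp_steady_state(mech_stf(1, 6, 0.2), 20), 5)
  expect_equal(stp_steady_state(mech_stf(1, 6, 0.2), 0), 1)
  expect_error(stp_steady_state(mech_none(), 1), "STD or STF")
})

test_that("3D STD Jacobian matches finite differences at a fixed point", {
  cc <- canon()
  std <- mech_std(1, 0.2)
  # self-consistent stimulated fixed point: solve with frozen-x scan
  tr <- simulate_ensemble(cc$weights, cc$params, cc$gain, std,
                          canon_protocol(), duration = 3.5)
  i <- length(tr$t)
  s0 <- c(tr$rE[i], tr$rI[i], tr$aux[i])
  vf <- function(s) c(
    (-s[1] + powerlaw_gain(s[3] * 1.8 * s[1] - s[2] + 3.0, 2)) / 0.020,
    (-s[2] + powerlaw_gain(s[1] - 0.6 * s[2] + 2.0, 2)) / 0.010,
    (1 - s[3]) / 0.2 - s[3] * s[1])
  expect_lt(max(abs(vf(s0))), 1e-3)          # effectively at steady state
  J_an <- jacobian_std_3d(cc$weights,
                          rate_params(0.020, 0.010, 3.0, 2),
                          cc$gain, std, s0[1], s0[2], s0[3])
  expect_equal(unname(J_an$entries), fd_jacobian(vf, s0),
               tolerance = 1e-4)
  # polynomial pieces agree with the assembled matrix
  expect_equal(J_an$tr, sum(diag(J_an$entries)), tolerance = 1e-10)
  expect_equal(J_an$det, det(J_an$entries), tolerance = 1e-8)
})

test_that("large-rate limit with depressed synapses is stabilizable", {
  cc <- canon()
  std <- mech_std(1, 0.2)
  rE <- 1e4
  x <- stp_steady_state(std, rE)
  J <- jacobian_std_3d(cc$weights, cc$params, cc$gain, std, rE,
                       rI = 1e4, x = x)
  expect_gt(-J$tr, 0)
  expect_gt(J$cofactor_sum, 0)
  expect_gt(-J$det, 0)
  expect_true(all(Re(J$eigenvalues) < 0))
})

test_that("characteristic function with depression", {
  cc <- canon()
  zg <- seq(-2, 8, length.out = 300)
  # x = 1 reproduces the plain curve exactly
  expect_equal(characteristic_function_std(cc$weights, cc$params,
                                           cc$gain, 1.55, 2, 1, zg)$F,
               characteristic_function(cc$weights, cc$params, cc$gain,
                                       1.55, 2, zg)$F)
  # depression flips the effective determinant sign
  expect_equal(-0.5 * 1.8 * 0.6 + 1.0, 0.46)
  # with det > 0 the curve bends downward at large z
  f_dep <- characteristic_function_std(cc$weights, cc$params, cc$gain,
                                       1.55, 2, 0.5,
                                       seq(50, 500, length.out = 100))$F
  expect_true(all(diff(f_dep) < 0))
  f_full <- characteristic_function(cc$weights, cc$params, cc$gain,
                                    1.55, 2,
                                    seq(50, 500, length.out = 100))$F
  expect_true(all(diff(f_full) > 0))
})

test_that("ISN index equals the leading eigenvalue of the frozen-I subsystem", {
  cc <- canon()
  std <- mech_std(1, 0.2)
  set.seed(11)
  for (i in 1:500) {
    w <- random_weights()
    rE <- runif(1, 0.01, 20); x <- runif(1, 0.01, 1)
    kE <- 2 * sqrt(rE)
    M1 <- matrix(c((x * w$JEE * kE - 1) / 0.020,
                   w$JEE * rE * kE / 0.020,
                   -x, -1 / 0.2 - rE), 2, byrow = TRUE)
    expect_equal(isn_index_std(w, cc$params, cc$gain, std, rE, x),
                 max(Re(eigen(M1, only.values = TRUE)$values)),
                 tolerance = 1e-8)
  }
})

test_that("paradoxical threshold and regime inclusion at rE = 1", {
  cc <- canon()
  std <- mech_std(1, 0.2)
  a <- isn_paradox_analysis_std(ensemble_weights(1.2, 1, 1, 0.6),
                                cc$params, cc$gain, std, rE = 1,
                                x = 0.5)
  expect_equal(a$paradox_threshold, 1 / 2.4)
  expect_gt(a$kI_nullcline, 0)
  map <- std_regime_map(cc$weights, cc$params, cc$gain, std,
                        JEE_grid = seq(0.1, 3, by = 0.1),
                        x_grid = seq(0.05, 1, by = 0.05), rE = 1)
  expect_true(all(map$isn[map$paradoxical]))         # paradox => ISN
  expect_gt(sum(map$isn), sum(map$paradoxical))       # strict subset
  expect_gt(sum(map$paradoxical), 0)
})

test_that("ISN index along the STD trajectory switches sign with input", {
  cc <- canon()
  std <- mech_std(1, 0.2)
  tr <- simulate_ensemble(cc$weights, cc$params, cc$gain, std,
                          canon_protocol(), duration = 6)
  ii <- isn_trajectory_index(tr, cc$weights, cc$params, cc$gain, std)
  expect_lt(mean(ii$isn_index[ii$t > 1.5 & ii$t < 2]), 0)
  expect_gt(mean(ii$isn_index[ii$t > 3 & ii$t < 4]), 0)
  expect_lt(mean(ii$isn_index[ii$t > 5.5]), 0)
  expect_gt(length(attr(ii, "sign_changes")), 0)
  expect_error(isn_trajectory_index(
    simulate_ensemble(cc$weights, cc$params, cc$gain, mech_none(),
                      stim_protocol(), duration = 0.1),
    cc$weights, cc$params, cc$gain, std), "STD")
})

test_that("elevated baseline drive puts the ensemble in the ISN regime", {
  cc <- canon()
  std <- mech_std(1, 0.2)
  p_hi <- rate_params(0.020, 0.010, gE = 2.3, gI = 2)
  tr <- simulate_ensemble(cc$weights, p_hi, cc$gain, std,
                          stim_protocol(), duration = 4)
  ii <- isn_trajectory_index(tr, cc$weights, p_hi, cc$gain, std)
  expect_gt(mean(ii$isn_index[ii$t > 3.5]), 0)
})

test_that("paradoxical probe: rI falls during stimulation, rises at baseline", {
  cc <- canon()
  std <- mech_std(1, 0.2)
  base <- stim_protocol(
    list(list(t_start = 6, t_end = 8, delta_gE = 1.45)),
    list(list(type = "inject_to_I", t0 = 2, t1 = 3, magnitude = 0.3)))
  trb <- simulate_ensemble(cc$weights, cc$params, cc$gain, std, base,
                           duration = 9)
  expect_gt(mean(trb$rI[trb$t > 2.5 & trb$t < 3]),
            mean(trb$rI[trb$t > 1.8 & trb$t < 2]))
  stim <- stim_protocol(
    list(list(t_start = 2, t_end = 6, delta_gE = 1.45)),
    list(list(type = "inject_to_I", t0 = 4, t1 = 5, magnitude = 0.3)))
  trs <- simulate_ensemble(cc$weights, cc$params, cc$gain, std, stim,
                           duration = 7)
  expect_lt(mean(trs$rI[trs$t > 4.5 & trs$t < 5]),
            mean(trs$rI[trs$t > 3.8 & trs$t < 4]))
})

test_that("frozen-inhibition perturbation decays at baseline, explodes when ISN", {
  cc <- canon()
  std <- mech_std(1, 0.2)
  pb <- stim_protocol(list(), list(
    list(type = "freeze_inhibition", t0 = 2, t1 = 2.3),
    list(type = "perturb_rE", t = 2.05, magnitude = 0.05)))
  tb <- simulate_ensemble(cc$weights, cc$params, cc$gain, std, pb,
                          duration = 3)
  r_pre <- tb$rE[max(which(tb$t < 2.05))]
  expect_lt(max(tb$rE[tb$t > 2.1 & tb$t < 2.3]), r_pre + 0.06)
  expect_lt(abs(tail(tb$rE, 1) - r_pre), 0.01)
  ps <- stim_protocol(
    list(list(t_start = 2, t_end = 6, delta_gE = 1.45)),
    list(list(type = "freeze_inhibition", t0 = 4, t1 = 4.3),
         list(type = "perturb_rE", t = 4.05, magnitude = 0.05)))
  ts <- simulate_ensemble(cc$weights, cc$params, cc$gain, std, ps,
                          duration = 7)
  r_pre <- ts$rE[max(which(ts$t < 4.05))]
  expect_gt(max(ts$rE[ts$t > 4.05 & ts$t < 4.3]), 100 * r_pre)
  expect_false(ts$diverged)   # STD re-stabilizes after the excursion
})

test_that("supralinear STD network amplifies far beyond the linear network", {
  cc <- canon()
  std <- mech_std(1, 0.2)
  tr <- simulate_ensemble(cc$weights, cc$params, cc$gain, std,
                          canon_protocol(), duration = 5)
  f <- extract_features(tr, c(2, 4))
  amp_nl <- amplification_index(f$onset_peak, 1.45)
  trl <- simulate_ensemble(cc$weights, cc$params, gain_params(1, 1),
                           std, canon_protocol(), duration = 5)
  fl <- extract_features(trl, c(2, 4))
  amp_lin <- amplification_index(fl$onset_peak, 1.45)
  expect_gt(amp_nl, 10 * amp_lin)
})
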
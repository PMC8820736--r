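test_that("Jacobian matches finite differences at a fixed point", {
  cc <- canon()
  fp <- find_fixed_points(cc$weights, cc$params, cc$gain, 1.55, 2)
  st <- fp$points[fp$points$stability == "stable", ][1, ]
  J_an <- jacobian_2d(cc$weights, cc$params, cc$gain, st$rE, st$rI)
  J_fd <- fd_jacobian(vf_2d(cc$weights, cc$params, cc$gain),
                      c(st$rE, st$rI))
  expect_equal(unname(J_an$entries), J_fd, tolerance = 1e-6)
})

test_that("silent state has the pure leak Jacobian", {
  cc <- canon()
  J <- jacobian_2d(cc$weights, cc$params, cc$gain, 0, 0)
  expect_equal(unname(J$entries), diag(c(-1 / 0.020, -1 / 0.010)))
  expect_error(jacobian_2d(cc$weights, cc$params, cc$gain, -1, 0),
               ">= 0")
})

test_that("linear gain makes stability input-independent", {
  cc <- canon()
  glin <- gain_params(1, 1)
  verdicts <- vapply(list(c(0.1, 0.1), c(5, 3), c(50, 80)),
                     function(s) stability_conditions_2d(
                       cc$weights, cc$params, glin, s[1], s[2])$stable,
                     logical(1))
  expect_true(all(verdicts == verdicts[1]))
  # and the ISN index is rate-independent
  idx <- isn_index_2d(cc$weights, cc$params, glin, c(0.5, 5, 50))
  expect_equal(diff(range(idx)), 0)
})

test_that("stability verdict agrees with numeric eigenvalues", {
  cc <- canon()
  set.seed(101)
  for (i in 1:1000) {
    w <- random_weights()
    rE <- runif(1, 0, 20); rI <- runif(1, 0, 20)
    sc <- stability_conditions_2d(w, cc$params, cc$gain, rE, rI)
    ev <- jacobian_2d(w, cc$params, cc$gain, rE, rI)$eigenvalues
    expect_identical(sc$stable, all(Re(ev) < 0))
  }
})

test_that("ISN index of the 2D ensemble", {
  cc <- canon()
  expect_equal(isn_index_2d(cc$weights, cc$params, cc$gain,
                            (1 / 3.6)^2), 0, tolerance = 1e-12)
  expect_equal(isn_index_2d(cc$weights, cc$params, cc$gain, 0),
               -1 / 0.020)
})

test_that("characteristic function values and monotonicity in gE", {
  cc <- canon()
  zg <- seq(-2, 6, length.out = 201)   # includes z = 0
  cf <- characteristic_function(cc$weights, cc$params, cc$gain,
                                1.55, 2, zg)
  expect_equal(cf$F[zg == 0], -(-0.6 * 1.55 + 2.0)^2 + 1.55,
               tolerance = 1e-12)
  cf_hi <- characteristic_function(cc$weights, cc$params, cc$gain,
                                   1.85, 2, zg)
  expect_true(all(cf_hi$F > cf$F))
  # equal increments of both drives still shift F upward when JII > JEI
  w2 <- ensemble_weights(1.8, 1.0, 1.0, 1.3)
  f0 <- characteristic_function(w2, cc$params, cc$gain, 1.55, 2, zg)$F
  f1 <- characteristic_function(w2, cc$params, cc$gain, 1.85, 2.3, zg)$F
  expect_true(all(f1 > f0))
  expect_error(characteristic_function(
    ensemble_weights(1.8, 1, 0, 0.6), cc$params, cc$gain, 1.55, 2, zg),
    "JEI")
  expect_error(characteristic_function(cc$weights, cc$params, cc$gain,
                                       1.55, 2, c(1, 1, 2)),
               "strictly increasing")
})

test_that("fixed-point structure: two below threshold, none above", {
  cc <- canon()
  fp_lo <- find_fixed_points(cc$weights, cc$params, cc$gain, 1.55, 2)
  expect_equal(fp_lo$n_points, 2L)
  expect_setequal(fp_lo$points$stability, c("stable", "saddle"))
  fp_hi <- find_fixed_points(cc$weights, cc$params, cc$gain, 3.0, 2)
  expect_equal(fp_hi$n_points, 0L)
})

test_that("stable fixed points agree with long-time simulation", {
  cc <- canon()
  fp <- find_fixed_points(cc$weights, cc$params, cc$gain, 1.55, 2)
  st <- fp$points[fp$points$stability == "stable", ][1, ]
  tr <- simulate_ensemble(cc$weights, cc$params, cc$gain, mech_none(),
                          stim_protocol(), duration = 4,
                          init = list(rE = st$rE * 1.1,
                                      rI = st$rI * 0.9))
  expect_lt(abs(tail(tr$rE, 1) - st$rE), 1e-4)
  expect_lt(abs(tail(tr$rI, 1) - st$rI), 1e-4)
})

test_that("roots of F coincide with direct 2D steady-state solutions", {
  cc <- canon()
  set.seed(7)
  n_checked <- 0
  while (n_checked < 200) {
    w <- random_weights()
    gE <- runif(1, 0, 3); gI <- runif(1, 0, 3)
    fp <- tryCatch(find_fixed_points(w, cc$params, cc$gain, gE, gI),
                   error = function(e) NULL)
    if (is.null(fp) || fp$n_points == 0) next
    for (i in seq_len(fp$n_points)) {
      res <- c(
        -fp$points$rE[i] + powerlaw_gain(
          w$JEE * fp$points$rE[i] - w$JEI * fp$points$rI[i] + gE, 2),
        -fp$points$rI[i] + powerlaw_gain(
          w$JIE * fp$points$rE[i] - w$JII * fp$points$rI[i] + gI, 2))
      expect_lt(max(abs(res)), 1e-8 * (1 + abs(fp$points$rE[i])))
    }
    n_checked <- n_checked + 1
  }
})

test_that("critical input separates the regimes and is monotone in JEE", {
  cc <- canon()
  gc <- critical_input(cc$weights, cc$params, cc$gain, gI = 2,
                       bracket = c(1.55, 3))
  expect_gt(gc, 1.55); expect_lt(gc, 3.0)
  expect_gt(find_fixed_points(cc$weights, cc$params, cc$gain,
                              gc - 1e-3, 2)$n_points, 0)
  expect_equal(find_fixed_points(cc$weights, cc$params, cc$gain,
                                 gc + 1e-3, 2)$n_points, 0L)
  # threshold decreases as recurrent excitation grows
  gcs <- vapply(c(1.7, 1.8, 2.0), function(jee)
    critical_input(ensemble_weights(jee, 1, 1, 0.6), cc$params,
                   cc$gain, gI = 2, bracket = c(0.5, 5)),
    numeric(1))
  expect_true(all(diff(gcs) < 0))
  # det(J) >= 0: no positive-feedback threshold
  out <- critical_input(ensemble_weights(1.0, 2.0, 1.0, 1.5),
                        cc$params, cc$gain, gI = 2)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "det")
})

test_that("regime scan grows its unstable region with JEE and gE", {
  cc <- canon()
  scan <- regime_scan_2d(cc$weights, cc$params, cc$gain, gI = 2,
                         JEE_grid = c(1.6, 1.9, 2.2),
                         gE_grid = c(1.0, 1.8, 2.6))
  unstable <- scan$n_fixed_points == 0
  m <- matrix(unstable, nrow = 3)          # rows: JEE, cols: gE
  # once unstable at some gE, stays unstable for larger gE (per JEE row)
  for (r in 1:3) expect_true(all(diff(m[r, ]) >= 0))
  # once unstable at some JEE, stays unstable for larger JEE (per column)
  for (cl in 1:3) expect_true(all(diff(m[, cl]) >= 0))
})
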
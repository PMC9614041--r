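test_that("contractile force is the product of its three factors", {
  h <- hill_params(f0_iso = 100)
  expect_identical(contractile_force(1, 1, 1, h), 100)
  expect_identical(contractile_force(0, 0.7, 0.9, h), 0)
  expect_equal(contractile_force(0.5, 0.8, 0.9, h), 36)
  expect_error(contractile_force(1.2, 1, 1, h), "\\[0, 1\\]")
  expect_error(contractile_force(0.5, -1, 1, h), "fl")
  # multiplicative separability: each factor acts linearly holding the others
  expect_equal(contractile_force(0.4, 0.6, 0.5, h),
               0.4 * contractile_force(1, 0.6, 0.5, h))
  expect_equal(contractile_force(0.4, 0.6, 0.5, h),
               0.6 * contractile_force(0.4, 1, 0.5, h))
})

test_that("force-length factor peaks at the optimum and is symmetric", {
  expect_identical(force_length(1), 1)
  expect_equal(force_length(1.2), force_length(0.8))
  expect_equal(force_length(1.45, width = 0.45), exp(-1))
  expect_true(all(force_length(seq(0.5, 1.8, by = 0.1)) <= 1))
  expect_error(force_length(0), "l_norm")
})

test_that("series-elastic force is slack below l_u and calibrated at strain u0", {
  h <- hill_params(f0_iso = 1000, l_u = 0.2, u0 = 0.04)
  expect_identical(sec_force(0.2, h), 0)
  expect_identical(sec_force(0.18, h), 0)
  expect_equal(sec_force(0.2 * 1.04, h), 1000)
  # continuity at l_u and monotone increase above it
  expect_lt(sec_force(0.2 + 1e-9, h), 1e-3)
  l <- seq(0.2, 0.22, length.out = 20)
  expect_true(all(diff(sec_force(l, h)) > 0))
  # linear variant obeys the same calibration
  hl <- hill_params(f0_iso = 1000, l_u = 0.2, u0 = 0.04, sec_form = "linear")
  expect_identical(sec_force(0.19, hl), 0)
  expect_equal(sec_force(0.2 * 1.04, hl), 1000)
  expect_equal(sec_force(0.2 * 1.02, hl), 500)
})

test_that("pennate force balance and tendon closure hold", {
  h0 <- hill_params(alpha = 0)
  expect_identical(pec_force(10, 10, h0), 0)
  expect_equal(pec_force(4, 10, h0), 6)
  expect_equal(tendon_force(6, 4, h0), 10)
  expect_identical(tendon_force(5, 0, h0), 5)
  h60 <- hill_params(alpha = 60)
  expect_equal(pec_force(4, 10, h60), (10 - 4 * 0.5) / 0.5, tolerance = 1e-12)
  expect_error(pec_force(1, 1, hill_params(alpha = 90)), "alpha")
  # general theorem of the two balances: f_t = f_sec + f_pec (1 - cos alpha),
  # hence f_t = f_sec at alpha = 0 (the loop-closing case above)
  for (alpha in c(0, 15, 45, 80)) {
    h <- hill_params(alpha = alpha)
    ca <- cos(alpha * pi / 180)
    for (f_cc in c(0, 3, 11)) for (f_sec in c(0, 2, 9)) {
      f_pec <- pec_force(f_cc, f_sec, h)
      expect_equal(tendon_force(f_pec, f_cc, h), f_sec + f_pec * (1 - ca),
                   tolerance = 1e-12)
    }
    # on the series-transmission locus f_sec = f_cc cos(alpha) the chain
    # f_t = f_pec + f_sec holds exactly (and the balance gives f_pec = 0)
    for (f_cc in c(0, 3, 11)) {
      f_sec <- f_cc * ca
      f_pec <- pec_force(f_cc, f_sec, h)
      expect_equal(f_pec, 0, tolerance = 1e-12)
      expect_equal(tendon_force(f_pec, f_cc, h), f_pec + f_sec,
                   tolerance = 1e-12)
    }
  }
})

test_that("force-velocity factor is the normalized inverted Hill relation", {
  expect_identical(force_velocity_factor(0, 1000, 2), 1)
  expect_identical(force_velocity_factor(1000, 1000, 2), 0)
  expect_equal(force_velocity_factor(500, 1000, 2), 500 / 1250)
  expect_identical(force_velocity_factor(2000, 1000, 2), 0)  # clamped
})

test_that("the full force chain composes consistently", {
  h <- hill_params(f0_iso = 1000, l_u = 0.2, alpha = 0)
  row <- hill_evaluate(a = 1, l_norm = 1, v = 0, l_sec = 0.2 * 1.04, params = h)
  expect_equal(row$f_cc, 1000)
  expect_equal(row$f_sec, 1000)
  expect_equal(row$f_pec, 0)
  expect_equal(row$f_t, row$f_pec + row$f_sec)
})

test_that("Hill parameter validation names the offending field", {
  expect_error(hill_params(u0 = 1.5), "u0")
  expect_error(hill_params(alpha = 95), "alpha")
  expect_error(hill_params(f0_iso = -1), "f0_iso")
})
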
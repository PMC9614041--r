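test_that("strain follows the shared-load formula and rejects invalid states", {
  p <- default_pcm()
  expect_equal(pcm_strain(1, 0, 0, p), 0)
  expect_equal(pcm_strain(2, 1, 0, p), -4)        # (0 - 1*8)/2
  expect_equal(pcm_strain(3, 2, 10, p), -4)       # (10/2.5 - 16)/3
  expect_error(pcm_strain(0, 0, 0, p), "unbound")
  expect_error(pcm_strain(2, 3, 0, p), "j")
  expect_error(pcm_strain(5, 0, 0, p), "i")       # i > N = 4
})

test_that("force balance reconstructs the applied force identically", {
  p <- default_pcm(N = 10)
  expect_equal(pcm_force_balance(1, 0, 0, p), 0)
  expect_equal(pcm_force_balance(4, 2, 7.3, p), 7.3)
  expect_equal(pcm_force_balance(2, 2, -1.0, p), -1.0)
  for (i in 1:10) for (j in 0:i) for (f in c(-20, -1, 0, 3.7, 55, 100)) {
    expect_equal(pcm_force_balance(i, j, f, p), f, tolerance = 1e-12)
  }
})

test_that("post-power-stroke load combines strain and stroke increment", {
  p <- default_pcm()
  expect_equal(pcm_post_stroke_force(1, 0, 0, p), 20)    # 2.5 * 8
  expect_equal(pcm_post_stroke_force(1, 1, 0, p), 0)     # eps = -d
  expect_equal(pcm_post_stroke_force(2, 1, 5, p), 12.5)  # 2.5 * ((2-8)/2 + 8)
})

test_that("unbinding is a catch bond: exponential suppression under load", {
  p <- default_pcm()
  # at (i, j) = (1, 1) the per-motor load equals the applied force:
  # f_pp = k_m * (f/k_m - d + d) = f
  expect_identical(pcm_unbinding_rate(1, 1, 0, p), p$k20_0)                    # f_pp = 0
  expect_equal(pcm_unbinding_rate(1, 1, p$f0_unbind, p), p$k20_0 * exp(-1))    # f_pp = force scale
  expect_equal(pcm_unbinding_rate(1, 1, 25.2, p), 80 * exp(-2))                # 10.827 / s
  # strictly decreasing in the per-motor load
  fgrid <- seq(0, 60, by = 2.5)
  rates <- vapply(fgrid, function(f) pcm_unbinding_rate(1, 1, f, p), numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("bound energy sums the stroke bias and both elastic reservoirs", {
  p <- default_pcm()
  expect_equal(pcm_bound_energy(1, 0, 0, p), 0)
  expect_equal(pcm_bound_energy(1, 1, 0, p), -60)   # eps = -d kills the elastic term
  expect_equal(pcm_bound_energy(2, 1, 0, p), -20)   # -60 + 1.25*(16 + 16)
  # elastic part alone is nonnegative
  pz <- default_pcm(e_pp = 0)
  for (i in 1:4) expect_true(all(pcm_bound_energy(i, 0:i, 13, pz) >= 0))
})

test_that("power-stroke occupancy is a proper, stable Boltzmann distribution", {
  p <- default_pcm(N = 100)
  for (i in c(1, 3, 17, 100)) for (f in c(0, 25, 80)) {
    b <- pcm_boltzmann(i, f, p)
    expect_equal(sum(b$prob), 1, tolerance = 1e-12)
    expect_true(all(b$prob >= 0 & b$prob <= 1))
    expect_true(is.finite(b$log_partition))
  }
  expect_error(pcm_boltzmann(0, 0, p), "bound")
  # engineered equal energies at i = 1: e_pp = 0 makes e_10 = e_11 = 0 at f = 0
  b1 <- pcm_boltzmann(1, 0, default_pcm(e_pp = 0))
  expect_equal(b1$prob, c(0.5, 0.5))
  # post-power-stroke strongly favored at the default stroke bias
  b2 <- pcm_boltzmann(2, 0, default_pcm())
  expect_gt(b2$prob[3], 1e6 * b2$prob[1])
  # high-temperature limit flattens the distribution
  bh <- pcm_boltzmann(5, 0, default_pcm(N = 8, kBT = 1e9))
  expect_lt(max(abs(bh$prob - 1 / 6)), 1e-6)
})

test_that("stable occupancy equals naive exponentiation where that is finite", {
  p <- default_pcm(N = 6, e_pp = -5)
  for (i in 1:6) for (f in c(0, 10)) {
    e <- pcm_bound_energy(i, 0:i, f, p)
    w <- exp(-e / p$kBT)
    expect_true(all(is.finite(w)))
    b <- pcm_boltzmann(i, f, p)
    expect_equal(b$prob, w / sum(w), tolerance = 1e-13)
    expect_equal(b$partition, sum(w), tolerance = 1e-13)
  }
})

test_that("binding-induced position change follows the mean-strain rule", {
  p <- default_pcm()
  expect_identical(pcm_delta_z_on(0, 0, p), 0)
  expect_error(pcm_delta_z_on(p$N, 0, p), "free motor")
  # occupancy pushed to j = 0 (strongly uphill stroke): eps_10 = 0, so no shift
  expect_equal(pcm_delta_z_on(1, 0, default_pcm(e_pp = 200)), 0, tolerance = 1e-5)
  # occupancy pushed to j = 1: dZ_on = -(1/2) * (-d) = +4 nm
  expect_equal(pcm_delta_z_on(1, 0, default_pcm(e_pp = -200)), 4, tolerance = 1e-5)
  # zero stroke increment and zero force: every strain vanishes
  expect_equal(pcm_delta_z_on(2, 0, default_pcm(d = 0)), 0)
})

test_that("state-conditional velocity matches a term-by-term hand evaluation", {
  p <- default_pcm(N = 4)
  # i = N > 1: no binding possible, no last-unbinding term
  expect_identical(pcm_ensemble_velocity(4, 0, p), 0)
  expect_error(pcm_ensemble_velocity(0, 0, p), "unbound")
  # i = 2: only the binding term survives
  expect_equal(pcm_ensemble_velocity(2, 7, p),
               (4 - 2) * p$k01 * pcm_delta_z_on(2, 7, p))
  # i = 1 at f = 0, defaults: independent arithmetic for all three terms.
  # eps_10 = 0, eps_11 = -8; e_10 = 0, e_11 = -60; f_pp(1,1) = 0 so Tr20 = 80.
  pr1 <- exp(60 / 4.14) / (1 + exp(60 / 4.14))
  dz1 <- -(0 * (1 - pr1) + (-8) * pr1) / 2
  v1_hand <- (4 - 1) * 40 * dz1 - (2 * 0 * (1 - pr1) + 80 * (-8) * pr1)
  expect_equal(pcm_ensemble_velocity(1, 0, p), v1_hand, tolerance = 1e-12)
})

test_that("parameter validation names the offending field", {
  expect_error(pcm_params(k_m = -1), "k_m")
  expect_error(pcm_params(N = 0), "N")
  expect_error(pcm_params(kBT = 0), "kBT")
  expect_error(pcm_params(k01 = -5), "k01")
  expect_error(pcm_params(f0_unbind = 0), "f0_unbind")
})
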
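test_that("default parameters reproduce the published defaults and derived quantities", {
  p <- default_parameters()
  expect_equal(p$R1, 12e-6)
  expect_equal(p$wd, 3e-6)
  expect_equal(p$La, 250e-6)
  expect_equal(p$R3, 150e-6)
  expect_equal(p$zeta, 0.8)
  expect_equal(p$k_s, 2e-14)
  expect_equal(p$mu_s, 4e3)
  expect_equal(p$f, 10)
  expect_equal(p$c, 1)
  expect_equal(p$D, 1.4e-10)
  expect_equal(p$lambda_wave, 0.1)
  expect_equal(p$lambda_wave * p$f, p$c)
  # geometric PVS volume ~ 6.36e4 um^3
  expect_equal(p$V_pvs * 1e18, pi * (15^2 - 12^2) * 250, tolerance = 1e-12)
  expect_equal(p$V_pvs * 1e18, 6.36e4, tolerance = 0.01)
})

test_that("Lame parameter follows 2 nu mu / (1 - 2 nu)", {
  expect_equal(lame_lambda(4, 0.45), 36)
  expect_equal(lame_lambda(123, 0), 0)
  expect_equal(lame_lambda(1, 0.25), 1)
  expect_error(lame_lambda(4, 0.5), "0.5")
})

test_that("PVS reference resistance: Darcy value, linear scaling, Poiseuille limit", {
  p <- default_parameters()
  R <- pvs_reference_resistance(p)
  # mu_f zeta La / (k_s A), A = pi(15^2 - 12^2) um^2
  expect_equal(R, 1e-3 * 0.8 * 250e-6 / (2e-14 * pi * 81e-12), tolerance = 1e-12)
  expect_equal(R, 3.93e16, tolerance = 0.005)
  p2 <- pvs_parameters(La = 500)
  expect_equal(pvs_reference_resistance(p2) / R, 2, tolerance = 1e-12)
  # Navier-Stokes limit: closed form equals an independent 1-D BVP solve
  pn <- pvs_parameters(k_s = Inf)
  Rn <- pvs_reference_resistance(pn)
  ora <- brinkman_profile_1d(pn, dpdz = -1 / pn$La)   # dp = 1 Pa over La
  expect_equal(1 / ora$q, Rn, tolerance = 1e-3)
  # resistance decreases with permeability and width
  expect_lt(pvs_reference_resistance(pvs_parameters(k_s = 4e-14)), R)
  expect_lt(pvs_reference_resistance(pvs_parameters(wd = 6)), R)
})

test_that("out-of-range parameters are rejected with informative errors", {
  expect_error(pvs_parameters(R1 = 40), "R1")
  expect_error(pvs_parameters(zeta = 0.95), "zeta")
  expect_error(pvs_parameters(mu_s = 20), "mu_s")
  expect_error(pvs_parameters(wd = -1), "wd")
  expect_error(pvs_parameters(nu = 0.55), "0.5")
  # but the long-arteriole study case is constructible without validation
  pl <- pvs_parameters(La = 0.1e6, validate = FALSE)
  expect_equal(pl$La, 0.1)
})

test_that("JSON configuration round-trips including the infinite-permeability flag", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(R1 = 15, k_s = "inf", mu_s = 6), f, auto_unbox = TRUE)
  p <- read_parameters(f)
  expect_equal(p$R1, 15e-6)
  expect_true(is.infinite(p$k_s))
  expect_equal(p$mu_s, 6e3)
  p2 <- read_parameters(f, overrides = list(mu_s = 2))
  expect_equal(p2$mu_s, 2e3)
  jsonlite::write_json(list(bogus = 1), f, auto_unbox = TRUE)
  expect_error(read_parameters(f), "bogus")
})
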
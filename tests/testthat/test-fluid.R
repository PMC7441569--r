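p <- default_parameters()

test_that("steady annular Brinkman flow matches the 1-D BVP oracle within 1% L2", {
  dp <- 10
  sol <- solve_fluid_steady(p, dp, nr = 24, nz = 16)
  ora <- brinkman_profile_1d(p, -dp / p$La)
  vo <- stats::approx(ora$r, ora$v, xout = sol$r)$y
  expect_lt(sqrt(sum((sol$vz_profile - vo)^2) / sum(vo^2)), 0.01)
  expect_equal(sol$q, ora$q, tolerance = 0.01)
})

test_that("the infinite-permeability limit reproduces annular Poiseuille flow", {
  pn <- pvs_parameters(k_s = Inf)
  dp <- 10
  sol <- solve_fluid_steady(pn, dp, nr = 24, nz = 16)
  expect_equal(sol$q, dp / annular_poiseuille_resistance(pn$R1, pn$R1 + pn$wd,
                                                         pn$mu_f, pn$La),
               tolerance = 0.01)
  ora <- brinkman_profile_1d(pn, -dp / pn$La)
  vo <- stats::approx(ora$r, ora$v, xout = sol$r)$y
  expect_lt(sqrt(sum((sol$vz_profile - vo)^2) / sum(vo^2)), 0.01)
})

test_that("zero forcing gives an identically quiescent field", {
  sol <- solve_fluid_steady(p, 0, nr = 8, nz = 8)
  expect_lt(max(abs(sol$vz)), 1e-20)
  expect_lt(max(abs(sol$vr)), 1e-20)
  expect_lt(diff(range(sol$p)), 1e-12)
})

test_that("a high but finite permeability approaches the Navier-Stokes solution", {
  # Brinkman drag negligible at k_s = 1e-8 m^2
  pk <- pvs_parameters(k_s = 1e-8, validate = FALSE)
  pn <- pvs_parameters(k_s = Inf)
  s1 <- solve_fluid_steady(pk, 5, nr = 16, nz = 12)
  s2 <- solve_fluid_steady(pn, 5, nr = 16, nz = 12)
  expect_equal(s1$q, s2$q, tolerance = 0.01)
  expect_equal(s1$vz_profile, s2$vz_profile, tolerance = 0.01)
})
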
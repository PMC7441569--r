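p <- default_parameters()

test_that("SVK stress: stress-free reference, frame indifference, linear limit", {
  expect_equal(svk_stress(diag(3), p), matrix(0, 3, 3))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_lt(max(abs(svk_stress(R, p))), 1e-8)
  # uniaxial stretch with free lateral contraction: sigma_axial = E e
  e <- 1e-4
  Fu <- diag(c(1 + e, 1 - p$nu * e, 1 - p$nu * e))
  s <- svk_stress(Fu, p)
  E_young <- 2 * p$mu_s * (1 + p$nu)
  expect_equal(s[1, 1], E_young * e, tolerance = 1e-3)
  expect_lt(max(abs(s[2, 2]), abs(s[3, 3])), abs(s[1, 1]) * 1e-2)
  expect_error(svk_stress(diag(c(-1, 1, 1)), p), "det F")
  # the printed-strain variant differs at finite strain but also vanishes at I
  expect_equal(svk_stress(diag(3), p, strain = "left-cauchy-green"),
               matrix(0, 3, 3))
})

test_that("static solve matches the Lame thick-cylinder closed form within 2%", {
  pr <- 100   # Pa, small load -> linear regime
  u_fem <- static_tissue_estimate(pr, p, nr = 64, nz = 8, bc_pial = "roller")
  u_lame <- lame_inner_displacement(pr, p)
  expect_equal(u_fem, abs(u_lame), tolerance = 0.02)
  expect_equal(static_tissue_estimate(0, p, nr = 8, nz = 4), 0)
})

test_that("dynamic solid step: rest stays at rest; small steps approach statics", {
  st <- solid_step(NULL, 0, 1e-3, p, nr = 8, nz = 8)
  expect_equal(max(abs(st$u)), 0)
  # constant traction, many steps: converges toward the static solution
  tr <- 50
  st <- NULL; sys <- NULL
  for (k in 1:60) {
    st <- solid_step(st, tr, 5e-4, p, nr = 16, nz = 8, sys = sys)
    sys <- st$sys
  }
  u_static <- static_tissue_estimate(tr, p, nr = 16, nz = 8, details = TRUE)
  expect_equal(max(abs(st$ur_interface)), max(abs(u_static$ur_interface)),
               tolerance = 0.05)
})
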
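# Coupled-solver properties on small, fast configurations. The
# quantitative comparisons against the published transport numbers live in
# test-acceptance.R; these tests check conservation and structural
# behavior of the discretization.

p <- default_parameters()

test_that("mass is conserved: boundary fluxes balance the domain volume rate", {
  mo <- wall_motion("heartbeat", p)
  rec <- run_rigid(p, mo, duration = 0.012, dt = 2e-4, nr_pvs = 6, nz = 24)
  V <- c(rec$V0, rec$V0, rec$V)
  n <- length(rec$V)
  qtot <- rec$q_pial + rec$q_par
  # BDF2-consistent volume rate (the first step is BDF1)
  dVdt2 <- (1.5 * V[3:(n + 2)] - 2 * V[2:(n + 1)] + 0.5 * V[1:n]) / rec$dt
  dVdt1 <- diff(c(rec$V0, rec$V)) / rec$dt
  err <- abs(c(dVdt1[1], dVdt2[-1]) + qtot) / max(abs(qtot))
  expect_lt(max(err[-1]), 1e-3)   # within 0.1% of the peak flux
})

test_that("zero wall motion leaves all fields identically zero", {
  rec <- run_coupled(p, NULL, duration = 0.003, dt = 1e-3,
                     nr_pvs = 4, nz = 8, nr_brain = 6)
  expect_equal(max(rec$max_v), 0)
  expect_equal(max(rec$max_p), 0)
  expect_equal(max(abs(rec$u_interface)), 0)
})

test_that("rigid-mode response is linear in the pulsation amplitude", {
  mo1 <- wall_motion("heartbeat", p)
  mo2 <- wall_motion("heartbeat", pvs_parameters(b1 = 2))
  r1 <- run_rigid(p, mo1, duration = 0.01, dt = 2e-4, nr_pvs = 6, nz = 24)
  r2 <- run_rigid(p, mo2, duration = 0.01, dt = 2e-4, nr_pvs = 6, nz = 24)
  expect_equal(r2$q_pial / r1$q_pial, rep(2, length(r1$q_pial)), tolerance = 0.01)
  expect_equal(max(r2$max_p) / max(r1$max_p), 2, tolerance = 0.01)
})

test_that("a very high permeability reproduces the Navier-Stokes limit", {
  mo <- wall_motion("heartbeat", p)
  pk <- pvs_parameters(k_s = 1e-8, validate = FALSE)
  pn <- pvs_parameters(k_s = Inf)
  # same outlet resistances so only the Brinkman drag differs
  rk <- run_rigid(pk, mo, duration = 0.008, dt = 2e-4, nr_pvs = 6, nz = 20)
  rn <- run_rigid(pn, mo, duration = 0.008, dt = 2e-4, nr_pvs = 6, nz = 20)
  expect_equal(rk$q_pial, rn$q_pial, tolerance = 0.01)
  expect_equal(max(rk$max_v), max(rn$max_v), tolerance = 0.01)
})

test_that("free decay with a motionless wall dissipates total energy", {
  init <- function(r, z) {
    list(ur = 5e-8 * (p$R3 - r) / (p$R3 - p$R1 - p$wd), uz = 0 * z)
  }
  rec <- run_coupled(p, NULL, duration = 0.03, dt = 5e-4,
                     nr_pvs = 4, nz = 12, nr_brain = 8,
                     init_solid = init, track_energy = TRUE)
  en <- rec$energy
  expect_gt(en[1], 0)
  # monotone decay once the impulsive start has settled
  expect_true(all(diff(en[-(1:2)]) <= 1e-12 * en[1]))
  expect_lt(en[length(en)], en[3])
})

test_that("coupled stepping converges the interface fixed point", {
  mo <- wall_motion("heartbeat", p)
  rec <- run_coupled(p, mo, duration = 0.004, dt = 2e-4,
                     nr_pvs = 6, nz = 16, nr_brain = 8)
  expect_lt(max(rec$iters), 12)     # never hits the iteration cap
  expect_gt(max(abs(rec$u_interface)), 0)  # the brain actually moves
})

test_that("the stepping interface advances state and reports diagnostics", {
  mo <- wall_motion("heartbeat", p)
  st <- flow_stepper(p, mo, mode = "rigid", nr_pvs = 4, nz = 10)
  st <- fluid_step(st, 2e-4)
  st <- fluid_step(st, 2e-4)
  expect_equal(st$t, 4e-4)
  expect_true(all(c("q_pial", "q_par", "V", "max_v") %in% names(st$last)))
  expect_gt(st$last$max_v, 0)
})
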
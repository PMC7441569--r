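p <- default_parameters()

test_that("heartbeat wave has the published amplitude, phase lag and zero start", {
  z <- seq(0, p$La, length.out = 41)
  tt <- seq(0, 0.1, length.out = 401)
  u <- outer(z, tt, function(z, t) heartbeat_displacement(z, t, p))
  expect_equal(max(abs(u)), 0.06e-6, tolerance = 0.02)   # Delta R_max
  expect_equal(heartbeat_displacement(z, 0, p), rep(0, length(z)))
  # phase difference across the PVS = 2 pi La / lambda
  m <- wall_motion("heartbeat", p)
  tau0 <- p$La / p$c
  expect_equal(2 * pi * p$f * tau0, 2 * pi * p$La / p$lambda_wave)
  expect_equal(2 * pi * p$La / p$lambda_wave, 0.0157, tolerance = 0.01)
  # the wave travels from the pial end toward the parenchyma: the pial end
  # leads in phase
  vparench <- m$velocity(0, 0); vpial <- m$velocity(p$La, 0)
  expect_true(vpial >= vparench)   # z = La sees the crest first
})

test_that("hyperemia dilation peaks at 1.8 um near 1.2 s and decays", {
  tt <- seq(0, 10, by = 0.01)
  u <- hyperemia_displacement(tt, p)
  expect_equal(u[1], 0)
  expect_equal(max(u), 1.8e-6, tolerance = 1e-6)
  expect_equal(tt[which.max(u)], 1.2, tolerance = 0.02)
  expect_lt(u[length(u)], 0.1 * max(u))
  # amplitude scales linearly with R1
  p2 <- pvs_parameters(R1 = 18)
  expect_equal(max(hyperemia_displacement(tt, p2)) / max(u), 1.5, tolerance = 1e-9)
})

test_that("sinusoid is 4% peak-to-peak, odd over half periods, frequency-limited", {
  tt <- seq(0, 20, by = 0.01)
  u <- sinusoid_displacement(tt, f = 0.05, p)
  expect_equal(max(abs(u)), 0.02 * p$R1, tolerance = 1e-9)
  expect_equal(max(abs(u)), 0.24e-6, tolerance = 1e-9)
  f <- 2
  u1 <- sinusoid_displacement(tt, f, p)
  u2 <- sinusoid_displacement(tt + 1 / (2 * f), f, p)
  expect_equal(u1 + u2, rep(0, length(tt)), tolerance = 1e-20)
  expect_error(wall_motion("sinusoid", p, f = 0.01), "0.05")
})

test_that("analytic wall velocity integrates back to the displacement", {
  for (kind in c("heartbeat", "hyperemia", "sinusoid")) {
    m <- wall_motion(kind, p, f = if (kind == "sinusoid") 2 else NULL)
    tend <- if (kind == "hyperemia") 3 else 0.35
    z0 <- p$La / 3
    num <- stats::integrate(function(s) m$velocity(z0, s), 0, tend,
                            rel.tol = 1e-10, subdivisions = 2000L)$value
    expect_equal(num, m$displacement(z0, tend) - m$displacement(z0, 0),
                 tolerance = 1e-6)
  }
})

test_that("heartbeat amplitude scales linearly with the pulsation percentage", {
  z <- p$La / 2; tt <- seq(0, 0.1, by = 1e-3)
  u1 <- max(abs(heartbeat_displacement(z, tt, p)))
  u2 <- max(abs(heartbeat_displacement(z, tt, pvs_parameters(b1 = 2))))
  expect_equal(u2 / u1, 2, tolerance = 1e-9)
})
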
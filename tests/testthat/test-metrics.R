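# Metric operations on synthetic records (no PDE solves needed here).

fake_record <- function(time, q_pial, q_par = 0 * q_pial, q_50 = q_pial,
                        mean_vz = 0 * q_pial, params = default_parameters()) {
  structure(list(time = time, dt = diff(time)[1], q_pial = q_pial,
                 q_par = q_par, q_50 = q_50,
                 V = params$V_pvs - cumsum(c(0, diff(time)) * (q_pial + q_par)),
                 V0 = params$V_pvs, mean_vz_down = mean_vz,
                 params = params, mode = "rigid",
                 motion = list(kind = "synthetic")),
            class = "pvs_flow_record")
}

p <- default_parameters()

test_that("mean downstream speed follows its definition on synthetic fields", {
  t <- seq(0.01, 1, by = 0.01)
  # uniform v_z = -1 um/s -> downstream speed 1 um/s
  r <- fake_record(t, 0 * t, mean_vz = rep(1e-6, length(t)))
  expect_equal(mean_downstream_speed(r), 1)
  # a pure standing oscillation time-averages to zero over whole periods
  r2 <- fake_record(t, 0 * t, mean_vz = 1e-6 * sin(2 * pi * 2 * t))
  expect_lt(abs(mean_downstream_speed(r2, c(0, 1))), 1e-3)
  expect_error(mean_downstream_speed(r, c(0, 2)), "window")
})

test_that("volume exchange fraction is the peak cumulative outflow over the fluid volume", {
  t <- seq(0.001, 1, by = 0.001)
  qa <- 1e-15 * sin(2 * pi * t)          # outflow then equal return
  r <- fake_record(t, qa)
  expected <- max(cumsum(c(0, diff(c(0, t))) * c(0, qa))) / (p$zeta * p$V_pvs)
  expect_equal(volume_exchange_fraction(r), expected, tolerance = 1e-6)
  # analytic: int_0^0.5 sin = 2/(2 pi)
  expect_equal(volume_exchange_fraction(r), 1e-15 / pi / (p$zeta * p$V_pvs),
               tolerance = 1e-3)
  # zero motion -> 0
  expect_equal(volume_exchange_fraction(fake_record(t, 0 * t)), 0)
  # geometric denominator differs by exactly zeta
  expect_equal(volume_exchange_fraction(r, denominator = "geometric") /
                 volume_exchange_fraction(r), p$zeta)
})

test_that("Reynolds and Peclet numbers follow their definitions with peak flux", {
  t <- seq(0.01, 1, by = 0.01)
  q0 <- 2e-14
  r <- fake_record(t, q0 * sin(2 * pi * t), q_50 = 0.5 * q0 * sin(2 * pi * t))
  dn <- dimensionless_numbers(r)
  A <- pi * ((p$R1 + p$wd)^2 - p$R1^2)
  expect_equal(dn[["Re"]], 2 * p$rho_f * q0 * p$wd / (p$mu_f * A))
  expect_equal(dn[["Pe_0"]], 2 * q0 * p$wd / (p$D * A))
  expect_equal(dn[["Pe_50"]] / dn[["Pe_0"]], 0.5)
  # Re/Pe ratio is rho D / mu by construction
  expect_equal(dn[["Re"]] / dn[["Pe_0"]], p$rho_f * p$D / p$mu_f)
  expect_equal(unname(dimensionless_numbers(fake_record(t, 0 * t))),
               c(0, 0, 0))
})

test_that("power-law fit recovers exact log-linear data and rejects bad input", {
  f <- c(0.05, 0.2, 1, 5, 10)
  fit <- powerlaw_fit(f, 2 * f^(-0.5))
  expect_equal(fit$A, 2, tolerance = 1e-10)
  expect_equal(fit$b, -0.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_error(powerlaw_fit(c(1, 2), c(1, 2)), "3")
  expect_error(powerlaw_fit(c(-1, 1, 2), c(1, 1, 1)), "positive")
})
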
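test_that("uniform flow displaces every particle exactly v dt per step", {
  vel <- function(t, xy) cbind(0 * xy[, 1], rep(-1e-6, nrow(xy)))  # -1 um/s in z
  pe <- advect_particles(NULL, dt = 0.1, duration = 5, seed_every = Inf,
                         n_r = 3, n_z = 5, velocity = vel,
                         domain = list(r = c(1e-5, 2e-5), z = c(0, 1e-2)))
  d0 <- pe$positions[, , 1]
  d1 <- pe$positions[, , length(pe$times)]
  expect_equal(d1[, 2] - d0[, 2], rep(-5e-6, nrow(d0)), tolerance = 1e-9)
  expect_equal(d1[, 1], d0[, 1])
})

test_that("forward Euler shows first-order convergence on a circular field", {
  # rigid rotation about (5e-4, 6e-4): return-to-start error halves with dt
  om <- 2 * pi
  ctr <- c(5e-4, 6e-4)
  vel <- function(t, xy) {
    cbind(-om * (xy[, 2] - ctr[2]), om * (xy[, 1] - ctr[1]))
  }
  err <- sapply(c(0.002, 0.001), function(dt) {
    pe <- advect_particles(NULL, dt = dt, duration = 1, seed_every = Inf,
                           n_r = 1, n_z = 1, velocity = vel,
                           domain = list(r = c(4.99e-4, 5.01e-4), z = c(0, 1e-3)))
    # single particle at (5e-4, 5e-4), orbit radius 1e-4, well inside z bounds
    p0 <- pe$positions[1, , 1]; p1 <- pe$positions[1, , length(pe$times)]
    sqrt(sum((p1 - p0)^2))
  })
  expect_equal(err[1] / err[2], 2, tolerance = 0.25)
})

test_that("SAS-side seeding adds one batch every 0.5 s", {
  vel <- function(t, xy) 0 * xy
  pe <- advect_particles(NULL, dt = 0.05, duration = 5, seed_every = 0.5,
                         seed_n = 7, n_r = 2, n_z = 3, velocity = vel,
                         domain = list(r = c(1e-5, 2e-5), z = c(0, 2.5e-4)))
  expect_equal(length(pe$batch_times), 10)
  expect_equal(sum(pe$batch > 0), 70)
  # seeded particles appear near the pial end
  sas <- pe$positions[pe$batch > 0, 2, length(pe$times)]
  expect_true(all(sas > 0.95 * 2.5e-4))
})

test_that("particles leaving through an end are flagged exited, not an error", {
  vel <- function(t, xy) cbind(0 * xy[, 1], rep(1e-4, nrow(xy)))  # fast out the top
  pe <- advect_particles(NULL, dt = 0.1, duration = 2, seed_every = Inf,
                         n_r = 2, n_z = 2, velocity = vel,
                         domain = list(r = c(1e-5, 2e-5), z = c(0, 1e-5)))
  expect_true(all(pe$exited))
})
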
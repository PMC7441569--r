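# Synthetic imagery generator: determinism, SNR calibration, ground truth.

test_that("generation is bit-identical for a fixed seed", {
  sp <- synthetic_spec(size = 96, n_frames = 5, n_lines = 20, snr = 4, seed = 7)
  m1 <- generate_line_movie(sp)
  m2 <- generate_line_movie(sp)
  expect_identical(m1$stack, m2$stack)
  t1 <- generate_two_channel_movie(sp)
  t2 <- generate_two_channel_movie(sp)
  expect_identical(t1$movie$red, t2$movie$red)
})

test_that("requested SNR levels are realized within 5%", {
  for (snr in c(4.14, 0.59)) {
    sp <- synthetic_spec(size = 128, n_frames = 4, n_lines = 30, snr = snr,
                         amplitude = 0, seed = 3)
    m <- generate_line_movie(sp)
    measured <- measure_snr(m$stack, m$signal_mask)
    expect_equal(measured, snr, tolerance = 0.05)
  }
})

test_that("zero-amplitude displacement leaves frames identical before noise", {
  sp <- synthetic_spec(size = 64, n_frames = 4, n_lines = 15, amplitude = 0,
                       snr = 10, seed = 2)
  m <- generate_line_movie(sp)
  expect_equal(m$clean[, , 1], m$clean[, , 4])
})

test_that("SNR measurement handles degenerate inputs", {
  img <- matrix(1, 16, 16)
  mask <- matrix(FALSE, 16, 16); mask[5:10, 5:10] <- TRUE
  expect_warning(s <- measure_snr(img, mask), "noiseless")
  expect_true(is.infinite(s))
  expect_error(measure_snr(img, matrix(FALSE, 16, 16)), "empty")
  set.seed(1)
  noise <- matrix(rnorm(256), 16, 16)
  expect_lt(abs(measure_snr(noise, mask)), 0.5)  # pure noise ~ 0
})

test_that("the non-compliant paradigm trims the tissue onset until PVS collapse", {
  sp <- synthetic_spec(size = 96, n_frames = 12, n_lines = 20,
                       vessel_radius = 15, dilation_frac = 0.3, gap = 2,
                       paradigm = "noncompliant", snr = 20, seed = 8)
  tc <- generate_two_channel_movie(sp)
  wall <- tc$truth$wall; tis <- tc$truth$tissue
  expect_true(any(wall > 0 & tis == 0))          # lagged onset
  expect_equal(tis[wall > sp$gap], (wall - sp$gap)[wall > sp$gap])
  # fsi paradigm is a scaled copy from the start
  spf <- synthetic_spec(size = 96, n_frames = 12, n_lines = 20,
                        vessel_radius = 15, rho = 0.5, snr = 20, seed = 8)
  tcf <- generate_two_channel_movie(spf)
  expect_equal(tcf$truth$tissue, 0.5 * tcf$truth$wall)
})

test_that("vessel larger than the frame is rejected", {
  expect_error(generate_two_channel_movie(
    synthetic_spec(size = 64, vessel_radius = 40)), "fit")
})
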
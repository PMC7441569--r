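# Unit tests of the imaging pipeline stages on small synthetic inputs.

test_that("crosstalk coefficient is recovered and bounded to (0, 1.5)", {
  set.seed(21)
  # sparse, largely non-overlapping channels (fluorescent structures)
  g <- array(abs(rnorm(32 * 32 * 4)) * (runif(32 * 32 * 4) < 0.1), c(32, 32, 4))
  r_true <- array(abs(rnorm(32 * 32 * 4)) * (runif(32 * 32 * 4) < 0.1), c(32, 32, 4))
  r_true[g > 0] <- 0   # distinct fluorescent structures do not overlap
  res <- remove_crosstalk(r_true + 0.3 * g, g)
  expect_lt(abs(res$alpha - 0.3), 0.02)
  # alpha recovered within +/- 0.02 on the two-channel generator output
  sp <- synthetic_spec(size = 96, n_frames = 6, n_lines = 25,
                       vessel_radius = 12, snr = 30, seed = 5)
  tc <- generate_two_channel_movie(sp)
  res2 <- remove_crosstalk(tc$movie$red, tc$movie$green)
  expect_lt(abs(res2$alpha - 0.3), 0.02)
  # zero green channel: warning, red returned untouched
  expect_warning(res3 <- remove_crosstalk(r_true, 0 * g), "zero")
  expect_equal(res3$red_fluorescence, r_true)
  expect_equal(res3$alpha, 0)
})

test_that("preprocessing recovers known frame translations and removes hot pixels", {
  set.seed(31)
  base <- matrix(0, 48, 48)
  for (i in 1:14) {
    cy <- runif(1, 10, 38); cx <- runif(1, 10, 38)
    base <- base + exp(-((row(base) - cy)^2 + (col(base) - cx)^2) / 6)
  }
  shifts <- rbind(c(0, 0), c(2, -1), c(-3, 2), c(1, 3), c(-2, -2), c(0, 1), c(3, 0))
  red <- array(0, c(48, 48, 7)); grn <- red
  for (t in 1:7) {
    red[, , t] <- fourier_shift(base, shifts[t, ])
    grn[, , t] <- fourier_shift(0.5 * base, shifts[t, ])
  }
  red[25, 25, 4] <- 5    # hot pixel (shot noise)
  mv <- preprocess(two_channel_movie(red, grn))
  # recovered relative shifts match the injected ones (the reference frame
  # fixes the arbitrary global offset)
  rel_est <- sweep(mv$shifts, 2, mv$shifts[1, ])
  rel_true <- sweep(shifts, 2, shifts[1, ])
  expect_lt(max(abs(rel_est - rel_true)), 0.15)
  # hot pixel removed by the (3,3,5) median
  expect_lt(mv$red[25, 25, 4], 1)
  # a static movie yields zero shifts
  stat <- array(rep(base, 5), c(48, 48, 5))
  mv2 <- preprocess(two_channel_movie(stat, stat))
  expect_lt(max(abs(mv2$shifts)), 1e-6)
  expect_error(preprocess(two_channel_movie(stat[, , 1:3, drop = FALSE],
                                            stat[, , 1:3, drop = FALSE])),
               "5 frames")
})

test_that("Radon-space segmentation measures disk area and tracks dilation", {
  img <- matrix(0, 64, 64)
  rr <- sqrt((row(img) - 32.5)^2 + (col(img) - 32.5)^2)
  img[rr <= 10] <- 1
  vt <- radon_diameter(array(img, c(64, 64, 1)))
  expect_equal(vt$area, pi * 100, tolerance = 0.10)
  st <- array(0, c(64, 64, 5))
  for (t in 1:5) st[, , t] <- (rr <= 8 * (1 + 0.15 * (t - 1) / 4)) * 1
  vt2 <- radon_diameter(st)
  expect_equal(vt2$diameter[5] / vt2$diameter[1], 1.15, tolerance = 0.02)
  # all-zero ROI is an invalid frame
  vt3 <- radon_diameter(array(0, c(32, 32, 1)))
  expect_false(vt3$valid[1])
})

test_that("HRF fitting recovers a known gamma kernel and gates on R^2", {
  set.seed(41)
  fr <- 3
  n <- 240
  bin <- rep(FALSE, n)
  bin[c(30, 90, 150, 200)] <- TRUE
  tk <- seq(0, 8, by = 1 / fr)
  kern <- gamma_kernel(tk, amp = 0.8, t_peak = 1.5, shape = 2.5)
  dia <- 20 + pvsflow:::convolve_causal(as.numeric(bin), kern)
  fit <- fit_hrf(bin, dia, frame_rate = fr)
  expect_true(fit$accepted)
  expect_gt(fit$r_squared, 0.99)
  expect_equal(unname(fit$par["t_peak"]), 1.5, tolerance = 0.05)
  expect_equal(unname(fit$par["amp"]), 0.8, tolerance = 0.05)
  # white noise uncorrelated with locomotion is rejected at the 0.6 gate
  fit2 <- fit_hrf(bin, 20 + rnorm(n), frame_rate = fr)
  expect_false(fit2$accepted)
  # no locomotion events -> undefined fit, rejected
  fit3 <- fit_hrf(rep(0, n), dia, frame_rate = fr)
  expect_false(fit3$accepted)
})

test_that("deconvolution recovers the impulse response of a known kernel", {
  set.seed(51)
  n <- 256
  stim <- as.numeric(runif(n) < 0.05)
  tk <- seq(0, 20, length.out = 64)
  kern <- gamma_kernel(tk, 1, 4, 2)
  # circular convolution so the generative model matches the FFT division
  resp <- Re(stats::fft(stats::fft(stim) * stats::fft(c(kern, rep(0, n - 64))),
                        inverse = TRUE)) / n
  ir <- deconvolve_ir(stim, resp, span = 64, eps_frac = 1e-8)
  expect_gt(cor(ir, kern), 0.98)
  expect_equal(which.max(ir), which.max(kern), tolerance = 2)
})
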
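test_that("bior3.3 filter bank reconstructs exactly", {
  f <- pvsflow:::bior33_filters()
  set.seed(4)
  x <- rnorm(128)
  st <- pvsflow:::dwt_step(x, f)
  r <- pvsflow:::idwt_step(st$a, st$d, f, pvsflow:::bior33_delay())
  expect_equal(r, x, tolerance = 1e-12)
})

test_that("denoising recovers a gamma-like displacement signal from noise", {
  set.seed(9)
  t <- seq(0, 10, length.out = 120)
  sig <- 2 * (t / 1.2)^2 * exp(2 * (1 - t / 1.2))
  y <- sig + rnorm(length(t), 0, 0.3)
  d <- wavelet_denoise(y)
  expect_lt(sqrt(mean((d - sig)^2)), 0.7 * sqrt(mean((y - sig)^2)))
  expect_equal(length(d), length(y))
  # short traces pass through untouched
  expect_equal(wavelet_denoise(1:5), 1:5)
})
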
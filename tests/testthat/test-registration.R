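make_texture <- function(n = 64, seed = 11, k = 25) {
  set.seed(seed)
  img <- matrix(0, n, n)
  for (i in seq_len(k)) {
    cy <- stats::runif(1, 8, n - 8); cx <- stats::runif(1, 8, n - 8)
    img <- img + exp(-((row(img) - cy)^2 + (col(img) - cx)^2) / 8)
  }
  img
}

test_that("known translations are recovered to well under 0.1 px", {
  img <- make_texture()
  for (sh in list(c(3, -2), c(-1, 4), c(1.25, -0.75), c(0.3, 0.45), c(0, 0))) {
    reg <- dft_register(img, fourier_shift(img, sh), upsample = 50)
    expect_lt(max(abs(reg$shift - sh)), 0.05)
    expect_lt(reg$error, 0.05)
  }
})

test_that("a flat frame is flagged rather than registered", {
  img <- make_texture()
  reg <- dft_register(img, matrix(0, 64, 64))
  expect_true(reg$flat || reg$error == 1)
})

test_that("rotated content cannot be matched by translation (large residual)", {
  img <- make_texture()
  th <- pi / 4
  yy <- as.vector(row(img)) - 32.5; xx <- as.vector(col(img)) - 32.5
  rot <- matrix(bilinear_sample(img, 32.5 + yy * cos(th) - xx * sin(th),
                                32.5 + yy * sin(th) + xx * cos(th)), 64, 64)
  reg <- dft_register(img, rot)
  expect_gt(reg$error, 0.5)
})

test_that("fourier shift is exact for integer shifts and invertible", {
  img <- make_texture()
  sh <- c(5, -3)
  expect_equal(fourier_shift(img, sh)[10:50, 10:50],
               img[10:50 - sh[1], 10:50 - sh[2]], tolerance = 1e-10)
  back <- fourier_shift(fourier_shift(img, c(1.3, -0.6)), -c(1.3, -0.6))
  # subpixel roundtrip loses only Nyquist-band energy
  expect_lt(max(abs(back - img)), 1e-5)
})
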
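# 1-D biorthogonal 3.3 wavelet transform (periodic convolution) and
# soft-threshold denoising for tile displacement traces. The filter bank is
# the standard bior3.3 pair; the reconstruction alignment (circular delay)
# is calibrated once at load time by perfect-reconstruction on a unit
# impulse, which guards against off-by-one filter phase conventions.

bior33_filters <- function() {
  dec_lo <- c(0.06629126073623884, -0.19887378220871652, -0.15467960838455727,
              0.99436891104358249, 0.99436891104358249, -0.15467960838455727,
              -0.19887378220871652, 0.06629126073623884) / sqrt(2)
  dec_hi <- c(0, 0, -0.17677669529663689, 0.53033008588991071,
              -0.53033008588991071, 0.17677669529663689, 0, 0) * sqrt(2)
  rec_lo <- c(0, 0, 0.17677669529663689, 0.53033008588991071,
              0.53033008588991071, 0.17677669529663689, 0, 0) * sqrt(2)
  rec_hi <- c(0.06629126073623884, 0.19887378220871652, -0.15467960838455727,
              -0.99436891104358249, 0.99436891104358249, 0.15467960838455727,
              -0.19887378220871652, -0.06629126073623884) / sqrt(2)
  list(dec_lo = dec_lo, dec_hi = dec_hi, rec_lo = rec_lo, rec_hi = rec_hi)
}

circ_filter <- function(x, h) {
  n <- length(x); L <- length(h)
  out <- numeric(n)
  for (k in seq_len(L)) {
    out <- out + h[k] * x[((seq_len(n) - k) %% n) + 1L]
  }
  out
}

dwt_step <- function(x, f) {
  a <- circ_filter(x, f$dec_lo)[seq(1, length(x), by = 2)]
  d <- circ_filter(x, f$dec_hi)[seq(1, length(x), by = 2)]
  list(a = a, d = d)
}

idwt_step <- function(a, d, f, delay) {
  n <- 2L * length(a)
  ua <- numeric(n); ua[seq(1, n, by = 2)] <- a
  ud <- numeric(n); ud[seq(1, n, by = 2)] <- d
  x <- circ_filter(ua, f$rec_lo) + circ_filter(ud, f$rec_hi)
  # circular delay compensation
  x[((seq_len(n) - 1L + delay) %% n) + 1L]
}

wavelet_env <- new.env(parent = emptyenv())

bior33_delay <- function() {
  if (!is.null(wavelet_env$delay)) return(wavelet_env$delay)
  f <- bior33_filters()
  n <- 32L
  e <- numeric(n); e[7L] <- 1
  st <- dwt_step(e, f)
  best <- 0L; besterr <- Inf
  for (d in 0:(n - 1L)) {
    r <- idwt_step(st$a, st$d, f, d)
    err <- sum((r - e)^2)
    if (err < besterr) { besterr <- err; best <- d }
  }
  if (besterr > 1e-16) warning("bior3.3 reconstruction calibration residual: ", besterr)
  wavelet_env$delay <- best
  best
}

#' Wavelet denoising of a displacement trace
#'
#' Level-`levels` biorthogonal 3.3 wavelet decomposition with soft
#' universal thresholding of the detail coefficients (threshold
#' `sigma * sqrt(2 log n)`, `sigma` estimated from the median absolute
#' deviation of the finest detail level), used to extract the slow
#' gamma-function-like displacement signal from frame-to-frame registration
#' noise.
#'
#' @param x Numeric trace.
#' @param levels Decomposition depth.
#' @return The denoised trace (same length).
#' @export
wavelet_denoise <- function(x, levels = 3) {
  n0 <- length(x)
  if (n0 < 8) return(x)
  f <- bior33_filters()
  delay <- bior33_delay()
  # pad (symmetric) to a multiple of 2^levels
  n <- as.integer(2^levels * ceiling(n0 / 2^levels))
  pad <- n - n0
  xp <- if (pad > 0) c(x, rev(x)[seq_len(pad)]) else x
  approx_ <- xp; details <- vector("list", levels)
  for (l in seq_len(levels)) {
    st <- dwt_step(approx_, f)
    details[[l]] <- st$d
    approx_ <- st$a
  }
  sigma <- stats::mad(details[[1]], constant = 1.4826)
  thr <- sigma * sqrt(2 * log(max(n, 2)))
  soft <- function(w) sign(w) * pmax(abs(w) - thr, 0)
  for (l in seq_len(levels)) details[[l]] <- soft(details[[l]])
  for (l in rev(seq_len(levels))) {
    approx_ <- idwt_step(approx_, details[[l]], f, delay)
  }
  approx_[seq_len(n0)]
}
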
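# Locomotion-triggered hemodynamic response: binarization of the treadmill
# velocity trace, gamma-kernel HRF fitting against the vessel diameter, and
# regularized frequency-domain deconvolution for impulse responses.

#' Binarize a locomotion velocity trace
#'
#' Movement frames are those whose acceleration magnitude (frame-to-frame
#' velocity change) exceeds `k` times the standard deviation during rest,
#' estimated robustly from the median absolute deviation of the whole
#' acceleration trace.
#'
#' @param velocity Treadmill velocity per frame.
#' @param k Threshold multiplier.
#' @return Logical vector (same length): `TRUE` = movement.
#' @export
binarize_locomotion <- function(velocity, k = 3) {
  acc <- c(0, diff(velocity))
  s <- stats::mad(acc)
  if (s == 0) s <- stats::sd(acc)
  if (is.na(s) || s == 0) return(rep(FALSE, length(velocity)))
  abs(acc) > k * s
}

#' Gamma-function response kernel
#'
#' `k(t) = amp (t/t_peak)^shape exp(shape (1 - t/t_peak))`, peaking at
#' `t_peak` with value `amp`.
#'
#' @param t Time, s (>= 0).
#' @param amp Peak amplitude.
#' @param t_peak Time to peak, s.
#' @param shape Shape exponent.
#' @return Kernel values.
#' @export
gamma_kernel <- function(t, amp = 1, t_peak = 1.2, shape = 2) {
  t <- pmax(t, 0)
  amp * (t / t_peak)^shape * exp(shape * (1 - t / t_peak))
}

convolve_causal <- function(x, kern) {
  n <- length(x); m <- length(kern)
  out <- numeric(n)
  for (k in seq_len(m)) {
    idx <- k:n
    out[idx] <- out[idx] + kern[k] * x[idx - k + 1L]
  }
  out
}

#' Fit a gamma-kernel hemodynamic response function
#'
#' Binarizes the locomotion trace, then least-squares fits the amplitude,
#' peak time and shape of a gamma kernel so that the convolution of the
#' binary locomotion with the kernel reproduces the (demeaned) vessel
#' diameter trace. Fits with goodness `R^2 <= 0.6` are flagged as rejected.
#'
#' @param locomotion Velocity trace per frame (or an already-binary
#'   logical vector).
#' @param diameter A [radon_diameter()] `vessel_trace` or a numeric
#'   diameter trace.
#' @param frame_rate Frames per second (taken from the trace if present).
#' @param r2_threshold Acceptance gate on the goodness of fit.
#' @param kernel_span Kernel length, s.
#' @return List with `par` (amp, t_peak, shape), `r_squared`, `accepted`,
#'   `fitted` trace, and the binarized locomotion used.
#' @export
fit_hrf <- function(locomotion, diameter, frame_rate = NULL,
                    r2_threshold = 0.6, kernel_span = 8) {
  dia <- if (inherits(diameter, "vessel_trace")) diameter$diameter else diameter
  if (is.null(frame_rate)) {
    frame_rate <- if (inherits(diameter, "vessel_trace")) diameter$frame_rate else 3
  }
  bin <- if (is.logical(locomotion)) locomotion else binarize_locomotion(locomotion)
  if (!any(bin)) {
    return(list(par = c(amp = NA, t_peak = NA, shape = NA), r_squared = NA,
                accepted = FALSE, reason = "no locomotion events",
                locomotion = bin))
  }
  y <- dia - mean(dia)
  tk <- seq(0, kernel_span, by = 1 / frame_rate)
  sst <- sum(y^2)
  ssr_fun <- function(th) {
    kern <- gamma_kernel(tk, exp(th[1]), exp(th[2]), exp(th[3]))
    pred <- convolve_causal(as.numeric(bin), kern)
    pred <- pred - mean(pred)
    sum((y - pred)^2)
  }
  # amplitude initialization from the response scale
  a0 <- max(abs(y)) / max(1, max(convolve_causal(as.numeric(bin), gamma_kernel(tk))))
  opt <- stats::optim(log(c(max(a0, 1e-6), 1.2, 2)), ssr_fun,
                      method = "Nelder-Mead",
                      control = list(maxit = 600, reltol = 1e-10))
  par <- exp(opt$par)
  names(par) <- c("amp", "t_peak", "shape")
  kern <- gamma_kernel(tk, par[1], par[2], par[3])
  pred <- convolve_causal(as.numeric(bin), kern)
  pred <- pred - mean(pred)
  r2 <- 1 - sum((y - pred)^2) / sst
  list(par = par, r_squared = r2, accepted = is.finite(r2) && r2 > r2_threshold,
       fitted = pred + mean(dia), kernel = kern, locomotion = bin)
}

#' Regularized deconvolution impulse response
#'
#' Frequency-domain (Wiener-style) deconvolution of a response trace by a
#' stimulus trace: `IR = ifft( R(w) conj(S(w)) / (|S(w)|^2 + eps) )`,
#' with `eps` a small fraction of the peak stimulus power.
#'
#' @param stimulus Stimulus trace (e.g. binarized locomotion).
#' @param response Response trace, same length.
#' @param span Number of lags (samples) of the impulse response to return.
#' @param eps_frac Regularization as a fraction of `max |S|^2`.
#' @return Numeric impulse response of length `span`.
#' @export
deconvolve_ir <- function(stimulus, response, span = length(stimulus) %/% 2,
                          eps_frac = 0.05) {
  stopifnot(length(stimulus) == length(response))
  s <- as.numeric(stimulus) - mean(stimulus)
  r <- response - mean(response)
  S <- stats::fft(s); R <- stats::fft(r)
  P <- Mod(S)^2
  H <- R * Conj(S) / (P + eps_frac * max(P))
  ir <- Re(stats::fft(H, inverse = TRUE)) / length(s)
  ir[seq_len(min(span, length(ir)))]
}
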
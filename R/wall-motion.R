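#' Prescribed arteriolar wall motion
#'
#' Radial displacement of the arteriolar wall driving the PVS flow, for the
#' three experiment families:
#' \describe{
#'   \item{heartbeat}{a sinusoidal wave of peak amplitude `(b1/2)% * R1`
#'     traveling from the pial end (`z = La`) into the brain (`z = 0`) at
#'     speed `c`, frequency `f`;}
#'   \item{hyperemia}{a uniform-in-z, gamma-shaped dilation peaking at
#'     `0.15 * R1` (1.8 um for the 12 um default) near `t = 1.2` s and
#'     decaying back over several seconds, emulating the arteriolar
#'     response to a brief increase in local neural activity;}
#'   \item{sinusoid}{a uniform-in-z sinusoid of peak amplitude `2% * R1`
#'     (4% peak-to-peak) at a chosen frequency, used for frequency sweeps.}
#' }
#' All waveforms are zero at `t = 0` so simulations start from rest.
#'
#' @param kind One of `"heartbeat"`, `"hyperemia"`, `"sinusoid"`.
#' @param params A [pvs_parameters] object.
#' @param f Frequency, Hz (sinusoid only; heartbeat uses `params$f`).
#' @param t_peak Time to peak dilation, s (hyperemia).
#' @param shape Dimensionless gamma shape exponent `k` of the hyperemia
#'   waveform `u(t) = dR * (t/t_peak)^k * exp(k (1 - t/t_peak))`.
#' @param amplitude Peak radial displacement, m. Defaults per kind:
#'   `(b1/2)%*R1` (heartbeat), `0.15*R1` (hyperemia), `0.02*R1` (sinusoid).
#' @param duration Suggested run duration, s (one period for periodic kinds,
#'   10 s for hyperemia).
#' @return A `wall_motion` object with elements `displacement(z, t)` and
#'   `velocity(z, t)` (vectorized over `z` and `t`, SI units), plus the
#'   resolved amplitude, frequency and duration.
#' @export
#' @examples
#' p <- default_parameters()
#' m <- wall_motion("heartbeat", p)
#' max(abs(m$displacement(seq(0, p$La, length = 50), 0.025)))  # ~0.06 um
wall_motion <- function(kind = c("heartbeat", "hyperemia", "sinusoid"),
                        params = default_parameters(),
                        f = NULL, t_peak = 1.2, shape = 2,
                        amplitude = NULL, duration = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    heartbeat = {
      a <- if (is.null(amplitude)) (params$b1 / 2) / 100 * params$R1 else amplitude
      fq <- params$f
      cw <- params$c
      La <- params$La
      disp <- function(z, t) {
        # traveling wave entering at the pial end (z = La), moving toward z = 0;
        # the t = 0 offset is subtracted so u(z, 0) = 0 exactly (the offset is
        # constant in time, so the wall velocity is the pure traveling wave)
        tau <- (La - z) / cw
        a * (sin(2 * pi * fq * (t - tau)) + sin(2 * pi * fq * tau))
      }
      vel <- function(z, t) {
        tau <- (La - z) / cw
        a * 2 * pi * fq * cos(2 * pi * fq * (t - tau))
      }
      structure(list(kind = kind, amplitude = a, f = fq, c = cw,
                     duration = if (is.null(duration)) 1 / fq else duration,
                     displacement = disp, velocity = vel),
                class = "wall_motion")
    },
    hyperemia = {
      dR <- if (is.null(amplitude)) 0.15 * params$R1 else amplitude
      k <- shape; tp <- t_peak
      disp <- function(z, t) {
        t <- pmax(t, 0)
        u <- dR * (t / tp)^k * exp(k * (1 - t / tp))
        if (length(z) > 1L && length(t) == 1L) rep(u, length(z)) else u + 0 * z
      }
      vel <- function(z, t) {
        t <- pmax(t, 0)
        du <- ifelse(t == 0, 0,
                     dR * exp(k * (1 - t / tp)) * (k / tp) *
                       ((t / tp)^(k - 1) - (t / tp)^k))
        if (length(z) > 1L && length(t) == 1L) rep(du, length(z)) else du + 0 * z
      }
      structure(list(kind = kind, amplitude = dR, t_peak = tp, shape = k,
                     duration = if (is.null(duration)) 10 else duration,
                     displacement = disp, velocity = vel),
                class = "wall_motion")
    },
    sinusoid = {
      fq <- if (is.null(f)) params$f else f
      if (fq < 0.05 || fq > 10) {
        stop("sinusoid frequency must lie in [0.05, 10] Hz")
      }
      a <- if (is.null(amplitude)) 0.02 * params$R1 else amplitude
      disp <- function(z, t) a * sin(2 * pi * fq * t) + 0 * z
      vel <- function(z, t) a * 2 * pi * fq * cos(2 * pi * fq * t) + 0 * z
      structure(list(kind = kind, amplitude = a, f = fq,
                     duration = if (is.null(duration)) 1 / fq else duration,
                     displacement = disp, velocity = vel),
                class = "wall_motion")
    })
}

#' @export
print.wall_motion <- function(x, ...) {
  cat(sprintf("Arteriolar wall motion '%s': peak amplitude %.3g um, duration %.3g s\n",
              x$kind, x$amplitude * 1e6, x$duration))
  if (!is.null(x$f)) cat(sprintf("  frequency %g Hz\n", x$f))
  if (!is.null(x$t_peak)) cat(sprintf("  time to peak %g s (shape %g)\n", x$t_peak, x$shape))
  invisible(x)
}

#' Heartbeat wall displacement
#'
#' Convenience wrappers evaluating the three waveform families directly.
#' `heartbeat_displacement` is the traveling pulse wave, zero at `t = 0`;
#' `hyperemia_displacement` the gamma-shaped dilation;
#' `sinusoid_displacement` the uniform 4% peak-to-peak sinusoid.
#'
#' @param z Axial position(s), m; `z = 0` is the parenchymal end, `z = La`
#'   the pial end.
#' @param t Time(s), s.
#' @param params A [pvs_parameters] object.
#' @param ... Passed to [wall_motion()].
#' @return Radial displacement, m.
#' @export
heartbeat_displacement <- function(z, t, params = default_parameters(), ...) {
  wall_motion("heartbeat", params, ...)$displacement(z, t)
}

#' @rdname heartbeat_displacement
#' @export
hyperemia_displacement <- function(t, params = default_parameters(), ...) {
  wall_motion("hyperemia", params, ...)$displacement(0, t)
}

#' @rdname heartbeat_displacement
#' @param f Sinusoid frequency, Hz, in `[0.05, 10]`.
#' @export
sinusoid_displacement <- function(t, f, params = default_parameters(), ...) {
  wall_motion("sinusoid", params, f = f, ...)$displacement(0, t)
}
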
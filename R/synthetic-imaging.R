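# Synthetic two-photon imagery for validating the displacement pipeline:
# a random field of anti-aliased line segments (neurite-like), displaced
# radially outward with a gamma-function time course, plus a two-channel
# variant with a dilating vessel lumen, channel crosstalk and additive
# noise at a prescribed signal-to-noise ratio.

#' Specification of a synthetic movie
#'
#' @param size Image side, px.
#' @param n_frames Number of frames.
#' @param frame_rate Frames per second.
#' @param n_lines Number of random line segments.
#' @param line_width Line Gaussian half-width, px.
#' @param amplitude Peak radial displacement, px.
#' @param t_peak Peak frame time, s.
#' @param shape Gamma shape exponent of the displacement time course.
#' @param center Displacement/vessel center `c(y, x)`, px.
#' @param vessel_radius Baseline vessel lumen radius, px.
#' @param dilation_frac Fractional dilation at the peak (e.g. 0.2 = 20%).
#' @param rho Tissue/wall displacement ratio in the two-channel generator.
#' @param paradigm `"fsi"` (tissue displacement is a scaled copy of the
#'   wall displacement) or `"noncompliant"` (tissue moves only after the
#'   wall has swept the PVS gap: onset-trimmed copy).
#' @param gap PVS width for the non-compliant paradigm, px.
#' @param alpha Green-into-red crosstalk coefficient.
#' @param snr Target signal-to-noise ratio (mean signal / noise sd).
#' @param noise `"gaussian"` (default) or `"poisson"`.
#' @param seed Random seed (reproducibility contract).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(size = 512, n_frames = 26, frame_rate = 3,
                           n_lines = 100, line_width = 1.2,
                           amplitude = 3, t_peak = NULL, shape = 2,
                           center = NULL, vessel_radius = 25,
                           dilation_frac = 0.2, rho = 0.5,
                           paradigm = c("fsi", "noncompliant"), gap = 2,
                           alpha = 0.3, snr = 4.14,
                           noise = c("gaussian", "poisson"), seed = 1) {
  paradigm <- match.arg(paradigm)
  noise <- match.arg(noise)
  if (snr <= 0) stop("snr must be positive")
  if (is.null(center)) center <- c((size + 1) / 2, (size + 1) / 2)
  if (is.null(t_peak)) t_peak <- 12 / frame_rate   # peak near frame 13
  structure(list(size = size, n_frames = n_frames, frame_rate = frame_rate,
                 n_lines = n_lines, line_width = line_width,
                 amplitude = amplitude, t_peak = t_peak, shape = shape,
                 center = center, vessel_radius = vessel_radius,
                 dilation_frac = dilation_frac, rho = rho,
                 paradigm = paradigm, gap = gap, alpha = alpha,
                 snr = snr, noise = noise, seed = seed),
            class = "synthetic_spec")
}

render_line_field <- function(spec) {
  set.seed(spec$seed)
  n <- spec$size
  img <- matrix(0, n, n)
  yy <- row(img); xx <- col(img)
  for (k in seq_len(spec$n_lines)) {
    x0 <- stats::runif(1, 1, n); y0 <- stats::runif(1, 1, n)
    th <- stats::runif(1, 0, pi)
    len <- stats::runif(1, 0.08 * n, 0.35 * n)
    x1 <- x0 + len * cos(th); y1 <- y0 + len * sin(th)
    # distance from each pixel to the segment
    vx <- x1 - x0; vy <- y1 - y0
    L2 <- vx^2 + vy^2
    tt <- pmin(pmax(((xx - x0) * vx + (yy - y0) * vy) / L2, 0), 1)
    d2 <- (xx - (x0 + tt * vx))^2 + (yy - (y0 + tt * vy))^2
    img <- img + exp(-d2 / (2 * spec$line_width^2))
  }
  img / max(img)
}

# displace an image radially outward by d px about center (backward warp)
radial_warp <- function(img, d, center) {
  if (d == 0) return(img)
  n1 <- nrow(img); n2 <- ncol(img)
  yy <- row(img) - center[1]; xx <- col(img) - center[2]
  rr <- sqrt(yy^2 + xx^2)
  rs <- pmax(rr - d, 0)
  sc <- ifelse(rr > 0, rs / rr, 0)
  matrix(bilinear_sample(img, center[1] + yy * sc, center[2] + xx * sc), n1, n2)
}

gamma_course <- function(spec) {
  t <- (seq_len(spec$n_frames) - 1) / spec$frame_rate
  gamma_kernel(t, 1, spec$t_peak, spec$shape)
}

add_noise <- function(stack, spec, signal_mask) {
  mean_sig <- mean(stack[rep(signal_mask, dim(stack)[3])])
  sd_noise <- mean_sig / spec$snr
  if (spec$noise == "gaussian") {
    stack + array(stats::rnorm(length(stack), 0, sd_noise), dim(stack))
  } else {
    lam <- pmax(stack, 0) / sd_noise^2 * mean_sig   # scale so var ~ sd_noise^2
    array(stats::rpois(length(stack), lam) * sd_noise^2 / mean_sig, dim(stack))
  }
}

#' Synthetic line-field movie with known radial displacement
#'
#' Renders a random field of anti-aliased line segments and displaces it
#' uniformly radially outward with a gamma-function time course, adding
#' noise to reach the requested signal-to-noise ratio. Deterministic for a
#' given seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `stack` (`size x size x n_frames`), `truth` (per-frame
#'   radial displacement, px), the noiseless `clean` stack, the line field,
#'   and the signal mask used to set the noise level.
#' @export
generate_line_movie <- function(spec) {
  base <- render_line_field(spec)
  course <- gamma_course(spec)
  truth <- spec$amplitude * course
  clean <- array(0, c(spec$size, spec$size, spec$n_frames))
  for (t in seq_len(spec$n_frames)) {
    clean[, , t] <- radial_warp(base, truth[t], spec$center)
  }
  mask <- base > 0.1
  set.seed(spec$seed + 1L)
  stack <- add_noise(clean, spec, mask)
  list(stack = stack, truth = truth, clean = clean, base = base,
       signal_mask = mask)
}

#' Synthetic two-channel movie (vessel + neurites)
#'
#' Red channel: a dilating soft-edged disk (the dye-filled vessel lumen)
#' whose radius follows a gamma-function dilation, plus `alpha` times the
#' green channel (crosstalk). Green channel: the line field displaced
#' radially with amplitude `rho` times the wall displacement (`"fsi"`
#' paradigm) or an onset-trimmed copy that only moves once the wall has
#' crossed the PVS gap (`"noncompliant"`). Both channels receive noise at
#' the target SNR.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `movie` (a [two_channel_movie]), `truth` (wall and
#'   tissue displacement per frame, px, plus `alpha`, `rho`), and the
#'   clean stacks.
#' @export
generate_two_channel_movie <- function(spec) {
  if (2 * (spec$vessel_radius * (1 + spec$dilation_frac)) > spec$size) {
    stop("vessel does not fit in the frame")
  }
  base <- render_line_field(spec)
  course <- gamma_course(spec)
  wall <- spec$vessel_radius * spec$dilation_frac * course
  tissue <- switch(spec$paradigm,
                   fsi = spec$rho * wall,
                   noncompliant = pmax(wall - spec$gap, 0))
  n <- spec$size
  yy <- matrix(rep(seq_len(n), n), n) - spec$center[1]
  xx <- matrix(rep(seq_len(n), each = n), n) - spec$center[2]
  rr <- sqrt(yy^2 + xx^2)
  red_c <- array(0, c(n, n, spec$n_frames))
  grn_c <- array(0, c(n, n, spec$n_frames))
  edge <- 1.5
  for (t in seq_len(spec$n_frames)) {
    R <- spec$vessel_radius + wall[t]
    red_c[, , t] <- 1 / (1 + exp((rr - R) / edge))
    grn_c[, , t] <- radial_warp(base, tissue[t], spec$center)
  }
  mask_r <- rr <= spec$vessel_radius
  mask_g <- base > 0.1
  set.seed(spec$seed + 2L)
  red <- add_noise(red_c + spec$alpha * grn_c, spec, mask_r)
  grn <- add_noise(grn_c, spec, mask_g)
  list(movie = two_channel_movie(red, grn, frame_rate = spec$frame_rate,
                                 pixel_size = 1, center = spec$center),
       truth = list(wall = wall, tissue = tissue, alpha = spec$alpha,
                    rho = spec$rho, course = course),
       clean = list(red = red_c, green = grn_c),
       masks = list(red = mask_r, green = mask_g))
}

#' Measure the signal-to-noise ratio of a stack
#'
#' Mean of the signal pixels divided by the standard deviation of the
#' background (non-signal) pixels.
#'
#' @param stack Image array (2-D or 3-D).
#' @param signal_mask Logical matrix marking signal pixels.
#' @return The SNR; infinite (with a warning) for a noiseless background.
#' @export
measure_snr <- function(stack, signal_mask) {
  if (!any(signal_mask)) stop("empty signal mask")
  if (all(signal_mask)) stop("mask leaves no background pixels")
  if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1))
  nt <- dim(stack)[3]
  sig <- mean(stack[rep(signal_mask, nt)])
  bg <- stats::sd(stack[rep(!signal_mask, nt)])
  if (bg == 0) {
    warning("noiseless background: SNR undefined (infinite)")
    return(Inf)
  }
  sig / bg
}
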
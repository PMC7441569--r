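# Piecewise rigid tissue-displacement estimation: overlapping 64x64 tiles
# (48 px overlap), iterative subpixel registration against a rest-period
# reference with convergence and residual-error gating, scrubbing/median
# fill, wavelet denoising; then direction and correlation gates and
# impulse-response summarization.

#' Candidate tile grid
#'
#' Top-left corners of overlapping square tiles covering an image.
#'
#' @param dims Image dimensions `c(H, W)`.
#' @param tile Tile side, px.
#' @param stride Grid stride, px (tile - overlap).
#' @return Matrix with columns `y`, `x`; one row per candidate position.
#' @export
tile_grid <- function(dims, tile = 64, stride = 16) {
  ys <- seq(1L, dims[1] - tile + 1L, by = stride)
  xs <- seq(1L, dims[2] - tile + 1L, by = stride)
  cbind(y = rep(ys, times = length(xs)), x = rep(xs, each = length(ys)))
}

#' Piecewise tissue displacement from the neurite channel
#'
#' Breaks the green-channel frames into overlapping tiles (default 64 px
#' with 48 px overlap), keeps tiles in the top 20th percentile of peak
#' reference fluorescence, and for each tile and frame estimates the
#' displacement by iterative subpixel DFT registration against the
#' reference tile (up to 5 iterations; converged when the last increment is
#' below 1% of the accumulated displacement). A frame's estimate is
#' accepted only if the iteration converged and the registration residual
#' is below `err_thresh`. Rejected time points are scrubbed and median
#' filled, and each tile trace is denoised with the biorthogonal-3.3
#' wavelet filter.
#'
#' @param stack Green-channel array `H x W x T` (registered).
#' @param reference Reference frame (average of rest frames); default the
#'   temporal median of the stack.
#' @param tile,stride Tile geometry, px.
#' @param top_pct Fluorescence gate: keep tiles whose peak reference
#'   fluorescence is in the top `top_pct` fraction.
#' @param maxit Registration iterations per tile and frame.
#' @param conv_frac Convergence gate: last increment < `conv_frac` x total.
#' @param err_thresh Registration residual gate.
#' @param pixel_size Pixel size, um.
#' @param denoise Apply wavelet denoising to the tile traces.
#' @param tiles Optional subset of qualified-tile indices to process.
#' @return A `displacement_series`: tile centers, displacement array
#'   `(tiles x frames x 2)` (dy, dx in px), per-frame acceptance, per-tile
#'   status and usable flags, and grid metadata (including the number of
#'   candidate positions before the fluorescence gate).
#' @export
piecewise_displacement <- function(stack, reference = NULL, tile = 64,
                                   stride = 16, top_pct = 0.20, maxit = 5,
                                   conv_frac = 0.01, err_thresh = 0.70,
                                   pixel_size = 1, denoise = TRUE,
                                   tiles = NULL) {
  d <- dim(stack)
  if (is.null(reference)) reference <- apply(stack, c(1, 2), stats::median)
  grid <- tile_grid(d[1:2], tile, stride)
  ncand <- nrow(grid)
  peakf <- vapply(seq_len(ncand), function(i) {
    max(reference[grid[i, 1] + 0:(tile - 1L), grid[i, 2] + 0:(tile - 1L)])
  }, numeric(1))
  qual <- which(peakf >= stats::quantile(peakf, 1 - top_pct))
  proc <- if (is.null(tiles)) qual else qual[tiles[tiles >= 1 & tiles <= length(qual)]]
  if (!length(proc)) {
    stop("no qualifying tiles to process (", length(qual), " qualified)")
  }
  ntile <- length(proc)
  nt <- d[3]
  disp <- array(0, c(ntile, nt, 2))
  accepted <- matrix(FALSE, ntile, nt)
  for (ii in seq_len(ntile)) {
    g <- grid[proc[ii], ]
    ry <- g[1] + 0:(tile - 1L); rx <- g[2] + 0:(tile - 1L)
    rt <- reference[ry, rx]
    for (t in seq_len(nt)) {
      ft <- stack[ry, rx, t]
      dtot <- c(0, 0); conv <- FALSE; err <- 1
      cur <- ft
      for (it in seq_len(maxit)) {
        reg <- dft_register(rt, cur)
        err <- reg$error
        dtot <- dtot + reg$shift
        inc <- sqrt(sum(reg$shift^2))
        tot <- sqrt(sum(dtot^2))
        if (inc <= max(conv_frac * tot, 0.02)) { conv <- TRUE; break }
        cur <- fourier_shift(ft, -dtot)
      }
      disp[ii, t, ] <- dtot
      accepted[ii, t] <- conv && err < err_thresh
    }
    # scrub + median fill + denoise
    for (cmp in 1:2) {
      tr <- disp[ii, , cmp]
      bad <- !accepted[ii, ]
      if (any(bad) && any(!bad)) {
        med <- stats::median(tr[!bad])
        for (t in which(bad)) {
          nb <- which(!bad & abs(seq_len(nt) - t) <= 3)
          tr[t] <- if (length(nb)) stats::median(tr[nb]) else med
        }
      }
      if (denoise && nt >= 8) tr <- wavelet_denoise(tr)
      disp[ii, , cmp] <- tr
    }
  }
  frac_ok <- rowMeans(accepted)
  structure(list(
    centers = cbind(y = grid[proc, 1] + (tile - 1) / 2,
                    x = grid[proc, 2] + (tile - 1) / 2),
    disp = disp, accepted = accepted, usable = frac_ok >= 0.75,
    frac_converged = frac_ok,
    n_candidates = ncand, n_qualified = length(qual), processed = proc,
    tile = tile, stride = stride, pixel_size = pixel_size
  ), class = "displacement_series")
}

#' @export
print.displacement_series <- function(x, ...) {
  cat(sprintf("Displacement series: %d/%d tiles processed (%d candidates), %d frames\n",
              nrow(x$centers), x$n_qualified, x$n_candidates, dim(x$disp)[2]))
  cat(sprintf("  usable tiles (>=75%% frames converged): %d (%.0f%%)\n",
              sum(x$usable), 100 * mean(x$usable)))
  invisible(x)
}

#' Gate displacement tiles and summarize impulse responses
#'
#' Keeps tiles whose mean displacement direction is radially outward from
#' the vessel center (within `angle_tol` degrees) and whose radial
#' displacement trace correlates with the vessel diameter trace (Pearson
#' r > `r_threshold`); then computes locomotion-deconvolved impulse
#' responses for the arteriolar wall (diameter/2) and the accepted tissue
#' tiles, aligns their peaks, and peak-normalizes (L-infinity).
#'
#' @param disp A [piecewise_displacement()] result.
#' @param vessel A [radon_diameter()] `vessel_trace` (or numeric diameter
#'   trace, um).
#' @param locomotion Velocity trace per frame (or logical binary).
#' @param center Vessel center `c(y, x)`, px.
#' @param angle_tol Direction gate half-width, degrees.
#' @param r_threshold Pearson correlation gate.
#' @param frame_rate Frames per second.
#' @return An `impulse_response` object: `time` (s), peak-normalized `wall`
#'   and `tissue` impulse responses, alignment `lag_s`, indices of
#'   `accepted` tiles, per-gate rejection counts, and the estimated
#'   tissue/wall displacement ratio.
#' @export
validate_and_summarize <- function(disp, vessel, locomotion, center,
                                   angle_tol = 30, r_threshold = 0.8,
                                   frame_rate = NULL) {
  dia <- if (inherits(vessel, "vessel_trace")) vessel$diameter else vessel
  if (is.null(frame_rate)) {
    frame_rate <- if (inherits(vessel, "vessel_trace")) vessel$frame_rate else 3
  }
  nt <- dim(disp$disp)[2]
  stopifnot(length(dia) == nt)
  ntile <- nrow(disp$centers)
  radial <- matrix(0, ntile, nt)
  dir_ok <- cor_ok <- logical(ntile)
  for (i in seq_len(ntile)) {
    rvec <- c(disp$centers[i, 1] - center[1], disp$centers[i, 2] - center[2])
    rhat <- rvec / max(sqrt(sum(rvec^2)), 1e-9)
    radial[i, ] <- disp$disp[i, , 1] * rhat[1] + disp$disp[i, , 2] * rhat[2]
    w <- sqrt(disp$disp[i, , 1]^2 + disp$disp[i, , 2]^2)
    if (sum(w) > 0) {
      mv <- c(sum(disp$disp[i, , 1] * w), sum(disp$disp[i, , 2] * w)) / sum(w)
      ang <- acos(pmin(pmax(sum(mv * rhat) / max(sqrt(sum(mv^2)), 1e-12), -1), 1))
      dir_ok[i] <- ang <= angle_tol * pi / 180
    }
    ct <- suppressWarnings(stats::cor(radial[i, ], dia))
    cor_ok[i] <- is.finite(ct) && ct > r_threshold
  }
  acc <- which(dir_ok & cor_ok & disp$usable)
  gate_counts <- c(direction = sum(!dir_ok), correlation = sum(!cor_ok),
                   convergence = sum(!disp$usable), accepted = length(acc))
  bin <- if (is.logical(locomotion)) locomotion else binarize_locomotion(locomotion)
  wall_disp <- (dia - stats::median(dia)) / 2
  span <- max(4L, nt %/% 2L)
  ir_wall <- deconvolve_ir(bin, wall_disp, span = span)
  out <- list(time = (seq_len(span) - 1L) / frame_rate,
              wall = NULL, tissue = NULL, lag_s = NA_real_,
              accepted = acc, gate_counts = gate_counts,
              displacement_ratio = NA_real_, radial = radial)
  if (max(abs(ir_wall)) > 0) out$wall <- ir_wall / max(abs(ir_wall))
  if (length(acc)) {
    irs <- vapply(acc, function(i) {
      ir <- deconvolve_ir(bin, radial[i, ] * disp$pixel_size, span = span)
      if (max(abs(ir)) > 0) ir / max(abs(ir)) else ir
    }, numeric(span))
    ir_tis <- rowMeans(irs)
    if (max(abs(ir_tis)) > 0) ir_tis <- ir_tis / max(abs(ir_tis))
    out$tissue <- ir_tis
    if (!is.null(out$wall)) {
      out$lag_s <- (which.max(ir_tis) - which.max(out$wall)) / frame_rate
    }
    peak_tis <- mean(vapply(acc, function(i) {
      max(abs(radial[i, ] - stats::median(radial[i, ]))) * disp$pixel_size
    }, numeric(1)))
    peak_wall <- max(abs(wall_disp))
    if (peak_wall > 0) out$displacement_ratio <- peak_tis / peak_wall
  }
  class(out) <- "impulse_response"
  out
}

#' @export
print.impulse_response <- function(x, ...) {
  cat(sprintf("Impulse-response summary: %d tiles accepted (rejected: %d direction, %d correlation, %d convergence)\n",
              x$gate_counts["accepted"], x$gate_counts["direction"],
              x$gate_counts["correlation"], x$gate_counts["convergence"]))
  if (!is.na(x$lag_s)) cat(sprintf("  wall-tissue peak lag: %.3g s\n", x$lag_s))
  if (!is.na(x$displacement_ratio)) {
    cat(sprintf("  tissue/wall displacement ratio: %.3g\n", x$displacement_ratio))
  }
  invisible(x)
}

#' @export
plot.impulse_response <- function(x, ...) {
  graphics::plot(x$time, x$wall, type = "l", col = "magenta", lwd = 2,
                 xlab = "time (s)", ylab = "peak-normalized impulse response",
                 ylim = range(c(x$wall, x$tissue), na.rm = TRUE), ...)
  if (!is.null(x$tissue)) graphics::lines(x$time, x$tissue, col = "darkgreen", lwd = 2)
  graphics::legend("topright", c("arteriolar wall", "brain tissue"),
                   col = c("magenta", "darkgreen"), lwd = 2, bty = "n")
  invisible(x)
}
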
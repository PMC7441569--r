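#' Two-channel two-photon movie container
#'
#' Holds a registered pair of image stacks: the red channel (vessel lumen,
#' dye-filled) and the green channel (YFP-expressing neurites), as
#' `H x W x T` arrays, with acquisition metadata.
#'
#' @param red,green Numeric arrays `H x W x T` of equal dimensions.
#' @param frame_rate Frames per second.
#' @param pixel_size Pixel size, um.
#' @param center Vessel center estimate `c(y, x)` in pixels.
#' @return A `two_channel_movie` object.
#' @export
two_channel_movie <- function(red, green, frame_rate = 3, pixel_size = 0.5,
                              center = dim(red)[1:2] / 2) {
  stopifnot(length(dim(red)) == 3, all(dim(red) == dim(green)))
  structure(list(red = red, green = green, frame_rate = frame_rate,
                 pixel_size = pixel_size, center = center,
                 shifts = NULL), class = "two_channel_movie")
}

#' @export
print.two_channel_movie <- function(x, ...) {
  d <- dim(x$red)
  cat(sprintf("Two-channel movie: %d x %d px, %d frames @ %g Hz, %g um/px\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_size))
  if (!is.null(x$shifts)) cat("  (motion corrected)\n")
  invisible(x)
}

#' Read a two-channel movie from TIFF stacks
#'
#' @param red_path,green_path Paths to single-channel multi-frame TIFFs.
#' @param ... Metadata passed to [two_channel_movie()].
#' @return A `two_channel_movie`.
#' @export
read_two_channel_tiff <- function(red_path, green_path, ...) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF stacks requires the 'tiff' package")
  }
  as_stack <- function(path) {
    fr <- tiff::readTIFF(path, all = TRUE)
    array(unlist(fr), dim = c(dim(fr[[1]])[1:2], length(fr)))
  }
  two_channel_movie(as_stack(red_path), as_stack(green_path), ...)
}

# 3D median filter (sy x sx in space, st frames in time), edge-replicated.
median_filter_3d <- function(stack, size = c(3, 3, 5)) {
  d <- dim(stack)
  oy <- (size[1] - 1L) %/% 2L; ox <- (size[2] - 1L) %/% 2L; ot <- (size[3] - 1L) %/% 2L
  out <- array(0, d)
  npix <- d[1] * d[2]
  nneig <- size[1] * size[2] * size[3]
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  for (t in seq_len(d[3])) {
    buf <- matrix(0, npix, nneig)
    k <- 0L
    for (dt in -ot:ot) for (dx in -ox:ox) for (dy in -oy:oy) {
      k <- k + 1L
      buf[, k] <- stack[cl(seq_len(d[1]) + dy, d[1]),
                        cl(seq_len(d[2]) + dx, d[2]),
                        cl(t + dt, d[3])]
    }
    out[, , t] <- matrixStats::rowMedians(buf)
  }
  out
}

#' Motion-correct and denoise a two-channel movie
#'
#' Rigid motion correction driven by the red (vessel) channel: each frame is
#' registered to the temporal median image by subpixel DFT registration and
#' both channels are translated by the recovered shift, so the vessel
#' center stays stationary. Shot noise is then removed with a 3x3 (space)
#' x 5 (frames) median filter.
#'
#' @param movie A [two_channel_movie].
#' @param median_size Median filter extents `c(y, x, t)`.
#' @param max_error Frames whose registration residual exceeds this are
#'   flagged (shift applied regardless).
#' @return The corrected movie; per-frame shifts in `$shifts`, flags in
#'   `$registration_flags`.
#' @export
preprocess <- function(movie, median_size = c(3, 3, 5), max_error = 0.9) {
  stopifnot(inherits(movie, "two_channel_movie"))
  d <- dim(movie$red)
  if (d[3] < 5) stop("need at least 5 frames")
  shifts <- matrix(0, d[3], 2)
  flags <- logical(d[3])
  red <- movie$red; green <- movie$green
  # two passes: the first median reference is blurred by the motion itself,
  # so re-estimate against the median of the corrected stack
  for (pass in 1:2) {
    ref <- apply(red, c(1, 2), stats::median)
    for (t in seq_len(d[3])) {
      reg <- dft_register(ref, red[, , t])
      shifts[t, ] <- shifts[t, ] + reg$shift
      flags[t] <- isTRUE(reg$flat) || reg$error > max_error
      if (any(reg$shift != 0)) {
        red[, , t] <- fourier_shift(movie$red[, , t], -shifts[t, ])
        green[, , t] <- fourier_shift(movie$green[, , t], -shifts[t, ])
      }
    }
  }
  out <- movie
  out$red <- median_filter_3d(red, median_size)
  out$green <- median_filter_3d(green, median_size)
  out$shifts <- shifts
  out$registration_flags <- flags
  out
}

#' Remove green-to-red channel crosstalk
#'
#' The recorded red image is modeled as the true red fluorescence plus a
#' constant fraction `alpha` of the green fluorescence; `alpha` is found by
#' one-dimensional minimization of `||r - alpha g||` over (0, 1.5) and the
#' corrected red channel is `r - alpha g`, clipped at zero.
#'
#' @param red,green Image stacks (or a [two_channel_movie] as `red`).
#' @return List with `red_fluorescence` and `alpha`.
#' @export
remove_crosstalk <- function(red, green = NULL) {
  if (inherits(red, "two_channel_movie")) {
    green <- red$green; red <- red$red
  }
  stopifnot(all(dim(red) == dim(green)))
  if (all(green == 0)) {
    warning("green channel is all zero; alpha set to the lower search bound")
    return(list(red_fluorescence = red, alpha = 0))
  }
  obj <- function(a) sqrt(sum((red - a * green)^2))
  opt <- stats::optimize(obj, interval = c(0, 1.5))
  alpha <- opt$minimum
  list(red_fluorescence = pmax(red - alpha * green, 0), alpha = alpha)
}
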
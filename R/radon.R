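# Radon-space vessel cross-section segmentation ("thresholding in Radon
# space"): forward transform over 0..180 degrees, per-angle normalization
# and thresholding at 0.2, filtered backprojection, then area extraction
# from the reconstructed image.

#' Radon transform of an image
#'
#' Line-integral projections of `img` for the given angles (degrees),
#' computed by bilinear rotation about the image center and column sums.
#'
#' @param img Numeric matrix.
#' @param angles Projection angles in degrees.
#' @return A matrix with one column per angle; rows index the projection
#'   offset (length = diagonal-padded size).
#' @export
radon_transform <- function(img, angles = 0:180) {
  nr <- nrow(img); nc <- ncol(img)
  np <- 2L * ceiling(sqrt(nr^2 + nc^2) / 2) + 1L
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  cp <- (np + 1) / 2
  out <- matrix(0, np, length(angles))
  gy <- rep(seq_len(np), np) - cp       # rotated-frame coordinates
  gx <- rep(seq_len(np), each = np) - cp
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    ys <- cy + gy * cos(th) - gx * sin(th)
    xs <- cx + gy * sin(th) + gx * cos(th)
    inside <- ys >= 1 & ys <= nr & xs >= 1 & xs <= nc
    vals <- numeric(np * np)
    vals[inside] <- bilinear_sample(img, ys[inside], xs[inside])
    out[, a] <- colSums(matrix(vals, np, np))
  }
  out
}

#' Inverse Radon transform (filtered backprojection)
#'
#' @param sino Sinogram as produced by [radon_transform()].
#' @param angles Angles (degrees) matching the sinogram columns.
#' @param out_size Output image size `c(rows, cols)`.
#' @return Reconstructed image.
#' @export
iradon <- function(sino, angles, out_size) {
  np <- nrow(sino)
  nfft <- 2^ceiling(log2(2 * np))
  freqs <- c(0:(nfft / 2), (nfft / 2 - 1):1) / nfft
  ramp <- freqs * 2                      # ramp filter
  filt <- matrix(0, np, ncol(sino))
  for (a in seq_len(ncol(sino))) {
    pz <- c(sino[, a], rep(0, nfft - np))
    fz <- Re(stats::fft(stats::fft(pz) * ramp, inverse = TRUE)) / nfft
    filt[, a] <- fz[seq_len(np)]
  }
  nr <- out_size[1]; nc <- out_size[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2; cp <- (np + 1) / 2
  yy <- rep(seq_len(nr), nc) - cy
  xx <- rep(seq_len(nc), each = nr) - cx
  rec <- numeric(nr * nc)
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    tpos <- yy * cos(th) + xx * sin(th) + cp
    t0 <- pmin(pmax(floor(tpos), 1L), np - 1L)
    ft <- tpos - t0
    rec <- rec + filt[t0, a] * (1 - ft) + filt[t0 + 1L, a] * ft
  }
  matrix(rec * pi / (2 * length(angles)), nr, nc)
}

#' Vessel lumen area and diameter by Radon-space thresholding
#'
#' Per frame: Radon transform of the vessel ROI for angles 0-180 degrees in
#' 1 degree steps; each angle's projection is min-max rescaled to [0, 1] and
#' values below 0.2 zeroed; the thresholded sinogram is backprojected and
#' the lumen area measured from the reconstruction (pixels above half of
#' its maximum, largest connected region). The equivalent diameter is
#' `2 sqrt(area/pi)`.
#'
#' @param roi_stack `H x W x T` array containing the full vessel
#'   cross-section (red channel ROI).
#' @param pixel_size Pixel size, um.
#' @param threshold Radon-space threshold (fraction of the per-angle
#'   range).
#' @param frame_rate Frames per second (stored on the result).
#' @return A `vessel_trace`: per-frame `area` (um^2), `diameter` (um),
#'   logical `valid` (empty segmentations are invalid and median-filled).
#' @export
radon_diameter <- function(roi_stack, pixel_size = 1, threshold = 0.2,
                           frame_rate = 3) {
  if (length(dim(roi_stack)) == 2L) roi_stack <- array(roi_stack, c(dim(roi_stack), 1))
  d <- dim(roi_stack)
  angles <- 0:180
  area_px <- numeric(d[3]); valid <- logical(d[3])
  for (t in seq_len(d[3])) {
    img <- roi_stack[, , t]
    rng <- max(img) - min(img)
    if (rng <= 0) { valid[t] <- FALSE; next }
    sino <- radon_transform(img, angles)
    smin <- matrixStats::colMins(sino); smax <- matrixStats::colMaxs(sino)
    span <- pmax(smax - smin, .Machine$double.eps)
    norm <- sweep(sweep(sino, 2, smin, "-"), 2, span, "/")
    norm[norm < threshold] <- 0
    rec <- iradon(norm, angles, d[1:2])
    mask <- rec > 0.5 * max(rec)
    if (!any(mask)) { valid[t] <- FALSE; next }
    area_px[t] <- largest_component_area(mask)
    valid[t] <- area_px[t] > 0
  }
  if (any(!valid) && any(valid)) {
    area_px[!valid] <- stats::median(area_px[valid])
  }
  area <- area_px * pixel_size^2
  structure(list(area = area, diameter = 2 * sqrt(area / pi),
                 valid = valid, pixel_size = pixel_size,
                 frame_rate = frame_rate), class = "vessel_trace")
}

#' @export
print.vessel_trace <- function(x, ...) {
  cat(sprintf("Vessel trace: %d frames, mean diameter %.2f um (%d invalid frames)\n",
              length(x$diameter), mean(x$diameter), sum(!x$valid)))
  invisible(x)
}

# Area (pixel count) of the largest 4-connected TRUE region.
largest_component_area <- function(mask) {
  if (requireNamespace("EBImage", quietly = TRUE)) {
    lab <- EBImage::bwlabel(mask)
    if (max(lab) == 0) return(0)
    return(max(tabulate(lab[lab > 0])))
  }
  # union-find on rows (fallback)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  parent <- integer(0)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (y in seq_len(nrow(mask))) for (x in seq_len(ncol(mask))) {
    if (!mask[y, x]) next
    up <- if (y > 1) lab[y - 1, x] else 0L
    lf <- if (x > 1) lab[y, x - 1] else 0L
    if (up == 0L && lf == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[y, x] <- nxt
    } else if (up > 0L && lf > 0L) {
      ru <- findp(up); rl <- findp(lf)
      parent[max(ru, rl)] <- min(ru, rl)
      lab[y, x] <- min(ru, rl)
    } else lab[y, x] <- max(up, lf)
  }
  if (nxt == 0L) return(0)
  roots <- vapply(seq_len(nxt), findp, integer(1))
  labs <- lab[lab > 0L]
  max(tabulate(roots[labs]))
}
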
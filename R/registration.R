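# Subpixel image registration by cross-correlation in the discrete Fourier
# domain: integer peak from the plain cross-correlation, refined on an
# upsampled DFT grid in a +/-1.5 px neighborhood (matrix-multiply DFT).
# The returned error is the normalized residual, sqrt(1 - ncc^2) with ncc
# the normalized correlation peak: 0 for a perfect translational match,
# approaching 1 when the images cannot be matched by a translation.

#' Subpixel DFT image registration
#'
#' Estimates the translation of `img` relative to `ref` by Fourier
#' cross-correlation with upsampled-DFT refinement.
#'
#' @param ref,img Numeric matrices of equal size.
#' @param upsample Subpixel refinement factor (registration resolution
#'   1/upsample px).
#' @return List with `shift = c(dy, dx)` (the displacement of `img`
#'   relative to `ref`: shifting `img` by `-shift` aligns it) and `error`,
#'   the normalized registration residual in [0, 1].
#' @export
dft_register <- function(ref, img, upsample = 20) {
  stopifnot(is.matrix(ref), all(dim(ref) == dim(img)))
  nr <- nrow(ref); nc <- ncol(ref)
  F1 <- stats::fft(ref); F2 <- stats::fft(img)
  CC <- stats::fft(Conj(F1) * F2, inverse = TRUE) / (nr * nc)
  peak <- which.max(abs(CC))
  pr <- ((peak - 1L) %% nr)
  pc <- ((peak - 1L) %/% nr)
  if (pr > nr / 2) pr <- pr - nr
  if (pc > nc / 2) pc <- pc - nc
  sh <- c(pr, pc)
  e1 <- sum(abs(F1)^2) / (nr * nc)   # = sum(ref^2) by Parseval
  e2 <- sum(abs(F2)^2) / (nr * nc)
  if (e1 <= 0 || e2 <= 0) {
    return(list(shift = c(0, 0), error = 1, flat = TRUE))
  }
  ccmax <- abs(CC[peak])
  if (upsample > 1) {
    # refine in a 1.5 px neighborhood at resolution 1/upsample
    usfac <- upsample
    nref <- ceiling(usfac * 1.5)
    dftshift <- floor(nref / 2)
    roff <- dftshift - sh[1] * usfac
    coff <- dftshift - sh[2] * usfac
    CCup <- dftups(F2 * Conj(F1), nref, nref, usfac, roff, coff)
    pk <- which.max(abs(CCup))
    rloc <- ((pk - 1L) %% nref) - dftshift
    cloc <- ((pk - 1L) %/% nref) - dftshift
    sh <- sh + c(rloc, cloc) / usfac
    ccmax <- abs(CCup[pk]) / (nr * nc)
  }
  ncc2 <- min(1, ccmax^2 / (e1 * e2))
  list(shift = sh, error = sqrt(1 - ncc2), flat = FALSE)
}

# Upsampled cross-correlation patch by matrix-multiply DFT.
dftups <- function(X, nor, noc, usfac, roff, coff) {
  nr <- nrow(X); nc <- ncol(X)
  fr <- c(0:(ceiling(nr / 2) - 1), -(floor(nr / 2)):-1)   # fft frequencies
  fc <- c(0:(ceiling(nc / 2) - 1), -(floor(nc / 2)):-1)
  kernr <- exp((2i * pi / (nr * usfac)) * outer(0:(nor - 1) - roff, fr))
  kernc <- exp((2i * pi / (nc * usfac)) * outer(fc, 0:(noc - 1) - coff))
  kernr %*% X %*% kernc
}

#' Translate an image by a (possibly subpixel) shift
#'
#' Fourier-domain translation: exact for periodic content, standard for
#' subpixel motion correction.
#'
#' @param img Numeric matrix.
#' @param shift `c(dy, dx)` displacement to apply.
#' @return The shifted image.
#' @export
fourier_shift <- function(img, shift) {
  nr <- nrow(img); nc <- ncol(img)
  fr <- c(0:(ceiling(nr / 2) - 1), -(floor(nr / 2)):-1) / nr
  fc <- c(0:(ceiling(nc / 2) - 1), -(floor(nc / 2)):-1) / nc
  ph <- exp(-2i * pi * (outer(fr * shift[1], rep(1, nc)) +
                        outer(rep(1, nr), fc * shift[2])))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (nr * nc)
}

# Bilinear sampling of img at (row, col) positions (vectors); values outside
# the support are clamped to the border.
bilinear_sample <- function(img, y, x) {
  nr <- nrow(img); nc <- ncol(img)
  y <- pmin(pmax(as.vector(y), 1), nr); x <- pmin(pmax(as.vector(x), 1), nc)
  y0 <- pmin(floor(y), nr - 1L); x0 <- pmin(floor(x), nc - 1L)
  fy <- y - y0; fx <- x - x0
  i00 <- cbind(y0, x0); i10 <- cbind(y0 + 1, x0)
  i01 <- cbind(y0, x0 + 1); i11 <- cbind(y0 + 1, x0 + 1)
  img[i00] * (1 - fy) * (1 - fx) + img[i10] * fy * (1 - fx) +
    img[i01] * (1 - fy) * fx + img[i11] * fy * fx
}
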
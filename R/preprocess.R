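#' @include AllClasses.R
NULL

.asEB <- function(pixels) EBImage::Image(t(pixels), colormode = EBImage::Grayscale)
.fromEB <- function(img) t(EBImage::imageData(img))

#' Z-score normalise an image
#'
#' Subtracts the image mean from every pixel and divides by the image
#' standard deviation (population SD, i.e. divisor `n`), producing the
#' normalised channel \eqn{I_n} with mean 0 and SD 1.  A constant image
#' has zero variance; it is returned as all zeros with a warning rather
#' than an error.
#'
#' @param pixels numeric matrix of intensities.
#' @return numeric matrix, mean 0 / SD 1 (or all zeros).
#' @examples
#' normalizeImage(matrix(c(0, 0, 2, 2), 2, 2))
#' @export
normalizeImage <- function(pixels) {
  stopifnot(is.matrix(pixels), length(pixels) > 0, all(is.finite(pixels)))
  mu <- mean(pixels)
  sdev <- sqrt(mean((pixels - mu)^2))
  if (sdev < 1e-12) {
    warning("constant image: zero variance, returning all zeros")
    return(matrix(0, nrow(pixels), ncol(pixels)))
  }
  (pixels - mu) / sdev
}

#' The 5x5 Gaussian smoothing kernel
#'
#' Separable 5-point Gaussian kernel (sigma 1.1, the conventional value
#' for a 5-tap filter), normalised to sum 1.
#'
#' @return 5x5 numeric matrix.
#' @export
gaussianKernel5 <- function() {
  sigma <- 1.1
  g <- exp(-((-2:2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  outer(g, g)
}

#' Histogram equalisation followed by Gaussian smoothing
#'
#' Produces the enhancement channel \eqn{I_g}: full-range histogram
#' equalisation (256 levels, CDF remapping normalised to the minimum
#' occupied level) applied first, then convolution with the fixed 5x5
#' Gaussian kernel ([gaussianKernel5()]), with replicated borders.  Input
#' and output are on the 0--255 scale.
#'
#' @param pixels numeric matrix, values in 0--255.
#' @return numeric matrix, values in [0, 255].
#' @export
equalizeBlur <- function(pixels) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)),
            min(pixels) >= 0, max(pixels) <= 255)
  eq <- if (diff(range(pixels)) < 1e-12) pixels else
    .fromEB(EBImage::equalize(.asEB(pixels / 255), range = c(0, 1),
                              levels = 256)) * 255
  blurred <- EBImage::filter2(.asEB(eq / 255), gaussianKernel5(),
                              boundary = "replicate")
  .clip(.fromEB(blurred) * 255, 0, 255)
}

# Morphological closing with edge replication, so structures touching the
# image border (the diaphragm band sits on the bottom edge) are not eroded
# away by the implicit background padding.
.closeBinary <- function(bin, radius) {
  if (radius < 1) return(bin)
  r <- as.integer(radius)
  nr <- nrow(bin); nc <- ncol(bin)
  padRows <- function(m, top, bottom) rbind(
    m[rep(1L, top), , drop = FALSE], m, m[rep(nrow(m), bottom), , drop = FALSE])
  padCols <- function(m, left, right) cbind(
    m[, rep(1L, left), drop = FALSE], m, m[, rep(ncol(m), right), drop = FALSE])
  padded <- padCols(padRows(bin, r, r), r, r)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  closed <- EBImage::imageData(EBImage::closing(
    EBImage::Image(t(padded)), kern = brush))
  t(closed)[r + seq_len(nr), r + seq_len(nc), drop = FALSE]
}

#' Segment the diaphragm region by intensity thresholding
#'
#' Computes the binary threshold
#' \eqn{t = i_{min} + coeff \cdot (i_{max} - i_{min})} from the extreme
#' intensities of the image, marks pixels with intensity \eqn{\ge t}, and
#' refines the binary map with a morphological closing (disc structuring
#' element of the given radius, borders replicated).
#'
#' @param pixels numeric matrix of intensities.
#' @param coeff threshold coefficient (default 0.9).
#' @param closingRadius disc radius in pixels for the closing (default 7,
#'   chosen for 224x224 inputs).
#' @return A [DiaphragmMask-class].
#' @examples
#' m <- matrix(c(rep(0, 12), rep(200, 4)), 4, 4)
#' thresholdUsed(diaphragmMask(m))  # 0 + 0.9 * 200 = 180
#' @export
diaphragmMask <- function(pixels, coeff = 0.9, closingRadius = 7) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  iMin <- min(pixels)
  iMax <- max(pixels)
  if (iMax - iMin < 1e-12)
    stop("degenerate intensity range: constant image", call. = FALSE)
  t <- iMin + coeff * (iMax - iMin)
  bin <- (pixels >= t) * 1
  closed <- .closeBinary(bin, closingRadius)
  new("DiaphragmMask", mask = closed * 1, thresholdUsed = t,
      iMin = iMin, iMax = iMax, coeff = coeff,
      closingRadius = as.numeric(closingRadius))
}

#' Remove the diaphragm region from an image
#'
#' Produces the channel \eqn{I_d}: pixels under the diaphragm mask (see
#' [diaphragmMask()]) are set to 0, all others are returned unchanged.
#' The operation is intended to be applied exactly once per source image
#' (zeroed pixels change the intensity extremes, so it is not
#' idempotent); [buildChannelStack()] enforces this by construction and
#' records it in the stack provenance.
#'
#' @inheritParams diaphragmMask
#' @return numeric matrix of the same shape.
#' @export
removeDiaphragm <- function(pixels, coeff = 0.9, closingRadius = 7) {
  m <- diaphragmMask(pixels, coeff = coeff, closingRadius = closingRadius)
  out <- pixels
  out[m@mask == 1] <- 0
  out
}

#' Resize a grayscale image (bilinear)
#'
#' @param pixels numeric matrix.
#' @param size target side length in pixels (square output).
#' @return numeric matrix `size x size`.
#' @export
resizeGray <- function(pixels, size) {
  if (nrow(pixels) == size && ncol(pixels) == size) return(pixels)
  .fromEB(EBImage::resize(.asEB(pixels), w = size, h = size))
}

.sourceFingerprint <- function(pixels) {
  sprintf("%dx%d:%.8e:%.8e", nrow(pixels), ncol(pixels), sum(pixels),
          sum(pixels * seq_along(pixels)))
}

#' Assemble the three-channel model input
#'
#' Resizes the grayscale source to `size x size` (bilinear), then stacks
#' the three preprocessed channels in fixed order: (1) the z-scored image
#' ([normalizeImage()]) min-max rescaled to [0, 1]; (2) the equalised and
#' blurred image ([equalizeBlur()]) divided by 255; (3) the
#' diaphragm-removed image ([removeDiaphragm()]) divided by 255.  All
#' channels derive from the same resized source, recorded in the stack's
#' `sourceId`; diaphragm removal is applied exactly once, recorded in the
#' provenance.
#'
#' With `mode = "raw-replicate"` the raw grayscale (divided by 255) is
#' replicated into all three channels instead; this mirrors feeding
#' unpreprocessed images to a 3-channel model and exists so the effect of
#' preprocessing can be measured.
#'
#' @param pixels numeric matrix on the 0--255 scale.
#' @param size target side length (default 224).
#' @param coeff,closingRadius passed to [diaphragmMask()].
#' @param mode `"preprocessed"` (default) or `"raw-replicate"`.
#' @return A [ChannelStack-class].
#' @export
buildChannelStack <- function(pixels, size = 224L, coeff = 0.9,
                              closingRadius = 7,
                              mode = c("preprocessed", "raw-replicate")) {
  mode <- match.arg(mode)
  img <- .clip(resizeGray(pixels, size), 0, 255)
  arr <- array(0, c(size, size, 3L))
  if (mode == "raw-replicate") {
    for (k in 1:3) arr[, , k] <- img / 255
    prov <- rep("raw_replicate", 3L)
  } else {
    z <- normalizeImage(img)
    rng <- range(z)
    arr[, , 1] <- if (diff(rng) < 1e-12) z * 0 else (z - rng[1]) / diff(rng)
    arr[, , 2] <- equalizeBlur(img) / 255
    arr[, , 3] <- removeDiaphragm(img, coeff = coeff,
                                  closingRadius = closingRadius) / 255
    prov <- c("normalized", "equalized_blurred", "diaphragm_removed_x1")
  }
  new("ChannelStack", channels = arr, provenance = prov,
      sourceId = .sourceFingerprint(img))
}
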
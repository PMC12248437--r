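#' @include nn-network.R
NULL

#' Grad-CAM arithmetic from activations and gradients
#'
#' The core computation, exposed separately so it can be verified
#' directly: for feature maps \eqn{A_k} and the gradients of the target
#' class score with respect to them, the channel weights are the global
#' average of each gradient map,
#' \eqn{\alpha_k = \frac{1}{HW}\sum_{i,j} \partial y_c / \partial A_k(i,j)},
#' and the raw class activation map is
#' \eqn{ReLU(\sum_k \alpha_k A_k)}.
#'
#' @param acts `(H, W, K)` activation array of the target layer.
#' @param grads `(H, W, K)` gradient array of the class score.
#' @return list with `alpha` (numeric K) and `raw` (H x W matrix,
#'   non-negative).
#' @export
gradCamMap <- function(acts, grads) {
  stopifnot(identical(dim(acts), dim(grads)), length(dim(acts)) == 3L)
  K <- dim(acts)[3]
  alpha <- vapply(seq_len(K), function(k) mean(grads[, , k]), 0)
  raw <- matrix(0, dim(acts)[1], dim(acts)[2])
  for (k in seq_len(K)) raw <- raw + alpha[k] * acts[, , k]
  raw[raw < 0] <- 0
  list(alpha = alpha, raw = raw)
}

.minMaxNormalize <- function(m) {
  mx <- max(m)
  if (mx <= 0) return(m * 0)            # all-zero map stays all-zero
  mn <- min(m)
  if (mx - mn < 1e-300) return(m * 0)
  (m - mn) / (mx - mn)
}

# Default target layer: the deepest stage whose feature map is at least
# 4 px across (the full-scale geometry targets the final convolutional
# stage, 7x7 at 224 input; scaled-down geometries fall back to the
# deepest stage that still has usable spatial resolution).
.defaultCamStage <- function(sizes) {
  ok <- which(sizes >= 4)
  if (length(ok)) return(max(ok))
  1L
}

#' Grad-CAM saliency map
#'
#' Computes the gradient of the target class score (the pre-softmax
#' logit) with respect to the activations of a convolutional stage,
#' global-average-pools the gradients into per-feature-map weights
#' \eqn{\alpha_k}, forms the weighted sum of the feature maps, applies a
#' ReLU to keep positive evidence, upsamples bilinearly to the input
#' resolution and min-max normalises to [0, 1] (an all-zero map stays
#' all-zero).  The normalised map is invariant to positive rescaling of
#' the class logit.
#'
#' @param model a trained `CxrModel`.
#' @param stack a [ChannelStack-class].
#' @param targetClass class name (default: the predicted class).
#' @param layer stage name `"conv2"` ... `"conv5"`; default picks the
#'   deepest stage with at least 7-pixel feature maps.
#' @return A [Heatmap-class].
#' @export
gradCam <- function(model, stack, targetClass = NULL, layer = NULL) {
  stopifnot(is(stack, "ChannelStack"))
  ch <- channels(stack)
  x <- array(ch, c(dim(ch)[1], dim(ch)[2], 3L, 1L))
  logits <- model$fwd(x, train = FALSE, keepActs = TRUE)
  if (is.null(targetClass)) {
    targetClass <- model$classes[which.max(logits[, 1])]
  } else if (!targetClass %in% model$classes) {
    stop("target class '", targetClass, "' not among: ",
         paste(model$classes, collapse = ", "), call. = FALSE)
  }
  sizes <- vapply(model$acts, function(a) dim(a)[1], 0)
  stage <- if (is.null(layer)) .defaultCamStage(sizes) else {
    st <- match(layer, paste0("conv", 2:5))
    if (is.na(st)) stop("layer must be one of conv2..conv5", call. = FALSE)
    st
  }
  kIdx <- match(targetClass, model$classes)
  dlogits <- matrix(0, length(model$classes), 1L)
  dlogits[kIdx, 1] <- 1
  dA <- model$bwdToStage(dlogits, stage)
  acts <- model$acts[[stage]]
  d <- dim(acts)
  cam <- gradCamMap(array(acts, d[1:3]), array(dA, d[1:3]))
  up <- resizeGray(cam$raw, dim(ch)[1])
  up[up < 0] <- 0                       # bilinear resize can undershoot 0
  new("Heatmap", alphaWeights = cam$alpha, raw = cam$raw,
      map = .minMaxNormalize(up), layer = paste0("conv", stage + 1L),
      targetClass = targetClass)
}

.jetColormap <- function(v) {
  ramp <- colorRamp(c("#00007F", "#0000FF", "#007FFF", "#00FFFF", "#7FFF7F",
                      "#FFFF00", "#FF7F00", "#FF0000", "#7F0000"))
  ramp(v) / 255
}

#' Overlay a heatmap on a grayscale image
#'
#' Renders the normalised heatmap through a jet colormap and
#' alpha-blends it onto the grayscale image:
#' `out = (1 - alpha) * gray + alpha * colormap(map)`.  An all-zero
#' heatmap returns the unmodified image (rendered as RGB); `alpha = 1`
#' returns the pure colormap.
#'
#' @param heatmap a [Heatmap-class] (or numeric matrix in [0, 1]).
#' @param pixels grayscale matrix on the 0--255 scale, same size as the
#'   heatmap's upsampled map.
#' @param alpha blend fraction in [0, 1] (default 0.4).
#' @param path optional PNG output path.
#' @return `(H, W, 3)` RGB array in [0, 1], invisibly if written.
#' @export
overlayHeatmap <- function(heatmap, pixels, alpha = 0.4, path = NULL) {
  m <- if (is(heatmap, "Heatmap")) heatmap@map else heatmap
  stopifnot(identical(dim(m), dim(pixels)), alpha >= 0, alpha <= 1)
  gray <- .clip(pixels / 255, 0, 1)
  out <- array(0, c(nrow(m), ncol(m), 3L))
  if (max(m) <= 0) {
    for (k in 1:3) out[, , k] <- gray
  } else {
    cols <- .jetColormap(as.vector(m))
    for (k in 1:3) {
      out[, , k] <- (1 - alpha) * gray +
        alpha * matrix(cols[, k], nrow(m), ncol(m))
    }
  }
  if (!is.null(path)) {
    img <- EBImage::Image(aperm(out, c(2, 1, 3)), colormode = EBImage::Color)
    EBImage::writeImage(img, path, type = "png", bits.per.sample = 8L)
    return(invisible(out))
  }
  out
}

#' Fraction of heatmap mass inside a bounding box
#'
#' Sum of normalised heatmap values inside the (optionally dilated)
#' rectangle divided by the total sum -- the localisation score used to
#' compare saliency maps against planted ground truth.
#'
#' @param heatmap a [Heatmap-class] or matrix.
#' @param bbox integer `(rowMin, colMin, rowMax, colMax)`.
#' @param dilate pixels to expand the box on every side (default 0).
#' @return numeric in [0, 1] (NA for an all-zero map).
#' @export
heatmapMassInBbox <- function(heatmap, bbox, dilate = 0L) {
  m <- if (is(heatmap, "Heatmap")) heatmap@map else heatmap
  tot <- sum(m)
  if (tot <= 0) return(NA_real_)
  r <- max(1L, bbox[1] - dilate):min(nrow(m), bbox[3] + dilate)
  c <- max(1L, bbox[2] - dilate):min(ncol(m), bbox[4] + dilate)
  sum(m[r, c]) / tot
}
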
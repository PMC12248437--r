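#' @include cxrnet-package.R
NULL

# ---- PhantomSpec -----------------------------------------------------------

#' Specification of a synthetic radiograph phantom
#'
#' Parameters controlling one generated phantom image: class label, image
#' size, the fraction of the image height occupied by the bright
#' diaphragm-like band, the intensity offset of the planted class
#' signature relative to its local background (on the 0--255 scale), the
#' standard deviation of the additive Gaussian noise, and the RNG seed.
#'
#' @slot label character, one of [cxrClasses()].
#' @slot imageSize integer, image side in pixels (square), at least 32.
#' @slot diaphragmHeightFrac numeric in (0, 0.5).
#' @slot signalContrast positive numeric.
#' @slot noiseSd non-negative numeric.
#' @slot seed integer seed.
#' @export
setClass("PhantomSpec", representation(
  label = "character",
  imageSize = "integer",
  diaphragmHeightFrac = "numeric",
  signalContrast = "numeric",
  noiseSd = "numeric",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!object@label %in% cxrClasses())
    msg <- c(msg, paste0("label must be one of: ",
                         paste(cxrClasses(), collapse = ", ")))
  if (object@imageSize < 32L) msg <- c(msg, "imageSize must be >= 32")
  if (object@diaphragmHeightFrac <= 0 || object@diaphragmHeightFrac >= 0.5)
    msg <- c(msg, "diaphragmHeightFrac must lie in (0, 0.5)")
  if (object@signalContrast <= 0) msg <- c(msg, "signalContrast must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a phantom specification
#'
#' @param label class label, one of [cxrClasses()].
#' @param imageSize image side in pixels (default 224).
#' @param diaphragmHeightFrac fraction of the image height taken by the
#'   bright bottom band (default 0.22).
#' @param signalContrast intensity offset of the planted signature above
#'   (or, for Pneumothorax, below) its local background, 0--255 scale
#'   (default 60).
#' @param noiseSd additive Gaussian noise standard deviation (default 8).
#' @param seed integer RNG seed (default 1).
#' @return A [PhantomSpec-class] object.
#' @examples
#' phantomSpec("Cardiomegaly", imageSize = 64, seed = 7)
#' @export
phantomSpec <- function(label, imageSize = 224L, diaphragmHeightFrac = 0.22,
                        signalContrast = 60, noiseSd = 8, seed = 1L) {
  .checkLabel(label)
  new("PhantomSpec", label = label, imageSize = as.integer(imageSize),
      diaphragmHeightFrac = diaphragmHeightFrac,
      signalContrast = signalContrast, noiseSd = noiseSd,
      seed = as.integer(seed))
}

# ---- PhantomImage ----------------------------------------------------------

#' A generated phantom radiograph with ground truth
#'
#' Holds the pixel matrix (integers in 0--255), the class label, the
#' bounding box of the planted signature (empty for "No Finding"), the
#' bounding box of the diaphragm band, and the exact logical mask of
#' signature pixels that were modified (the bbox is its tight enclosure).
#' Bounding boxes are integer vectors `(rowMin, colMin, rowMax, colMax)`.
#'
#' @slot pixels numeric matrix, values in 0--255.
#' @slot label character class label.
#' @slot signatureBbox integer(4) or integer(0).
#' @slot diaphragmBbox integer(4).
#' @slot signatureMask logical matrix (same shape as pixels) or 0x0.
#' @slot lungMask logical matrix marking the two lung fields.
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("PhantomImage", representation(
  pixels = "matrix",
  label = "character",
  signatureBbox = "integer",
  diaphragmBbox = "integer",
  signatureMask = "matrix",
  lungMask = "matrix",
  spec = "PhantomSpec"
))

setValidity("PhantomImage", function(object) {
  msg <- character()
  s <- nrow(object@pixels)
  inIm <- function(b) length(b) == 4L && all(b >= 1L) &&
    b[3] <= s && b[4] <= ncol(object@pixels) && b[1] <= b[3] && b[2] <= b[4]
  if (length(object@signatureBbox) && !inIm(object@signatureBbox))
    msg <- c(msg, "signatureBbox outside image")
  if (!inIm(object@diaphragmBbox)) msg <- c(msg, "diaphragmBbox outside image")
  if (object@label == "No Finding" && length(object@signatureBbox))
    msg <- c(msg, "No Finding phantom must not carry a signature bbox")
  if (length(msg)) msg else TRUE
})

# ---- DiaphragmMask ---------------------------------------------------------

#' Binary diaphragm segmentation mask
#'
#' The thresholded-and-closed binary mask of the bright diaphragm region,
#' together with the threshold actually used and the intensity extremes of
#' the source image it was derived from.
#'
#' @slot mask binary (0/1) matrix.
#' @slot thresholdUsed numeric threshold `t`.
#' @slot iMin,iMax numeric intensity extremes of the source image.
#' @slot coeff the threshold coefficient used.
#' @slot closingRadius radius (pixels) of the disc structuring element.
#' @export
setClass("DiaphragmMask", representation(
  mask = "matrix",
  thresholdUsed = "numeric",
  iMin = "numeric",
  iMax = "numeric",
  coeff = "numeric",
  closingRadius = "numeric"
))

setValidity("DiaphragmMask", function(object) {
  msg <- character()
  if (!all(object@mask %in% c(0, 1))) msg <- c(msg, "mask values must be 0/1")
  if (object@thresholdUsed < object@iMin || object@thresholdUsed > object@iMax)
    msg <- c(msg, "threshold must lie within [iMin, iMax]")
  if (length(msg)) msg else TRUE
})

# ---- ChannelStack ----------------------------------------------------------

#' Three-channel model input
#'
#' The stacked model input built from one grayscale radiograph: channel 1
#' is the z-scored image rescaled to [0, 1], channel 2 the
#' equalised-and-blurred image divided by 255, channel 3 the
#' diaphragm-removed image divided by 255.  `provenance` records which
#' preprocessing produced each channel and `sourceId` fingerprints the
#' common source image (all three channels must derive from the same
#' source).
#'
#' @slot channels numeric array, `size x size x 3`, values in [0, 1].
#' @slot provenance character(3).
#' @slot sourceId character(1) fingerprint of the source image.
#' @export
setClass("ChannelStack", representation(
  channels = "array",
  provenance = "character",
  sourceId = "character"
))

setValidity("ChannelStack", function(object) {
  d <- dim(object@channels)
  msg <- character()
  if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "channels must be H x W x 3")
  if (length(object@provenance) != 3L) msg <- c(msg, "provenance must have length 3")
  if (length(msg)) msg else TRUE
})

# ---- AugmentationPlan ------------------------------------------------------

#' Class-balancing augmentation plan
#'
#' Per-class number of augmented samples required to bring every class up
#' to the reference class count, plus a per-class flag enabling the
#' extended transforms (zoom, brightness/contrast) for classes with low
#' original representation.
#'
#' @slot counts named numeric, original per-class counts.
#' @slot reference character, the reference class.
#' @slot plan named numeric, augmented samples to create per class.
#' @slot extended named logical, extended-transform flag per class.
#' @export
setClass("AugmentationPlan", representation(
  counts = "numeric",
  reference = "character",
  plan = "numeric",
  extended = "logical"
))

setValidity("AugmentationPlan", function(object) {
  msg <- character()
  if (!object@reference %in% names(object@counts))
    msg <- c(msg, "reference class missing from counts")
  ref <- object@counts[object@reference]
  expect <- pmax(0, ref - object@counts)
  if (!isTRUE(all.equal(unname(object@plan[names(object@counts)]),
                        unname(expect))))
    msg <- c(msg, "plan must equal max(0, reference - count) per class")
  if (object@plan[object@reference] != 0)
    msg <- c(msg, "reference class plan must be 0")
  if (length(msg)) msg else TRUE
})

# ---- MetricsReport ---------------------------------------------------------

#' Multi-class evaluation report
#'
#' Confusion matrix (rows = true class, columns = predicted class),
#' overall accuracy, per-class precision/recall/F1 and one-vs-rest binary
#' accuracy, macro averages, and one-vs-rest ROC curves with AUC.
#'
#' @slot confusion numeric matrix.
#' @slot accuracy numeric(1).
#' @slot perClass data.frame with one row per class.
#' @slot macro named numeric (precision, recall, f1).
#' @slot auc named numeric, one-vs-rest AUC per class (NA if undefined).
#' @slot roc list of per-class data.frames with columns fpr, tpr.
#' @export
setClass("MetricsReport", representation(
  confusion = "matrix",
  accuracy = "numeric",
  perClass = "data.frame",
  macro = "numeric",
  auc = "numeric",
  roc = "list"
))

# ---- Heatmap ---------------------------------------------------------------

#' Grad-CAM heatmap
#'
#' The pooled-gradient channel weights, the raw (post-ReLU) class
#' activation map at feature resolution, and the bilinearly upsampled map
#' at image resolution normalised to [0, 1].
#'
#' @slot alphaWeights numeric, one pooled-gradient weight per feature map.
#' @slot raw numeric matrix at feature-map resolution (non-negative).
#' @slot map numeric matrix at image resolution, values in [0, 1].
#' @slot layer character, name of the targeted stage.
#' @slot targetClass character.
#' @export
setClass("Heatmap", representation(
  alphaWeights = "numeric",
  raw = "matrix",
  map = "matrix",
  layer = "character",
  targetClass = "character"
))

setValidity("Heatmap", function(object) {
  msg <- character()
  if (any(object@raw < 0)) msg <- c(msg, "raw map must be non-negative")
  if (any(object@map < -1e-9) || any(object@map > 1 + 1e-9))
    msg <- c(msg, "upsampled map must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

# ---- SplitPlan -------------------------------------------------------------

#' Train/validation/test split plan
#'
#' Row-level partition assignments.  `assignments` has one row per
#' manifest row with columns `id`, `label`, `dataset`, `partition`
#' (train/test) and `fold` (validation fold index within the training
#' partition; validating on one of `folds` folds gives the 4:1
#' train:validation ratio when `folds = 5`).
#'
#' @slot assignments data.frame.
#' @slot scenario character.
#' @slot folds integer.
#' @slot seed integer.
#' @export
setClass("SplitPlan", representation(
  assignments = "data.frame",
  scenario = "character",
  folds = "integer",
  seed = "integer"
))

# ---- Generics and accessors ------------------------------------------------

#' @rdname PhantomImage-class
#' @param object,x an object.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname PhantomImage-class
#' @export
setMethod("pixels", "PhantomImage", function(x) x@pixels)

#' @rdname PhantomImage-class
#' @export
setGeneric("imageLabel", function(x) standardGeneric("imageLabel"))
#' @rdname PhantomImage-class
#' @export
setMethod("imageLabel", "PhantomImage", function(x) x@label)

#' @rdname PhantomImage-class
#' @export
setGeneric("signatureBbox", function(x) standardGeneric("signatureBbox"))
#' @rdname PhantomImage-class
#' @export
setMethod("signatureBbox", "PhantomImage", function(x)
  if (length(x@signatureBbox)) x@signatureBbox else NULL)

#' @rdname PhantomImage-class
#' @export
setGeneric("lungMask", function(x) standardGeneric("lungMask"))
#' @rdname PhantomImage-class
#' @export
setMethod("lungMask", "PhantomImage", function(x) x@lungMask)

#' @rdname PhantomImage-class
#' @export
setGeneric("diaphragmBbox", function(x) standardGeneric("diaphragmBbox"))
#' @rdname PhantomImage-class
#' @export
setMethod("diaphragmBbox", "PhantomImage", function(x) x@diaphragmBbox)

#' @rdname DiaphragmMask-class
#' @param x a \code{DiaphragmMask}.
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname DiaphragmMask-class
#' @export
setMethod("maskMatrix", "DiaphragmMask", function(x) x@mask)

#' @rdname DiaphragmMask-class
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))
#' @rdname DiaphragmMask-class
#' @export
setMethod("thresholdUsed", "DiaphragmMask", function(x) x@thresholdUsed)

#' @rdname ChannelStack-class
#' @param x a \code{ChannelStack}.
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @rdname ChannelStack-class
#' @export
setMethod("channels", "ChannelStack", function(x) x@channels)

#' @rdname ChannelStack-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname ChannelStack-class
#' @export
setMethod("provenance", "ChannelStack", function(x) x@provenance)

#' @rdname AugmentationPlan-class
#' @param x an \code{AugmentationPlan}.
#' @export
setGeneric("plannedCounts", function(x) standardGeneric("plannedCounts"))
#' @rdname AugmentationPlan-class
#' @export
setMethod("plannedCounts", "AugmentationPlan", function(x) x@plan)

#' @rdname AugmentationPlan-class
#' @export
setGeneric("extendedClasses", function(x) standardGeneric("extendedClasses"))
#' @rdname AugmentationPlan-class
#' @export
setMethod("extendedClasses", "AugmentationPlan", function(x)
  names(x@extended)[x@extended])

# ---- show methods ----------------------------------------------------------

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", object@label, sprintf("%dx%d", object@imageSize,
      object@imageSize), "contrast", object@signalContrast,
      "noiseSd", object@noiseSd, "seed", object@seed, "\n")
})

setMethod("show", "PhantomImage", function(object) {
  cat("PhantomImage:", object@label, sprintf("(%d x %d)",
      nrow(object@pixels), ncol(object@pixels)), "\n")
  if (length(object@signatureBbox))
    cat("  signature bbox:", paste(object@signatureBbox, collapse = ", "), "\n")
  cat("  diaphragm bbox:", paste(object@diaphragmBbox, collapse = ", "), "\n")
})

setMethod("show", "DiaphragmMask", function(object) {
  cat(sprintf("DiaphragmMask: threshold %.3f (iMin %.1f, iMax %.1f, coeff %.2f), %d px marked\n",
              object@thresholdUsed, object@iMin, object@iMax, object@coeff,
              sum(object@mask)))
})

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@channels)
  cat(sprintf("ChannelStack: %d x %d x 3 [%s]\n", d[1], d[2],
              paste(object@provenance, collapse = ", ")))
})

setMethod("show", "AugmentationPlan", function(object) {
  cat("AugmentationPlan (reference:", object@reference, "=",
      object@counts[object@reference], ")\n")
  df <- data.frame(original = object@counts,
                   augment = object@plan[names(object@counts)],
                   extended = object@extended[names(object@counts)])
  print(df)
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: accuracy %.4f (n = %d)\n", object@accuracy,
              sum(object@confusion)))
  cat("  macro precision/recall/F1:",
      sprintf("%.4f", object@macro["precision"]),
      sprintf("%.4f", object@macro["recall"]),
      sprintf("%.4f", object@macro["f1"]), "\n")
})

setMethod("show", "Heatmap", function(object) {
  cat(sprintf("Heatmap (%s @ %s): raw %d x %d, map %d x %d\n",
              object@targetClass, object@layer, nrow(object@raw),
              ncol(object@raw), nrow(object@map), ncol(object@map)))
})

setMethod("show", "SplitPlan", function(object) {
  tab <- table(object@assignments$partition)
  cat("SplitPlan scenario", object@scenario, "-",
      paste(names(tab), tab, collapse = ", "),
      sprintf("(%d folds)\n", object@folds))
})
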
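#' @include nn-blocks.R
NULL

.stageWidths <- function(arch, widthDiv) {
  base <- switch(arch,
    resnet50 = list(stem = 64, mid = c(64, 128, 256, 512)),
    resnext50 = list(stem = 64, mid = c(128, 256, 512, 1024)),
    fsrfnet50 = list(stem = 64, mid = c(128, 256, 512, 1024)),
    stop("unknown arch '", arch, "'; use resnet50, resnext50 or fsrfnet50",
         call. = FALSE))
  list(stem = base$stem %/% widthDiv,
       mid = base$mid %/% widthDiv,
       out = c(256, 512, 1024, 2048) %/% widthDiv)
}

#' Model configuration
#'
#' Describes one of the three backbones.  `scale = "full"` is the
#' reference geometry (224 input, stage depths \{3, 4, 6, 3\},
#' cardinality/groups 32, reduction 16); `scale = "tiny"` divides all
#' widths by 8, uses a 64-pixel input, one block per stage, 2 groups and
#' reduction 4, sized so training and property tests run on one CPU.
#' Any field can be overridden explicitly.
#'
#' @param arch `"resnet50"`, `"resnext50"` or `"fsrfnet50"`.
#' @param scale `"full"` or `"tiny"`.
#' @param inputSize input image side in pixels.
#' @param stageDepths integer(4), blocks per stage.
#' @param cardinality groups of the ResNeXt 3x3 convolution (C).
#' @param branches FSRF branch count (M).
#' @param groups FSRF branch convolution groups (G).
#' @param reduction attention reduction ratio (r).
#' @param numClasses output classes (default 5).
#' @param widthDiv divisor applied to all channel widths.
#' @param dropout dropout probability before the classifier head
#'   (default 0).
#' @return A list of class `CxrModelConfig`.
#' @examples
#' modelConfig("fsrfnet50", scale = "tiny")
#' @export
modelConfig <- function(arch = c("resnet50", "resnext50", "fsrfnet50"),
                        scale = c("full", "tiny"),
                        inputSize = NULL, stageDepths = NULL,
                        cardinality = NULL, branches = 2L, groups = NULL,
                        reduction = NULL, numClasses = 5L, widthDiv = NULL,
                        dropout = 0) {
  arch <- match.arg(arch)
  scale <- match.arg(scale)
  full <- scale == "full"
  cfg <- list(
    arch = arch, scale = scale,
    inputSize = as.integer(inputSize %||% if (full) 224L else 64L),
    stageDepths = as.integer(stageDepths %||%
                               if (full) c(3L, 4L, 6L, 3L) else rep(1L, 4)),
    cardinality = as.integer(cardinality %||% if (full) 32L else 2L),
    branches = as.integer(branches),
    groups = as.integer(groups %||% if (full) 32L else 2L),
    reduction = as.integer(reduction %||% if (full) 16L else 4L),
    numClasses = as.integer(numClasses),
    widthDiv = as.integer(widthDiv %||% if (full) 1L else 8L),
    dropout = dropout)
  stopifnot(length(cfg$stageDepths) == 4L, cfg$branches >= 2L)
  w <- .stageWidths(arch, cfg$widthDiv)
  if (any(w$mid %% cfg$reduction != 0) && arch == "fsrfnet50")
    stop("reduction ratio must divide the stage bottleneck widths")
  cfg$widths <- w
  class(cfg) <- "CxrModelConfig"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a classifier network
#'
#' Assembles the configured backbone: a 7x7 stride-2 stem convolution
#' with batch normalisation and ReLU, a 3x3 stride-2 max pool, four
#' stages of the configured block type (ResNet bottleneck, ResNeXt
#' grouped bottleneck, or FSRF attention unit; the first block of stages
#' 2--4 downsamples with stride 2), global average pooling, and a fully
#' connected softmax head over the five classes.
#'
#' @param config a [modelConfig()].
#' @param seed integer seed for weight initialisation.
#' @return A model object of class `CxrModel`.
#' @examples
#' m <- buildModel(modelConfig("resnet50", scale = "tiny"), seed = 1)
#' countParams(m)
#' @export
buildModel <- function(config, seed = 1L) {
  stopifnot(inherits(config, "CxrModelConfig"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  w <- config$widths
  makeBlock <- function(inCh, midCh, outCh, stride) {
    switch(config$arch,
      resnet50 = nnBottleneck(inCh, midCh, outCh, stride, cardinality = 1L),
      resnext50 = nnBottleneck(inCh, midCh, outCh, stride,
                               cardinality = config$cardinality),
      fsrfnet50 = nnFSRFUnit(inCh, midCh, outCh, stride,
                             branches = config$branches,
                             groups = config$groups,
                             reduction = config$reduction))
  }
  stages <- vector("list", 4L)
  inCh <- w$stem
  for (s in 1:4) {
    blocks <- vector("list", config$stageDepths[s])
    for (b in seq_len(config$stageDepths[s])) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      blocks[[b]] <- makeBlock(inCh, w$mid[s], w$out[s], stride)
      inCh <- w$out[s]
    }
    stages[[s]] <- nnSeq(blocks)
  }
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$classes <- cxrClasses()[seq_len(config$numClasses)]
  # the input gradient of the stem convolution is never consumed
  m$stem <- nnSeq(nnConv(3L, w$stem, 7L, stride = 2L, pad = 3L,
                         inputGrad = FALSE),
                  nnBN(w$stem), nnReLU())
  m$pool <- nnMaxPool(3L, 2L, 1L)
  m$stages <- stages
  m$gap <- nnGAP()
  m$drop <- nnDropout(config$dropout)
  m$fc <- nnLinear(w$out[4], config$numClasses)
  m$leaves <- function() c(m$stem$leaves(), do.call(c, lapply(m$stages,
                           function(s) s$leaves())), m$fc$leaves())
  m$fwd <- function(x, train = TRUE, keepActs = FALSE) {
    a <- m$pool$fwd(m$stem$fwd(x, train), train)
    acts <- if (keepActs) list() else NULL
    for (s in 1:4) {
      a <- m$stages[[s]]$fwd(a, train)
      if (keepActs) acts[[paste0("conv", s + 1L)]] <- a
    }
    if (keepActs) m$acts <- acts
    m$fc$fwd(m$drop$fwd(m$gap$fwd(a, train), train), train)
  }
  m$bwd <- function(dlogits) {
    da <- m$gap$bwd(m$drop$bwd(m$fc$bwd(dlogits)))
    for (s in 4:1) da <- m$stages[[s]]$bwd(da)
    m$stem$bwd(m$pool$bwd(da))
  }
  # backward from the logits down to (and excluding) the output of stage
  # `toStage`; returns the gradient w.r.t. that stage's output
  m$bwdToStage <- function(dlogits, toStage) {
    da <- m$gap$bwd(m$drop$bwd(m$fc$bwd(dlogits)))
    if (toStage < 4L) for (s in 4:(toStage + 1L)) da <- m$stages[[s]]$bwd(da)
    da
  }
  class(m) <- c("CxrModel", "environment")
  m
}

#' Number of trainable parameters
#'
#' @param model a `CxrModel`.
#' @return integer parameter count.
#' @export
countParams <- function(model) {
  sum(vapply(model$leaves(), function(lf)
    sum(vapply(lf$pnames, function(nm) length(lf[[nm]]), 0L)), 0L))
}

#' @export
print.CxrModel <- function(x, ...) {
  cat(sprintf("CxrModel: %s (%s), input %d, %d classes, %d parameters\n",
              x$config$arch, x$config$scale, x$config$inputSize,
              x$config$numClasses, countParams(x)))
  invisible(x)
}

#' Architecture stage summary
#'
#' Shape arithmetic for the configured backbone: for each stage the
#' output spatial size, the block composition, and the block count.
#' Computed analytically from the configuration (no weights are
#' allocated), so it also describes the full-scale geometry cheaply.
#'
#' @param config a [modelConfig()].
#' @return data.frame with columns stage, output, blocks, n.
#' @examples
#' modelSummary(modelConfig("fsrfnet50"))
#' @export
modelSummary <- function(config) {
  stopifnot(inherits(config, "CxrModelConfig"))
  w <- config$widths
  s0 <- config$inputSize
  conv1 <- ceiling(s0 / 2)
  pool <- ceiling(conv1 / 2)
  sizes <- c(pool, ceiling(pool / 2), ceiling(pool / 4), ceiling(pool / 8))
  blockTxt <- function(s) switch(config$arch,
    resnet50 = sprintf("1x1,%d | 3x3,%d | 1x1,%d", w$mid[s], w$mid[s], w$out[s]),
    resnext50 = sprintf("1x1,%d | 3x3,%d,C=%d | 1x1,%d", w$mid[s], w$mid[s],
                        config$cardinality, w$out[s]),
    fsrfnet50 = sprintf("1x1,%d | FSRF M=%d,G=%d,r=%d | 1x1,%d", w$mid[s],
                        config$branches, config$groups, config$reduction,
                        w$out[s]))
  rbind(
    data.frame(stage = "conv1", output = sprintf("%dx%d", conv1, conv1),
               blocks = sprintf("7x7,%d, stride 2", w$stem), n = 1L),
    data.frame(stage = "pool", output = sprintf("%dx%d", pool, pool),
               blocks = "3x3 max pool, stride 2", n = 1L),
    data.frame(stage = paste0("conv", 2:5),
               output = sprintf("%dx%d", sizes, sizes),
               blocks = vapply(1:4, blockTxt, ""),
               n = config$stageDepths),
    data.frame(stage = "head", output = "1x1",
               blocks = sprintf("global average pool, %d-d fc, softmax",
                                config$numClasses), n = 1L))
}

#' Classify one preprocessed input
#'
#' Runs the network on a single [ChannelStack-class] and returns the
#' class probabilities (softmax over the 5-class head), the predicted
#' label (highest probability; ties broken by the canonical class order
#' of [cxrClasses()], i.e. the lowest class index wins), and the logits.
#'
#' @param model a `CxrModel`.
#' @param stack a [ChannelStack-class] (spatial size must match the
#'   model's `inputSize`).
#' @return list with elements `label`, `probabilities`, `logits`.
#' @export
predictStack <- function(model, stack) {
  stopifnot(is(stack, "ChannelStack"))
  ch <- channels(stack)
  if (dim(ch)[1] != model$config$inputSize)
    stop("stack spatial size ", dim(ch)[1], " does not match model input ",
         model$config$inputSize, call. = FALSE)
  x <- array(ch, c(dim(ch)[1], dim(ch)[2], 3L, 1L))
  logits <- model$fwd(x, train = FALSE)
  p <- .softmaxProbs(logits)[, 1]
  names(p) <- model$classes
  list(label = model$classes[which.max(p)], probabilities = p,
       logits = logits[, 1])
}

#' Batch class probabilities
#'
#' @param model a `CxrModel`.
#' @param x `(H, W, 3, N)` input array.
#' @param batchSize forward-pass batch size.
#' @return `(numClasses, N)` probability matrix (columns sum to 1).
#' @export
predictProbs <- function(model, x, batchSize = 64L) {
  N <- dim(x)[4]
  K <- model$config$numClasses
  out <- matrix(0, K, N, dimnames = list(model$classes, NULL))
  i <- 1L
  while (i <= N) {
    j <- min(i + batchSize - 1L, N)
    out[, i:j] <- .softmaxProbs(model$fwd(x[, , , i:j, drop = FALSE],
                                          train = FALSE))
    i <- j + 1L
  }
  out
}

#' Save / load model weights
#'
#' Serialises the configuration and all parameter arrays (including
#' batch-normalisation running statistics) to an RDS file, and rebuilds
#' an identical model from such a file.
#'
#' @param model a `CxrModel`.
#' @param path file path.
#' @return `saveModel` returns `path` invisibly; `loadModel` returns a
#'   `CxrModel`.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(config = model$config,
               params = .snapshotParams(model$leaves())), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  m <- buildModel(obj$config, seed = 1L)
  .restoreParams(m$leaves(), obj$params)
  m
}
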
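#' @include cxrnet-package.R
NULL

# The CNN engine.
#
# Modules are environments exposing a uniform interface:
#   $fwd(x, train)  forward pass, caching what backward needs
#   $bwd(dy)        backward pass, returning dx and storing parameter
#                   gradients in g<name> fields
#   $leaves()       flat list of parameter-owning leaf modules
#   $pnames         names of parameter fields on a leaf ("w", "b", ...)
#
# Activation tensors are arrays with dim (H, W, C, N); vector features
# (pooled descriptors, logits) are matrices with dim (C, N).

.newModule <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$pnames <- character()
  e$leaves <- function() list(e)
  class(e) <- c("cxrModule", "environment")
  e
}

# ---- broadcast / reduction helpers ----------------------------------------

# (C, N) channel matrix -> (H, W, C, N) array, constant over space
.bcChannel <- function(v, H, W) {
  d <- dim(v)
  array(rep(as.vector(v), each = H * W), c(H, W, d[1], d[2]))
}

# (H, W, N) spatial map -> (H, W, C, N) array, constant over channels
.bcSpatial <- function(a, C) {
  d <- dim(a)
  aperm(array(a, c(d[1], d[2], d[3], C)), c(1, 2, 4, 3))
}

.spatialSum <- function(x) {
  d <- dim(x)
  matrix(colSums(matrix(x, nrow = d[1] * d[2])), d[3], d[4])
}

.spatialMean <- function(x) .spatialSum(x) / (dim(x)[1] * dim(x)[2])

# reshape (H, W, C, N) -> (H*W*N, C) matrix with channels as columns
.toChannelCols <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}

.fromChannelCols <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

# ---- convolution -----------------------------------------------------------

#' @noRd
nnConv <- function(inCh, outCh, k, stride = 1L, pad = NULL, groups = 1L,
                   bias = FALSE, inputGrad = TRUE) {
  if (is.null(pad)) pad <- k %/% 2L
  if (inCh %% groups != 0L || outCh %% groups != 0L)
    stop("channels must be divisible by groups")
  e <- .newModule("conv")
  e$stride <- as.integer(stride); e$pad <- as.integer(pad)
  e$groups <- as.integer(groups)
  e$inputGrad <- isTRUE(inputGrad)
  sdw <- sqrt(2 / (k * k * inCh / groups))
  e$w <- array(rnorm(k * k * (inCh / groups) * outCh, 0, sdw),
               c(k, k, inCh / groups, outCh))
  e$pnames <- "w"
  if (bias) { e$b <- numeric(outCh); e$pnames <- c("w", "b") }
  e$fwd <- function(x, train = TRUE) {
    e$x <- x
    .conv2dForward(x, e$w, if (is.null(e$b)) numeric(0) else e$b,
                   e$stride, e$pad, e$groups)
  }
  e$bwd <- function(dy) {
    r <- .conv2dBackward(e$x, e$w, dy, e$stride, e$pad, e$groups, e$inputGrad)
    e$gw <- r$dw
    if (!is.null(e$b)) e$gb <- r$db
    r$dx
  }
  e
}

# ---- batch normalisation ---------------------------------------------------

#' @noRd
nnBN <- function(ch, momentum = 0.1, eps = 1e-5) {
  e <- .newModule("bn")
  e$gamma <- rep(1, ch); e$beta <- rep(0, ch)
  e$rmean <- rep(0, ch); e$rvar <- rep(1, ch)
  e$momentum <- momentum; e$eps <- eps
  e$pnames <- c("gamma", "beta")
  e$fwd <- function(x, train = TRUE) {
    d <- dim(x); m <- d[1] * d[2] * d[4]
    xr <- .toChannelCols(x)
    if (train) {
      mu <- colMeans(xr)
      xc <- xr - rep(mu, each = m)
      v <- colMeans(xc * xc)
      invstd <- 1 / sqrt(v + e$eps)
      xhat <- xc * rep(invstd, each = m)
      e$rmean <- (1 - e$momentum) * e$rmean + e$momentum * mu
      e$rvar <- (1 - e$momentum) * e$rvar + e$momentum * v
    } else {
      invstd <- 1 / sqrt(e$rvar + e$eps)
      xhat <- (xr - rep(e$rmean, each = m)) * rep(invstd, each = m)
    }
    e$xhat <- xhat; e$invstd <- invstd; e$m <- m; e$d <- d; e$train <- train
    y <- xhat * rep(e$gamma, each = m) + rep(e$beta, each = m)
    .fromChannelCols(y, d)
  }
  e$bwd <- function(dy) {
    m <- e$m; d <- e$d
    dyr <- .toChannelCols(dy)
    e$ggamma <- colSums(dyr * e$xhat)
    e$gbeta <- colSums(dyr)
    dxhat <- dyr * rep(e$gamma, each = m)
    if (e$train) {
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * e$xhat)
      dxr <- (dxhat - rep(s1 / m, each = m) -
                e$xhat * rep(s2 / m, each = m)) * rep(e$invstd, each = m)
    } else {
      dxr <- dxhat * rep(e$invstd, each = m)
    }
    .fromChannelCols(dxr, d)
  }
  e
}

# ---- simple layers ---------------------------------------------------------

#' @noRd
nnReLU <- function() {
  e <- .newModule("relu")
  e$fwd <- function(x, train = TRUE) { e$mask <- x > 0; x * e$mask }
  e$bwd <- function(dy) dy * e$mask
  e
}

#' @noRd
nnMaxPool <- function(k = 3L, stride = 2L, pad = 1L) {
  e <- .newModule("maxpool")
  e$fwd <- function(x, train = TRUE) {
    r <- .maxPoolForward(x, as.integer(k), as.integer(stride), as.integer(pad))
    e$idx <- r$idx; e$xdim <- dim(x)
    r$y
  }
  e$bwd <- function(dy) .maxPoolBackward(e$idx, dy, as.integer(e$xdim))
  e
}

#' @noRd
nnGAP <- function() {
  e <- .newModule("gap")
  e$fwd <- function(x, train = TRUE) { e$d <- dim(x); .spatialMean(x) }
  e$bwd <- function(dy) {
    d <- e$d
    .bcChannel(dy, d[1], d[2]) / (d[1] * d[2])
  }
  e
}

#' @noRd
nnLinear <- function(inF, outF, initSd = NULL) {
  e <- .newModule("linear")
  if (is.null(initSd)) initSd <- sqrt(2 / inF)
  e$w <- matrix(rnorm(outF * inF, 0, initSd), outF, inF)
  e$b <- numeric(outF)
  e$pnames <- c("w", "b")
  e$fwd <- function(x, train = TRUE) { e$x <- x; e$w %*% x + e$b }
  e$bwd <- function(dy) {
    e$gw <- dy %*% t(e$x)
    e$gb <- rowSums(dy)
    t(e$w) %*% dy
  }
  e
}

#' @noRd
nnDropout <- function(p) {
  e <- .newModule("dropout")
  e$p <- p
  e$fwd <- function(x, train = TRUE) {
    if (!train || e$p <= 0) { e$mask <- NULL; return(x) }
    e$mask <- (array(runif(length(x)), dim(x)) >= e$p) / (1 - e$p)
    x * e$mask
  }
  e$bwd <- function(dy) if (is.null(e$mask)) dy else dy * e$mask
  e
}

#' @noRd
nnSeq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) && !is.environment(mods[[1]]))
    mods <- mods[[1]]
  e <- .newModule("seq")
  e$mods <- mods
  e$fwd <- function(x, train = TRUE) {
    for (m in e$mods) x <- m$fwd(x, train)
    x
  }
  e$bwd <- function(dy) {
    for (m in rev(e$mods)) dy <- m$bwd(dy)
    dy
  }
  e$leaves <- function() do.call(c, lapply(e$mods, function(m) m$leaves()))
  e
}

# ---- loss ------------------------------------------------------------------

# softmax cross-entropy; logits (K, N), y integer class indices in 1..K
.softmaxCrossEntropy <- function(logits, y) {
  K <- nrow(logits); N <- ncol(logits)
  z <- logits - rep(apply(logits, 2, max), each = K)
  ez <- exp(z)
  p <- ez / rep(colSums(ez), each = K)
  idx <- y + K * (seq_len(N) - 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = p, dlogits = dlogits / N)
}

.softmaxProbs <- function(logits) {
  K <- nrow(logits)
  z <- logits - rep(apply(logits, 2, max), each = K)
  ez <- exp(z)
  ez / rep(colSums(ez), each = K)
}

# ---- Adam ------------------------------------------------------------------

# One Adam update over all leaf parameters.  Weight decay is applied as
# L2 regularisation added to the gradient (classic Adam + weight decay).
.adamStep <- function(leaves, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weightDecay = 0) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (lf in leaves) {
    for (nm in lf$pnames) {
      g <- lf[[paste0("g", nm)]]
      if (is.null(g)) next
      if (weightDecay > 0) g <- g + weightDecay * lf[[nm]]
      mkey <- paste0(".am_", nm); vkey <- paste0(".av_", nm)
      m <- lf[[mkey]]; v <- lf[[vkey]]
      if (is.null(m)) { m <- g * 0; v <- g * 0 }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      lf[[mkey]] <- m; lf[[vkey]] <- v
      lf[[nm]] <- lf[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  invisible(NULL)
}

.snapshotParams <- function(leaves) {
  lapply(leaves, function(lf) {
    s <- lapply(lf$pnames, function(nm) lf[[nm]])
    names(s) <- lf$pnames
    if (identical(lf$kind, "bn")) { s$rmean <- lf$rmean; s$rvar <- lf$rvar }
    s
  })
}

.restoreParams <- function(leaves, snap) {
  for (i in seq_along(leaves)) {
    for (nm in names(snap[[i]])) leaves[[i]][[nm]] <- snap[[i]][[nm]]
  }
  invisible(NULL)
}
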
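#' @include nn-layers.R
NULL

# ---- average-max channel attention (AMC) ----------------------------------

#' Average-max channel attention module
#'
#' Captures inter-channel dependencies: the input feature map is pooled
#' over space by both average and max pooling, each descriptor is passed
#' through a shared two-layer bottleneck MLP (hidden width
#' `channels / reduction`), the two outputs are summed and squashed with
#' a sigmoid, yielding one gate in (0, 1) per channel.
#'
#' The returned module exposes `$fwd(x)` taking an `(H, W, C, N)` array
#' and returning a `(C, N)` gate matrix, and `$bwd(dgate)` returning the
#' gradient with respect to the input.
#'
#' @param channels number of input channels.
#' @param reduction bottleneck reduction ratio r (must divide `channels`).
#' @return A module environment.
#' @export
nnAMC <- function(channels, reduction) {
  if (channels %% reduction != 0)
    stop("reduction ratio must divide the channel count")
  hid <- channels %/% reduction
  e <- .newModule("amc")
  e$W1 <- matrix(rnorm(hid * channels, 0, sqrt(2 / channels)), hid, channels)
  e$b1 <- numeric(hid)
  e$W2 <- matrix(rnorm(channels * hid, 0, sqrt(2 / hid)), channels, hid)
  e$b2 <- numeric(channels)
  e$pnames <- c("W1", "b1", "W2", "b2")
  e$fwd <- function(x, train = TRUE) {
    d <- dim(x); HW <- d[1] * d[2]
    e$d <- d
    za <- .spatialMean(x)                       # (C, N)
    mm <- .colMaxIdx(matrix(x, nrow = HW))      # columns indexed (c, n)
    zm <- matrix(mm$max, d[3], d[4])
    e$maxIdx <- mm$idx
    mlp <- function(z) {
      a1 <- e$W1 %*% z + e$b1
      h <- a1 * (a1 > 0)
      list(h = h, mask = a1 > 0, out = e$W2 %*% h + e$b2)
    }
    fa <- mlp(za); fm <- mlp(zm)
    e$za <- za; e$zm <- zm; e$fa <- fa; e$fm <- fm
    s <- fa$out + fm$out
    e$gate <- 1 / (1 + exp(-s))
    e$gate
  }
  e$bwd <- function(dgate) {
    d <- e$d; HW <- d[1] * d[2]
    ds <- dgate * e$gate * (1 - e$gate)
    back <- function(f, z) {
      dh <- (t(e$W2) %*% ds) * f$mask
      list(gW2 = ds %*% t(f$h), gb2 = rowSums(ds),
           gW1 = dh %*% t(z), gb1 = rowSums(dh),
           dz = t(e$W1) %*% dh)
    }
    ba <- back(e$fa, e$za); bm <- back(e$fm, e$zm)
    e$gW1 <- ba$gW1 + bm$gW1; e$gb1 <- ba$gb1 + bm$gb1
    e$gW2 <- ba$gW2 + bm$gW2; e$gb2 <- ba$gb2 + bm$gb2
    dx <- .bcChannel(ba$dz, d[1], d[2]) / HW
    # scatter max-pool branch gradient to the argmax positions
    cn <- d[3] * d[4]
    lin <- e$maxIdx + HW * (seq_len(cn) - 1L)
    dx[lin] <- dx[lin] + as.vector(bm$dz)
    dx
  }
  e
}

# ---- average-max spatial attention (AMS) ----------------------------------

#' Average-max spatial attention module
#'
#' Captures inter-spatial relationships: channel-wise average and max
#' maps are concatenated into a 2-channel map, convolved with a single
#' `kernel x kernel` filter, and squashed with a sigmoid, yielding one
#' gate in (0, 1) per spatial location.
#'
#' `$fwd(x)` takes an `(H, W, C, N)` array and returns an `(H, W, N)`
#' gate array; `$bwd(dgate)` returns the input gradient.
#'
#' @param kernel convolution kernel size (default 7).
#' @return A module environment.
#' @export
nnAMS <- function(kernel = 7L) {
  e <- .newModule("ams")
  e$w <- array(rnorm(kernel * kernel * 2, 0, sqrt(2 / (kernel * kernel * 2))),
               c(kernel, kernel, 2L, 1L))
  e$b <- numeric(1)
  e$pnames <- c("w", "b")
  pad <- as.integer(kernel) %/% 2L
  e$fwd <- function(x, train = TRUE) {
    d <- dim(x); C <- d[3]
    e$d <- d
    avg <- array(0, c(d[1], d[2], d[4]))
    for (c in seq_len(C)) {
      xs <- x[, , c, , drop = FALSE]
      dim(xs) <- c(d[1], d[2], d[4])
      avg <- avg + xs
    }
    avg <- avg / C
    mm <- .colMaxIdx(matrix(aperm(x, c(3, 1, 2, 4)), nrow = C))
    mx <- array(mm$max, c(d[1], d[2], d[4]))
    e$chIdx <- mm$idx
    stack <- array(0, c(d[1], d[2], 2L, d[4]))
    stack[, , 1, ] <- avg
    stack[, , 2, ] <- mx
    e$stack <- stack
    s <- .conv2dForward(stack, e$w, e$b, 1L, pad, 1L)   # (H, W, 1, N)
    g <- 1 / (1 + exp(-s))
    e$gate <- array(g, c(d[1], d[2], d[4]))
    e$gate
  }
  e$bwd <- function(dgate) {
    d <- e$d; C <- d[3]
    ds <- array(dgate * e$gate * (1 - e$gate), c(d[1], d[2], 1L, d[4]))
    r <- .conv2dBackward(e$stack, e$w, ds, 1L, pad, 1L)
    e$gw <- r$dw; e$gb <- r$db
    dstack <- r$dx
    davg <- dstack[, , 1, , drop = FALSE]
    dim(davg) <- c(d[1], d[2], d[4])
    dmx <- dstack[, , 2, , drop = FALSE]
    dim(dmx) <- c(d[1], d[2], d[4])
    dxp <- matrix(0, C, d[1] * d[2] * d[4])       # (C, h*w*n) layout
    dxp[e$chIdx + C * (seq_len(ncol(dxp)) - 1L)] <- as.vector(dmx)
    dx <- aperm(array(dxp, c(C, d[1], d[2], d[4])), c(2, 3, 1, 4))
    dx + .bcSpatial(array(davg, c(d[1], d[2], d[4])), C) / C
  }
  e
}

# ---- residual bottleneck (ResNet / ResNeXt) --------------------------------

#' Residual bottleneck block
#'
#' The classic bottleneck residual unit H(x) = activation(F(x) + x):
#' 1x1 reduce, 3x3 convolution (grouped when `cardinality > 1`, giving
#' the ResNeXt aggregated-transform variant), 1x1 expand, each followed
#' by batch normalisation, with a ReLU after the addition.  When the
#' channel counts or stride differ, the shortcut is a strided 1x1
#' projection; otherwise it is the identity.
#'
#' @param inCh,midCh,outCh input, bottleneck and output channel counts.
#' @param stride spatial stride of the 3x3 convolution.
#' @param cardinality number of groups of the 3x3 convolution (1 for
#'   ResNet, C for ResNeXt).
#' @return A module environment (`$fwd`, `$bwd`, `$leaves`).
#' @export
nnBottleneck <- function(inCh, midCh, outCh, stride = 1L, cardinality = 1L) {
  e <- .newModule("bottleneck")
  e$main <- nnSeq(
    nnConv(inCh, midCh, 1L), nnBN(midCh), nnReLU(),
    nnConv(midCh, midCh, 3L, stride = stride, groups = cardinality),
    nnBN(midCh), nnReLU(),
    nnConv(midCh, outCh, 1L), nnBN(outCh))
  e$proj <- if (inCh != outCh || stride != 1L)
    nnSeq(nnConv(inCh, outCh, 1L, stride = stride, pad = 0L), nnBN(outCh))
  else NULL
  e$relu <- nnReLU()
  e$fwd <- function(x, train = TRUE) {
    f <- e$main$fwd(x, train)
    s <- if (is.null(e$proj)) x else e$proj$fwd(x, train)
    e$relu$fwd(f + s, train)
  }
  e$bwd <- function(dy) {
    dz <- e$relu$bwd(dy)
    dx <- e$main$bwd(dz)
    dx + if (is.null(e$proj)) dz else e$proj$bwd(dz)
  }
  e$leaves <- function() c(e$main$leaves(),
                           if (!is.null(e$proj)) e$proj$leaves() else list())
  e
}

# ---- feature-selective / spatial receptive field (FSRF) core ---------------

#' FSRF block core: multi-branch convolution with attention-gated fusion
#'
#' `M` parallel grouped convolutions with distinct kernel sizes (3x3 and
#' 5x5 for M = 2, growing by +2 per extra branch) produce branch feature
#' maps.  Their sum drives the channel ([nnAMC()]) and spatial
#' ([nnAMS()]) attention gates.  Each branch's gated descriptor (global
#' average of the branch map modulated by both gates) is passed through a
#' shared bottleneck MLP, and a softmax across the M branches per channel
#' yields selection weights that sum to 1 everywhere they apply; the
#' output is the weight-combined sum of the branch maps.  Because the
#' selection MLP is shared across branches, identical branch features
#' receive exactly 1/M each.
#'
#' @param channels channel count (input = output).
#' @param branches number of parallel branches M (>= 2).
#' @param groups groups G of each branch convolution.
#' @param reduction reduction ratio r of the attention bottlenecks.
#' @param stride spatial stride of the branch convolutions.
#' @param kernels kernel sizes, one per branch (default 3, 5, 7, ...).
#' @return A module environment.
#' @export
nnFSRFCore <- function(channels, branches = 2L, groups = 1L, reduction = 4L,
                       stride = 1L, kernels = NULL) {
  if (branches < 2L) stop("FSRF requires at least 2 branches")
  if (is.null(kernels)) kernels <- seq(3L, by = 2L, length.out = branches)
  if (length(kernels) < branches)
    stop("kernel list shorter than the number of branches")
  if (channels %% reduction != 0)
    stop("reduction ratio must divide the channel count")
  hid <- channels %/% reduction
  e <- .newModule("fsrf_core")
  e$M <- as.integer(branches)
  e$branchMods <- lapply(seq_len(branches), function(m)
    nnSeq(nnConv(channels, channels, kernels[m], stride = stride,
                 groups = groups),
          nnBN(channels), nnReLU()))
  e$amc <- nnAMC(channels, reduction)
  e$ams <- nnAMS()
  e$V1 <- matrix(rnorm(hid * channels, 0, sqrt(2 / channels)), hid, channels)
  e$c1 <- numeric(hid)
  e$V2 <- matrix(rnorm(channels * hid, 0, sqrt(2 / hid)), channels, hid)
  e$c2 <- numeric(channels)
  e$pnames <- c("V1", "c1", "V2", "c2")

  e$fwd <- function(x, train = TRUE) {
    M <- e$M
    B <- lapply(e$branchMods, function(m) m$fwd(x, train))
    U <- Reduce(`+`, B)
    d <- dim(U); HW <- d[1] * d[2]
    ac <- e$amc$fwd(U, train)               # (C, N)
    as_ <- e$ams$fwd(U, train)              # (H, W, N)
    gate <- .bcChannel(ac, d[1], d[2]) * .bcSpatial(as_, d[3])
    Z <- vector("list", M); Hh <- vector("list", M); Eo <- vector("list", M)
    for (m in seq_len(M)) {
      Z[[m]] <- .spatialSum(B[[m]] * gate) / HW
      a1 <- e$V1 %*% Z[[m]] + e$c1
      Hh[[m]] <- list(h = a1 * (a1 > 0), mask = a1 > 0)
      Eo[[m]] <- e$V2 %*% Hh[[m]]$h + e$c2
    }
    # softmax across branches, per channel and sample
    mx <- Reduce(pmax, Eo)
    ex <- lapply(Eo, function(o) exp(o - mx))
    tot <- Reduce(`+`, ex)
    Wt <- lapply(ex, function(z) z / tot)
    V <- array(0, d)
    for (m in seq_len(M)) V <- V + .bcChannel(Wt[[m]], d[1], d[2]) * B[[m]]
    e$B <- B; e$d <- d; e$gate <- gate; e$ac <- ac; e$as_ <- as_
    e$Z <- Z; e$Hh <- Hh; e$Wt <- Wt
    V
  }

  e$bwd <- function(dV) {
    M <- e$M; d <- e$d; HW <- d[1] * d[2]
    dB <- vector("list", M)
    dWt <- vector("list", M)
    for (m in seq_len(M)) {
      dWt[[m]] <- .spatialSum(dV * e$B[[m]])
      dB[[m]] <- .bcChannel(e$Wt[[m]], d[1], d[2]) * dV
    }
    # softmax backward
    dot <- Reduce(`+`, Map(function(w, dw) w * dw, e$Wt, dWt))
    e$gV1 <- 0; e$gc1 <- 0; e$gV2 <- 0; e$gc2 <- 0
    dgate <- array(0, d)
    for (m in seq_len(M)) {
      dE <- e$Wt[[m]] * (dWt[[m]] - dot)
      dh <- (t(e$V2) %*% dE) * e$Hh[[m]]$mask
      e$gV2 <- e$gV2 + dE %*% t(e$Hh[[m]]$h)
      e$gc2 <- e$gc2 + rowSums(dE)
      e$gV1 <- e$gV1 + dh %*% t(e$Z[[m]])
      e$gc1 <- e$gc1 + rowSums(dh)
      dZ <- t(e$V1) %*% dh
      dG <- .bcChannel(dZ, d[1], d[2]) / HW
      dB[[m]] <- dB[[m]] + dG * e$gate
      dgate <- dgate + dG * e$B[[m]]
    }
    dac <- .spatialSum(dgate * .bcSpatial(e$as_, d[3]))
    das <- array(0, c(d[1], d[2], d[4]))
    acFull <- .bcChannel(e$ac, d[1], d[2])
    tmp <- dgate * acFull
    for (c in seq_len(d[3])) {
      ts <- tmp[, , c, , drop = FALSE]
      dim(ts) <- c(d[1], d[2], d[4])
      das <- das + ts
    }
    dU <- e$amc$bwd(dac) + e$ams$bwd(das)
    dx <- 0
    for (m in seq_len(M)) dx <- dx + e$branchMods[[m]]$bwd(dB[[m]] + dU)
    dx
  }

  e$leaves <- function() c(
    do.call(c, lapply(e$branchMods, function(m) m$leaves())),
    e$amc$leaves(), e$ams$leaves(), list(e))
  e
}

#' FSRF unit (bottleneck residual unit with an FSRF core)
#'
#' 1x1 reduce convolution, the FSRF multi-branch attention core
#' ([nnFSRFCore()]), and a 1x1 expand convolution, wrapped in a residual
#' shortcut exactly like [nnBottleneck()].
#'
#' @inheritParams nnBottleneck
#' @param branches,groups,reduction FSRF core hyperparameters (M, G, r).
#' @return A module environment.
#' @export
nnFSRFUnit <- function(inCh, midCh, outCh, stride = 1L, branches = 2L,
                       groups = 1L, reduction = 4L) {
  e <- .newModule("fsrf_unit")
  e$main <- nnSeq(
    nnConv(inCh, midCh, 1L), nnBN(midCh), nnReLU(),
    nnFSRFCore(midCh, branches = branches, groups = groups,
               reduction = reduction, stride = stride),
    nnConv(midCh, outCh, 1L), nnBN(outCh))
  e$proj <- if (inCh != outCh || stride != 1L)
    nnSeq(nnConv(inCh, outCh, 1L, stride = stride, pad = 0L), nnBN(outCh))
  else NULL
  e$relu <- nnReLU()
  e$fwd <- function(x, train = TRUE) {
    f <- e$main$fwd(x, train)
    s <- if (is.null(e$proj)) x else e$proj$fwd(x, train)
    e$relu$fwd(f + s, train)
  }
  e$bwd <- function(dy) {
    dz <- e$relu$bwd(dy)
    dx <- e$main$bwd(dz)
    dx + if (is.null(e$proj)) dz else e$proj$bwd(dz)
  }
  e$leaves <- function() c(e$main$leaves(),
                           if (!is.null(e$proj)) e$proj$leaves() else list())
  e
}
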
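# Independent reference implementations used as oracles, plus shared
# fixtures.  Everything here is deliberately naive and written without
# reference to the package's computational paths.

# direct 6-loop convolution
naiveConv2d <- function(x, w, b, stride, pad, groups) {
  d <- dim(x)
  kh <- dim(w)[1]; kw <- dim(w)[2]; cing <- dim(w)[3]; Cout <- dim(w)[4]
  coutg <- Cout / groups
  Ho <- (d[1] + 2 * pad - kh) %/% stride + 1
  Wo <- (d[2] + 2 * pad - kw) %/% stride + 1
  y <- array(0, c(Ho, Wo, Cout, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(Cout)) {
    g <- (co - 1) %/% coutg
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- if (length(b)) b[co] else 0
      for (ci in seq_len(cing)) for (dh in seq_len(kh)) for (dw in seq_len(kw)) {
        h <- (ho - 1) * stride - pad + dh
        wc <- (wo - 1) * stride - pad + dw
        if (h >= 1 && h <= d[1] && wc >= 1 && wc <= d[2])
          acc <- acc + x[h, wc, g * cing + ci, n] * w[dh, dw, ci, co]
      }
      y[ho, wo, co, n] <- acc
    }
  }
  y
}

# classic histogram equalisation by CDF remapping (min-normalised form),
# on the 0-255 integer scale
naiveEqualize <- function(pixels) {
  x <- round(pixels)
  h <- tabulate(x + 1L, 256L)
  cdf <- cumsum(h) / sum(h)
  cdfMin <- min(cdf[cdf > 0])
  map <- (cdf - cdfMin) / (1 - cdfMin) * 255
  matrix(map[x + 1L], nrow(pixels), ncol(pixels))
}

# brute-force counting metrics for a multi-class problem
naiveCountMetrics <- function(yTrue, yPred, classes) {
  K <- length(classes)
  conf <- matrix(0L, K, K)
  for (i in seq_along(yTrue))
    conf[yTrue[i], yPred[i]] <- conf[yTrue[i], yPred[i]] + 1L
  prec <- rec <- numeric(K)
  for (k in seq_len(K)) {
    tp <- conf[k, k]
    prec[k] <- if (sum(conf[, k]) > 0) tp / sum(conf[, k]) else NA_real_
    rec[k] <- if (sum(conf[k, ]) > 0) tp / sum(conf[k, ]) else NA_real_
  }
  list(confusion = conf, accuracy = sum(diag(conf)) / length(yTrue),
       precision = prec, recall = rec)
}

# rank-based (Mann-Whitney) AUC, ties handled by midranks
naiveAuc <- function(positive, scores) {
  r <- rank(scores)
  nPos <- sum(positive)
  nNeg <- sum(!positive)
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# sigmoid for attention oracles
sigm <- function(x) 1 / (1 + exp(-x))

# mean intensity difference between the signature bbox and the surrounding
# background ring.  The ring excludes the diaphragm band and its dome
# transition, and for lesions interior to a lung field (effusion,
# pneumonia) it is restricted to the lung, since that darker tissue is
# the lesion's actual background.
bboxRingDiff <- function(ph, dilateFrac = 0.04) {
  bb <- signatureBbox(ph)
  px <- pixels(ph)
  s <- nrow(px)
  d <- round(dilateFrac * s)
  rampTop <- diaphragmBbox(ph)[1] - round(0.04 * s) - 1L
  rs <- max(1, bb[1] - d):min(rampTop, bb[3] + d)
  cs <- max(1, bb[2] - d):min(s, bb[4] + d)
  ring <- matrix(FALSE, s, s); ring[rs, cs] <- TRUE
  inm <- matrix(FALSE, s, s); inm[bb[1]:bb[3], bb[2]:bb[4]] <- TRUE
  ring <- ring & !inm
  # the pneumothorax crescent sits on the lung boundary, so its background
  # legitimately includes the adjacent chest wall; keep the full ring there
  if (imageLabel(ph) %in% c("Effusion", "Pneumonia")) {
    ringLung <- ring & lungMask(ph)
    if (sum(ringLung) >= 30) ring <- ringLung
  }
  mean(px[inm]) - mean(px[ring])
}

# ---- shared scaled-down training fixture -----------------------------------
# One seeded scaled-down experiment shared by the learning, Grad-CAM and
# end-to-end tests: 200 training + 50 held-out phantoms per class at 64 px,
# one augmented copy per training image, tiny FSRF backbone.  Cached so the
# suite trains exactly once.

.fixtureEnv <- new.env()

tinyPhantomData <- function() {
  if (!is.null(.fixtureEnv$data)) return(.fixtureEnv$data)
  dir <- file.path(tempdir(), "cxrnet-fixture-phantoms")
  mf <- generatePhantomDataset(stats::setNames(rep(250, 5), cxrClasses()),
                               seed = 11, outDir = dir, imageSize = 64)
  d <- stacksFromManifest(mf, size = 64, closingRadius = 3)
  set.seed(401)
  tr <- unlist(lapply(split(seq_along(d$y), d$y), function(ii) ii[1:200]))
  hold <- setdiff(seq_along(d$y), tr)
  .fixtureEnv$data <- list(manifest = mf, x = d$x, y = d$y, train = tr,
                           holdout = hold, dir = dir)
  .fixtureEnv$data
}

# training inputs: originals plus two augmented copies each (flips/
# rotation/shift/crop from the default policy), mirroring the study's
# augmentation protocol
tinyTrainTensors <- function(mode = "preprocessed") {
  key <- paste0("tensors_", mode)
  if (!is.null(.fixtureEnv[[key]])) return(.fixtureEnv[[key]])
  d <- tinyPhantomData()
  tr <- d$train
  n <- length(tr)
  if (mode == "preprocessed") {
    xtr <- d$x[, , , tr, drop = FALSE]
    xhold <- d$x[, , , d$holdout, drop = FALSE]
  } else {
    dd <- stacksFromManifest(d$manifest, size = 64, mode = "raw-replicate")
    xtr <- dd$x[, , , tr, drop = FALSE]
    xhold <- dd$x[, , , d$holdout, drop = FALSE]
  }
  pol <- augmentPolicy()
  X <- array(0, c(64, 64, 3, 3L * n))
  X[, , , seq_len(n)] <- xtr
  set.seed(99)
  for (i in seq_len(2L * n)) {
    src <- d$manifest$path[tr[((i - 1L) %% n) + 1L]]
    img <- randomAugment(readGrayImage(src), pol)
    X[, , , n + i] <- channels(buildChannelStack(img, size = 64,
                                                 closingRadius = 3,
                                                 mode = mode))
  }
  out <- list(x = X, y = rep(d$y[tr], 3), xHold = xhold,
              yHold = d$y[d$holdout])
  .fixtureEnv[[key]] <- out
  out
}

trainedTinyModel <- function(mode = "preprocessed") {
  key <- paste0("model_", mode)
  if (!is.null(.fixtureEnv[[key]])) return(.fixtureEnv[[key]])
  tt <- tinyTrainTensors(mode)
  m <- buildModel(modelConfig("fsrfnet50", scale = "tiny"), seed = 5)
  fit <- trainModel(m, tt$x, tt$y, tt$xHold, tt$yHold,
                    config = trainConfig(epochs = 5, seed = 3,
                                         weightDecay = 0.005))
  pv <- predictProbs(fit$model, tt$xHold)
  acc <- mean(apply(pv, 2, which.max) == tt$yHold)
  out <- list(model = fit$model, history = fit$history, holdoutAcc = acc)
  .fixtureEnv[[key]] <- out
  out
}

# a very small model/config for fast mechanical tests (not for learning)
microConfig <- function(arch = "fsrfnet50") {
  modelConfig(arch, scale = "tiny", inputSize = 32L)
}
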
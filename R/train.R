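#' @include nn-network.R
NULL

#' Training configuration
#'
#' Defaults follow the study protocol: batch size 32, up to 100 epochs,
#' Adam with learning rate 0.001 and weight decay 0.001, cross-entropy
#' loss, early stopping on validation loss with patience 10 (best
#' weights restored), fivefold cross-validation.
#'
#' @param batchSize mini-batch size (>= 1).
#' @param epochs maximum epochs.
#' @param learningRate Adam learning rate.
#' @param weightDecay L2 weight decay added to gradients.
#' @param patience early-stopping patience in epochs (on validation
#'   loss); `Inf` disables early stopping.
#' @param seed RNG seed for batch shuffling.
#' @param folds cross-validation folds (>= 2).
#' @return list of class `CxrTrainConfig`.
#' @export
trainConfig <- function(batchSize = 32L, epochs = 100L, learningRate = 0.001,
                        weightDecay = 0.001, patience = 10L, seed = 1L,
                        folds = 5L) {
  stopifnot(batchSize >= 1L, folds >= 2L)
  structure(list(batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 learningRate = learningRate, weightDecay = weightDecay,
                 patience = patience, seed = as.integer(seed),
                 folds = as.integer(folds)),
            class = "CxrTrainConfig")
}

.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Build a train/validation/test split plan
#'
#' Two evaluation scenarios are supported.  In scenario 1 one dataset is
#' used entirely for training (and validation) and a second dataset
#' entirely for testing.  In scenario 2 (also used for a single dataset)
#' the rows are split into stratified 80% train / 20% test.  Within the
#' training partition, rows are assigned to `folds` stratified
#' cross-validation folds; holding out one of five folds as the
#' validation set realises the 4:1 train:validation ratio.  Augmented
#' data must only ever be generated from the training partition (see
#' [executePlan()]).
#'
#' @param manifest data.frame with columns `path`, `label` (the training
#'   dataset in scenario 1, everything otherwise).
#' @param scenario `"1"` or `"2"`.
#' @param seed integer seed.
#' @param testManifest second dataset (required for scenario 1).
#' @param folds number of validation folds (default 5).
#' @param testFraction held-out fraction for scenario 2 (default 0.2).
#' @return A [SplitPlan-class].
#' @export
makeSplit <- function(manifest, scenario = c("2", "1"), seed = 1L,
                      testManifest = NULL, folds = 5L, testFraction = 0.2) {
  scenario <- match.arg(scenario)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  if (scenario == "1") {
    if (is.null(testManifest))
      stop("scenario 1 requires two dataset manifests", call. = FALSE)
    asg <- rbind(
      data.frame(path = manifest$path, label = manifest$label,
                 dataset = "A", partition = "train",
                 stringsAsFactors = FALSE),
      data.frame(path = testManifest$path, label = testManifest$label,
                 dataset = "B", partition = "test",
                 stringsAsFactors = FALSE))
  } else {
    y <- manifest$label
    part <- rep("train", nrow(manifest))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      nTest <- round(length(idx) * testFraction)
      part[sample(idx, nTest)] <- "test"
    }
    asg <- data.frame(path = manifest$path, label = manifest$label,
                      dataset = "combined", partition = part,
                      stringsAsFactors = FALSE)
  }
  asg$fold <- NA_integer_
  tr <- asg$partition == "train"
  asg$fold[tr] <- .stratifiedFolds(asg$label[tr], folds)
  for (p in c("train", "test")) {
    missing <- setdiff(unique(asg$label), unique(asg$label[asg$partition == p]))
    if (length(missing))
      warning("classes missing from ", p, " partition: ",
              paste(missing, collapse = ", "))
  }
  asg$id <- seq_len(nrow(asg))
  new("SplitPlan", assignments = asg, scenario = scenario,
      folds = as.integer(folds), seed = as.integer(seed))
}

#' Load manifest images as a model input tensor
#'
#' Reads every image, resizes to `size`, builds the three-channel stack
#' ([buildChannelStack()]) and returns the `(size, size, 3, N)` array
#' together with the integer-coded labels.
#'
#' @param manifest data.frame with `path`, `label`.
#' @param size model input size.
#' @param mode `"preprocessed"` or `"raw-replicate"` (see
#'   [buildChannelStack()]).
#' @param coeff,closingRadius passed to [buildChannelStack()].
#' @return list with `x` (array) and `y` (integer class indices into
#'   [cxrClasses()]).
#' @export
stacksFromManifest <- function(manifest, size = 224L,
                               mode = c("preprocessed", "raw-replicate"),
                               coeff = 0.9, closingRadius = 7) {
  mode <- match.arg(mode)
  N <- nrow(manifest)
  x <- array(0, c(size, size, 3L, N))
  for (i in seq_len(N)) {
    img <- readGrayImage(manifest$path[i])
    x[, , , i] <- channels(buildChannelStack(img, size = size, coeff = coeff,
                                             closingRadius = closingRadius,
                                             mode = mode))
  }
  y <- match(manifest$label, cxrClasses())
  if (anyNA(y)) stop("manifest contains unknown labels", call. = FALSE)
  list(x = x, y = y)
}

#' Train a model
#'
#' Minimises softmax cross-entropy with Adam (learning rate and weight
#' decay from `config`), shuffling mini-batches each epoch under the
#' configured seed.  After every epoch the validation loss and accuracy
#' are computed; training stops when the validation loss has not
#' improved for `patience` epochs, and the weights of the best
#' validation epoch are restored.  A non-finite training loss aborts
#' with diagnostics.
#'
#' @param model a `CxrModel` (modified in place).
#' @param x `(H, W, 3, N)` training inputs.
#' @param y integer class indices (1-based) or character labels.
#' @param valX,valY optional validation set.
#' @param config a [trainConfig()].
#' @param verbose print per-epoch progress.
#' @return list with `model`, `history` (data.frame epoch/trainLoss/
#'   trainAcc/valLoss/valAcc), `bestEpoch`, `stoppedEarly`.
#' @export
trainModel <- function(model, x, y, valX = NULL, valY = NULL,
                       config = trainConfig(), verbose = FALSE) {
  if (is.character(y) || is.factor(y)) y <- match(as.character(y), model$classes)
  if (!is.null(valY) && (is.character(valY) || is.factor(valY)))
    valY <- match(as.character(valY), model$classes)
  N <- dim(x)[4]
  stopifnot(N == length(y), N >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  leaves <- model$leaves()
  hist <- data.frame()
  bestVal <- Inf; bestEpoch <- 0L; bestSnap <- NULL; sinceBest <- 0L
  step <- 0L
  stoppedEarly <- FALSE
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(N)
    totLoss <- 0; totCorrect <- 0
    i <- 1L
    while (i <= N) {
      j <- min(i + config$batchSize - 1L, N)
      idx <- perm[i:j]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[idx]
      logits <- model$fwd(xb, train = TRUE)
      ce <- .softmaxCrossEntropy(logits, yb)
      if (!is.finite(ce$loss))
        stop(sprintf(
          "training diverged: non-finite loss at epoch %d (batch %d-%d)",
          epoch, i, j), call. = FALSE)
      totLoss <- totLoss + ce$loss * length(idx)
      totCorrect <- totCorrect + sum(apply(ce$probs, 2, which.max) == yb)
      model$bwd(ce$dlogits)
      if (config$learningRate > 0) {
        step <- step + 1L
        .adamStep(leaves, config$learningRate, step,
                  weightDecay = config$weightDecay)
      }
      i <- j + 1L
    }
    row <- data.frame(epoch = epoch, trainLoss = totLoss / N,
                      trainAcc = totCorrect / N,
                      valLoss = NA_real_, valAcc = NA_real_)
    if (!is.null(valX)) {
      pv <- predictProbs(model, valX)
      idxv <- valY + nrow(pv) * (seq_len(ncol(pv)) - 1L)
      row$valLoss <- -mean(log(pmax(pv[idxv], 1e-12)))
      row$valAcc <- mean(apply(pv, 2, which.max) == valY)
      if (row$valLoss < bestVal - 1e-12) {
        bestVal <- row$valLoss; bestEpoch <- epoch; sinceBest <- 0L
        bestSnap <- .snapshotParams(leaves)
      } else {
        sinceBest <- sinceBest + 1L
      }
    }
    hist <- rbind(hist, row)
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f acc %.3f val loss %s acc %s",
                      epoch, row$trainLoss, row$trainAcc,
                      format(row$valLoss, digits = 4),
                      format(row$valAcc, digits = 3)))
    if (!is.null(valX) && is.finite(config$patience) &&
        sinceBest >= config$patience) {
      stoppedEarly <- TRUE
      break
    }
  }
  if (!is.null(bestSnap)) .restoreParams(leaves, bestSnap)
  list(model = model, history = hist,
       bestEpoch = if (bestEpoch > 0L) bestEpoch else nrow(hist),
       stoppedEarly = stoppedEarly)
}

#' Multi-class evaluation metrics
#'
#' Builds the K x K confusion matrix (rows = true class, columns =
#' predicted class), the overall accuracy, per-class precision
#' (TP / (TP + FP)), recall (TP / (TP + FN)), F1 (harmonic mean) and
#' one-vs-rest binary accuracy ((TP + TN) / n), macro (unweighted)
#' averages, and -- when probabilities are supplied -- one-vs-rest ROC
#' curves with trapezoidal AUC.  A class absent from `yTrue` has
#' undefined recall; it is reported as `NA` with a warning and excluded
#' from the macro averages.
#'
#' @param yTrue,yPred character labels or integer indices into `classes`.
#' @param yProb optional `(K, n)` or `(n, K)` probability matrix.
#' @param classes class names (default [cxrClasses()]).
#' @return A [MetricsReport-class].
#' @export
computeMetrics <- function(yTrue, yPred, yProb = NULL,
                           classes = cxrClasses()) {
  toChar <- function(v) if (is.numeric(v)) classes[v] else as.character(v)
  yTrue <- factor(toChar(yTrue), levels = classes)
  yPred <- factor(toChar(yPred), levels = classes)
  stopifnot(length(yTrue) == length(yPred), !anyNA(yTrue), !anyNA(yPred))
  n <- length(yTrue)
  conf <- unclass(table(true = yTrue, predicted = yPred))
  acc <- sum(diag(conf)) / n
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  tn <- n - tp - fp - fn
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  absent <- rowSums(conf) == 0
  if (any(absent)) {
    warning("classes absent from yTrue (recall undefined, excluded from macro): ",
            paste(classes[absent], collapse = ", "))
    recall[absent] <- NA_real_
  }
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall),
               ifelse(is.na(precision) | is.na(recall), NA_real_, 0))
  ovrAccuracy <- (tp + tn) / n
  keep <- !absent
  macro <- c(precision = mean(precision[keep], na.rm = TRUE),
             recall = mean(recall[keep], na.rm = TRUE),
             f1 = mean(f1[keep], na.rm = TRUE))
  aucs <- stats::setNames(rep(NA_real_, length(classes)), classes)
  rocs <- list()
  if (!is.null(yProb)) {
    yProb <- as.matrix(yProb)
    if (nrow(yProb) == length(classes) && ncol(yProb) == n)
      yProb <- t(yProb)
    stopifnot(nrow(yProb) == n, ncol(yProb) == length(classes))
    for (k in seq_along(classes)) {
      pos <- yTrue == classes[k]
      if (length(unique(pos)) < 2L) next
      r <- pROC::roc(response = pos, predictor = yProb[, k],
                     levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
      aucs[k] <- as.numeric(pROC::auc(r))
      rocs[[classes[k]]] <- data.frame(fpr = 1 - r$specificities,
                                       tpr = r$sensitivities)
    }
  }
  perClass <- data.frame(class = classes, precision = precision,
                         recall = recall, f1 = f1,
                         ovrAccuracy = ovrAccuracy, auc = aucs,
                         row.names = NULL)
  new("MetricsReport", confusion = conf, accuracy = acc,
      perClass = perClass, macro = macro, auc = aucs, roc = rocs)
}

#' One-vs-rest AUC
#'
#' Trapezoidal area under the ROC curve for a binary response.
#'
#' @param positive logical vector (TRUE = positive class).
#' @param scores numeric scores, higher = more positive.
#' @return numeric AUC.
#' @export
ovrAuc <- function(positive, scores) {
  r <- pROC::roc(response = positive, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Cross-validated training
#'
#' Splits the data into stratified folds, trains a fresh model on each
#' fold complement (the held-out fold serves as the validation set for
#' early stopping and is then evaluated), and aggregates the per-fold
#' metrics.
#'
#' @param x `(H, W, 3, N)` inputs.
#' @param y labels (character or integer indices).
#' @param modelCfg a [modelConfig()].
#' @param config a [trainConfig()]; `config$folds` folds are used.
#' @param verbose print progress.
#' @return list with `folds` (per-fold [MetricsReport-class]s), `fold`
#'   (the fold assignment vector), and `summary` (data.frame of mean and
#'   sd of accuracy and macro metrics across folds).
#' @export
crossValidate <- function(x, y, modelCfg, config = trainConfig(),
                          verbose = FALSE) {
  if (is.character(y) || is.factor(y)) y <- match(as.character(y), cxrClasses())
  k <- config$folds
  if (k > min(table(y)))
    stop("folds exceed the smallest class count", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  fold <- .stratifiedFolds(y, k)
  reports <- vector("list", k)
  accs <- numeric(k)
  for (f in seq_len(k)) {
    hold <- fold == f
    m <- buildModel(modelCfg, seed = .deriveSeed(config$seed, f))
    cfgF <- config
    cfgF$seed <- .deriveSeed(config$seed, 100L + f)
    fit <- trainModel(m, x[, , , !hold, drop = FALSE], y[!hold],
                      x[, , , hold, drop = FALSE], y[hold],
                      config = cfgF, verbose = verbose)
    pv <- predictProbs(fit$model, x[, , , hold, drop = FALSE])
    pred <- apply(pv, 2, which.max)
    reports[[f]] <- computeMetrics(y[hold], pred, t(pv))
    accs[f] <- reports[[f]]@accuracy
    if (verbose) message(sprintf("fold %d: accuracy %.3f", f, accs[f]))
  }
  gather <- function(fun) vapply(reports, fun, 0)
  summ <- data.frame(
    metric = c("accuracy", "macroPrecision", "macroRecall", "macroF1"),
    mean = c(mean(accs), mean(gather(function(r) r@macro["precision"])),
             mean(gather(function(r) r@macro["recall"])),
             mean(gather(function(r) r@macro["f1"]))),
    sd = c(sd(accs), sd(gather(function(r) r@macro["precision"])),
           sd(gather(function(r) r@macro["recall"])),
           sd(gather(function(r) r@macro["f1"]))))
  list(folds = reports, fold = fold, summary = summ)
}
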
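test_that("scenario 2 splits are stratified 80:20 with disjoint folds", {
  mf <- data.frame(path = sprintf("img%03d.png", 1:500),
                   label = rep(cxrClasses(), each = 100))
  sp <- makeSplit(mf, scenario = "2", seed = 4)
  asg <- sp@assignments
  for (cls in cxrClasses()) {
    expect_equal(sum(asg$partition == "train" & asg$label == cls), 80L)
    expect_equal(sum(asg$partition == "test" & asg$label == cls), 20L)
  }
  # each training row sits in exactly one of five folds; folds stratified
  tr <- asg[asg$partition == "train", ]
  expect_true(all(tr$fold %in% 1:5))
  expect_true(all(table(tr$fold, tr$label) == 16L))
  expect_true(all(is.na(asg$fold[asg$partition == "test"])))
  # determinism
  sp2 <- makeSplit(mf, scenario = "2", seed = 4)
  expect_identical(sp@assignments, sp2@assignments)
})

test_that("scenario 1 keeps the two datasets fully separate", {
  a <- data.frame(path = sprintf("a%03d.png", 1:50),
                  label = rep(cxrClasses(), 10))
  b <- data.frame(path = sprintf("b%03d.png", 1:25),
                  label = rep(cxrClasses(), 5))
  sp <- makeSplit(a, scenario = "1", seed = 1, testManifest = b)
  asg <- sp@assignments
  expect_true(all(asg$partition[asg$dataset == "A"] == "train"))
  expect_true(all(asg$partition[asg$dataset == "B"] == "test"))
  expect_equal(sum(asg$partition == "test"), 25L)
  expect_error(makeSplit(a, scenario = "1", seed = 1), "two dataset")
  # missing class warning
  b2 <- b[b$label != "Pneumonia", ]
  expect_warning(makeSplit(a, scenario = "1", seed = 1, testManifest = b2),
                 "Pneumonia")
})

test_that("metrics match a brute-force counting oracle on random labelings", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(30:120, 1)
    yt <- sample(1:5, n, replace = TRUE)
    yp <- sample(1:5, n, replace = TRUE)
    got <- suppressWarnings(computeMetrics(yt, yp))
    want <- naiveCountMetrics(yt, yp, cxrClasses())
    expect_identical(unname(unclass(got@confusion)), unname(want$confusion))
    expect_identical(got@accuracy, want$accuracy)
    expect_equal(unname(got@perClass$precision), want$precision)
    expect_equal(unname(got@perClass$recall), want$recall)
  }
})

test_that("confusion matrix conserves counts and accuracy equals its trace", {
  set.seed(5)
  yt <- sample(1:5, 300, replace = TRUE)
  yp <- sample(1:5, 300, replace = TRUE)
  r <- computeMetrics(yt, yp)
  expect_equal(sum(r@confusion), 300)
  expect_equal(unname(rowSums(r@confusion)),
               unname(as.integer(table(factor(yt, levels = 1:5)))))
  expect_equal(r@accuracy, sum(diag(r@confusion)) / 300)
})

test_that("binary toy confusion and perfect predictions behave as computed", {
  # two-class toy embedded in the 5-class frame: [[8,2],[1,9]]
  yt <- c(rep(1, 10), rep(2, 10))
  yp <- c(rep(1, 8), rep(2, 2), rep(1, 1), rep(2, 9))
  r <- suppressWarnings(computeMetrics(yt, yp))
  expect_equal(r@accuracy, 17 / 20)
  yt5 <- rep(1:5, each = 4)
  prob <- matrix(0.02, 20, 5)
  prob[cbind(1:20, yt5)] <- 0.92
  rp <- computeMetrics(yt5, yt5, prob)
  expect_equal(rp@accuracy, 1)
  expect_true(all(rp@perClass$precision == 1, rp@perClass$recall == 1,
                  rp@perClass$f1 == 1))
  expect_true(all(rp@auc == 1))
})

test_that("AUC matches the rank-based oracle and is 0.5 for uninformative scores", {
  set.seed(41)
  for (i in 1:5) {
    pos <- sample(c(TRUE, FALSE), 200, replace = TRUE)
    sc <- rnorm(200)
    expect_equal(ovrAuc(pos, sc), naiveAuc(pos, sc), tolerance = 1e-12)
  }
  set.seed(42)
  pos <- sample(c(TRUE, FALSE), 5000, replace = TRUE)
  sc <- runif(5000)
  expect_lt(abs(ovrAuc(pos, sc) - 0.5), 0.03)
})

test_that("a class absent from the truth is reported NA with a warning", {
  yt <- sample(1:4, 60, replace = TRUE)   # Pneumonia never occurs
  yp <- sample(1:5, 60, replace = TRUE)
  expect_warning(r <- computeMetrics(yt, yp), "Pneumonia")
  expect_true(is.na(r@perClass$recall[5]))
  expect_false(anyNA(r@macro))
})

test_that("zero learning rate leaves weights untouched and history flat", {
  set.seed(52)
  m <- buildModel(microConfig("resnet50"), seed = 9)
  before <- cxrnet:::.snapshotParams(m$leaves())
  x <- array(runif(32 * 32 * 3 * 20), c(32, 32, 3, 20))
  y <- rep(1:5, 4)
  # one full batch per epoch: batch statistics are then identical across
  # epochs, so with a zero learning rate the loss trace is exactly flat
  fit <- trainModel(m, x, y, config = trainConfig(epochs = 3, seed = 1,
                                                  learningRate = 0,
                                                  batchSize = 32))
  after <- cxrnet:::.snapshotParams(m$leaves())
  for (i in seq_along(before))
    for (nm in setdiff(names(before[[i]]), c("rmean", "rvar")))
      expect_identical(before[[i]][[nm]], after[[i]][[nm]])
  expect_equal(length(unique(round(fit$history$trainLoss, 10))), 1L)
})

test_that("training twice with the same seed yields identical histories", {
  set.seed(53)
  x <- array(runif(32 * 32 * 3 * 30), c(32, 32, 3, 30))
  y <- rep(1:5, 6)
  run <- function() {
    m <- buildModel(microConfig("fsrfnet50"), seed = 7)
    trainModel(m, x, y, x[, , , 1:10, drop = FALSE], y[1:10],
               config = trainConfig(epochs = 2, seed = 31,
                                    batchSize = 10))$history
  }
  expect_identical(run(), run())
})

test_that("early stopping restores the best validation epoch", {
  d <- tinyPhantomData()
  idx <- unlist(lapply(split(seq_along(d$y), d$y), function(ii) ii[1:12]))
  hol <- unlist(lapply(split(seq_along(d$y), d$y), function(ii) ii[13:16]))
  m <- buildModel(microConfig("resnet50"), seed = 11)
  x <- d$x[1:32, 1:32, , idx, drop = FALSE]
  xv <- d$x[1:32, 1:32, , hol, drop = FALSE]
  fit <- trainModel(m, x, d$y[idx], xv, d$y[hol],
                    config = trainConfig(epochs = 6, seed = 2, patience = 2,
                                         batchSize = 16))
  h <- fit$history
  expect_equal(fit$bestEpoch, which.min(h$valLoss))
  expect_lte(fit$bestEpoch, nrow(h))
  if (fit$stoppedEarly)
    expect_equal(nrow(h), fit$bestEpoch + 2)
})

test_that("cross-validation partitions each class evenly and aggregates", {
  d <- tinyPhantomData()
  idx <- unlist(lapply(split(seq_along(d$y), d$y), function(ii) ii[1:10]))
  x <- d$x[1:32, 1:32, , idx, drop = FALSE]
  y <- d$y[idx]
  cv <- crossValidate(x, y, microConfig("resnet50"),
                      config = trainConfig(epochs = 1, seed = 13, folds = 5,
                                           batchSize = 16))
  expect_length(cv$folds, 5L)
  expect_true(all(table(cv$fold, y) == 2L))
  accs <- vapply(cv$folds, function(r) r@accuracy, 0)
  m <- cv$summary$mean[cv$summary$metric == "accuracy"]
  expect_gte(m, min(accs))
  expect_lte(m, max(accs))
  cv2 <- crossValidate(x, y, microConfig("resnet50"),
                       config = trainConfig(epochs = 1, seed = 13, folds = 5,
                                            batchSize = 16))
  expect_identical(cv$fold, cv2$fold)
  expect_error(crossValidate(x, y, microConfig("resnet50"),
                             config = trainConfig(folds = 11, seed = 1)),
               "smallest class")
})

test_that("training aborts with diagnostics on divergence", {
  m <- buildModel(microConfig("resnet50"), seed = 15)
  m$fc$w[] <- 1e308   # force a non-finite loss immediately
  x <- array(runif(32 * 32 * 3 * 10), c(32, 32, 3, 10))
  expect_error(trainModel(m, x, rep(1:5, 2),
                          config = trainConfig(epochs = 1, seed = 1)),
               "non-finite")
})
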
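# Block-level oracle equivalence: each architectural component is compared
# against an independent naive composition of its defining formulas,
# using the module's own (randomly initialised) weights.

test_that("compiled convolution matches the naive 6-loop oracle", {
  set.seed(21)
  cases <- list(
    list(H = 6, C = 4, N = 2, k = 3, Co = 8, st = 1, g = 1, pd = 1),
    list(H = 7, C = 4, N = 1, k = 3, Co = 4, st = 2, g = 1, pd = 1),
    list(H = 8, C = 6, N = 2, k = 5, Co = 6, st = 2, g = 2, pd = 2),
    list(H = 6, C = 4, N = 2, k = 1, Co = 8, st = 1, g = 4, pd = 0))
  for (cs in cases) {
    x <- array(rnorm(cs$H^2 * cs$C * cs$N), c(cs$H, cs$H, cs$C, cs$N))
    w <- array(rnorm(cs$k^2 * (cs$C / cs$g) * cs$Co),
               c(cs$k, cs$k, cs$C / cs$g, cs$Co))
    b <- rnorm(cs$Co)
    got <- cxrnet:::.conv2dForward(x, w, b, cs$st, cs$pd, cs$g)
    want <- naiveConv2d(x, w, b, cs$st, cs$pd, cs$g)
    expect_lt(max(abs(got - want)) / max(1, max(abs(want))), 1e-10)
  }
})

test_that("residual block with zero residual weights is the identity on positive input", {
  set.seed(22)
  blk <- nnBottleneck(6, 4, 6, stride = 1, cardinality = 1)
  for (lf in blk$main$leaves())
    for (nm in lf$pnames) if (nm %in% c("w", "gamma")) lf[[nm]][] <- 0
  x <- array(abs(rnorm(8 * 8 * 6 * 2)) + 0.1, c(8, 8, 6, 2))
  y <- blk$fwd(x, train = FALSE)
  expect_equal(y, x, tolerance = 1e-12)
})

test_that("strided blocks halve the spatial dimensions", {
  set.seed(23)
  blk <- nnBottleneck(4, 4, 8, stride = 2, cardinality = 2)
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4, 1))
  expect_equal(dim(blk$fwd(x, train = TRUE))[1:2], c(8L, 8L))
  fu <- nnFSRFUnit(4, 4, 8, stride = 2, branches = 2, groups = 2,
                   reduction = 2)
  expect_equal(dim(fu$fwd(x, train = TRUE))[1:2], c(8L, 8L))
})

test_that("bottleneck block matches a naive layer-by-layer composition", {
  set.seed(24)
  blk <- nnBottleneck(6, 4, 8, stride = 2, cardinality = 2)
  x <- array(rnorm(8 * 8 * 6 * 2), c(8, 8, 6, 2))
  got <- blk$fwd(x, train = FALSE)   # eval mode: BN uses running stats
  # oracle: conv -> BN(running) -> relu chain plus projection shortcut
  bnEval <- function(z, bn) {
    d <- dim(z)
    for (c in seq_len(d[3]))
      z[, , c, ] <- (z[, , c, ] - bn$rmean[c]) / sqrt(bn$rvar[c] + bn$eps) *
        bn$gamma[c] + bn$beta[c]
    z
  }
  relu <- function(z) z * (z > 0)
  mods <- blk$main$mods
  h <- relu(bnEval(naiveConv2d(x, mods[[1]]$w, numeric(0), 1, 0, 1), mods[[2]]))
  h <- relu(bnEval(naiveConv2d(h, mods[[4]]$w, numeric(0), 2, 1, 2), mods[[5]]))
  h <- bnEval(naiveConv2d(h, mods[[7]]$w, numeric(0), 1, 0, 1), mods[[8]])
  s <- bnEval(naiveConv2d(x, blk$proj$mods[[1]]$w, numeric(0), 2, 0, 1),
              blk$proj$mods[[2]])
  want <- relu(h + s)
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("channel attention matches its formula and degenerate cases", {
  set.seed(25)
  amc <- nnAMC(8, 2)
  # all-zero input with zero biases: sigmoid(0) = 0.5 per channel
  z0 <- array(0, c(4, 4, 8, 2))
  expect_equal(unname(amc$fwd(z0)), matrix(0.5, 8, 2), tolerance = 1e-12)
  # spatially constant input: avg and max branches coincide
  xc <- array(rep(rnorm(8 * 2), each = 16), c(4, 4, 8, 2))
  zc <- matrix(xc[1, 1, , ], 8, 2)
  mlp <- function(z) amc$W2 %*% pmax(amc$W1 %*% z + amc$b1, 0) + amc$b2
  expect_equal(amc$fwd(xc), sigm(2 * mlp(zc)), tolerance = 1e-10)
  # random input: full formula with separate avg / max descriptors
  x <- array(rnorm(5 * 5 * 8 * 3), c(5, 5, 8, 3))
  za <- apply(x, c(3, 4), mean)
  zm <- apply(x, c(3, 4), max)
  expect_equal(amc$fwd(x), sigm(mlp(za) + mlp(zm)), tolerance = 1e-10)
  expect_error(nnAMC(8, 3), "divide")
})

test_that("spatial attention matches its formula and degenerate cases", {
  set.seed(26)
  ams <- nnAMS(7)
  # single-channel input: avg map = max map = the input itself
  x1 <- array(rnorm(6 * 6), c(6, 6, 1, 1))
  stack <- array(0, c(6, 6, 2, 1))
  stack[, , 1, ] <- x1[, , 1, ]
  stack[, , 2, ] <- x1[, , 1, ]
  want <- sigm(naiveConv2d(stack, ams$w, ams$b, 1, 3, 1))
  expect_equal(ams$fwd(x1), array(want, c(6, 6, 1)), tolerance = 1e-10)
  # constant input gives a constant attention map (away from borders the
  # padded convolution is shift-invariant; assert the interior)
  xc <- array(3.7, c(9, 9, 4, 1))
  g <- ams$fwd(xc)
  expect_lt(diff(range(g[4:6, 4:6, 1])), 1e-12)
  # random multi-channel input: channel-wise avg and max then conv
  x <- array(rnorm(6 * 6 * 5 * 2), c(6, 6, 5, 2))
  st <- array(0, c(6, 6, 2, 2))
  st[, , 1, ] <- apply(x, c(1, 2, 4), mean)
  st[, , 2, ] <- apply(x, c(1, 2, 4), max)
  want <- sigm(naiveConv2d(st, ams$w, ams$b, 1, 3, 1))
  expect_equal(ams$fwd(x), array(want, c(6, 6, 2)), tolerance = 1e-10)
})

test_that("FSRF soft-attention weights are uniform for identical branches", {
  set.seed(27)
  core <- nnFSRFCore(8, branches = 2, groups = 2, reduction = 2)
  # force both branch transforms to be identical
  b1 <- core$branchMods[[1]]$leaves()
  b2 <- core$branchMods[[2]]$leaves()
  w1 <- b1[[1]]$w
  # make the 5x5 kernel equal to the 3x3 kernel zero-padded
  w5 <- array(0, dim(b2[[1]]$w))
  w5[2:4, 2:4, , ] <- w1
  b2[[1]]$w <- w5
  for (nm in c("gamma", "beta")) b2[[2]][[nm]] <- b1[[2]][[nm]]
  x <- array(rnorm(7 * 7 * 8 * 2), c(7, 7, 8, 2))
  y <- core$fwd(x, train = TRUE)
  expect_equal(core$Wt[[1]], core$Wt[[2]], tolerance = 1e-12)
  expect_equal(unname(core$Wt[[1]][1, 1]), 0.5, tolerance = 1e-12)
  # output equals the common branch feature (weights sum to 1)
  expect_equal(y, core$B[[1]], tolerance = 1e-10)
})

test_that("FSRF branch selection weights always sum to one", {
  set.seed(28)
  for (M in c(2L, 3L)) {
    core <- nnFSRFCore(8, branches = M, groups = 2, reduction = 2)
    x <- array(rnorm(6 * 6 * 8 * 4), c(6, 6, 8, 4))
    core$fwd(x, train = TRUE)
    tot <- Reduce(`+`, core$Wt)
    expect_lt(max(abs(tot - 1)), 1e-6)
  }
})

test_that("FSRF core matches a step-by-step scripted oracle", {
  set.seed(29)
  core <- nnFSRFCore(8, branches = 2, groups = 2, reduction = 2)
  x <- array(rnorm(7 * 7 * 8 * 2), c(7, 7, 8, 2))
  got <- core$fwd(x, train = FALSE)
  bnEval <- function(z, bn) {
    for (c in seq_len(dim(z)[3]))
      z[, , c, ] <- (z[, , c, ] - bn$rmean[c]) / sqrt(bn$rvar[c] + bn$eps) *
        bn$gamma[c] + bn$beta[c]
    z
  }
  relu <- function(z) z * (z > 0)
  branch <- function(mods, k, pad) relu(bnEval(
    naiveConv2d(x, mods[[1]]$w, numeric(0), 1, pad, 2), mods[[2]]))
  B1 <- branch(core$branchMods[[1]]$mods, 3, 1)
  B2 <- branch(core$branchMods[[2]]$mods, 5, 2)
  U <- B1 + B2
  ac <- core$amc$fwd(U)                 # modules already oracle-checked
  as_ <- core$ams$fwd(U)
  gate <- array(0, dim(U))
  for (c in 1:8) for (n in 1:2) gate[, , c, n] <- ac[c, n] * as_[, , n]
  sel <- function(B) {
    z <- apply(B * gate, c(3, 4), mean)
    core$V2 %*% pmax(core$V1 %*% z + core$c1, 0) + core$c2
  }
  e1 <- sel(B1); e2 <- sel(B2)
  w1 <- exp(e1) / (exp(e1) + exp(e2)); w2 <- 1 - w1
  want <- array(0, dim(U))
  for (c in 1:8) for (n in 1:2)
    want[, , c, n] <- w1[c, n] * B1[, , c, n] + w2[c, n] * B2[, , c, n]
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("zeroing one branch leaves the other scaled by its selection weight", {
  set.seed(30)
  core <- nnFSRFCore(8, branches = 2, groups = 2, reduction = 2)
  for (lf in core$branchMods[[2]]$leaves())
    for (nm in lf$pnames) if (nm %in% c("w", "gamma", "beta")) lf[[nm]][] <- 0
  x <- array(rnorm(6 * 6 * 8 * 1), c(6, 6, 8, 1))
  y <- core$fwd(x, train = FALSE)
  scaled <- array(0, dim(y))
  for (c in 1:8) scaled[, , c, 1] <- core$Wt[[1]][c, 1] * core$B[[1]][, , c, 1]
  expect_equal(y, scaled, tolerance = 1e-10)
  expect_equal(max(abs(core$B[[2]])), 0)
})

test_that("error paths: kernel list shorter than branches, spatial mismatch", {
  expect_error(nnFSRFCore(8, branches = 3, groups = 2, reduction = 2,
                          kernels = c(3, 5)), "kernel list")
  set.seed(31)
  blk <- nnBottleneck(4, 4, 8, stride = 1)
  x <- array(rnorm(6 * 6 * 5), c(6, 6, 5, 1))
  expect_error(blk$fwd(x), "channels")
})

test_that("gradients flow through the identity path when residual weights are zero", {
  set.seed(32)
  blk <- nnBottleneck(6, 4, 6, stride = 1)
  for (lf in blk$main$leaves())
    for (nm in lf$pnames) if (nm %in% c("w", "gamma")) lf[[nm]][] <- 0
  x <- array(abs(rnorm(6 * 6 * 6)) + 0.1, c(6, 6, 6, 1))
  blk$fwd(x, train = TRUE)
  dx <- blk$bwd(array(1, c(6, 6, 6, 1)))
  expect_gt(max(abs(dx)), 0.99)
})

test_that("block backward passes match finite differences", {
  set.seed(33)
  mods <- list(
    bottleneck = list(nnBottleneck(4, 4, 6, stride = 2, cardinality = 2),
                      c(7, 7, 4, 2)),
    fsrf = list(nnFSRFUnit(4, 4, 6, stride = 1, branches = 2, groups = 2,
                           reduction = 2), c(6, 6, 4, 2)))
  for (nm in names(mods)) {
    mod <- mods[[nm]][[1]]
    xdim <- mods[[nm]][[2]]
    x <- array(rnorm(prod(xdim)), xdim)
    y <- mod$fwd(x, train = TRUE)
    tgt <- array(rnorm(length(y)), dim(y))
    dx <- mod$bwd(tgt)
    loss <- function(xx) sum(mod$fwd(xx, train = TRUE) * tgt)
    idx <- sample(length(x), 5)
    for (i in idx) {
      eps <- 1e-5
      xp <- x; xp[i] <- x[i] + eps
      xm <- x; xm[i] <- x[i] - eps
      ng <- (loss(xp) - loss(xm)) / (2 * eps)
      expect_lt(abs(ng - dx[i]) / max(1e-3, abs(ng)), 1e-3)
    }
  }
})
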
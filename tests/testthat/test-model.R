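## Flatten / unflatten network parameters for finite-difference checks.
flattenParams <- function(p) {
  c(as.numeric(p$Wx), as.numeric(p$Wh), as.numeric(p$b),
    unlist(lapply(p$Wd, as.numeric)), unlist(lapply(p$bd, as.numeric)),
    as.numeric(p$Wo), as.numeric(p$bo))
}

unflattenParams <- function(v, tmpl) {
  out <- tmpl
  k <- 0L
  take <- function(n) {
    r <- v[(k + 1):(k + n)]; k <<- k + n; r
  }
  out$Wx <- matrix(take(length(tmpl$Wx)), nrow(tmpl$Wx))
  out$Wh <- matrix(take(length(tmpl$Wh)), nrow(tmpl$Wh))
  out$b <- take(length(tmpl$b))
  out$Wd <- lapply(tmpl$Wd, function(m) matrix(take(length(m)), nrow(m)))
  out$bd <- lapply(tmpl$bd, function(b) take(length(b)))
  out$Wo <- matrix(take(length(tmpl$Wo)), nrow(tmpl$Wo))
  out$bo <- take(length(tmpl$bo))
  out
}

test_that("configuration constructors validate their inputs", {
  cfg <- networkConfig(45)
  expect_equal(cfg$windowLength, 30L)
  expect_equal(cfg$recurrentSize, 20L)
  expect_equal(cfg$nDenseLayers, 4L)
  expect_equal(cfg$head, "binary_softmax")
  expect_error(networkConfig(0), "inputSize")
  tc <- trainingConfig()
  expect_equal(tc$maxEpochs, 60L)
  expect_equal(tc$patience, 12L)
  expect_equal(tc$learningRate, 1e-3)
  expect_error(trainingConfig(maxEpochs = 10, patience = 10), "patience")
})

test_that("nParameters matches the closed-form count", {
  D <- 45; H <- 20; W <- 20; L <- 4
  cfg <- networkConfig(D)
  set.seed(1)
  net <- buildNetwork(cfg)
  expected <- 4 * H * D + 4 * H * H + 4 * H +   # LSTM
    (W * H + W) + (L - 1) * (W * W + W) +       # dense stack
    2 * W + 2                                   # softmax head
  expect_equal(nParameters(net), as.integer(expected))
  set.seed(1)
  netr <- buildNetwork(networkConfig(D, head = "regression_relu"))
  expect_equal(nParameters(netr), as.integer(expected - (2 * W + 2) + W + 1))
})

test_that("analytic gradients match finite differences for both heads", {
  set.seed(42)
  for (head in c("binary_softmax", "regression_relu")) {
    cfg <- networkConfig(3, windowLength = 4, recurrentSize = 4,
                         nDenseLayers = 2, denseWidth = 5, head = head)
    net <- buildNetwork(cfg)
    nWin <- 5
    X <- matrix(rnorm(nWin * 4 * 3, sd = 0.5), nWin * 4, 3)
    starts <- seq(1, by = 4, length.out = nWin)
    y <- if (head == "binary_softmax") c(0, 1, 1, 0, 1) else runif(5, 0.5, 2)
    res <- .cg_loss_grad(net$params, X, as.integer(starts), as.numeric(y),
                         4L, if (head == "binary_softmax") 0L else 1L)
    g <- flattenParams(res$grad)
    v0 <- flattenParams(net$params)
    eps <- 1e-5
    idx <- sort(sample(length(v0), 60))   # spot-check across all blocks
    idx <- unique(c(idx, 1, length(v0)))
    num <- vapply(idx, function(i) {
      vp <- v0; vp[i] <- vp[i] + eps
      vm <- v0; vm[i] <- vm[i] - eps
      lp <- .cg_loss_grad(unflattenParams(vp, net$params), X,
                          as.integer(starts), as.numeric(y), 4L,
                          if (head == "binary_softmax") 0L else 1L)$loss
      lm <- .cg_loss_grad(unflattenParams(vm, net$params), X,
                          as.integer(starts), as.numeric(y), 4L,
                          if (head == "binary_softmax") 0L else 1L)$loss
      (lp - lm) / (2 * eps)
    }, 1)
    expect_lt(max(abs(num - g[idx])), 1e-6)
  }
})

test_that("training is deterministic given a seed and stops early", {
  set.seed(5)
  cfg <- networkConfig(4, windowLength = 5, recurrentSize = 4,
                       nDenseLayers = 2, denseWidth = 5)
  nWin <- 24
  X <- matrix(rnorm(nWin * 5 * 4), nWin * 5, 4)
  starts <- seq(1, by = 5, length.out = nWin)
  y <- rep(c(0, 1), nWin / 2)
  tcfg <- trainingConfig(maxEpochs = 10, patience = 3, batchSize = 8)
  set.seed(9); net0 <- buildNetwork(cfg)
  m1 <- trainNetwork(net0, X, starts, y, X, starts, y, tcfg, seed = 7)
  m2 <- trainNetwork(net0, X, starts, y, X, starts, y, tcfg, seed = 7)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history$valLoss, m2$history$valLoss)
  m3 <- trainNetwork(net0, X, starts, y, X, starts, y, tcfg, seed = 8)
  expect_false(identical(m1$params, m3$params))
  ## early-stopping bookkeeping
  expect_lte(m1$history$epochsRun, tcfg$maxEpochs)
  expect_lte(m1$history$bestEpoch, m1$history$epochsRun)
  expect_equal(m1$history$bestValLoss, min(m1$history$valLoss))
  ## the returned weights are those of the best epoch: re-evaluating the
  ## validation loss reproduces bestValLoss
  lv <- .cg_loss_grad(m1$params, X, as.integer(starts), as.numeric(y), 5L, 0L)$loss
  expect_equal(lv, m1$history$bestValLoss, tolerance = 1e-10)
})

test_that("the network separates a linearly separable toy problem", {
  set.seed(6)
  D <- 6; Tw <- 8; nPer <- 30
  ## class 0 activates input 1, class 1 activates input 2
  mk <- function(col) {
    do.call(rbind, lapply(seq_len(nPer), function(i) {
      m <- matrix(rnorm(Tw * D, 0, 0.05), Tw, D)
      m[, col] <- m[, col] + 0.8
      m
    }))
  }
  X <- rbind(mk(1), mk(2))
  starts <- seq(1, by = Tw, length.out = 2 * nPer)
  y <- rep(c(0, 1), each = nPer)
  cfg <- networkConfig(D, windowLength = Tw, recurrentSize = 6,
                       nDenseLayers = 2, denseWidth = 8)
  set.seed(10)
  net <- buildNetwork(cfg)
  net <- trainNetwork(net, X, starts, y, X, starts, y,
                      trainingConfig(maxEpochs = 40, patience = 10,
                                     batchSize = 16), seed = 1)
  pred <- predictNetwork(net, X, starts)
  expect_equal(dim(pred), c(2 * nPer, 2))
  expect_equal(rowSums(pred), rep(1, 2 * nPer), tolerance = 1e-9)
  m <- evaluateClassification(y, pred)
  expect_gte(m$accuracy, 0.95)
})

test_that("the regression head fits scaled targets on a toy problem", {
  set.seed(60)
  D <- 4; Tw <- 6; n <- 40
  lv <- runif(n, 0.3, 1.5)
  X <- do.call(rbind, lapply(lv, function(s)
    matrix(s + rnorm(Tw * D, 0, 0.02), Tw, D)))
  starts <- seq(1, by = Tw, length.out = n)
  cfg <- networkConfig(D, windowLength = Tw, recurrentSize = 5,
                       nDenseLayers = 2, denseWidth = 6,
                       head = "regression_relu")
  set.seed(61)
  net <- buildNetwork(cfg)
  net <- trainNetwork(net, X, starts, lv, X, starts, lv,
                      trainingConfig(maxEpochs = 50, patience = 15,
                                     batchSize = 8), seed = 2)
  pred <- predictNetwork(net, X, starts)
  expect_true(all(pred >= 0))
  m <- evaluateRegression(lv, pred)
  expect_gt(m$pearson, 0.9)
})

test_that("classification metrics match a hand-computed confusion table", {
  truth <- c(1, 1, 1, 0, 0, 0, 0, 1)
  pred <-  c(1, 0, 1, 0, 1, 0, 0, 1)
  m <- evaluateClassification(truth, pred)
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$fn, 1); expect_equal(m$tn, 3)
  expect_equal(m$accuracy, 6 / 8)
  expect_equal(m$precision, 3 / 4)
  expect_equal(m$recall, 3 / 4)
  expect_equal(m$f1, 2 * (3/4) * (3/4) / (3/4 + 3/4))
  ## zero denominators give NA, never 0
  m2 <- evaluateClassification(c(0, 0), c(0, 0))
  expect_true(is.na(m2$precision) && is.na(m2$recall) && is.na(m2$f1))
  expect_equal(m2$accuracy, 1)
  ## probability-matrix input takes the argmax
  pm <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  m3 <- evaluateClassification(c(0, 1), pm)
  expect_equal(m3$accuracy, 1)
})

test_that("regression metrics match hand computation and NA rules", {
  truth <- c(1, 2, 3, 4)
  pred <- c(1.5, 2, 2.5, 5)
  m <- evaluateRegression(truth, pred)
  expect_equal(m$rmse, sqrt(mean(c(0.5, 0, -0.5, 1)^2)))
  expect_equal(m$pearson, cor(truth, pred))
  expect_true(is.na(evaluateRegression(c(1, 2), c(3, 3))$pearson))
})

test_that("buildWindowSet stacks walks and caps windows evenly", {
  m1 <- matrix(1, 10, 3); m2 <- matrix(2, 4, 3); m3 <- matrix(3, 40, 3)
  ws <- buildWindowSet(list(m1, m2, m3), labels = c(0, 1, 1),
                       windowLength = 5, stride = 1, maxWindowsPerWalk = 6)
  expect_equal(nrow(ws$X), 54)
  expect_equal(ws$nWindows, c(6L, 0L, 6L))   # 10 steps -> 6 starts; 4 -> none
  expect_equal(sum(ws$y == 0), 6)
  ## window starts point into the right walk block
  expect_true(all(ws$starts[ws$walk == 1] <= 6))
  expect_true(all(ws$starts[ws$walk == 3] > 14))
  ## capped starts are evenly spread over the stride-1 range
  s3 <- ws$starts[ws$walk == 3] - 14
  expect_equal(s3[1], 1L)
  expect_equal(s3[length(s3)], 40 - 5 + 1)
  expect_error(buildWindowSet(list(m1, matrix(0, 5, 2)), c(0, 1)),
               "differing vector widths")
})
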
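# Convolutional classifier: layer arithmetic, gradients, training.

test_that("valid cross-correlation with logistic activation", {
  out <- convLayerForward(c(1, 1, 1, 1, 1, 0, 0), matrix(1, 1, 5), 0)
  expect_equal(as.numeric(out), 1 / (1 + exp(-c(5, 4, 3))), tolerance = 1e-12)
  # zero kernel: constant sigma(0) = 0.5
  out0 <- convLayerForward(c(1, 0, 1, 0), matrix(0, 1, 2), 0)
  expect_equal(as.numeric(out0), rep(0.5, 3))
  expect_error(convLayerForward(c(1, 0), matrix(1, 1, 5), 0), "shorter")
})

test_that("multi-channel convolution sums channels before bias and activation", {
  set.seed(701)
  C <- 2L; L <- 9L; n <- 3L; k <- 4L
  x <- matrix(runif(C * L), C, L)
  ker <- array(runif(n * C * k, -1, 1), dim = c(n, C, k))
  b <- runif(n)
  got <- convLayerForward(x, ker, b)
  # explicit double-loop oracle
  W <- L - k + 1L
  want <- matrix(0, n, W)
  for (i in seq_len(n))
    for (w in seq_len(W)) {
      z <- b[i]
      for (ch in seq_len(C))
        for (a in seq_len(k))
          z <- z + ker[i, ch, a] * x[ch, w + a - 1L]
      want[i, w] <- 1 / (1 + exp(-z))
    }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("max pooling drops a trailing partial window", {
  expect_equal(maxPool(c(0.2, 0.8, 0.5, 0.4)), c(0.8, 0.5))
  expect_equal(maxPool(c(0.9, 0.1, 0.3)), 0.9)
  expect_length(maxPool(0.7), 0L)
  m <- rbind(c(1, 3, 2, 0, 9), c(4, 1, 1, 2, 5))
  expect_equal(maxPool(m), rbind(c(3, 2), c(4, 2)))
})

test_that("dimension chain follows the (L-K+1)/2 rule with floor pooling", {
  d <- cnnDimensions(6443)
  expect_equal(unlist(d),
               c(conv1 = 6439L, pool1 = 3219L, conv2 = 3215L,
                 pool2 = 1607L, flatten = 32140L))
  # forward-pass output shapes match the closed form for random configs
  set.seed(702)
  for (rep in 1:20) {
    L <- sample(30:120, 1)
    k1 <- sample(2:6, 1); k2 <- sample(2:4, 1)
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    d <- cnnDimensions(L, k1, k2, 2L, n2)
    if (d$pool1 < k2 || d$pool2 < 1L) next
    cfg <- cnnConfig(L, 2, k1 = k1, n1 = n1, k2 = k2, n2 = n2,
                     hidden = 4, seed = rep)
    set.seed(rep)
    par <- rnaFragNet:::.cnnInit(cfg)
    X <- matrix(rbinom(3 * L, 1, 0.5), 3, L)
    fw <- rnaFragNet:::.cnnForward(par, cfg, X, cache = TRUE)
    expect_equal(ncol(fw$Y), d$flatten)
    expect_equal(dim(fw$A1), c(3L * d$conv1, n1))
    expect_equal(dim(fw$A2), c(3L * d$conv2, n2))
  }
})

test_that("kernel configuration bound counts nonzero binary patterns", {
  expect_equal(kernelConfigurationBound(5), 31L)
  expect_equal(kernelConfigurationBound(3), 7L)
})

test_that("softmax output is a probability vector; zero weights are uniform", {
  cfg <- cnnConfig(20, 4, k1 = 3, n1 = 2, k2 = 2, n2 = 3, hidden = 5,
                   seed = 1)
  par <- lapply(rnaFragNet:::.cnnInit(cfg), function(w) w * 0)
  model <- new("CnnModel", config = cfg, W1 = par$W1, b1 = par$b1,
               W2 = par$W2, b2 = par$b2, M1 = par$M1, bh = par$bh,
               M2 = par$M2, bo = par$bo,
               classLabels = c("a", "b", "c", "d"),
               fragmentCodes = sprintf("f%d", 1:20))
  p <- forwardCnn(model, rbinom(20, 1, 0.5))
  expect_equal(unname(p), rep(0.25, 4))
  # tie-break: first class label for every row
  pr <- predict(model, matrix(rbinom(60, 1, 0.5), 3, 20))
  expect_equal(pr$class, rep("a", 3))
  expect_equal(unname(rowSums(pr$prob)), rep(1, 3), tolerance = 1e-9)
  expect_error(forwardCnn(model, rep(1, 7)), "expected input length 20")
})

test_that("analytic gradients match central finite differences", {
  cfg <- cnnConfig(12, 3, k1 = 3, n1 = 2, k2 = 2, n2 = 2, hidden = 5,
                   seed = 7)
  set.seed(7)
  par <- rnaFragNet:::.cnnInit(cfg)
  set.seed(8)
  X <- matrix(rbinom(5 * 12, 1, 0.5), 5, 12)
  storage.mode(X) <- "double"
  Y <- rnaFragNet:::.oneHot(sample(c("a", "b", "c"), 5, replace = TRUE),
                            c("a", "b", "c"))
  lg <- rnaFragNet:::.cnnLossGrad(par, cfg, X, Y)
  eps <- 1e-5
  worst <- 0
  for (nm in names(par)) {
    w <- par[[nm]]
    for (qi in seq_along(w)) {
      p2 <- par
      p2[[nm]][qi] <- w[qi] + eps
      lp <- rnaFragNet:::.cnnLossGrad(p2, cfg, X, Y)$loss
      p2[[nm]][qi] <- w[qi] - eps
      lm <- rnaFragNet:::.cnnLossGrad(p2, cfg, X, Y)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- lg$grads[[nm]][qi]
      worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("full-batch loss is non-increasing at a small learning rate", {
  set.seed(703)
  L <- 16L
  X <- matrix(rbinom(8 * L, 1, 0.5), 8, L)
  storage.mode(X) <- "double"
  Y <- rnaFragNet:::.oneHot(rep(c("a", "b"), 4), c("a", "b"))
  cfg <- cnnConfig(L, 2, k1 = 3, n1 = 2, k2 = 2, n2 = 2, hidden = 4,
                   learningRate = 0.01, seed = 3)
  set.seed(3)
  par <- rnaFragNet:::.cnnInit(cfg)
  prev <- rnaFragNet:::.cnnLossGrad(par, cfg, X, Y)$loss
  for (ep in 1:50) {
    lg <- rnaFragNet:::.cnnLossGrad(par, cfg, X, Y)
    for (nm in names(par))
      par[[nm]] <- par[[nm]] - cfg$learningRate * lg$grads[[nm]]
    cur <- rnaFragNet:::.cnnLossGrad(par, cfg, X, Y)$loss
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("separable classes are fit exactly and training is seed-deterministic", {
  set.seed(704)
  n <- 100L; L <- 30L
  X0 <- matrix(rbinom(n * L, 1, 0.2), n, L); X0[, 3:7] <- 1L
  X1 <- matrix(rbinom(n * L, 1, 0.2), n, L); X1[, 20:24] <- 1L
  X <- rbind(X0, X1)
  colnames(X) <- sprintf("f%d", seq_len(L))
  y <- rep(c("c0", "c1"), each = n)
  cfg <- cnnConfig(L, 2, hidden = 50, epochs = 200, seed = 0)
  m <- trainCnn(X, y, cfg)
  expect_equal(mean(predict(m, X)$class == y), 1.0)
  m2 <- trainCnn(X, y, cfg)
  expect_identical(m@W1, m2@W1)
  expect_identical(m@M1, m2@M1)
  expect_identical(m@bo, m2@bo)
})

test_that("training validates labels, classes and matrix values", {
  X <- matrix(rbinom(40, 1, 0.5), 8, 5)
  colnames(X) <- sprintf("f%d", 1:5)
  cfg <- cnnConfig(5, 2, k1 = 2, n1 = 2, k2 = 1, n2 = 2, hidden = 3,
                   epochs = 1, seed = 1)
  expect_error(trainCnn(X, rep("a", 3), cfg), "label count 3")
  expect_error(trainCnn(X, rep("a", 8), cfg), "2 classes")
  Xbad <- X; Xbad[1, 1] <- 2
  expect_error(trainCnn(Xbad, rep(c("a", "b"), 4), cfg), "boolean")
})

test_that("prediction rejects a mismatched feature space", {
  X <- matrix(rbinom(40, 1, 0.5), 8, 5)
  colnames(X) <- sprintf("f%d", 1:5)
  cfg <- cnnConfig(5, 2, k1 = 2, n1 = 2, k2 = 1, n2 = 2, hidden = 3,
                   epochs = 1, seed = 1)
  m <- trainCnn(X, rep(c("a", "b"), 4), cfg)
  expect_error(predict(m, X[, 1:4]), "feature space mismatch")
  single <- predict(m, X[1, , drop = FALSE])
  expect_length(single$class, 1L)
})

test_that("models reload bit-exactly from the JSON archive", {
  set.seed(705)
  X <- matrix(rbinom(120, 1, 0.5), 12, 10)
  colnames(X) <- sprintf("f%d", 1:10)
  cfg <- cnnConfig(10, 2, k1 = 3, n1 = 2, k2 = 2, n2 = 2, hidden = 4,
                   epochs = 2, seed = 9)
  m <- trainCnn(X, rep(c("a", "b"), 6), cfg)
  mf <- withr::local_tempfile(fileext = ".json")
  writeCnnModel(m, mf)
  back <- readCnnModel(mf)
  expect_identical(back@W1, m@W1)
  expect_identical(back@M1, m@M1)
  expect_identical(back@fragmentCodes, m@fragmentCodes)
  expect_identical(predict(back, X)$prob, predict(m, X)$prob)
})
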
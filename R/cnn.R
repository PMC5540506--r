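# Convolutional network over boolean fragment-containment vectors.
#
# Architecture: valid (no-padding, stride-1) cross-correlation with n1
# width-k1 kernels and logistic activation; width-2 max-pooling (odd
# trailing element dropped); a second convolutional layer with n2
# multi-channel width-k2 kernels, logistic, width-2 max-pooling; flatten;
# one tanh hidden layer; softmax output. Trained by seeded mini-batch SGD
# on the categorical cross-entropy.

#' Dimension chain of the convolutional layers
#'
#' Valid convolution maps length L to L - k + 1; width-`pool` max-pooling
#' floors to `(L - k + 1) %/% pool` (odd trailing elements are dropped).
#'
#' @param inputLength feature count L.
#' @param k1,k2 kernel widths. @param pool pooling width. @param n2
#'   second-layer kernel count (for the flattened length).
#' @return list with `conv1`, `pool1`, `conv2`, `pool2` per-kernel lengths
#'   and the flattened length `flatten = n2 * pool2`.
#' @examples
#' cnnDimensions(6443)  # 6439 -> 3219 -> 3215 -> 1607 -> 32140
#' @export
cnnDimensions <- function(inputLength, k1 = 5L, k2 = 5L, pool = 2L,
                          n2 = 20L) {
  conv1 <- inputLength - k1 + 1L
  pool1 <- conv1 %/% pool
  conv2 <- pool1 - k2 + 1L
  pool2 <- conv2 %/% pool
  list(conv1 = as.integer(conv1), pool1 = as.integer(pool1),
       conv2 = as.integer(conv2), pool2 = as.integer(pool2),
       flatten = as.integer(n2 * pool2))
}

#' Upper bound on useful first-layer kernels for binary inputs
#'
#' With binary input vectors, a width-k window can take only the distinct
#' nonzero 0/1 configurations, which bounds how many first-layer kernels
#' can detect distinct patterns. Counted by explicit enumeration of all
#' width-k binary configurations, excluding the all-zero one.
#'
#' @param k kernel width.
#' @return integer count (31 for k = 5).
#' @export
kernelConfigurationBound <- function(k) {
  stopifnot(k >= 1L, k <= 20L)
  grid <- as.matrix(expand.grid(rep(list(0:1), k)))
  sum(rowSums(grid) > 0L)
}

#' CNN hyperparameter configuration
#'
#' Defaults follow the evaluated architecture: width-5 kernels in both
#' convolutional layers, 10 then 20 kernels, pool width 2, 500 hidden
#' units. Loss is categorical cross-entropy minimised by mini-batch SGD;
#' weights start uniform scaled by fan-in; all randomness (initialisation
#' and per-epoch shuffling) is driven by `seed`.
#'
#' @param inputLength feature count L (columns of the boolean matrix).
#' @param nClasses number of classes.
#' @param k1,n1 first-layer kernel width and count.
#' @param k2,n2 second-layer kernel width and count.
#' @param pool pooling width (fixed at 2).
#' @param hidden hidden units of the perceptron.
#' @param learningRate,batchSize,epochs SGD settings.
#' @param seed integer RNG seed.
#' @return validated config list.
#' @export
cnnConfig <- function(inputLength, nClasses, k1 = 5L, n1 = 10L, k2 = 5L,
                      n2 = 20L, pool = 2L, hidden = 500L,
                      learningRate = 0.1, batchSize = 20L, epochs = 200L,
                      seed = 1L) {
  cfg <- list(inputLength = as.integer(inputLength),
              nClasses = as.integer(nClasses), k1 = as.integer(k1),
              n1 = as.integer(n1), k2 = as.integer(k2),
              n2 = as.integer(n2), pool = as.integer(pool),
              hidden = as.integer(hidden), learningRate = learningRate,
              epochs = as.integer(epochs), batchSize = as.integer(batchSize),
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(inputLength, nClasses, k1, n1, k2, n2, hidden, epochs,
              batchSize) < 1L) || learningRate <= 0)
      stop("all CNN hyperparameters must be positive", call. = FALSE)
    if (pool != 2L) stop("pool width is fixed at 2", call. = FALSE)
    if (inputLength < k1)
      stop(sprintf("input length %d is shorter than kernel width %d",
                   inputLength, k1), call. = FALSE)
  })
  d <- cnnDimensions(cfg$inputLength, cfg$k1, cfg$k2, cfg$pool, cfg$n2)
  if (d$pool1 < cfg$k2)
    stop(sprintf("pooled length %d is shorter than second kernel width %d",
                 d$pool1, cfg$k2), call. = FALSE)
  if (d$pool2 < 1L)
    stop("second pooled length is empty; reduce kernel widths",
         call. = FALSE)
  cfg
}

#' Forward pass of one convolutional layer
#'
#' Valid (no-padding) cross-correlation with stride 1 followed by the
#' logistic function. Single-channel: `x` is a numeric vector and
#' `kernels` an n-by-k matrix. Multi-channel: `x` is a channels-by-L matrix
#' and `kernels` an n-by-C-by-k array; channel contributions are summed
#' before the bias and activation.
#'
#' @param x input vector (or channels-by-L matrix).
#' @param kernels kernel matrix (or array, see above).
#' @param biases numeric vector, one per kernel.
#' @return matrix n-by-(L-k+1) of activated outputs.
#' @examples
#' convLayerForward(c(1, 1, 1, 1, 1, 0, 0), matrix(1, 1, 5), 0)
#' @export
convLayerForward <- function(x, kernels, biases) {
  if (is.matrix(x) && length(dim(kernels)) == 3L) {
    C <- nrow(x); L <- ncol(x)
    n <- dim(kernels)[1L]; k <- dim(kernels)[3L]
    if (dim(kernels)[2L] != C)
      stop("kernel channel count differs from input channels",
           call. = FALSE)
    if (L < k)
      stop(sprintf("input length %d is shorter than kernel width %d", L, k),
           call. = FALSE)
    W <- L - k + 1L
    z <- matrix(0, n, W)
    for (ch in seq_len(C))
      z <- z + .convCross(x[ch, ], kernels[, ch, , drop = FALSE][, 1L, ,
                                                                 drop = TRUE])
    .sigmoid(z + biases)
  } else {
    if (!is.matrix(kernels)) kernels <- matrix(kernels, nrow = 1L)
    L <- length(x); k <- ncol(kernels)
    if (L < k)
      stop(sprintf("input length %d is shorter than kernel width %d", L, k),
           call. = FALSE)
    .sigmoid(.convCross(x, kernels) + biases)
  }
}

## Raw cross-correlation of a vector with each kernel row: n x (L-k+1).
.convCross <- function(x, kernels) {
  if (!is.matrix(kernels)) kernels <- matrix(kernels, nrow = 1L)
  k <- ncol(kernels)
  W <- length(x) - k + 1L
  xc <- vapply(seq_len(k) - 1L, function(a) x[seq_len(W) + a],
               numeric(W))            # W x k
  kernels %*% t(matrix(xc, ncol = k))
}

#' Max-pooling with non-overlapping windows
#'
#' Takes the maximum over consecutive windows of width `pool`; a trailing
#' partial window is dropped (floor-length policy), so the output length is
#' `floor(length(f)/pool)`. A matrix input is pooled along columns, per
#' row.
#'
#' @param f numeric vector or matrix (rows = kernels/channels).
#' @param pool window width.
#' @return pooled vector or matrix.
#' @examples
#' maxPool(c(0.2, 0.8, 0.5, 0.4))  # 0.8 0.5
#' maxPool(c(0.9, 0.1, 0.3))       # 0.9 (trailing 0.3 dropped)
#' @export
maxPool <- function(f, pool = 2L) {
  if (is.matrix(f)) {
    P <- ncol(f) %/% pool
    if (P == 0L) return(f[, 0L, drop = FALSE])
    out <- vapply(seq_len(P), function(t)
      apply(f[, (t - 1L) * pool + seq_len(pool), drop = FALSE], 1L, max),
      numeric(nrow(f)))
    matrix(out, nrow = nrow(f))
  } else {
    if (length(f) == 0L) stop("empty input", call. = FALSE)
    P <- length(f) %/% pool
    if (P == 0L) return(numeric(0))
    m <- matrix(f[seq_len(P * pool)], nrow = pool)
    apply(m, 2L, max)
  }
}

# ---- batched internal forward/backward -----------------------------------

## Uniform initialisation, scale chosen per layer: first-layer kernels
## start in +-1 so that width-k windows of 0/1 inputs give pre-activations
## spanning the responsive range of the logistic (tiny kernels leave the
## downstream activations almost constant across samples and SGD stalls at
## the class prior); deeper layers are scaled down by fan-in as usual.
.cnnInit <- function(cfg) {
  d <- cnnDimensions(cfg$inputLength, cfg$k1, cfg$k2, cfg$pool, cfg$n2)
  u <- function(n, scale) stats::runif(n, -1, 1) * scale
  list(W1 = matrix(u(cfg$n1 * cfg$k1, 1), cfg$n1, cfg$k1),
       b1 = numeric(cfg$n1),
       W2 = matrix(u(cfg$n2 * cfg$n1 * cfg$k2, sqrt(6 / (cfg$n1 * cfg$k2))),
                   cfg$n2, cfg$n1 * cfg$k2),
       b2 = numeric(cfg$n2),
       M1 = matrix(u(d$flatten * cfg$hidden, 1 / sqrt(d$flatten)),
                   d$flatten, cfg$hidden),
       bh = numeric(cfg$hidden),
       M2 = matrix(u(cfg$hidden * cfg$nClasses, 1 / sqrt(cfg$hidden)),
                   cfg$hidden, cfg$nClasses),
       bo = numeric(cfg$nClasses))
}

.addRowwise <- function(m, v) m + matrix(v, nrow(m), length(v), byrow = TRUE)

## X: B x L matrix. Returns softmax probabilities and (optionally) the
## cache needed for backprop. Intermediate activations are stored as
## (B*positions) x kernels matrices, sample index fastest.
.cnnForward <- function(par, cfg, X, cache = FALSE) {
  B <- nrow(X)
  d <- cnnDimensions(cfg$inputLength, cfg$k1, cfg$k2, cfg$pool, cfg$n2)
  W1l <- d$conv1; P1 <- d$pool1; W2l <- d$conv2; P2 <- d$pool2

  idx1 <- as.vector(outer(seq_len(W1l), seq_len(cfg$k1) - 1L, "+"))
  XC1 <- matrix(X[, idx1, drop = FALSE], nrow = B * W1l)     # (B*W1) x k1
  A1 <- .sigmoid(.addRowwise(XC1 %*% t(par$W1), par$b1))     # (B*W1) x n1

  r1 <- as.vector(outer(seq_len(B), (2L * seq_len(P1) - 2L) * B, "+"))
  A1a <- A1[r1, , drop = FALSE]
  A1b <- A1[r1 + B, , drop = FALSE]
  take1 <- A1a >= A1b
  A1p <- pmax(A1a, A1b)                                      # (B*P1) x n1

  XC2 <- matrix(0, B * W2l, cfg$n1 * cfg$k2)
  ra <- vector("list", cfg$k2)
  for (a in seq_len(cfg$k2)) {
    ra[[a]] <- as.vector(outer(seq_len(B), (seq_len(W2l) - 2L + a) * B, "+"))
    XC2[, (a - 1L) * cfg$n1 + seq_len(cfg$n1)] <- A1p[ra[[a]], , drop = FALSE]
  }
  A2 <- .sigmoid(.addRowwise(XC2 %*% t(par$W2), par$b2))     # (B*W2) x n2

  r2 <- as.vector(outer(seq_len(B), (2L * seq_len(P2) - 2L) * B, "+"))
  A2a <- A2[r2, , drop = FALSE]
  A2b <- A2[r2 + B, , drop = FALSE]
  take2 <- A2a >= A2b
  A2p <- pmax(A2a, A2b)                                      # (B*P2) x n2

  Y <- matrix(as.vector(A2p), nrow = B)                      # B x flatten
  H <- tanh(.addRowwise(Y %*% par$M1, par$bh))
  Z <- .addRowwise(H %*% par$M2, par$bo)
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  P <- E / rowSums(E)

  if (!cache) return(P)
  list(P = P, H = H, Y = Y, A2 = A2, take2 = take2, r2 = r2,
       XC2 = XC2, ra = ra, A1 = A1, take1 = take1, r1 = r1,
       XC1 = XC1, dims = d, B = B)
}

## Mean categorical cross-entropy and analytic gradients.
.cnnLossGrad <- function(par, cfg, X, Yhot) {
  fw <- .cnnForward(par, cfg, X, cache = TRUE)
  B <- fw$B
  loss <- -sum(Yhot * log(pmax(fw$P, 1e-300))) / B

  dZ <- (fw$P - Yhot) / B
  gM2 <- t(fw$H) %*% dZ
  gbo <- colSums(dZ)
  dH <- dZ %*% t(par$M2)
  dZh <- dH * (1 - fw$H^2)
  gM1 <- t(fw$Y) %*% dZh
  gbh <- colSums(dZh)
  dY <- dZh %*% t(par$M1)

  d <- fw$dims
  dA2p <- matrix(as.vector(dY), nrow = B * d$pool2)          # (B*P2) x n2
  dA2 <- matrix(0, B * d$conv2, cfg$n2)
  dA2[fw$r2, ] <- dA2p * fw$take2
  dA2[fw$r2 + B, ] <- dA2[fw$r2 + B, , drop = FALSE] + dA2p * !fw$take2
  A2 <- fw$A2
  dZ2 <- dA2 * A2 * (1 - A2)
  gW2 <- t(dZ2) %*% fw$XC2
  gb2 <- colSums(dZ2)
  dXC2 <- dZ2 %*% par$W2                                     # (B*W2) x n1*k2

  ## scatter-add the column blocks of dXC2 back onto the pooled C1 output
  dA1p <- matrix(0, B * d$pool1, cfg$n1)
  for (a in seq_len(cfg$k2)) {
    blk <- dXC2[, (a - 1L) * cfg$n1 + seq_len(cfg$n1), drop = FALSE]
    tab <- rowsum(blk, fw$ra[[a]], reorder = FALSE)
    acc <- matrix(0, B * d$pool1, cfg$n1)
    acc[as.integer(rownames(tab)), ] <- tab
    dA1p <- dA1p + acc
  }

  dA1 <- matrix(0, B * d$conv1, cfg$n1)
  dA1[fw$r1, ] <- dA1p * fw$take1
  dA1[fw$r1 + B, ] <- dA1[fw$r1 + B, , drop = FALSE] + dA1p * !fw$take1
  A1 <- fw$A1
  dZ1 <- dA1 * A1 * (1 - A1)
  gW1 <- t(dZ1) %*% fw$XC1
  gb1 <- colSums(dZ1)

  list(loss = loss,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    M1 = gM1, bh = gbh, M2 = gM2, bo = gbo))
}

.oneHot <- function(labels, classOrder) {
  m <- matrix(0, length(labels), length(classOrder))
  m[cbind(seq_along(labels), match(labels, classOrder))] <- 1
  m
}

#' Train the convolutional classifier
#'
#' Mini-batch stochastic gradient descent on the categorical cross-entropy
#' of the softmax output. Initialisation and per-epoch shuffling are seeded
#' from `config$seed`, so identical inputs and seed give bit-identical
#' models. The fragment column order and the (sorted) class-label order are
#' frozen into the returned model.
#'
#' @param x a [FeatureMatrix-class] (or plain 0/1 matrix with column
#'   names).
#' @param labels character vector of class labels, one per row of `x`.
#' @param config a [cnnConfig()] list; its `inputLength`/`nClasses` must
#'   match the data.
#' @return A [CnnModel-class].
#' @seealso [predict,CnnModel-method], [writeCnnModel()]
#' @export
trainCnn <- function(x, labels, config) {
  X <- if (is(x, "FeatureMatrix")) x@values else x
  codes <- if (is(x, "FeatureMatrix")) x@fragments@canonicalCode else
    (colnames(X) %||% sprintf("f%d", seq_len(ncol(X))))
  if (!all(X %in% c(0L, 1L)))
    stop("feature matrix values must be boolean 0/1", call. = FALSE)
  if (length(labels) != nrow(X))
    stop(sprintf("label count %d differs from matrix rows %d",
                 length(labels), nrow(X)), call. = FALSE)
  if (anyNA(labels)) stop("missing class labels", call. = FALSE)
  classOrder <- sort(unique(labels))
  if (length(classOrder) != config$nClasses)
    stop(sprintf("config expects %d classes but data has %d",
                 config$nClasses, length(classOrder)), call. = FALSE)
  if (ncol(X) != config$inputLength)
    stop(sprintf("config expects input length %d but matrix has %d columns",
                 config$inputLength, ncol(X)), call. = FALSE)
  storage.mode(X) <- "double"
  Yhot <- .oneHot(labels, classOrder)

  set.seed(config$seed)
  par <- .cnnInit(config)
  n <- nrow(X)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batchSize)
    for (s in starts) {
      take <- ord[s:min(s + config$batchSize - 1L, n)]
      lg <- .cnnLossGrad(par, config, X[take, , drop = FALSE],
                         Yhot[take, , drop = FALSE])
      for (nm in names(par))
        par[[nm]] <- par[[nm]] - config$learningRate * lg$grads[[nm]]
    }
  }
  new("CnnModel", config = config, W1 = par$W1, b1 = par$b1, W2 = par$W2,
      b2 = par$b2, M1 = par$M1, bh = par$bh, M2 = par$M2, bo = par$bo,
      classLabels = classOrder, fragmentCodes = codes)
}

.modelPar <- function(object)
  list(W1 = object@W1, b1 = object@b1, W2 = object@W2, b2 = object@b2,
       M1 = object@M1, bh = object@bh, M2 = object@M2, bo = object@bo)

#' Predict classes for feature vectors
#'
#' Runs the forward pass and assigns each row the argmax class; ties are
#' broken toward the lowest class index in the model's class order.
#'
#' @param object a [CnnModel-class].
#' @param newdata a [FeatureMatrix-class] whose column order matches the
#'   model's frozen fragment codes (checked), or a plain 0/1 matrix of
#'   matching width.
#' @param ... ignored.
#' @return list with `class` (character vector) and `prob` (rows =
#'   samples, columns = classes).
#' @export
setMethod("predict", "CnnModel", function(object, newdata, ...) {
  X <- if (is(newdata, "FeatureMatrix")) newdata@values else newdata
  if (is(newdata, "FeatureMatrix") &&
      !identical(newdata@fragments@canonicalCode, object@fragmentCodes))
    stop("feature space mismatch: matrix columns differ from the model's frozen fragment codes",
         call. = FALSE)
  if (ncol(X) != object@config$inputLength)
    stop(sprintf("feature space mismatch: model expects %d features, got %d",
                 object@config$inputLength, ncol(X)), call. = FALSE)
  storage.mode(X) <- "double"
  P <- .cnnForward(.modelPar(object), object@config, X)
  dimnames(P) <- list(rownames(X), object@classLabels)
  list(class = object@classLabels[max.col(P, ties.method = "first")],
       prob = P)
})

#' Forward pass through a trained model
#'
#' @param model a [CnnModel-class].
#' @param x a single boolean feature vector of the model's input length.
#' @return probability vector over classes (sums to 1).
#' @export
forwardCnn <- function(model, x) {
  if (length(x) != model@config$inputLength)
    stop(sprintf("expected input length %d, got %d",
                 model@config$inputLength, length(x)), call. = FALSE)
  p <- .cnnForward(.modelPar(model), model@config,
                   matrix(as.numeric(x), nrow = 1L))
  structure(as.numeric(p), names = model@classLabels)
}

# ---- model serialization --------------------------------------------------

#' Save / load a trained model
#'
#' The model is stored as a single JSON archive holding the config, class
#' order, frozen fragment codes, and all weight arrays with shape metadata
#' at full floating-point precision, so a reloaded model reproduces
#' predictions bit-exactly.
#'
#' @param model a [CnnModel-class].
#' @param path file path (.json).
#' @return `writeCnnModel()`: the path, invisibly; `readCnnModel()`: the
#'   model.
#' @export
writeCnnModel <- function(model, path) {
  par <- .modelPar(model)
  arrays <- lapply(par, function(w) {
    list(dim = if (is.matrix(w)) dim(w) else length(w),
         values = sprintf("%.17g", as.numeric(w)))
  })
  obj <- list(format = "rnaFragNet-cnn-model-v1",
              config = model@config,
              classLabels = model@classLabels,
              fragmentCodes = model@fragmentCodes,
              arrays = arrays)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCnnModel
#' @export
readCnnModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "rnaFragNet-cnn-model-v1"))
    stop("not a model file: ", path, call. = FALSE)
  cfg <- as.list(obj$config)
  intFields <- c("inputLength", "nClasses", "k1", "n1", "k2", "n2", "pool",
                 "hidden", "epochs", "batchSize", "seed")
  for (f in intFields) cfg[[f]] <- as.integer(cfg[[f]])
  arr <- function(nm) {
    a <- obj$arrays[[nm]]
    v <- as.numeric(a$values)
    if (length(a$dim) == 2L) matrix(v, a$dim[1L], a$dim[2L]) else v
  }
  new("CnnModel", config = cfg, W1 = arr("W1"), b1 = arr("b1"),
      W2 = arr("W2"), b2 = arr("b2"), M1 = arr("M1"), bh = arr("bh"),
      M2 = arr("M2"), bo = arr("bo"),
      classLabels = as.character(obj$classLabels),
      fragmentCodes = as.character(obj$fragmentCodes))
}
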
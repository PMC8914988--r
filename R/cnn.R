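#' Specification of the three-block convolutional classifier
#'
#' The network takes a raw 20x10x1 pressure frame and applies three blocks,
#' each: 3x3 convolution (stride 1, zero padding 1; 64 / 128 / 256 output
#' channels) -> batch normalization -> ReLU -> 2x2 max pooling (stride 2)
#' with spatial paddings (0,1), (1,1) and none per block. The 3x2x256
#' feature map is flattened (1536 values) and one fully connected layer
#' produces the class scores. Pooling pads conceptually with -Inf so padding
#' never wins the max; on the non-negative post-ReLU activations this equals
#' zero padding.
#'
#' @param inputRows,inputCols input frame size, default 20 x 10.
#' @param channels output channels of the three blocks.
#' @param poolPad list of (rowPad, colPad) per block.
#' @param nClasses number of activity classes, default 18.
#' @param lr Adam learning rate, default 1e-4.
#' @param epochs training epochs, default 30.
#' @param batchSize minibatch size, default 40.
#' @param inputScale multiplicative input scaling; default 1/4095 maps the
#'   12-bit sensor range to [0, 1].
#' @return list of class \code{"CNNSpec"} including the verified per-block
#'   shape \code{trace}.
#' @examples
#' cnnSpec()$trace   # 20x10 -> 10x6 -> 6x4 -> 3x2
#' @export
cnnSpec <- function(inputRows = 20L, inputCols = 10L,
                    channels = c(64L, 128L, 256L),
                    poolPad = list(c(0L, 1L), c(1L, 1L), c(0L, 0L)),
                    nClasses = 18L, lr = 1e-4, epochs = 30L,
                    batchSize = 40L, inputScale = 1 / 4095) {
  stopifnot(length(channels) == length(poolPad))
  h <- inputRows; w <- inputCols
  trace <- list(c(h, w))
  for (bl in seq_along(channels)) {
    ph <- poolPad[[bl]][1]; pw <- poolPad[[bl]][2]
    if ((h + 2 * ph) %% 2 != 0 || (w + 2 * pw) %% 2 != 0)
      stop(sprintf("block %d: pooled extent (%d, %d) is not divisible by 2",
                   bl, h + 2 * ph, w + 2 * pw))
    h <- (h + 2 * ph) %/% 2L; w <- (w + 2 * pw) %/% 2L
    if (h < 1 || w < 1) stop("input too small for the pooling pyramid")
    trace[[bl + 1]] <- c(h, w)
  }
  structure(list(inputRows = as.integer(inputRows),
                 inputCols = as.integer(inputCols),
                 channels = as.integer(channels), poolPad = poolPad,
                 nClasses = as.integer(nClasses), lr = lr,
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 inputScale = inputScale, trace = trace,
                 flatFeatures = as.integer(h * w * channels[length(channels)])),
            class = "CNNSpec")
}

#' Build (initialize) the CNN
#'
#' He-initialized convolution and fully connected weights, unit-gamma /
#' zero-beta batch norm, zero running means and unit running variances.
#' Deterministic under \code{seed}.
#'
#' @param spec a [cnnSpec()].
#' @param seed integer RNG seed for the initialization.
#' @return list of class \code{"CNNModel"}.
#' @export
buildCnn <- function(spec = cnnSpec(), seed = 1L) {
  stopifnot(inherits(spec, "CNNSpec"))
  set.seed(seed)
  params <- list()
  cin <- 1L
  for (bl in seq_along(spec$channels)) {
    cout <- spec$channels[bl]
    params[[paste0("convW", bl)]] <-
      array(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))), c(3, 3, cin, cout))
    params[[paste0("convB", bl)]] <- numeric(cout)
    params[[paste0("bnG", bl)]] <- rep(1, cout)
    params[[paste0("bnB", bl)]] <- numeric(cout)
    cin <- cout
  }
  params$fcW <- matrix(rnorm(spec$nClasses * spec$flatFeatures, 0,
                             sqrt(2 / spec$flatFeatures)),
                       spec$nClasses, spec$flatFeatures)
  params$fcB <- numeric(spec$nClasses)
  running <- list()
  for (bl in seq_along(spec$channels)) {
    running[[paste0("mean", bl)]] <- numeric(spec$channels[bl])
    running[[paste0("var", bl)]] <- rep(1, spec$channels[bl])
  }
  structure(list(spec = spec, params = params, running = running,
                 classes = NULL), class = "CNNModel")
}

#' @export
print.CNNModel <- function(x, ...) {
  tr <- vapply(x$spec$trace, function(d) paste(d, collapse = "x"), "")
  cat("CNNModel:", paste(tr, collapse = " -> "), "\n")
  cat(sprintf("  channels %s, %d classes, %d parameters\n",
              paste(x$spec$channels, collapse = "/"), x$spec$nClasses,
              nParameters(x)))
  invisible(x)
}

#' Total trainable parameter count
#' @param model a \code{CNNModel}.
#' @return integer scalar; a pure function of the spec.
#' @export
nParameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

## ---- layer primitives -----------------------------------------------------
## tensors are arrays [H, W, B, C]: with channels last, the "HWB x C" matrix
## view used for every channel contraction is a plain (copy-only) reshape

toMat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  x
}
toArr <- function(m, h, w, b) {
  array(m, c(h, w, b, ncol(m)))
}

## memoized im2col index matrices keyed by the input dims; entry [row, col]
## with row = (r, c, b) and col = (ki, kj, ci) holds the linear index of
## pad[r + ki - 1, c + kj - 1, b, ci], matching the (3, 3, cin, cout) weight
## layout flattened to a (9*cin, cout) matrix
.im2colCache <- new.env(parent = emptyenv())

im2colIndex <- function(h, w, bt, cin) {
  key <- paste(h, w, bt, cin)
  hit <- .im2colCache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L; wp <- w + 2L
  r0 <- rep.int(0:(h - 1), w * bt)
  c0 <- rep.int(rep(0:(w - 1), each = h), bt)
  b0 <- rep(0:(bt - 1), each = h * w)
  rowBase <- r0 + hp * c0 + hp * wp * b0
  ki <- rep.int(0:2, 3 * cin)
  kj <- rep.int(rep(0:2, each = 3), cin)
  ci <- rep(0:(cin - 1), each = 9)
  colBase <- ki + hp * kj + hp * wp * bt * ci
  idx <- outer(rowBase, colBase, `+`) + 1L
  .im2colCache[[key]] <- idx
  idx
}

## 3x3 stride-1 pad-1 convolution as one (HWB x 9Cin) %*% (9Cin x Cout)
## product over the gathered patch matrix
convForward <- function(x, W, b) {
  d <- dim(x); h <- d[1]; w <- d[2]; bt <- d[3]; cin <- d[4]
  pad <- array(0, c(h + 2, w + 2, bt, cin))
  pad[2:(h + 1), 2:(w + 1), , ] <- x
  cout <- dim(W)[4]
  idx <- im2colIndex(h, w, bt, cin)
  xcol <- pad[idx]
  dim(xcol) <- dim(idx)
  ym <- xcol %*% matrix(W, 9 * cin, cout)
  ym <- sweep(ym, 2, b, "+")
  list(out = toArr(ym, h, w, bt), xcol = xcol, idx = idx,
       padDim = dim(pad))
}

convBackward <- function(dy, cache, W) {
  d <- dim(dy); h <- d[1]; w <- d[2]; bt <- d[3]; cout <- d[4]
  cin <- dim(W)[3]
  dym <- toMat(dy)
  db <- colSums(dym)
  dW <- array(crossprod(cache$xcol, dym), dim(W))
  dxcol <- dym %*% t(matrix(W, 9 * cin, cout))
  ## col2im: scatter-add the nine offset blocks back onto the padded grid;
  ## indices within one offset are unique, so vector indexing accumulates
  dpad <- numeric(prod(cache$padDim))
  for (k in 1:9) {
    cols <- seq.int(k, 9 * cin, by = 9)
    vidx <- as.vector(cache$idx[, cols])
    dpad[vidx] <- dpad[vidx] + as.vector(dxcol[, cols])
  }
  dim(dpad) <- cache$padDim
  list(dx = dpad[2:(h + 1), 2:(w + 1), , , drop = FALSE], dW = dW, db = db)
}

bnForward <- function(x, gamma, beta, running, train, momentum = 0.1,
                      eps = 1e-5) {
  d <- dim(x)
  m <- toMat(x)
  if (train) {
    mu <- colMeans(m)
    va <- colMeans(m^2) - mu^2
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * va
  } else {
    mu <- running$mean; va <- running$var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(m, 2, mu, "-"), 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = toArr(y, d[1], d[2], d[3]), xhat = xhat, invstd = invstd,
       running = running, dims = d)
}

bnBackward <- function(dy, cache, gamma) {
  d <- cache$dims
  dym <- toMat(dy)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  n <- nrow(dym)
  t1 <- sweep(dym, 2, colMeans(dym), "-")
  t2 <- sweep(cache$xhat, 2, colMeans(dym * cache$xhat), "*")
  dxm <- sweep(t1 - t2, 2, gamma * cache$invstd, "*")
  list(dx = toArr(dxm, d[1], d[2], d[3]), dgamma = dgamma, dbeta = dbeta)
}

## 2x2 stride-2 max pooling with per-axis spatial padding; the pad value is
## -Inf so padded positions can never win the max
poolForward <- function(x, padH, padW) {
  d <- dim(x); h <- d[1]; w <- d[2]
  hp <- h + 2 * padH; wp <- w + 2 * padW
  pad <- array(-Inf, c(hp, wp, d[3], d[4]))
  pad[padH + seq_len(h), padW + seq_len(w), , ] <- x
  ro <- list(seq(1, hp, 2), seq(2, hp, 2))
  co <- list(seq(1, wp, 2), seq(2, wp, 2))
  cand <- list(pad[ro[[1]], co[[1]], , , drop = FALSE],
               pad[ro[[2]], co[[1]], , , drop = FALSE],
               pad[ro[[1]], co[[2]], , , drop = FALSE],
               pad[ro[[2]], co[[2]], , , drop = FALSE])
  out <- pmax(cand[[1]], cand[[2]], cand[[3]], cand[[4]])
  ## first maximum wins: assign in reverse priority so candidate 1 overwrites
  arg <- array(4L, dim(out))
  arg[cand[[3]] == out] <- 3L
  arg[cand[[2]] == out] <- 2L
  arg[cand[[1]] == out] <- 1L
  list(out = out, arg = arg, inDim = d, padH = padH, padW = padW)
}

poolBackward <- function(dy, cache) {
  d <- cache$inDim
  hp <- d[1] + 2 * cache$padH; wp <- d[2] + 2 * cache$padW
  g <- array(0, c(hp, wp, d[3], d[4]))
  ro <- list(seq(1, hp, 2), seq(2, hp, 2))
  co <- list(seq(1, wp, 2), seq(2, wp, 2))
  sel <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (k in 1:4) {
    blk <- g[ro[[sel[[k]][1]]], co[[sel[[k]][2]]], , , drop = FALSE]
    use <- cache$arg == k
    blk[use] <- blk[use] + dy[use]
    g[ro[[sel[[k]][1]]], co[[sel[[k]][2]]], , ] <- blk
  }
  g[cache$padH + seq_len(d[1]), cache$padW + seq_len(d[2]), , , drop = FALSE]
}

## full forward pass; returns logits (nClasses x B) and per-layer caches
cnnForward <- function(model, x, train = FALSE) {
  spec <- model$spec; p <- model$params
  caches <- list()
  a <- x
  for (bl in seq_along(spec$channels)) {
    cv <- convForward(a, p[[paste0("convW", bl)]], p[[paste0("convB", bl)]])
    rn <- list(mean = model$running[[paste0("mean", bl)]],
               var = model$running[[paste0("var", bl)]])
    bn <- bnForward(cv$out, p[[paste0("bnG", bl)]], p[[paste0("bnB", bl)]],
                    rn, train)
    if (train) {
      model$running[[paste0("mean", bl)]] <- bn$running$mean
      model$running[[paste0("var", bl)]] <- bn$running$var
    }
    relu <- pmax(bn$out, 0)
    pl <- poolForward(relu, spec$poolPad[[bl]][1], spec$poolPad[[bl]][2])
    caches[[bl]] <- list(conv = cv, bn = bn, reluMask = bn$out > 0, pool = pl)
    a <- pl$out
  }
  d <- dim(a)                               # [h, w, batch, channels]
  fmap <- aperm(a, c(1, 2, 4, 3))           # [h, w, channels, batch]
  flat <- matrix(fmap, d[1] * d[2] * d[4], d[3])
  logits <- sweep(p$fcW %*% flat, 1, p$fcB, "+")
  list(logits = logits, flat = flat, featureMap = fmap, caches = caches,
       model = model)
}

## softmax cross-entropy; yIdx are 1-based class indices
softmaxLoss <- function(logits, yIdx) {
  z <- sweep(logits, 2, apply(logits, 2, max), "-")
  ez <- exp(z)
  probs <- sweep(ez, 2, colSums(ez), "/")
  b <- ncol(logits)
  loss <- -mean(log(pmax(probs[cbind(yIdx, seq_len(b))], 1e-300)))
  dlog <- probs
  dlog[cbind(yIdx, seq_len(b))] <- dlog[cbind(yIdx, seq_len(b))] - 1
  list(loss = loss, dlogits = dlog / b, probs = probs)
}

cnnBackward <- function(model, fwd, dlogits) {
  spec <- model$spec; p <- model$params
  grads <- list(fcW = dlogits %*% t(fwd$flat), fcB = rowSums(dlogits))
  dflat <- t(p$fcW) %*% dlogits
  da <- aperm(array(dflat, dim(fwd$featureMap)), c(1, 2, 4, 3))
  for (bl in rev(seq_along(spec$channels))) {
    ch <- fwd$caches[[bl]]
    da <- poolBackward(da, ch$pool)
    da <- da * ch$reluMask
    bnb <- bnBackward(da, ch$bn, p[[paste0("bnG", bl)]])
    grads[[paste0("bnG", bl)]] <- bnb$dgamma
    grads[[paste0("bnB", bl)]] <- bnb$dbeta
    cvb <- convBackward(bnb$dx, ch$conv, p[[paste0("convW", bl)]])
    grads[[paste0("convW", bl)]] <- cvb$dW
    grads[[paste0("convB", bl)]] <- cvb$db
    da <- cvb$dx
  }
  grads
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## coerce frames / arrays to the scaled [H, W, 1, N] input tensor
asInputTensor <- function(x, spec) {
  if (is(x, "SleeveFrames")) x <- frameArray(x)
  d <- dim(x)
  if (length(d) == 3L) x <- array(x, c(d, 1L))   # [H, W, N, channel]
  d <- dim(x)
  if (d[1] != spec$inputRows || d[2] != spec$inputCols || d[4] != 1L)
    stop(sprintf("input shape %s incompatible with spec %dx%dx1",
                 paste(d, collapse = "x"), spec$inputRows, spec$inputCols))
  x * spec$inputScale
}

#' Train the CNN
#'
#' Minibatch training with softmax cross-entropy and Adam (learning rate and
#' schedule from the spec: default 1e-4, 30 epochs, batch size 40). Batch
#' normalization uses batch statistics during training and exponentially
#' averaged running statistics at prediction time. Fully reproducible from
#' \code{seed} on one machine.
#'
#' @param model a [buildCnn()] model.
#' @param x a [SleeveFrames-class] or a \code{[H, W, N]} array of raw frames.
#' @param labels class labels (>= 2 distinct values).
#' @param epochs,batchSize,lr overrides of the spec values.
#' @param seed RNG seed governing the minibatch shuffle.
#' @param verbose print per-epoch loss.
#' @return the trained model; \code{$history} holds per-epoch mean loss and
#'   training accuracy.
#' @export
trainCnn <- function(model, x, labels, epochs = NULL, batchSize = NULL,
                     lr = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "CNNModel"))
  spec <- model$spec
  epochs <- if (is.null(epochs)) spec$epochs else epochs
  batchSize <- if (is.null(batchSize)) spec$batchSize else batchSize
  lr <- if (is.null(lr)) spec$lr else lr
  xt <- asInputTensor(x, spec)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2) stop("training needs at least 2 classes")
  if (nlevels(y) > spec$nClasses)
    stop("more classes than the network's output size")
  yIdx <- as.integer(y)
  n <- dim(xt)[3]
  state <- adamInit(model$params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    losses <- c(); correct <- 0L
    for (start in seq(1, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1, n)]
      xb <- xt[, , idx, , drop = FALSE]
      fwd <- cnnForward(model, xb, train = TRUE)
      model <- fwd$model                     # running BN stats updated
      sl <- softmaxLoss(fwd$logits, yIdx[idx])
      grads <- cnnBackward(model, fwd, sl$dlogits)
      upd <- adamStep(model$params, grads, state, lr)
      model$params <- upd$params; state <- upd$state
      losses <- c(losses, sl$loss)
      correct <- correct + sum(max.col(t(fwd$logits)) == yIdx[idx])
    }
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                         accuracy = correct / n))
    if (verbose)
      message(sprintf("epoch %2d  loss %.4f  acc %.3f", ep, mean(losses),
                      correct / n))
  }
  model$classes <- levels(y)
  model$history <- history
  model
}

#' Predict activity classes with a trained CNN
#'
#' @param model a trained \code{CNNModel}.
#' @param x frames as in [trainCnn()].
#' @return factor of predicted classes.
#' @export
predictCnn <- function(model, x) {
  if (is.null(model$classes)) stop("model has not been trained")
  xt <- asInputTensor(x, model$spec)
  n <- dim(xt)[3]
  preds <- character(n)
  ## bounded-memory prediction in chunks
  for (start in seq(1, n, by = 200)) {
    idx <- start:min(start + 199, n)
    fwd <- cnnForward(model, xt[, , idx, , drop = FALSE], train = FALSE)
    preds[idx] <- model$classes[max.col(t(fwd$logits))]
  }
  factor(preds, levels = model$classes)
}

#' Cross-validated CNN evaluation on raw frames
#'
#' Runs the same stratified 10-fold or leave-one-subject-out harness as the
#' classical classifiers, but on the raw 20x10 frames (no preprocessing, no
#' feature extraction); the network is re-initialized and re-trained from
#' scratch in every fold. Metrics are averaged over folds and confusion
#' matrices pooled, exactly as in [runKFold()].
#'
#' @param frames a [SleeveFrames-class] dataset.
#' @param scheme "kfold" or "loso".
#' @param k folds for the k-fold scheme.
#' @param spec a [cnnSpec()].
#' @param epochs,batchSize,lr training overrides.
#' @param seed RNG seed (fold assignment, per-fold initialization, shuffles).
#' @return A [SleeveEval-class] with classifier id \code{"cnn"}.
#' @export
evaluateCnn <- function(frames, scheme = c("kfold", "loso"), k = 10L,
                        spec = cnnSpec(), epochs = NULL, batchSize = NULL,
                        lr = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(is(frames, "SleeveFrames"))
  fd <- as.data.frame(frameData(frames))
  y <- droplevels(as.factor(fd$activity))
  lev <- levels(y)
  fold <- if (scheme == "kfold") {
    if (k < 2) stop("k must be >= 2")
    stratifiedFolds(y, k, seed)
  } else {
    us <- unique(fd$subject_id)
    if (length(us) < 2) stop("leave-one-subject-out needs >= 2 subjects")
    match(fd$subject_id, us)
  }
  v <- frameArray(frames)
  folds <- sort(unique(fold))
  pooled <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  per <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    te <- fold == folds[fi]
    model <- buildCnn(spec, seed = seed + fi)
    model <- trainCnn(model, v[, , !te, drop = FALSE], y[!te],
                      epochs = epochs, batchSize = batchSize, lr = lr,
                      seed = seed + 1000L + fi)
    pred <- factor(as.character(predictCnn(model, v[, , te, drop = FALSE])),
                   levels = lev)
    cm <- table(factor(y[te], levels = lev), pred)
    pooled <- pooled + as.matrix(unclass(cm))
    per[[fi]] <- data.frame(fold = folds[fi], n = sum(te), t(macroMetrics(cm)))
  }
  per <- do.call(rbind, per)
  mp <- mean(per$macroP); mr <- mean(per$macroR)
  new("SleeveEval", scheme = scheme, classifier = "cnn",
      accuracy = mean(per$accuracy), macroP = mp, macroR = mr,
      macroF1 = if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0,
      perFold = per, confusion = pooled)
}
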
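# Frame classifier: the six-conv / four-dense network used to label behavior
# video frames, its temporal mean-image preprocessing, augmentation, training
# by SGD with cross-entropy, and per-frame probability prediction.

#' Classifier configuration
#'
#' The reference topology: six 3x3 convolutional layers, each followed by
#' ReLU and 2x2 max pooling with stride 2, dropout 0.2 after the last four
#' convolutional blocks; four dense layers with ReLU after all but the
#' last, dropout 0.3 after the first three; softmax output; cross-entropy
#' minimized by stochastic gradient descent. Input frames are
#' `119 x 150 x 3` patches at full scale. Convolutions use zero-padded
#' "same" borders so that six halvings remain well-defined at both the full
#' and desk-scale input sizes. Augmentation draws rotation, scale and shift
#' uniformly from \[-10, 10\] (degrees / % / %) plus horizontal flips.
#'
#' @param inputShape `c(H, W, C)` (default `c(119, 150, 3)`).
#' @param nConv,kernel,pool,poolStride,nDense architecture constants.
#' @param convFilters integer vector of filter counts per conv layer
#'   (default doubling from 8).
#' @param denseWidths widths of the dense layers excluding the output layer
#'   (default geometrically decreasing); the output width is the class
#'   count.
#' @param dropoutConv,dropoutDense dropout rates (0.2 on the last four conv
#'   blocks, 0.3 on the first three dense layers).
#' @param batchSize,epochs,lr,momentum SGD settings (reference profile: 128
#'   and 150 epochs; learning rate and momentum are free parameters here).
#' @param gradClip global gradient-norm clip applied to each SGD step.
#' @param warmupFrac fraction of total steps over which the learning rate
#'   ramps linearly from zero.
#' @param augmentation list with `rotation`, `scale`, `shift` ranges and
#'   `flip`.
#' @param copiesPerImage range of augmented copies per original image.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return a validated list of class `"ClassifierConfig"`.
#' @export
classifierConfig <- function(inputShape = c(119, 150, 3),
                             nConv = 6L, kernel = c(3, 3), pool = c(2, 2),
                             poolStride = c(2, 2), nDense = 4L,
                             convFilters = NULL, denseWidths = NULL,
                             dropoutConv = 0.2, dropoutDense = 0.3,
                             batchSize = 128L, epochs = 150L, lr = 0.01,
                             momentum = 0.9, gradClip = 5, warmupFrac = 0.1,
                             augmentation = list(rotation = c(-10, 10),
                                                 scale = c(-10, 10),
                                                 shift = c(-10, 10),
                                                 flip = TRUE),
                             copiesPerImage = c(10L, 50L),
                             seed = 0L) {
  stopifnot(length(inputShape) == 3L, all(kernel == c(3, 3)),
            all(pool == c(2, 2)), all(poolStride == c(2, 2)),
            dropoutConv > 0, dropoutConv < 1, dropoutDense > 0,
            dropoutDense < 1, epochs >= 1L, batchSize >= 1L, lr > 0)
  if (is.null(convFilters))
    convFilters <- pmin(64L, 8L * 2L^(floor((seq_len(nConv) - 1) / 2)))
  if (length(convFilters) != nConv)
    stop("convFilters must have one entry per convolutional layer")
  structure(list(inputShape = inputShape, nConv = as.integer(nConv),
                 kernel = kernel, pool = pool, poolStride = poolStride,
                 nDense = as.integer(nDense), convFilters = convFilters,
                 denseWidths = denseWidths, dropoutConv = dropoutConv,
                 dropoutDense = dropoutDense, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 gradClip = gradClip, warmupFrac = warmupFrac,
                 augmentation = augmentation, copiesPerImage = copiesPerImage,
                 seed = as.integer(seed)),
            class = "ClassifierConfig")
}

#' Desk-scale training profile
#'
#' A reduced profile for CPU-bound runs: 64 x 64 x 3 inputs, 15 epochs,
#' batch size 32 and a smaller filter ramp. The reference full-scale
#' profile remains available through [classifierConfig()] defaults.
#'
#' @param ... overrides forwarded to [classifierConfig()].
#' @return a `"ClassifierConfig"`.
#' @export
deskClassifierConfig <- function(...) {
  args <- list(inputShape = c(64, 64, 3), epochs = 15L, batchSize = 32L,
               convFilters = c(8L, 16L, 32L, 64L, 64L, 128L),
               denseWidths = c(256L, 128L, 64L),
               lr = 0.03, momentum = 0.5, ...)
  do.call(classifierConfig, args[!duplicated(names(args), fromLast = TRUE)])
}

#' Temporal mean images
#'
#' For a frame at time t, the mean of frames t-1, t and t+1; the first and
#' last frames are discarded, so `n` frames yield `n - 2` mean images.
#'
#' @param frames numeric array `n x H x W` or `n x H x W x C` with n >= 3.
#' @return array of the same kind with `n - 2` leading entries.
#' @export
makeMeanImages <- function(frames) {
  d <- dim(frames)
  if (is.null(d) || d[1] < 3L) stop("need at least 3 frames")
  n <- d[1]
  idx <- function(i) if (length(d) == 3L) frames[i, , , drop = FALSE]
    else frames[i, , , , drop = FALSE]
  out <- (idx(1:(n - 2)) + idx(2:(n - 1)) + idx(3:n)) / 3
  dim(out) <- c(n - 2L, d[-1])
  out
}

bilinearSample <- function(img, ys, xs) {
  # img: H x W; ys/xs same-length coordinate vectors; zero outside
  H <- nrow(img); W <- ncol(img)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  pick <- function(yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    v <- numeric(length(yy))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  pick(y0, x0) * (1 - fy) * (1 - fx) + pick(y0 + 1, x0) * fy * (1 - fx) +
    pick(y0, x0 + 1) * (1 - fy) * fx + pick(y0 + 1, x0 + 1) * fy * fx
}

#' Affine image transform
#'
#' Rotation about the image center, isotropic scaling, fractional
#' translation and optional horizontal flip, with bilinear interpolation
#' and zero fill outside the source. The identity settings return the image
#' unchanged.
#'
#' @param img `H x W` or `H x W x C` numeric array.
#' @param angleDeg rotation in degrees.
#' @param scale isotropic scale factor.
#' @param shiftFrac `c(dy, dx)` as fractions of the image size.
#' @param flip horizontal mirror.
#' @return transformed image, same shape.
#' @export
affineTransformImage <- function(img, angleDeg = 0, scale = 1,
                                 shiftFrac = c(0, 0), flip = FALSE) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- expand.grid(y = seq_len(H), x = seq_len(W))
  xo <- g$x
  if (flip) xo <- W + 1 - xo
  yo <- g$y - cy - shiftFrac[1] * H
  xo <- xo - cx - shiftFrac[2] * W
  th <- -angleDeg * pi / 180
  ys <- (cos(th) * yo - sin(th) * xo) / scale + cy
  xs <- (sin(th) * yo + cos(th) * xo) / scale + cx
  apply1 <- function(m) matrix(bilinearSample(m, ys, xs), H, W)
  if (length(d) == 2L) apply1(img)
  else {
    out <- img
    for (c_ in seq_len(d[3])) out[, , c_] <- apply1(img[, , c_])
    out
  }
}

#' Augment a labeled image set
#'
#' Generates randomly rotated/scaled/shifted/flipped copies of each image,
#' with per-class copy counts chosen so that the augmented totals are
#' balanced across classes: the target per-class total is the configured
#' copies-per-image times the largest original class count, and smaller
#' classes contribute proportionally more copies per image. Augmentation
#' never alters the label.
#'
#' @param dataset list with `x` (`n x H x W x C`) and `y` (factor).
#' @param cfg a [classifierConfig()]; ranges come from `cfg$augmentation`
#'   and the per-image copy base from `cfg$copiesPerImage[1]`.
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return augmented dataset in the same format.
#' @export
augmentDataset <- function(dataset, cfg, seed = cfg$seed) {
  x <- dataset$x; y <- dataset$y
  d <- dim(x)
  counts <- table(y)
  target <- cfg$copiesPerImage[1] * max(counts)
  aug <- cfg$augmentation
  outX <- list(); outY <- list()
  withr::with_seed(as.integer(seed), {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      reps <- rep(idx, length.out = target)
      imgs <- array(0, dim = c(target, d[2], d[3], d[4]))
      for (k in seq_along(reps)) {
        imgs[k, , , ] <- affineTransformImage(
          x[reps[k], , , ],
          angleDeg = runif(1, aug$rotation[1], aug$rotation[2]),
          scale = 1 + runif(1, aug$scale[1], aug$scale[2]) / 100,
          shiftFrac = runif(2, aug$shift[1], aug$shift[2]) / 100,
          flip = isTRUE(aug$flip) && runif(1) < 0.5)
      }
      outX[[cl]] <- imgs
      outY[[cl]] <- rep(cl, target)
    }
  })
  xAll <- do.call(abind1, outX)
  list(x = xAll, y = factor(unlist(outY), levels = levels(y)),
       classes = levels(y))
}

abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], 0))
  out <- array(0, dim = c(n, d[-1]))
  at <- 0L
  for (p in parts) {
    np <- dim(p)[1]
    out[at + seq_len(np), , , ] <- p
    at <- at + np
  }
  out
}

#' Build the network
#'
#' Assembles the configured topology with He-initialized weights (seeded).
#' Dense widths default to a geometric ramp from the flattened
#' convolutional feature size down to the class count.
#'
#' @param cfg a [classifierConfig()].
#' @param nClasses number of output classes (>= 2).
#' @param classes optional class names stored with the model.
#' @return an object of class `"cnnClassifier"`.
#' @export
buildModel <- function(cfg, nClasses, classes = NULL) {
  stopifnot(nClasses >= 2L)
  H <- cfg$inputShape[1]; W <- cfg$inputShape[2]; C <- cfg$inputShape[3]
  layers <- list()
  glorot <- function(nOut, nIn) {
    # Glorot-uniform: keeps the dense stack's logits small at initialization
    lim <- sqrt(6 / (nIn + nOut))
    matrix(runif(nOut * nIn, -lim, lim), nrow = nOut)
  }
  heInit <- function(nOut, nIn) {
    # He-normal for the ReLU convolution stack: preserves activation
    # variance through depth
    matrix(rnorm(nOut * nIn, sd = sqrt(2 / nIn)), nrow = nOut)
  }
  addConv <- function(layers, cIn, f, dropout) {
    W0 <- heInit(f, 9 * cIn)
    layers[[length(layers) + 1L]] <- list(type = "conv", W = W0,
                                          b = rep(0, f), filters = f,
                                          vW = W0 * 0, vb = rep(0, f))
    layers[[length(layers) + 1L]] <- list(type = "relu")
    layers[[length(layers) + 1L]] <- list(type = "pool")
    if (!is.null(dropout))
      layers[[length(layers) + 1L]] <- list(type = "dropout", rate = dropout)
    layers
  }
  withr::with_seed(cfg$seed, {
    cIn <- C
    for (l in seq_len(cfg$nConv)) {
      drop <- if (l > cfg$nConv - 4L) cfg$dropoutConv else NULL
      layers <- addConv(layers, cIn, cfg$convFilters[l], drop)
      H <- ceiling(H / 2); W <- ceiling(W / 2)
      cIn <- cfg$convFilters[l]
    }
    flat <- H * W * cIn
    layers[[length(layers) + 1L]] <- list(type = "flatten")
    widths <- cfg$denseWidths
    if (is.null(widths)) {
      ramp <- exp(seq(log(max(flat, nClasses + 1)), log(nClasses),
                      length.out = cfg$nDense + 1L))
      widths <- pmax(round(ramp[-c(1, length(ramp))]), nClasses)
    }
    if (length(widths) != cfg$nDense - 1L)
      stop("denseWidths must have nDense - 1 entries")
    dIn <- flat
    for (l in seq_len(cfg$nDense)) {
      dOutW <- if (l < cfg$nDense) widths[l] else nClasses
      W0 <- glorot(dOutW, dIn)
      layers[[length(layers) + 1L]] <- list(type = "dense", W = W0,
                                            b = rep(0, dOutW), units = dOutW,
                                            vW = W0 * 0, vb = rep(0, dOutW))
      if (l < cfg$nDense) {
        layers[[length(layers) + 1L]] <- list(type = "relu")
        if (l <= 3L)
          layers[[length(layers) + 1L]] <- list(type = "dropout",
                                                rate = cfg$dropoutDense)
      }
      dIn <- dOutW
    }
  })
  structure(list(layers = layers, cfg = cfg, nClasses = nClasses,
                 classes = classes), class = "cnnClassifier")
}

#' Architecture summary
#'
#' One row per layer with its type and size parameters, for introspection
#' against the configured topology.
#'
#' @param model a `"cnnClassifier"`.
#' @return data.frame with `layer`, `type`, `size`, `rate`.
#' @export
modelArchitecture <- function(model) {
  rows <- lapply(seq_along(model$layers), function(i) {
    lay <- model$layers[[i]]
    data.frame(layer = i, type = lay$type,
               size = switch(lay$type, conv = lay$filters,
                             dense = lay$units, NA_integer_),
               rate = if (lay$type == "dropout") lay$rate else NA_real_)
  })
  do.call(rbind, rows)
}

#' @export
print.cnnClassifier <- function(x, ...) {
  arch <- modelArchitecture(x)
  cat(sprintf("cnnClassifier: %d conv, %d dense layers, %d classes (input %s)\n",
              sum(arch$type == "conv"), sum(arch$type == "dense"),
              x$nClasses, paste(x$cfg$inputShape, collapse = "x")))
  invisible(x)
}

datasetToBatch <- function(x) {
  # n x H x W x C  ->  H x W x C x n
  aperm(x, c(2, 3, 4, 1))
}

#' Train the frame classifier
#'
#' Minimizes softmax cross-entropy by mini-batch stochastic gradient
#' descent under a fixed seed (shuffling, dropout and initialization are
#' all reproducible). A stratified fraction is held out and the accuracy on
#' it returned. When the training set is smaller than the configured batch
#' size the batch is reduced to the set size with a message.
#'
#' @param dataset list with `x` (`n x H x W x C` in \[0, 1\]) and `y`
#'   (factor).
#' @param cfg a [classifierConfig()]; `cfg$inputShape` must match the data.
#' @param validFraction stratified held-out fraction (default 0.2).
#' @param verbose print per-epoch loss.
#' @return list with `model`, `history` (per-epoch loss), `heldOutAccuracy`
#'   and the held-out `confusion` table.
#' @export
trainClassifier <- function(dataset, cfg, validFraction = 0.2,
                            verbose = FALSE) {
  x <- dataset$x; y <- dataset$y
  d <- dim(x)
  if (!all(d[2:4] == cfg$inputShape))
    stop("dataset images do not match cfg$inputShape")
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  model <- buildModel(cfg, nlevels(y), classes = levels(y))
  yIdx <- as.integer(y)
  withr::with_seed(cfg$seed + 1L, {
    validIdx <- unlist(lapply(split(seq_len(d[1]), y), function(ix) {
      sample(ix, max(1L, round(length(ix) * validFraction)))
    }))
    trainIdx <- setdiff(seq_len(d[1]), validIdx)
    batchSize <- cfg$batchSize
    if (length(trainIdx) < batchSize) {
      message("training set smaller than batch size; reducing batch to ",
              length(trainIdx))
      batchSize <- length(trainIdx)
    }
    history <- numeric(cfg$epochs)
    xb <- datasetToBatch(x)
    # center inputs on the training-set mean; the offset travels with the
    # model so prediction sees the same representation
    model$inputMean <- mean(xb[, , , trainIdx])
    xb <- xb - model$inputMean
    probe <- xb[, , , trainIdx[seq_len(min(64L, length(trainIdx)))],
                drop = FALSE]
    model <- lsuvInit(model, probe)
    nBatch <- length(seq(1L, length(trainIdx), by = batchSize))
    totalSteps <- cfg$epochs * nBatch
    warmSteps <- max(1L, round(cfg$warmupFrac * totalSteps))
    step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(trainIdx)
      losses <- c()
      for (start in seq(1L, length(ord), by = batchSize)) {
        ix <- ord[start:min(start + batchSize - 1L, length(ord))]
        xbatch <- xb[, , , ix, drop = FALSE]
        fw <- nnForward(model, xbatch, train = TRUE)
        ls <- nnLoss(fw$out, yIdx[ix])
        grads <- nnBackward(model, fw$caches, ls$dLogits)
        step <- step + 1L
        lr <- if (step < warmSteps) cfg$lr * step / warmSteps else cfg$lr
        model <- nnUpdate(model, grads, lr, cfg$momentum, cfg$gradClip)
        losses <- c(losses, ls$loss)
      }
      history[ep] <- mean(losses)
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
    }
  })
  probs <- predictModel(model, x[validIdx, , , , drop = FALSE])
  pred <- max.col(probs, ties.method = "first")
  acc <- mean(pred == yIdx[validIdx])
  list(model = model, history = history, heldOutAccuracy = acc,
       confusion = table(truth = y[validIdx],
                         predicted = levels(y)[pred]))
}

#' Predict class probabilities for a stack of images
#'
#' @param model a trained `"cnnClassifier"`.
#' @param x array `n x H x W x C`.
#' @return matrix `n x nClasses` of softmax probabilities.
#' @export
predictModel <- function(model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (!all(dim(x)[2:4] == model$cfg$inputShape))
    stop("input shape does not match the model")
  out <- matrix(0, nrow = dim(x)[1], ncol = model$nClasses)
  step <- 64L
  offset <- model$inputMean
  if (is.null(offset)) offset <- 0
  for (start in seq(1L, dim(x)[1], by = step)) {
    ix <- start:min(start + step - 1L, dim(x)[1])
    xb <- datasetToBatch(x[ix, , , , drop = FALSE]) - offset
    logits <- nnForward(model, xb, train = FALSE)$out
    out[ix, ] <- t(softmaxProbs(logits))
  }
  colnames(out) <- model$classes
  out
}

#' Per-frame class probabilities for a video
#'
#' Applies the temporal mean-image preprocessing, then the classifier. The
#' first and last frames have no mean image and are therefore unlabeled;
#' predictions are aligned to the original frame indices.
#'
#' @param model a trained `"cnnClassifier"`.
#' @param video array `n x H x W` (grayscale, replicated to 3 channels) or
#'   `n x H x W x C`.
#' @return matrix `(n - 2) x nClasses`; `attr(, "frame")` gives the
#'   original frame index of each row.
#' @export
predictStream <- function(model, video) {
  d <- dim(video)
  if (length(d) == 3L) {
    v <- array(0, dim = c(d, model$cfg$inputShape[3]))
    for (c_ in seq_len(model$cfg$inputShape[3])) v[, , , c_] <- video
    video <- v
    d <- dim(video)
  }
  if (!all(d[2:4] == model$cfg$inputShape))
    stop("video frames do not match the model input shape")
  mi <- makeMeanImages(video)
  probs <- predictModel(model, mi)
  attr(probs, "frame") <- seq(2L, d[1] - 1L)
  probs
}
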
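# Minimal CNN engine in base R: im2col convolution on BLAS matrix products,
# 2x2/2 max pooling, inverted dropout, dense layers, softmax cross-entropy,
# and plain SGD with optional momentum. Batches are arrays (H, W, C, N).
# Only what the frame classifier needs: 3x3 kernels, stride 1, zero-padded
# "same" convolution.

convForward3 <- function(x, W, b) {
  # x: (H, Wd, C, N); W: (F x 9C); b: length F; same padding, stride 1
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  F_ <- nrow(W)
  xcol <- cppIm2col3(as.vector(x), H, Wd, C, N)
  outMat <- W %*% xcol + b               # F x (H*Wd*N)
  out <- cppConvOut(outMat, H, Wd, F_, N)
  list(out = out, xcol = xcol)
}

convBackward3 <- function(dOut, x, W, xcol, needInputGrad = TRUE) {
  d <- dim(dOut); H <- d[1]; Wd <- d[2]; F_ <- d[3]; N <- d[4]
  C <- dim(x)[3]
  dOutMat <- cppChannelsFirst(as.vector(dOut), H, Wd, F_, N)
  dW <- tcrossprod(dOutMat, xcol)
  db <- rowSums(dOutMat)
  dX <- NULL
  if (needInputGrad) {
    # gradient w.r.t. input = same-padded conv of dOut with flipped kernels,
    # input/output channels swapped
    Warr <- array(t(W), dim = c(3, 3, C, F_))          # (i, j, c, f)
    Wback <- t(matrix(aperm(Warr[3:1, 3:1, , , drop = FALSE], c(1, 2, 4, 3)),
                      nrow = 9 * F_))                   # C x 9F
    dX <- convForward3(dOut, Wback, rep(0, C))$out
  }
  list(dX = dX, dW = dW, db = db)
}

poolForward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  Hp <- 2L * ceiling(H / 2); Wp <- 2L * ceiling(W / 2)
  if (Hp != H || Wp != W) {
    xp <- array(-Inf, dim = c(Hp, Wp, d[3], d[4]))
    xp[seq_len(H), seq_len(W), , ] <- x
  } else xp <- x
  o1 <- seq(1L, Hp, 2L); o2 <- seq(2L, Hp, 2L)
  p1 <- seq(1L, Wp, 2L); p2 <- seq(2L, Wp, 2L)
  a <- xp[o1, p1, , , drop = FALSE]; b <- xp[o2, p1, , , drop = FALSE]
  cc <- xp[o1, p2, , , drop = FALSE]; dd <- xp[o2, p2, , , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  m1 <- a >= out
  m2 <- !m1 & b >= out
  m3 <- !m1 & !m2 & cc >= out
  arg <- 4L - 3L * m1 - 2L * m2 - m3
  list(out = out, arg = arg, inDim = d)
}

poolBackward <- function(dOut, cache) {
  d <- cache$inDim
  Hp <- 2L * dim(dOut)[1]; Wp <- 2L * dim(dOut)[2]
  dxp <- array(0, dim = c(Hp, Wp, d[3], d[4]))
  o1 <- seq(1L, Hp, 2L); o2 <- seq(2L, Hp, 2L)
  p1 <- seq(1L, Wp, 2L); p2 <- seq(2L, Wp, 2L)
  put <- function(rows, cols, which) {
    g <- dOut * (cache$arg == which)
    dxp[rows, cols, , ] <<- dxp[rows, cols, , , drop = FALSE] + g
  }
  put(o1, p1, 1L); put(o2, p1, 2L); put(o1, p2, 3L); put(o2, p2, 4L)
  dxp[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE]
}

softmaxProbs <- function(logits) {
  # logits: K x N
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), `/`)
}

nnForward <- function(model, x, train = FALSE) {
  caches <- vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    lay <- model$layers[[li]]
    res <- switch(lay$type,
      conv = {
        r <- convForward3(x, lay$W, lay$b)
        list(out = r$out, cache = list(x = x, xcol = r$xcol))
      },
      relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
      pool = {
        r <- poolForward(x)
        list(out = r$out, cache = r)
      },
      dropout = {
        if (train) {
          keep <- 1 - lay$rate
          mask <- array(as.numeric(runif(length(x)) < keep) / keep, dim = dim(x))
          list(out = x * mask, cache = list(mask = mask))
        } else list(out = x, cache = NULL)
      },
      flatten = {
        N <- dim(x)[length(dim(x))]
        list(out = matrix(x, ncol = N), cache = list(dim = dim(x)))
      },
      dense = list(out = lay$W %*% x + lay$b, cache = list(x = x)),
      stop("unknown layer type ", lay$type)
    )
    x <- res$out
    caches[[li]] <- res$cache
  }
  list(out = x, caches = caches)
}

nnBackward <- function(model, caches, dOut) {
  grads <- vector("list", length(model$layers))
  for (li in rev(seq_along(model$layers))) {
    lay <- model$layers[[li]]
    cache <- caches[[li]]
    if (lay$type == "conv") {
      g <- convBackward3(dOut, cache$x, lay$W, cache$xcol,
                         needInputGrad = li > 1L)
      grads[[li]] <- list(dW = g$dW, db = g$db)
      dOut <- g$dX
    } else if (lay$type == "relu") {
      dOut <- dOut * cache$mask
    } else if (lay$type == "pool") {
      dOut <- poolBackward(dOut, cache)
    } else if (lay$type == "dropout") {
      if (!is.null(cache)) dOut <- dOut * cache$mask
    } else if (lay$type == "flatten") {
      dOut <- array(dOut, dim = cache$dim)
    } else if (lay$type == "dense") {
      grads[[li]] <- list(dW = dOut %*% t(cache$x), db = rowSums(dOut))
      dOut <- t(lay$W) %*% dOut
    }
  }
  grads
}

nnLoss <- function(logits, yIdx) {
  # logits: K x N, yIdx: integer class per column
  p <- softmaxProbs(logits)
  N <- ncol(logits)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(yIdx, seq_len(N))] + eps))
  dLogits <- p
  dLogits[cbind(yIdx, seq_len(N))] <- dLogits[cbind(yIdx, seq_len(N))] - 1
  list(loss = loss, dLogits = dLogits / N)
}

lsuvInit <- function(model, x, tol = 0.05, maxIter = 4) {
  # layer-sequential unit-variance init: rescale each conv/dense layer so
  # its output has unit sd on a probe batch; keeps signal propagation
  # healthy through depth regardless of input scale
  for (li in seq_along(model$layers)) {
    lay <- model$layers[[li]]
    if (!lay$type %in% c("conv", "dense")) next
    for (iter in seq_len(maxIter)) {
      sub <- structure(list(layers = model$layers[seq_len(li)]),
                       class = "cnnClassifier")
      s <- sd(nnForward(sub, x, train = FALSE)$out)
      if (!is.finite(s) || s == 0) break
      if (abs(s - 1) < tol) break
      model$layers[[li]]$W <- model$layers[[li]]$W / s
      model$layers[[li]]$vW <- model$layers[[li]]$W * 0
    }
  }
  model
}

nnUpdate <- function(model, grads, lr, momentum = 0, gradClip = Inf) {
  if (is.finite(gradClip)) {
    gnorm2 <- 0
    for (g in grads) if (!is.null(g)) gnorm2 <- gnorm2 + sum(g$dW^2) + sum(g$db^2)
    scale <- min(1, gradClip / sqrt(gnorm2))
    if (scale < 1)
      grads <- lapply(grads, function(g) {
        if (is.null(g)) return(NULL)
        list(dW = g$dW * scale, db = g$db * scale)
      })
  }
  for (li in seq_along(model$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    lay <- model$layers[[li]]
    if (momentum > 0) {
      lay$vW <- momentum * lay$vW - lr * g$dW
      lay$vb <- momentum * lay$vb - lr * g$db
      lay$W <- lay$W + lay$vW
      lay$b <- lay$b + lay$vb
    } else {
      lay$W <- lay$W - lr * g$dW
      lay$b <- lay$b - lr * g$db
    }
    model$layers[[li]] <- lay
  }
  model
}
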